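#' CRY-deficient parameter set
#'
#' Models CRY deficiency (e.g. Cry-null mutants) by reducing the CRY
#' production rate `r5` by `knockdown_fraction` (default 95%, i.e.
#' `r5 -> 0.05 * r5`). Under 12:12 light-dark this yields nearly diurnal,
#' elevated PER oscillations; in constant darkness the rhythm collapses to
#' a near-constant level.
#'
#' @param params a [clock_params()] object.
#' @param knockdown_fraction fraction of CRY production removed, in
#'   `[0, 1]`; 0 is the identity.
#' @return A `clock_params` object with the reduced `r5`.
#' @examples
#' cry_deficiency(clock_params())$r5 # 0.25
#' @export
cry_deficiency <- function(params = clock_params(),
                           knockdown_fraction = 0.95) {
  stopifnot(inherits(params, "clock_params"))
  if (length(knockdown_fraction) != 1 || is.na(knockdown_fraction) ||
    knockdown_fraction < 0 || knockdown_fraction > 1) {
    stop("knockdown_fraction must lie in [0, 1]", call. = FALSE)
  }
  params$r5 <- (1 - knockdown_fraction) * params$r5
  validate_clock_params(params)
}

#' REV-ERB peak of an entrained trajectory
#'
#' The reference value used to scale agonist doses: the maximum of REV over
#' the final entrained 24-hr cycle.
#'
#' @param entrained a `clock_trajectory`.
#' @return REV peak concentration (nM).
#' @export
rev_peak_reference <- function(entrained) {
  stopifnot(inherits(entrained, "clock_trajectory"))
  w <- final_cycle_window(entrained)
  max(entrained$state[w, "REV"])
}

#' Set the agonist amount of a state
#'
#' An injection is modelled as an instantaneous jump: at the injection
#' instant the agonist state `Ag` is set to the dose while every other
#' state is continuous.
#'
#' @param state named 16-state vector (a row of a trajectory).
#' @param dose agonist amount (nM), >= 0.
#' @return 17-component state with `Ag = dose`.
#' @export
inject_agonist <- function(state, dose) {
  if (length(dose) != 1 || is.na(dose) || dose < 0) {
    stop("dose must be a single nonnegative number", call. = FALSE)
  }
  state <- check_state(state[clock_state_names()])
  c(state, Ag = as.numeric(dose))
}

#' REV-ERB agonist injection experiment
#'
#' Reproduces the agonist protocol: entrain a control run under 12:12
#' light-dark, inject a single agonist dose at a chosen Zeitgeber time (by
#' default twice the entrained REV-ERB peak, an intentionally exaggerated
#' dose), and integrate the treated and control systems side by side under
#' the continuing light schedule. The agonist decays with half-life
#' `t_half` and acts as an additional REV-ERB-like repressor in the Bmal1
#' equation only.
#'
#' @param params a [clock_params()] object.
#' @param schedule a [light_schedule()]; the phase of the continuing run is
#'   anchored so `t %% 24` remains ZT.
#' @param injection_ZT Zeitgeber time of the injection, in `[0, 24)`.
#' @param dose_multiplier dose as a multiple of the entrained REV-ERB peak
#'   (ignored when `dose` is given).
#' @param dose absolute dose (nM), overriding `dose_multiplier`.
#' @param post_days days to integrate after the injection (>= 7 to permit
#'   re-entrainment analysis).
#' @param entrained optionally a pre-computed control entrainment from
#'   [entrain_clock()] (with matching `params` and `schedule`), to avoid
#'   repeating the burn-in.
#' @param dt output grid spacing (hr).
#' @param agonist_affects_da see [full_rhs()].
#' @param ... further arguments to [entrain_clock()].
#' @return An `agonist_experiment`: list with `treated` and `control`
#'   trajectories (common time grid starting at the injection), `dose`,
#'   `injection_ZT` and `rev_peak`.
#' @examples
#' \donttest{
#' ent <- entrain_clock()
#' exp0 <- agonist_experiment(entrained = ent, injection_ZT = 0)
#' phase_shift(exp0$treated, exp0$control, "P_N")
#' }
#' @export
agonist_experiment <- function(params = clock_params(),
                               schedule = light_schedule("LD"),
                               injection_ZT = 0, dose_multiplier = 2,
                               dose = NULL, post_days = 8,
                               entrained = NULL, dt = 0.05,
                               agonist_affects_da = FALSE, ...) {
  if (injection_ZT < 0 || injection_ZT >= 24) {
    stop("injection_ZT must lie in [0, 24)", call. = FALSE)
  }
  if (is.null(entrained)) {
    entrained <- entrain_clock(params, schedule, dt = dt, ...)
  }
  params <- entrained$params
  rev_peak <- rev_peak_reference(entrained)
  if (is.null(dose)) dose <- dose_multiplier * rev_peak
  if (dose < 0) stop("dose must be >= 0", call. = FALSE)

  # injection instant: last grid time with t mod 24 == injection_ZT
  zt <- entrained$time %% 24
  hit <- which(abs(zt - injection_ZT) < dt / 2)
  if (!length(hit)) {
    stop("injection_ZT does not fall on the trajectory grid", call. = FALSE)
  }
  i0 <- hit[length(hit)]
  t0 <- entrained$time[i0]
  y0 <- entrained$state[i0, ]
  span <- c(t0, t0 + 24 * post_days)

  control <- simulate_clock(params, schedule,
    init = y0, t_span = span,
    dt = dt, rtol = entrained$solver$rtol, atol = entrained$solver$atol,
    method = entrained$solver$method
  )
  treated <- simulate_clock(params, schedule,
    init = inject_agonist(y0, dose), t_span = span, dt = dt,
    rtol = entrained$solver$rtol, atol = entrained$solver$atol,
    method = entrained$solver$method,
    agonist_affects_da = agonist_affects_da
  )
  structure(
    list(
      treated = treated, control = control, dose = dose,
      injection_ZT = injection_ZT, injection_time = t0,
      rev_peak = rev_peak
    ),
    class = "agonist_experiment"
  )
}

#' @export
print.agonist_experiment <- function(x, ...) {
  cat(sprintf(
    "<agonist_experiment> injection at ZT%.2f, dose %.4g nM (%.3g x REV peak)\n",
    x$injection_ZT, x$dose, x$dose / x$rev_peak
  ))
  cat(sprintf(
    "post-injection span: %.0f hr\n",
    diff(range(x$control$time))
  ))
  invisible(x)
}
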