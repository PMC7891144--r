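new_trajectory <- function(time, state, params, schedule, solver,
                           perturbations = list(), burn_in_hours = 0,
                           extra = list()) {
  structure(
    c(
      list(
        time = time, state = state, params = params, schedule = schedule,
        solver = solver, perturbations = perturbations,
        burn_in_hours = burn_in_hours
      ),
      extra
    ),
    class = "clock_trajectory"
  )
}

#' Integrate the model
#'
#' Runs the full ODE system with a stiff-capable variable-step solver
#' (deSolve's `lsoda` by default) and returns a dense trajectory. The
#' output grid spacing defaults to 0.05 hr, fine enough for the rhythm
#' analysis utilities. Integration is deterministic: identical inputs give
#' identical trajectories.
#'
#' @param params a [clock_params()] object.
#' @param schedule a [light_schedule()].
#' @param init named initial state ([default_state()]); append an `Ag`
#'   component (17th state) to simulate an agonist run.
#' @param t_span numeric length-2, start and end time (hr). Simulation time
#'   is Zeitgeber-anchored (`t %% 24` = ZT, lights-on at ZT0).
#' @param dt output grid spacing (hr).
#' @param rtol,atol relative/absolute solver tolerance.
#' @param method deSolve integration method.
#' @param agonist_affects_da see [full_rhs()].
#' @return A `clock_trajectory`: list with `time` (hr), `state` (matrix,
#'   one column per state variable), and the parameters, schedule and
#'   solver settings needed to reproduce the run.
#' @examples
#' tr <- simulate_clock(t_span = c(0, 24))
#' tail(as.data.frame(tr))[, 1:4]
#' @export
simulate_clock <- function(params = clock_params(),
                           schedule = light_schedule("LD"),
                           init = default_state(),
                           t_span = c(0, 240), dt = 0.05,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda",
                           agonist_affects_da = FALSE) {
  stopifnot(inherits(params, "clock_params"))
  agonist <- "Ag" %in% names(init)
  init <- check_state(init, agonist = agonist)
  if (length(t_span) != 2 || any(!is.finite(t_span)) ||
    t_span[2] < t_span[1]) {
    stop("t_span must be finite with t_span[2] >= t_span[1]", call. = FALSE)
  }
  solver <- list(method = method, rtol = rtol, atol = atol, dt = dt)
  if (t_span[2] == t_span[1]) {
    state <- matrix(init, nrow = 1, dimnames = list(NULL, names(init)))
    return(new_trajectory(t_span[1], state, params, schedule, solver))
  }
  times <- seq(t_span[1], t_span[2], by = dt)
  if (times[length(times)] < t_span[2]) times <- c(times, t_span[2])
  out <- integrate_block(
    init, times, params, schedule, solver,
    agonist = agonist, agonist_affects_da = agonist_affects_da
  )
  new_trajectory(out$time, out$state, params, schedule, solver)
}

# one deSolve call + sanity checks on the result
integrate_block <- function(init, times, params, schedule, solver,
                            agonist = FALSE, agonist_affects_da = FALSE) {
  f <- make_derivs(params, light_function(schedule),
    agonist = agonist, agonist_affects_da = agonist_affects_da
  )
  out <- try(
    deSolve::ode(
      y = unname(init), times = times, func = f, parms = NULL,
      method = solver$method, rtol = solver$rtol, atol = solver$atol
    ),
    silent = TRUE
  )
  if (inherits(out, "try-error")) {
    stop("solver failure: ", attr(out, "condition")$message, call. = FALSE)
  }
  state <- unclass(out)[, -1, drop = FALSE]
  colnames(state) <- names(init)
  tt <- unclass(out)[, 1]
  bad <- which(!stats::complete.cases(state) |
    apply(state, 1, function(r) any(!is.finite(r))))
  if (length(bad)) {
    stop(sprintf(
      "integration produced non-finite state at t = %.4f hr",
      tt[bad[1]]
    ), call. = FALSE)
  }
  neg <- which(apply(state, 1, min) < -1e-6)
  if (length(neg)) {
    stop(sprintf(
      "integration produced negative state at t = %.4f hr", tt[neg[1]]
    ), call. = FALSE)
  }
  if (length(tt) < length(times)) {
    stop(sprintf(
      "solver stopped early; last successful time t = %.4f hr",
      tt[length(tt)]
    ), call. = FALSE)
  }
  list(time = tt, state = state)
}

#' Entrain the model to a light schedule
#'
#' Integrates from the default start until the solution is periodic with
#' the 24-hour forcing, then returns the final cycles. Convergence is
#' measured on all 16 variables as the sup-norm difference between
#' consecutive 24-hour cycles, relative to each variable's peak on the
#' current cycle; all variables must fall below `cycle_tol`. The default
#' burn-in of 40 days is dictated by the slowest state: MAO turns over at
#' `d_m = 0.016`/hr (a ~60 hr time constant), so its transient spans
#' several weeks.
#'
#' @param params,schedule,init,dt,rtol,atol,method as [simulate_clock()].
#' @param burn_in_days minimum days to integrate before returning (>= 1).
#' @param max_days give up (with the residual history in the error) if the
#'   cycle residual has not fallen below `cycle_tol` by this day.
#' @param cycle_tol convergence threshold for the relative cycle residual.
#' @param keep_cycles number of final 24-hr cycles to return.
#' @return A `clock_trajectory` covering the last `keep_cycles` cycles
#'   (time stays absolute, so `t %% 24` is still ZT), with extra fields
#'   `residual_history`, `achieved_residual` and `days_run`.
#' @examples
#' \donttest{
#' ent <- entrain_clock()
#' rhythm_summary(ent)
#' }
#' @export
entrain_clock <- function(params = clock_params(),
                          schedule = light_schedule("LD"),
                          burn_in_days = 40, max_days = 90,
                          cycle_tol = 1e-4, keep_cycles = 3,
                          init = default_state(), dt = 0.05,
                          rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(burn_in_days >= 1, max_days >= burn_in_days, keep_cycles >= 1)
  solver <- list(method = method, rtol = rtol, atol = atol, dt = dt)
  day_grid <- seq(0, 24, by = dt)
  n_day <- length(day_grid)

  prev_cycle <- NULL
  cycles <- vector("list", max_days)
  residuals <- rep(NA_real_, max_days)
  y <- check_state(init)
  for (day in seq_len(max_days)) {
    out <- integrate_block(
      y, (day - 1) * 24 + day_grid, params, schedule, solver
    )
    cycles[[day]] <- out
    y <- out$state[n_day, ]
    if (!is.null(prev_cycle)) {
      peaks <- apply(out$state, 2, function(x) max(abs(x)))
      peaks[peaks == 0] <- 1
      residuals[day] <- max(
        apply(abs(out$state - prev_cycle), 2, max) / peaks
      )
      if (day >= burn_in_days && residuals[day] < cycle_tol) break
    }
    prev_cycle <- out$state
  }
  days_run <- day
  if (is.na(residuals[days_run]) || residuals[days_run] >= cycle_tol) {
    stop(sprintf(
      paste0(
        "entrainment did not converge within %d days ",
        "(last residual %.3g, tolerance %.3g); residual history: %s"
      ),
      max_days, residuals[days_run], cycle_tol,
      paste(signif(residuals[seq_len(days_run)], 3), collapse = ", ")
    ), call. = FALSE)
  }

  keep <- seq(max(1, days_run - keep_cycles + 1), days_run)
  time <- c()
  state <- NULL
  for (i in seq_along(keep)) {
    d <- cycles[[keep[i]]]
    sel <- if (i == 1) seq_len(n_day) else 2:n_day # drop duplicated joint
    time <- c(time, d$time[sel])
    state <- rbind(state, d$state[sel, , drop = FALSE])
  }
  new_trajectory(
    time, state, params, schedule, solver,
    burn_in_hours = 24 * (days_run - keep_cycles),
    extra = list(
      residual_history = residuals[seq_len(days_run)],
      achieved_residual = residuals[days_run],
      days_run = days_run
    )
  )
}

#' Continue an entrained run in constant darkness
#'
#' Takes the final state of a light-entrained trajectory and continues the
#' integration with a constant light multiplier (free-running conditions).
#' Absolute time continues from the entrained run, so nominal ZT labels
#' remain comparable with the preceding light-dark cycles.
#'
#' @param entrained a `clock_trajectory` from [entrain_clock()].
#' @param days length of the constant-darkness run.
#' @param dd_level constant light multiplier; defaults to the entrained
#'   schedule's `dd_level` (1, the sinusoid's mean).
#' @param dt output grid spacing (hr).
#' @return A `clock_trajectory` under the DD schedule.
#' @export
run_constant_darkness <- function(entrained, days = 12, dd_level = NULL,
                                  dt = 0.05) {
  stopifnot(inherits(entrained, "clock_trajectory"))
  if (is.null(dd_level)) dd_level <- entrained$schedule$dd_level
  dd <- light_schedule("DD", dd_level = dd_level)
  t0 <- entrained$time[length(entrained$time)]
  y0 <- entrained$state[nrow(entrained$state), ]
  simulate_clock(
    params = entrained$params, schedule = dd, init = y0,
    t_span = c(t0, t0 + 24 * days), dt = dt,
    rtol = entrained$solver$rtol, atol = entrained$solver$atol,
    method = entrained$solver$method
  )
}

#' Restrict a trajectory to a time window
#'
#' @param trajectory a `clock_trajectory`.
#' @param t_min,t_max window bounds (hr), inclusive.
#' @return The windowed `clock_trajectory`.
#' @export
window_trajectory <- function(trajectory, t_min = -Inf, t_max = Inf) {
  stopifnot(inherits(trajectory, "clock_trajectory"))
  keep <- trajectory$time >= t_min & trajectory$time <= t_max
  if (!any(keep)) stop("empty time window", call. = FALSE)
  trajectory$time <- trajectory$time[keep]
  trajectory$state <- trajectory$state[keep, , drop = FALSE]
  trajectory
}

#' @export
print.clock_trajectory <- function(x, ...) {
  tr <- range(x$time)
  cat(sprintf(
    "<clock_trajectory> %d states, t = %.2f..%.2f hr (%d points, dt = %g)\n",
    ncol(x$state), tr[1], tr[2], length(x$time), x$solver$dt
  ))
  print(x$schedule)
  if (!is.null(x$achieved_residual)) {
    cat(sprintf(
      "entrained: %d days run, cycle residual %.3g\n",
      x$days_run, x$achieved_residual
    ))
  }
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  data.frame(time_hr = x$time, x$state, check.names = FALSE)
}

#' Long-format view of a trajectory
#'
#' @param trajectory a `clock_trajectory`.
#' @return Data frame with columns `time_hr`, `variable`, `value_nM`.
#' @export
tidy_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "clock_trajectory"))
  vars <- colnames(trajectory$state)
  data.frame(
    time_hr = rep(trajectory$time, times = length(vars)),
    variable = rep(vars, each = length(trajectory$time)),
    value_nM = as.vector(trajectory$state)
  )
}
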