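#' Model parameters for the circadian-dopamine network
#'
#' Constructs the full named parameter set of the model: the core
#' BMAL1-CLOCK/PER/CRY oscillator, the REV-ERB/ROR secondary feedback loop,
#' the downstream dopaminergic elements (TH, MAO, DRD3), and the agonist
#' half-life. All concentrations are in nanomolar (nM) and all first-order
#' rates in per hour (1/hr); production rates are nM/hr. Defaults are the
#' published reference values of the model and reproduce its entrained
#' behaviour without modification.
#'
#' Parameter groups:
#' \describe{
#'   \item{core clock}{`K_d` (nM, BMAL1-CLOCK / nuclear PER-CRY dissociation
#'     constant), `rho_c`, `k_c` (1/nM), `n_c` (Hill-type exponent of the
#'     nuclear-CRY repression function), `r1`--`r6`, `r2`--`r4` being the
#'     PER phosphorylation chain, `m_c`, `d4`--`d7`, `tau_c`, `tau_n`, `m`,
#'     `d_p`, `d_c`, `beta_bc`, `d_bc`, and the light modulation amplitude
#'     `xi` (dimensionless).}
#'   \item{secondary loop}{`n`, `kappa_rev`, `kappa` (BMAL1-CLOCK saturation
#'     of REV-ERB and ROR production), `rho_s`, `k_s`, `epsilon_s` (nM;
#'     exactly 0 in the reference set, the tight-binding limit), `n_s`,
#'     `alpha_s`, `kappa_s`, `r_rev`, `d_rev`, `b_ror`, `r_ror`, `d_ror`,
#'     `beta`, `d_s`.}
#'   \item{DA elements}{`rho_th`, `k_th`, `epsilon_th`, `n_th`, `alpha_th`,
#'     `kappa_th`, `b_th`, `d_th` (TH), `r_m`, `d_m` (MAO; note the slow MAO
#'     turnover, d_m = 0.016/hr), `rho_dr`, `k_dr`, `epsilon_dr`, `n_dr`,
#'     `alpha_dr`, `kappa_dr`, `b_dr`, `d_dr` (DRD3).}
#'   \item{agonist}{`t_half` (hr), the exponential-decay half-life of the
#'     REV-ERB agonist; 4.8 hr so that an injected dose undergoes five
#'     half-lives in 24 hours.}
#' }
#'
#' @param ... named parameter overrides, e.g. `clock_params(r5 = 0.25)`.
#'   Unknown names are an error (the message lists the valid names).
#' @return An object of class `clock_params`: a named list of numeric
#'   scalars.
#' @examples
#' p <- clock_params()
#' p$r5
#' cry <- clock_params(r5 = 0.05 * clock_params()$r5)
#' @seealso [cry_deficiency()], [da_coupling_overrides()]
#' @export
clock_params <- function(...) {
  p <- default_clock_params()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(overrides), names(p))
    if (length(bad)) {
      stop(
        "unknown parameter name(s): ", paste(bad, collapse = ", "),
        "\nvalid names are: ", paste(names(p), collapse = ", "),
        call. = FALSE
      )
    }
    p[names(overrides)] <- overrides
  }
  validate_clock_params(p)
}

default_clock_params <- function() {
  list(
    # core circadian clock
    K_d = 0.02, rho_c = 3, k_c = 0.5, n_c = 3,
    r1 = 5, r2 = 0.45, r3 = 0.45, r4 = 0.45,
    m_c = 0.5, d4 = 0.6, tau_c = 0.5,
    r5 = 5, d5 = 0.1, d6 = 0.12, r6 = 0.75, d7 = 0.2,
    tau_n = 0.1, m = 0.5, d_p = 0.25, d_c = 0.2,
    beta_bc = 0.1, d_bc = 0.1, xi = 2 / 3,
    # secondary loop
    n = 2, kappa_rev = 0.2, kappa = 1.5,
    rho_s = 1, k_s = 0.5, epsilon_s = 0, n_s = 5.3,
    alpha_s = 3.7, kappa_s = 1,
    r_rev = 1.5, d_rev = 0.5, b_ror = 0.1, r_ror = 1.8, d_ror = 0.25,
    beta = 0.9, d_s = 3,
    # DA elements
    rho_th = 1, k_th = 10, epsilon_th = 0.4, n_th = 1,
    alpha_th = 1.23, kappa_th = 1, b_th = 0.85, d_th = 5.6,
    r_m = 3, d_m = 0.016,
    rho_dr = 1, k_dr = 10, epsilon_dr = 0.4, n_dr = 1,
    alpha_dr = 0.53, kappa_dr = 10, b_dr = 0.3, d_dr = 3,
    # REV-ERB agonist
    t_half = 4.8
  )
}

hill_exponents <- c("n", "n_c", "n_s", "n_th", "n_dr")

validate_clock_params <- function(p) {
  vals <- unlist(p, use.names = TRUE)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("all parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop(
      "negative parameter value(s): ",
      paste(names(vals)[vals < 0], collapse = ", "),
      call. = FALSE
    )
  }
  if (any(vals[hill_exponents] <= 0)) {
    stop("Hill exponents (", paste(hill_exponents, collapse = ", "),
      ") must be > 0",
      call. = FALSE
    )
  }
  if (p$t_half <= 0) stop("t_half must be > 0", call. = FALSE)
  structure(lapply(p, as.numeric), class = "clock_params")
}

#' @export
print.clock_params <- function(x, ...) {
  cat("<clock_params> ", length(x), " model parameters (nM, 1/hr)\n",
    sep = ""
  )
  v <- unlist(x)
  def <- unlist(default_clock_params())
  changed <- names(v)[v != def[names(v)]]
  if (length(changed)) {
    cat("non-default:",
      paste(sprintf("%s=%g", changed, v[changed]), collapse = ", "), "\n"
    )
  } else {
    cat("all at reference values\n")
  }
  invisible(x)
}

#' State variables of the model
#'
#' The model tracks 16 concentrations (nM): the four cytosolic PER
#' phosphoforms `P1`--`P4`, cytosolic CRY `C`, the cytosolic PER-CRY dimer
#' `PC`, nuclear PER-CRY `PC_N`, nuclear PER `P_N`, nuclear CRY `C_N`, the
#' BMAL1-CLOCK activator `BC`, the secondary-loop species `REV` (REV-ERB),
#' `ROR` and `S` (Bmal1), and the dopaminergic elements `TH`, `MAO` and
#' `DRD3`. An optional 17th state `Ag` carries the amount of a REV-ERB
#' agonist. This ordering is fixed and used by every trajectory, writer and
#' reader in the package.
#'
#' @return Character vector of the 16 state names, in canonical order.
#' @export
clock_state_names <- function() {
  c(
    "P1", "P2", "P3", "P4", "C", "PC", "PC_N", "P_N", "C_N", "BC",
    "REV", "ROR", "S", "TH", "MAO", "DRD3"
  )
}

#' Default initial state
#'
#' The model's initial conditions are not constrained by data; the entrained
#' limit cycle is attracting, so any positive start reaches the same cycle
#' after the burn-in. The conventional start is every state at 0.1 nM.
#'
#' @param value concentration (nM) assigned to every state.
#' @param agonist if non-`NULL`, an initial agonist amount `Ag` (nM) appended
#'   as a 17th state.
#' @return Named numeric vector of length 16 (or 17 with `agonist`).
#' @export
default_state <- function(value = 0.1, agonist = NULL) {
  y <- stats::setNames(rep(value, 16), clock_state_names())
  if (!is.null(agonist)) {
    if (agonist < 0) stop("agonist amount must be >= 0", call. = FALSE)
    y <- c(y, Ag = as.numeric(agonist))
  }
  y
}

check_state <- function(state, agonist = FALSE) {
  want <- clock_state_names()
  if (agonist) want <- c(want, "Ag")
  if (length(state) != length(want)) {
    stop("state must have ", length(want), " components (",
      paste(want, collapse = ", "), ")",
      call. = FALSE
    )
  }
  if (is.null(names(state))) names(state) <- want
  if (!all(names(state) == want)) {
    stop("state names must be, in order: ", paste(want, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(state) || any(!is.finite(state))) {
    stop("state contains non-finite values", call. = FALSE)
  }
  if (any(state < 0)) stop("state must be nonnegative", call. = FALSE)
  state
}
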