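# Right-hand side of the coupled ODE system.
#
# State ordering (fixed): P1, P2, P3, P4, C, PC, PC_N, P_N, C_N, BC,
# REV, ROR, S, TH, MAO, DRD3 [, Ag]. The light multiplier scales only the
# P1 production term. In agonist runs the Bmal1 (S) repression/activation
# pair receives REV + Ag in place of REV; the REV equation itself and, by
# default, the TH/DRD3 equations are untouched.

# Factory: bakes parameters and the light function into a fast closure with
# the deSolve calling convention func(t, y, parms).
make_derivs <- function(params, light_fun, agonist = FALSE,
                        agonist_affects_da = FALSE) {
  K_d <- params$K_d; rho_c <- params$rho_c; k_c <- params$k_c
  n_c <- params$n_c
  r1 <- params$r1; r2 <- params$r2; r3 <- params$r3; r4 <- params$r4
  m_c <- params$m_c; d4 <- params$d4; tau_c <- params$tau_c
  r5 <- params$r5; d5 <- params$d5; d6 <- params$d6; r6 <- params$r6
  d7 <- params$d7; tau_n <- params$tau_n; m <- params$m
  d_p <- params$d_p; d_c <- params$d_c
  beta_bc <- params$beta_bc; d_bc <- params$d_bc
  n <- params$n; kap_rev_n <- params$kappa_rev^params$n
  kappa <- params$kappa
  rho_s <- params$rho_s; k_s <- params$k_s; eps_s <- params$epsilon_s
  n_s <- params$n_s; alpha_s <- params$alpha_s; kappa_s <- params$kappa_s
  r_rev <- params$r_rev; d_rev <- params$d_rev
  b_ror <- params$b_ror; r_ror <- params$r_ror; d_ror <- params$d_ror
  beta <- params$beta; d_s <- params$d_s
  rho_th <- params$rho_th; k_th <- params$k_th; eps_th <- params$epsilon_th
  n_th <- params$n_th; alpha_th <- params$alpha_th
  kappa_th <- params$kappa_th; b_th <- params$b_th; d_th <- params$d_th
  r_m <- params$r_m; d_m <- params$d_m
  rho_dr <- params$rho_dr; k_dr <- params$k_dr; eps_dr <- params$epsilon_dr
  n_dr <- params$n_dr; alpha_dr <- params$alpha_dr
  kappa_dr <- params$kappa_dr; b_dr <- params$b_dr; d_dr <- params$d_dr
  decay_ag <- log(2) / params$t_half

  # scalar free fraction, clamped against the integrator's tiny negative
  # excursions; analytic limits at P = 0 and D = 0
  ff <- function(P, I, D) {
    if (P < 0) P <- 0
    if (I < 0) I <- 0
    if (P == 0) {
      if (D + I == 0) return(1)
      return(D / (D + I))
    }
    b <- P - I - D
    s <- sqrt(b * b + 4 * D * P)
    if (b >= 0) (b + s) / (2 * P) else if (D == 0) 0 else 2 * D / (s - b)
  }

  function(t, y, parms) {
    P1 <- y[1L]; P2 <- y[2L]; P3 <- y[3L]; P4 <- y[4L]; C <- y[5L]
    PC <- y[6L]; PCN <- y[7L]; PN <- y[8L]; CN <- y[9L]; BC <- y[10L]
    REV <- y[11L]; ROR <- y[12L]; S <- y[13L]; TH <- y[14L]
    MAO <- y[15L]; DRD3 <- y[16L]
    Ag <- if (agonist) max(y[17L], 0) else 0

    BC_fr <- ff(BC, PCN, K_d)
    FC <- rho_c / (1 + k_c * max(CN, 0))^n_c
    l <- light_fun(t)
    prod_core <- FC * BC_fr

    dP1 <- r1 * l * prod_core - r2 * P1
    dP2 <- r2 * P1 - r3 * P2
    dP3 <- r3 * P2 - r4 * P3
    dP4 <- r4 * P3 + m_c * PC - d4 * P4 - tau_c * P4 * C
    dC <- r5 * prod_core + m_c * PC - d5 * C - tau_c * P4 * C
    dPC <- tau_c * P4 * C - d6 * PC - m_c * PC
    dPCN <- r6 * PC - d7 * PCN + tau_n * PN * CN - m * PCN
    dPN <- m * PCN - tau_n * PN * CN - d_p * PN
    dCN <- m * PCN - tau_n * PN * CN - d_c * CN
    dBC <- beta_bc * S - d_bc * BC

    bn <- BC_fr^n
    dREV <- r_rev * (bn / (kap_rev_n + bn)) * FC - d_rev * REV
    dROR <- b_ror + r_ror * (BC_fr / (kappa + BC_fr)) * FC - d_ror * ROR

    rep_s <- REV + Ag
    f_s <- ff(S, rep_s, eps_s)
    dS <- beta + rho_s / (1 + k_s * (1 - f_s))^n_s +
      alpha_s * f_s * ROR / (ROR + kappa_s) - d_s * S

    rep_da <- if (agonist_affects_da) REV + Ag else REV
    f_th <- ff(TH, rep_da, eps_th)
    dTH <- b_th + rho_th / (1 + k_th * (1 - f_th))^n_th +
      alpha_th * f_th * ROR / (ROR + kappa_th) - d_th * TH
    dMAO <- r_m * prod_core - d_m * MAO
    f_dr <- ff(DRD3, rep_da, eps_dr)
    dDRD3 <- b_dr + rho_dr / (1 + k_dr * (1 - f_dr))^n_dr +
      alpha_dr * f_dr * ROR / (ROR + kappa_dr) - d_dr * DRD3

    d <- c(
      dP1, dP2, dP3, dP4, dC, dPC, dPCN, dPN, dCN, dBC,
      dREV, dROR, dS, dTH, dMAO, dDRD3
    )
    if (agonist) d <- c(d, -decay_ag * Ag)
    list(d)
  }
}

#' Full derivative vector of the model
#'
#' Assembles the complete right-hand side (nM/hr): the core clock block
#' (P1..BC), the REV-ERB/ROR/Bmal1 secondary loop, the dopaminergic block
#' (TH, MAO, DRD3) and, when `agonist_on`, the exponentially decaying
#' agonist state `Ag`. In agonist runs the Bmal1 equation's repression and
#' activation terms act on `REV + Ag` instead of `REV`; the REV-ERB
#' equation and (by default) the TH and DRD3 equations are not modified.
#' At `Ag = 0` the agonist system reduces exactly to the plain system.
#'
#' @param state named nonnegative state vector in canonical order (see
#'   [clock_state_names()]); 17 components including `Ag` when
#'   `agonist_on`.
#' @param t time (hr).
#' @param params a [clock_params()] object.
#' @param light_fun function of time returning the light multiplier (e.g.
#'   from a [light_schedule()]); scales only the P1 production term.
#' @param agonist_on include the agonist state and its action on Bmal1.
#' @param agonist_affects_da optional extension (off by default, and not
#'   part of the reference model): let the agonist also act as repressor in
#'   the TH and DRD3 equations.
#' @return Named derivative vector (nM/hr), same length as `state`.
#' @examples
#' d <- full_rhs(default_state(), 0, clock_params(), function(t) 1)
#' @export
full_rhs <- function(state, t, params = clock_params(),
                     light_fun = function(t) 1,
                     agonist_on = FALSE, agonist_affects_da = FALSE) {
  state <- check_state(state, agonist = agonist_on)
  f <- make_derivs(params, light_fun,
    agonist = agonist_on,
    agonist_affects_da = agonist_affects_da
  )
  d <- f(t, unname(state), NULL)[[1]]
  stats::setNames(d, names(state))
}

#' @describeIn full_rhs Core clock block only (P1, P2, P3, P4, C, PC, PC_N,
#'   P_N, C_N, BC); the remaining states enter only through `S` in the BC
#'   equation.
#' @export
core_rhs <- function(state, t, params = clock_params(),
                     light_fun = function(t) 1) {
  full_rhs(state, t, params, light_fun)[1:10]
}

#' @describeIn full_rhs Secondary loop block (REV, ROR, S).
#' @export
loop_rhs <- function(state, params = clock_params()) {
  full_rhs(state, 0, params, function(t) 1)[11:13]
}

#' @describeIn full_rhs Dopaminergic block (TH, MAO, DRD3).
#' @export
da_rhs <- function(state, params = clock_params()) {
  full_rhs(state, 0, params, function(t) 1)[14:16]
}
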