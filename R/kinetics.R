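#' Free fraction of a sequestered protein
#'
#' Stoichiometric (protein-sequestration) repression: a protein of total
#' concentration `P` binds an inhibitor of total concentration `I` with
#' dissociation constant `D`; the fraction of `P` left unbound is the
#' positive root of the binding quadratic,
#' \deqn{f(P, I, D) = \frac{P - I - D + \sqrt{(P - I - D)^2 + 4 D P}}{2 P}.}
#'
#' The formula is evaluated in a rationalized form when `P - I - D < 0` to
#' avoid catastrophic cancellation, and the removable singularities are
#' filled with their analytic limits: at `P = 0` the free fraction is
#' `D / (D + I)` (1 when `I = D = 0`), and in the tight-binding limit
#' `D = 0` it is `max(0, 1 - I/P)`. The `D = 0` branch is exercised by the
#' reference parameter set, which uses a zero dissociation constant for the
#' REV-ERB/Bmal1 interaction.
#'
#' @param P total protein (nM), vectorized.
#' @param I total inhibitor (nM).
#' @param D dissociation constant (nM).
#' @return Free fraction in `[0, 1]`, recycled to the common length.
#' @examples
#' free_fraction(1, 0, 0.02) # no inhibitor: 1
#' free_fraction(2, 1, 0)    # tight binding: 0.5
#' @export
free_fraction <- function(P, I, D) {
  k <- max(length(P), length(I), length(D))
  P <- rep_len(as.numeric(P), k)
  I <- rep_len(as.numeric(I), k)
  D <- rep_len(as.numeric(D), k)
  if (any(P < 0) || any(I < 0) || any(D < 0)) {
    stop("free_fraction: P, I and D must be nonnegative", call. = FALSE)
  }
  out <- numeric(k)
  zero <- P == 0
  if (any(zero)) {
    tot <- D[zero] + I[zero]
    out[zero] <- ifelse(tot == 0, 1, D[zero] / tot)
  }
  if (any(!zero)) {
    p <- P[!zero]
    b <- p - I[!zero] - D[!zero]
    s <- sqrt(b * b + 4 * D[!zero] * p)
    f <- ifelse(
      b >= 0,
      (b + s) / (2 * p),
      # rationalized: (b + s) = 4 D P / (s - b), exact when D = 0
      ifelse(D[!zero] == 0, 0, 2 * D[!zero] / (s - b))
    )
    out[!zero] <- pmin(1, pmax(0, f))
  }
  out
}

#' Transcriptional repression by nuclear CRY
#'
#' Nuclear CRY represses BMAL1-CLOCK-driven transcription independently of
#' sequestration. The production multiplier is
#' \deqn{F(C_N) = \rho_c / (1 + k_c C_N)^{n_c},}
#' strictly decreasing in `C_N` with `F(0) = rho_c`.
#'
#' @param C_N nuclear CRY concentration (nM), vectorized.
#' @param params a [clock_params()] object (uses `rho_c`, `k_c`, `n_c`).
#' @return Positive multiplier, at most `rho_c`.
#' @export
cry_repression <- function(C_N, params = clock_params()) {
  if (any(C_N < 0)) stop("cry_repression: C_N must be >= 0", call. = FALSE)
  params$rho_c / (1 + params$k_c * C_N)^params$n_c
}

#' Saturating activation of REV-ERB and ROR production by BMAL1-CLOCK
#'
#' Free BMAL1-CLOCK drives REV-ERB production through a Hill term
#' `G1(x) = x^n / (kappa_rev^n + x^n)` (n = 2 in the reference set) and ROR
#' production through the Michaelis-Menten term `G2(x) = x / (kappa + x)`.
#' Both vanish at 0 and increase toward 1.
#'
#' @param BC_fr free BMAL1-CLOCK fraction in `[0, 1]`.
#' @param params a [clock_params()] object.
#' @return Saturation factor in `[0, 1)`.
#' @export
bc_saturation_rev <- function(BC_fr, params = clock_params()) {
  stopifnot(all(BC_fr >= 0), all(BC_fr <= 1))
  BC_fr^params$n / (params$kappa_rev^params$n + BC_fr^params$n)
}

#' @rdname bc_saturation_rev
#' @export
bc_saturation_ror <- function(BC_fr, params = clock_params()) {
  stopifnot(all(BC_fr >= 0), all(BC_fr <= 1))
  BC_fr / (params$kappa + BC_fr)
}

#' Competitive repression/activation of a RORE-controlled target
#'
#' REV-ERB and ROR compete at the ROR response element (RORE) of a target
#' gene's promoter. With `f = free_fraction(X, REV, eps)` the fraction of
#' target not bound by REV-ERB, the production of the target splits into a
#' repression term that falls as REV-ERB occupancy rises,
#' \deqn{R = \rho / (1 + k (1 - f))^{n},}
#' and an activation term carried by ROR on the free promoter,
#' \deqn{A = \alpha \, f \, ROR / (ROR + \kappa).}
#' One kernel serves the three structurally identical target pairs in the
#' model: Bmal1 (`S`), tyrosine hydroxylase (`TH`) and the D3 receptor
#' (`DRD3`), each with its own parameter subscripts.
#'
#' @param X target concentration (nM).
#' @param REV repressor concentration (nM); in agonist runs of the Bmal1
#'   equation this is `REV + Ag`.
#' @param ROR activator concentration (nM).
#' @param rho,k,eps,n_exp,alpha,kappa_half kinetic constants of the pair.
#' @return List with components `repression` and `activation` (nM/hr
#'   contributions), both nonnegative.
#' @examples
#' p <- clock_params()
#' # Bmal1 pair with no repressor and ROR at its half-saturation:
#' rep_act_pair(1, 0, 1, p$rho_s, p$k_s, p$epsilon_s, p$n_s, p$alpha_s, p$kappa_s)
#' @export
rep_act_pair <- function(X, REV, ROR, rho, k, eps, n_exp, alpha, kappa_half) {
  if (any(X < 0) || any(REV < 0) || any(ROR < 0)) {
    stop("rep_act_pair: concentrations must be nonnegative", call. = FALSE)
  }
  f <- free_fraction(X, REV, eps)
  list(
    repression = rho / (1 + k * (1 - f))^n_exp,
    activation = alpha * f * ROR / (ROR + kappa_half)
  )
}

#' Sinusoidal light input
#'
#' The 12:12 light-dark schedule is modelled as
#' \deqn{\ell(t) = \xi \sin(\pi t / 12) + 1,}
#' a 24-hour sinusoid with mean 1. Time is Zeitgeber-referenced: lights on
#' at ZT0, `l` maximal at ZT6, dark spanning ZT12-24. The multiplier scales
#' only the light-driven PER production term of the model.
#'
#' @param t time (hr), vectorized.
#' @param xi dimensionless modulation amplitude (default 2/3).
#' @return Light multiplier, positive for `xi < 1`.
#' @export
light_input <- function(t, xi = 2 / 3) {
  xi * sin(pi * t / 12) + 1
}

#' Exponential agonist decay
#'
#' A REV-ERB agonist dose decays exponentially with half-life `t_half`
#' (default 4.8 hr, i.e. five half-lives in 24 hours, after which a drug is
#' conventionally considered negligible):
#' `Ag(t) = Ag0 * 2^(-t / t_half)`.
#'
#' @param Ag0 initial amount (nM).
#' @param t time since the dose (hr), nonnegative.
#' @param t_half half-life (hr).
#' @return Remaining amount (nM).
#' @export
agonist_decay <- function(Ag0, t, t_half = 4.8) {
  if (any(Ag0 < 0)) stop("agonist_decay: Ag0 must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("agonist_decay: t must be >= 0", call. = FALSE)
  if (t_half <= 0) stop("agonist_decay: t_half must be > 0", call. = FALSE)
  Ag0 * 2^(-t / t_half)
}
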