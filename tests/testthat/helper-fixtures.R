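# Shared fixtures, memoized across test files within one run. All heavy
# simulations (40-day entrainments, multi-day perturbation runs) are
# computed once and reused.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

entrained_ld <- function() {
  fixture("entrained_ld", function() entrain_clock())
}

dd_run <- function() {
  # 30 days so the free-running cycle (period well below 24 hr) settles;
  # MAO's slow turnover dominates the transient
  fixture("dd_run", function() run_constant_darkness(entrained_ld(), days = 30))
}

cry_ld <- function() {
  fixture("cry_ld", function() entrain_clock(cry_deficiency(clock_params())))
}

cry_dd <- function() {
  fixture("cry_dd", function() run_constant_darkness(cry_ld(), days = 12))
}

agonist_zt0 <- function() {
  fixture("agonist_zt0", function() {
    agonist_experiment(entrained = entrained_ld(), injection_ZT = 0)
  })
}

agonist_zt9 <- function() {
  fixture("agonist_zt9", function() {
    agonist_experiment(entrained = entrained_ld(), injection_ZT = 9)
  })
}

# minimal trajectory object around synthetic signals, for metric oracles
make_traj <- function(time, signals) {
  state <- do.call(cbind, signals)
  colnames(state) <- names(signals)
  circadopa:::new_trajectory(
    time = time, state = state, params = clock_params(),
    schedule = light_schedule("DD"),
    solver = list(method = "none", rtol = NA, atol = NA, dt = diff(time[1:2]))
  )
}

# independent fixed-step classical Runge-Kutta integrator (oracle for the
# stiff solver); returns states at every `keep`-th step
rk4_integrate <- function(derivs, y0, t0, t1, dt, keep = 50L) {
  n_steps <- round((t1 - t0) / dt)
  out_t <- numeric(n_steps %/% keep + 1)
  out_y <- matrix(NA_real_, n_steps %/% keep + 1, length(y0))
  out_t[1] <- t0
  out_y[1, ] <- y0
  y <- y0
  t <- t0
  j <- 1L
  for (i in seq_len(n_steps)) {
    k1 <- derivs(t, y, NULL)[[1]]
    k2 <- derivs(t + dt / 2, y + dt / 2 * k1, NULL)[[1]]
    k3 <- derivs(t + dt / 2, y + dt / 2 * k2, NULL)[[1]]
    k4 <- derivs(t + dt, y + dt * k3, NULL)[[1]]
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t0 + i * dt
    if (i %% keep == 0L) {
      j <- j + 1L
      out_t[j] <- t
      out_y[j, ] <- y
    }
  }
  list(time = out_t[seq_len(j)], state = out_y[seq_len(j), , drop = FALSE])
}
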