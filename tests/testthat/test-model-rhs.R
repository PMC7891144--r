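zero_state <- function(...) {
  y <- stats::setNames(rep(0, 16), clock_state_names())
  ov <- c(...)
  y[names(ov)] <- ov
  y
}

test_that("core block reproduces hand-computed term balances", {
  p <- clock_params()
  # state with only the cytosolic PER-CRY dimer present: PC feeds back into
  # P4 at m_c and drains at d6 + m_c = 0.62/hr, and seeds PC_N at r6
  y <- zero_state(PC = 1)
  d <- core_rhs(y, 0, p, function(t) 1)
  expect_equal(unname(d["P4"]), p$m_c * 1) # +0.5
  expect_equal(unname(d["PC"]), -(p$d6 + p$m_c)) # -0.62
  expect_equal(unname(d["PC_N"]), p$r6) # +0.75
  expect_equal(unname(d["P1"]), p$r1 * p$rho_c) # BC_fr -> 1 at origin
  # phosphorylation chain is conservative pass-through
  y2 <- zero_state(P1 = 2, P2 = 3)
  d2 <- core_rhs(y2, 0, p, function(t) 0)
  expect_equal(unname(d2["P2"]), p$r2 * 2 - p$r3 * 3)
  expect_equal(unname(d2["P3"]), p$r3 * 3)
  # BC integrates Bmal1: dBC = beta_bc*S - d_bc*BC
  y3 <- zero_state(S = 4, BC = 1)
  expect_equal(
    unname(core_rhs(y3, 0, p)["BC"]), p$beta_bc * 4 - p$d_bc * 1
  )
})

test_that("secondary loop block matches its production/degradation terms", {
  p <- clock_params()
  # at the origin BC_fr = K_d/(K_d + 0) = 1, F(0) = rho_c
  d <- loop_rhs(zero_state(), p)
  expect_equal(
    unname(d["REV"]), p$r_rev * (1 / (p$kappa_rev^2 + 1)) * p$rho_c
  )
  expect_equal(
    unname(d["ROR"]), p$b_ror + p$r_ror * (1 / (p$kappa + 1)) * p$rho_c
  )
  # Bmal1 at the origin: basal + full repression-term value (f(0,0,0)=1)
  expect_equal(unname(d["S"]), p$beta + p$rho_s) # 1.9
  # a REV=0 trajectory keeps REV nonnegative: production is nonnegative
  expect_gte(unname(d["REV"]), 0)
  # ROR is bounded by its scalar comparison ODE
  ror_cap <- (p$b_ror + p$r_ror * p$rho_c) / p$d_ror
  tr <- simulate_clock(p, light_schedule("LD"), t_span = c(0, 240))
  expect_true(all(tr$state[, "ROR"] <= ror_cap))
})

test_that("dopaminergic block matches its production/degradation terms", {
  p <- clock_params()
  d <- da_rhs(zero_state(), p)
  expect_equal(unname(d["TH"]), p$b_th + p$rho_th) # 1.85
  expect_equal(unname(d["DRD3"]), p$b_dr + p$rho_dr) # 1.3
  # MAO is pure decay when BC is fully sequestered (BC_fr ~ 0)
  y <- zero_state(PC_N = 1e12, MAO = 2)
  expect_equal(unname(da_rhs(y, p)["MAO"]), -p$d_m * 2, tolerance = 1e-8)
})

test_that("full rhs is consistent with a central difference of the flow", {
  p <- clock_params()
  sch <- light_schedule("LD")
  # take a mid-transient state so every term is active
  tr <- simulate_clock(p, sch, t_span = c(0, 50))
  y <- tr$state[nrow(tr$state), ]
  h <- 1e-3
  fine <- simulate_clock(p, sch, init = y, t_span = c(50, 50 + 2 * h), dt = h)
  d <- full_rhs(
    fine$state[2, ], 50 + h, p, function(t) light_value(sch, t)
  )
  central <- (fine$state[3, ] - fine$state[1, ]) / (2 * h)
  expect_equal(d, central, tolerance = 1e-5)
})

test_that("agonist coupling enters only the Bmal1 equation", {
  p <- clock_params()
  set.seed(7)
  for (k in 1:100) {
    y <- stats::setNames(runif(16, 0, 3), clock_state_names())
    d_plain <- full_rhs(y, 5, p, function(t) 1)
    # Ag = 0 reduces exactly to the plain system
    d_ag0 <- full_rhs(c(y, Ag = 0), 5, p, function(t) 1, agonist_on = TRUE)
    expect_equal(d_ag0[1:16], d_plain)
    expect_equal(unname(d_ag0["Ag"]), 0)
    # Ag > 0: only dS and dAg may differ, and dS cannot increase when the
    # activator is scarce (repression falls, activation is capped)
    ag <- runif(1, 0.1, 5)
    d_ag <- full_rhs(c(y, Ag = ag), 5, p, function(t) 1, agonist_on = TRUE)
    expect_equal(d_ag[setdiff(clock_state_names(), "S")],
      d_plain[setdiff(clock_state_names(), "S")]
    )
    expect_equal(unname(d_ag["Ag"]), -log(2) / p$t_half * ag)
    y_small_ror <- y
    y_small_ror["ROR"] <- 0
    d1 <- full_rhs(c(y_small_ror, Ag = ag), 5, p, function(t) 1,
      agonist_on = TRUE
    )
    d0 <- full_rhs(c(y_small_ror, Ag = 0), 5, p, function(t) 1,
      agonist_on = TRUE
    )
    expect_lte(d1[["S"]], d0[["S"]] + 1e-12)
  }
})

test_that("optional extension lets the agonist repress TH and DRD3", {
  p <- clock_params()
  y <- c(zero_state(TH = 1, DRD3 = 1, ROR = 1, S = 1), Ag = 2)
  d_def <- full_rhs(y, 0, p, function(t) 1, agonist_on = TRUE)
  d_ext <- full_rhs(y, 0, p, function(t) 1,
    agonist_on = TRUE, agonist_affects_da = TRUE
  )
  expect_lt(d_ext[["TH"]], d_def[["TH"]])
  expect_lt(d_ext[["DRD3"]], d_def[["DRD3"]])
  expect_equal(d_ext[["S"]], d_def[["S"]]) # S already sees Ag by default
})

test_that("nonnegative orthant is forward-invariant from random starts", {
  set.seed(11)
  for (k in 1:10) {
    y0 <- stats::setNames(runif(16, 0, 5), clock_state_names())
    tr <- simulate_clock(
      init = y0, t_span = c(0, 48), dt = 0.1
    )
    expect_gte(min(tr$state), -10 * tr$solver$atol)
  }
})

test_that("system is autonomous under constant light", {
  p <- clock_params()
  dd <- light_schedule("DD")
  y0 <- default_state(0.5)
  a <- simulate_clock(p, dd, init = y0, t_span = c(0, 48))
  b <- simulate_clock(p, dd, init = y0, t_span = c(100, 148))
  expect_equal(a$state, b$state, tolerance = 1e-7)
})
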