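test_that("the mean-field derivative matches a hand evaluation", {
  spec <- model_spec(4)
  p <- rate_parameters(alpha = 0.2, beta = 0.1, beta2 = 0.05,
                       gamma1 = 0.3, gamma2 = 0.02)
  d <- ode_rhs(spec, p, c(400, 300, 300, 0), L = 0)
  # term-by-term: dN = -80 + 30 + 15; dP = 80 - 30 - 90; dNR = 90 - 15 - 6
  expect_equal(unname(d), c(-35, -40, 69, 6))

  # all-negative start: only the activation reaction has nonzero flow
  d0 <- ode_rhs(model_spec(3), rate_parameters(0.2, 0.1, 0.05, 0.3),
                c(1000, 0, 0, 0), L = 0.5)
  aL <- 0.2 * (1 + 10 * 0.5)
  expect_equal(unname(d0), c(-1000 * aL, 1000 * aL, 0, 0))
})

test_that("derivatives conserve total cell number for random states", {
  set.seed(4)
  for (ps in random_rates(20, n_states = 4, seed = 4)) {
    st <- runif(4, 0, 1000)
    d <- ode_rhs(model_spec(4), ps, st, L = runif(1))
    expect_equal(sum(d), 0, tolerance = 1e-12)
  }
})

test_that("a 3-state spec keeps the NRPS derivative identically zero", {
  p <- rate_parameters(0.2, 0.1, 0.05, 0.3)
  d <- ode_rhs(model_spec(3), p, c(100, 500, 400, 0), L = 1)
  expect_identical(unname(d[4]), 0)
})

test_that("symmetric two-state dynamics relax to half positive", {
  p <- rate_parameters(0.4, 0.4)
  tr <- simulate_ode(p, stimulation_protocol(0, 0), c(0, 24 * 50))
  expect_equal(tr$f_positive[2], 0.5, tolerance = 1e-6)
})

test_that("closed form solves the two-state equation under decaying LPS", {
  p <- rate_parameters(0.3, 0.6)
  grid <- seq(0, 48, length.out = 25)[-1]
  tr <- simulate_ode(p, condition_protocol("1000"), grid)
  cf <- closed_form_two_state(p, L0 = 1, t_h = grid)
  expect_lt(max(abs(tr$positive - cf)) / 1000, 1e-6)
  expect_equal(closed_form_two_state(p, 1, 0), 0)
})

test_that("the no-LPS limit of the closed form is the textbook relaxation", {
  p <- rate_parameters(0.25, 0.55)
  tt <- c(2, 8, 24, 72)
  expected <- 1000 * p$alpha / (p$alpha + p$beta) *
    (1 - exp(-(p$alpha + p$beta) * tt / 24))
  expect_equal(closed_form_two_state(p, L0 = 0, t_h = tt), expected,
               tolerance = 1e-8)
})

test_that("equilibrium positive count matches the rate ratio", {
  expect_equal(equilibrium_positive(rate_parameters(0.3, 0.3), 1000), 500)
  expect_equal(equilibrium_positive(rate_parameters(0.2, 0.1), 900), 600)
  expect_error(equilibrium_positive(rate_parameters(0, 0)), "degenerate")
  # ODE converges to the equilibrium within 0.1% by t = 20/(alpha+beta)
  for (ps in random_rates(5, n_states = 2, seed = 11)) {
    t_eq <- 20 / (ps$alpha + ps$beta) * 24
    tr <- simulate_ode(ps, stimulation_protocol(0, 0), c(0, t_eq))
    expect_equal(tr$positive[2], equilibrium_positive(ps, 1000),
                 tolerance = 1e-3)
  }
})

test_that("quasi-equilibrium reduces to equilibrium without LPS and in time", {
  p <- rate_parameters(0.3, 0.5)
  eq <- equilibrium_positive(p, 1000)
  expect_equal(quasi_equilibrium_positive(p, L0 = 0, t_h = 5), eq)
  expect_equal(quasi_equilibrium_positive(p, L0 = 1, t_h = 24 * 400), eq,
               tolerance = 1e-9)
})

test_that("fast switching tracks the quasi-equilibrium curve", {
  # switch 100x faster than the LPS decay, so P/N equilibrate at each L
  p <- rate_parameters(alpha = 25, beta = 25, delta = 0.5)
  grid <- seq(12, 96, by = 12)
  tr <- simulate_ode(p, condition_protocol("1000"), grid)
  pq <- quasi_equilibrium_positive(p, L0 = 1, t_h = grid)
  expect_equal(tr$positive, pq, tolerance = 5e-3)
})

test_that("the model hierarchy nests: 4-state(gamma2=0) = 3-state = 2-state", {
  grid <- seq(0, 48, by = 4)
  prot <- condition_protocol("1000/1000")
  for (ps in random_rates(5, n_states = 3, seed = 21)) {
    t4 <- simulate_ode(ps, prot, grid, spec = model_spec(4))
    t3 <- simulate_ode(ps, prot, grid, spec = model_spec(3))
    expect_equal(t4$positive, t3$positive, tolerance = 1e-8)
    expect_equal(t4$nrps, rep(0, length(grid)))
  }
  for (ps in random_rates(3, n_states = 2, seed = 22)) {
    t3 <- simulate_ode(ps, prot, grid, spec = model_spec(3))
    t2 <- simulate_ode(ps, prot, grid, spec = model_spec(2))
    expect_equal(t3$positive, t2$positive, tolerance = 1e-8)
    expect_equal(t3$nrs, rep(0, length(grid)))
  }
})

test_that("trajectories conserve cells and respond monotonically to dose", {
  p <- rate_parameters(0.2, 0.3, 0.05, 0.2, 0.01)
  tr <- simulate_ode(p, condition_protocol("10/1000"), seq(0, 48, by = 2),
                     spec = model_spec(4))
  expect_equal(tr$negative + tr$positive + tr$nrs + tr$nrps,
               rep(1000, nrow(tr)), tolerance = 1e-7)
  # positive fraction during the first response is non-decreasing in dose
  p3 <- rate_parameters(0.2, 0.3, 0.05, 0.2)
  pf <- vapply(c(1, 10, 100, 1000), function(d) {
    simulate_ode(p3, condition_protocol(as.character(d)), 8)$f_positive
  }, numeric(1))
  expect_true(all(diff(pf) >= 0))
})

test_that("the batch propagator agrees with the adaptive integrator", {
  prot <- condition_protocol("10/1000")
  tt <- c(8, 16, 26, 32, 40)
  sets <- random_rates(10, n_states = 4, seed = 31)
  par <- do.call(rbind, lapply(sets, function(p) as.data.frame(unclass(p)[1:5])))
  bf <- batch_state_fractions(par, prot, tt)
  for (i in seq_along(sets)) {
    tr <- simulate_ode(sets[[i]], prot, tt, spec = model_spec(4), n_cells = 1)
    expect_equal(bf$positive[i, ], tr$f_positive, tolerance = 1e-6)
    expect_equal(bf$nrps[i, ], tr$f_nrps, tolerance = 1e-6)
  }
})
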