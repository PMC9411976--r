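test_that("the default design emits 3 x 65 x 8 = 1560 parameter sets", {
  d <- efast_design(n_curves = 3, n_samples = 65, seed = 11)
  expect_equal(nrow(d$sets), 1560)
  expect_equal(length(d$parameters), 8)
  expect_true("dummy" %in% d$parameters)
  expect_equal(d$omega_max, 8)
})

test_that("degenerate and invalid designs behave as documented", {
  d1 <- efast_design(list(x = c(0, 1)), n_curves = 1, n_samples = 33, seed = 1)
  expect_equal(nrow(d1$sets), 33)
  expect_error(efast_design(list(x = c(0, 1)), n_samples = 5), "too small")
  expect_error(efast_design(list(x = c(0, Inf))), "finite")
})

test_that("all sampled values stay inside their declared ranges", {
  rng <- list(a = c(0.01, 1), b = c(1, 20), dummy = c(0.5, 2))
  d <- efast_design(rng, n_curves = 2, n_samples = 65, seed = 3)
  for (nm in names(rng)) {
    expect_true(all(d$sets[[nm]] >= rng[[nm]][1] - 1e-12))
    expect_true(all(d$sets[[nm]] <= rng[[nm]][2] + 1e-12))
  }
  # the same seed reproduces the design exactly
  d2 <- efast_design(rng, n_curves = 2, n_samples = 65, seed = 3)
  expect_identical(d$sets, d2$sets)
})

test_that("zero output variance is flagged, not silently reported", {
  d <- efast_design(list(x = c(0, 1)), n_curves = 1, n_samples = 33, seed = 9)
  y <- efast_evaluate(d, function(p) data.frame(y = rep(3, nrow(p))))
  expect_warning(res <- efast_analyze(d, y), "zero output variance")
  expect_true(is.na(res$Si))
})

test_that("a dominant linear coefficient wins the first-order index", {
  d <- efast_design(list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1),
                         dummy = c(0, 1)),
                    n_curves = 3, n_samples = 65, seed = 2)
  y <- efast_evaluate(d, function(p) data.frame(y = 5 * p$x1 + p$x2 + 0.5 * p$x3))
  res <- efast_analyze(d, y)
  res_y <- res[res$output == "y", ]
  expect_equal(res_y$parameter[which.max(res_y$Si)], "x1")
  expect_lte(res_y$Si[res_y$parameter == "dummy"], 0.05)
  # analytic shares of variance for independent uniform inputs
  v <- c(25, 1, 0.25) / 26.25
  got <- res_y$Si[match(c("x1", "x2", "x3"), res_y$parameter)]
  expect_equal(got, v, tolerance = 0.06)
})

test_that("Si never exceeds STi beyond estimator tolerance", {
  d <- efast_design(list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi)),
                    n_curves = 3, n_samples = 65, seed = 5)
  res <- efast_analyze(d, efast_evaluate(d, function(p)
    data.frame(y = ishigami(p$x1, p$x2, p$x3))))
  expect_true(all(res$Si <= res$STi + 0.02))
  expect_true(all(res$Si >= -0.02 & res$STi <= 1 + 0.02))
})

test_that("Ishigami indices agree with a Monte-Carlo Sobol oracle", {
  d <- efast_design(list(x1 = c(-pi, pi), x2 = c(-pi, pi), x3 = c(-pi, pi)),
                    n_curves = 5, n_samples = 257, seed = 3)
  res <- efast_analyze(d, efast_evaluate(d, function(p)
    data.frame(y = ishigami(p$x1, p$x2, p$x3))))
  oracle <- sobol_mc_ishigami(n = 2^16, seed = 99)
  got <- res[match(c("x1", "x2", "x3"), res$parameter), ]
  expect_lt(max(abs(got$Si - oracle$Si)), 0.05)
  expect_lt(max(abs(got$STi - oracle$STi)), 0.05)
})

test_that("the model runner is deterministic with the ODE engine", {
  rng <- list(alpha = c(0.01, 1), beta = c(0.01, 1), gamma1 = c(0.01, 1),
              dummy = c(0.01, 1))
  d <- efast_design(rng, n_curves = 1, n_samples = 33, seed = 7)
  y1 <- efast_run(d, condition_protocol("1000"), readout_time_h = 16,
                  engine = "ode")
  y2 <- efast_run(d, condition_protocol("1000"), readout_time_h = 16,
                  engine = "ode")
  expect_identical(y1, y2)
  # per-set outputs conserve the total cell count
  tot <- y1$negative + y1$positive + y1$nrs + y1$nrps
  expect_equal(tot, rep(1000, nrow(y1)), tolerance = 1e-6)
})

test_that("stochastic replicate means vary like sd over root replicates", {
  p <- rate_parameters(0.3, 0.4, 0.05, 0.3)
  prot <- condition_protocol("1000")
  reps <- vapply(1:30, function(r) {
    simulate_gillespie(p, prot, 16, n_cells = 1000, seed = 400 + r)$positive
  }, numeric(1))
  se_emp <- stats::sd(reps) / sqrt(30)
  # repeat the 30-replicate mean a few times; its spread matches the SE
  means <- vapply(0:5, function(b) {
    mean(vapply(1:30, function(r) {
      simulate_gillespie(p, prot, 16, n_cells = 1000,
                         seed = 1000 + 30 * b + r)$positive
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(stats::sd(means) / se_emp - 1), 1.2)
})

test_that("dummy indices on model outputs sit at the noise floor", {
  rng <- list(alpha = c(0.01, 1), beta = c(0.01, 1), beta2 = c(0.01, 1),
              gamma1 = c(0.01, 1), gamma2 = c(0.01, 1), dummy = c(0.01, 1))
  d <- efast_design(rng, n_curves = 3, n_samples = 65, seed = 13)
  y <- efast_run(d, condition_protocol("1000"), readout_time_h = 16,
                 engine = "ode")
  res <- efast_analyze(d, y)
  dum <- res[res$parameter == "dummy", ]
  expect_true(all(dum$Si <= 0.05))
  tst <- efast_dummy_test(res)
  expect_true(all(c("p_Si", "p_STi") %in% names(tst)))
  # the strongest real parameter is significantly above the dummy
  strongest <- res[res$output == "positive", ]
  strongest <- strongest$parameter[which.max(strongest$STi)]
  expect_lt(min(tst$p_STi[tst$parameter == strongest &
                            tst$output == "positive"]), 0.2)
})
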