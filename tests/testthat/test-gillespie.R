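test_that("runs are reproducible from a seed and conserve cells exactly", {
  p <- rate_parameters(0.2, 0.3, 0.05, 0.2, 0.01)
  prot <- condition_protocol("1000/1000")
  a <- simulate_gillespie(p, prot, seq(0, 48, by = 2), model_spec(4), seed = 5)
  b <- simulate_gillespie(p, prot, seq(0, 48, by = 2), model_spec(4), seed = 5)
  expect_identical(a$positive, b$positive)
  expect_identical(attr(a, "n_events"), attr(b, "n_events"))
  expect_true(all(a$negative + a$positive + a$nrs + a$nrps == 1000))
  c2 <- simulate_gillespie(p, prot, seq(0, 48, by = 2), model_spec(4), seed = 6)
  expect_false(identical(a$positive, c2$positive))
})

test_that("the symmetric two-state chain hovers at half positive", {
  p <- rate_parameters(0.5, 0.5)
  # long stationary window after a 20/(alpha+beta)-day burn-in
  grid <- seq(500, 4500, by = 10) * 24 / 100
  g <- simulate_gillespie(p, stimulation_protocol(0, 0), grid,
                          n_cells = 1000, seed = 17)
  m <- mean(g$f_positive)
  se <- stats::sd(g$f_positive) / sqrt(nrow(g) / 10) # crude decorrelation
  expect_lt(abs(m - 0.5), 3 * max(se, 0.005))
})

test_that("the ensemble mean matches the mean-field ODE", {
  p <- rate_parameters(0.3, 0.4, 0.05, 0.3)
  prot <- condition_protocol("1000/1000")
  grid <- seq(4, 40, length.out = 10)
  ens <- simulate_ensemble(p, prot, grid, n_reps = 100, base_seed = 42)
  tr <- simulate_ode(p, prot, grid)
  pos <- ens[ens$state == "positive", ]
  z <- abs(pos$mean - tr$positive) / pos$se
  expect_gte(sum(z <= 3), 9)
})

test_that("state occupancy matches the master-equation marginals", {
  skip_if_not_installed("Matrix")
  # constant LPS (delta = 0) on a 50-cell toy: cells are iid, so pooled
  # state counts over replicates are multinomial with the matrix-
  # exponential occupation probabilities
  p <- rate_parameters(0.6, 0.5, 0.3, 0.8, 0.4, mu = 10, delta = 0)
  prot <- stimulation_protocol(0, 1000)
  t_h <- 18
  probs <- ctmc_probs(p, L = 1, t_d = t_h / 24)
  counts <- matrix(0L, 2000, 4)
  set.seed(99)
  for (r in seq_len(2000)) {
    g <- simulate_gillespie(p, prot, t_h, model_spec(4), n_cells = 50,
                            seed = NULL)
    counts[r, ] <- c(g$negative, g$positive, g$nrs, g$nrps)
  }
  pooled <- colSums(counts)
  expect_equal(sum(pooled), 2000 * 50)
  gof <- suppressWarnings(stats::chisq.test(pooled, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("the permanent state is absorbing in every run", {
  p <- rate_parameters(0.5, 0.2, 0.1, 0.6, 0.3)
  prot <- stimulation_protocol(0, 1000, washout = TRUE)
  for (s in 1:5) {
    g <- simulate_gillespie(p, prot, seq(0, 72, by = 2), model_spec(4),
                            n_cells = 500, seed = s)
    expect_true(all(diff(g$nrps) >= 0))
  }
})

test_that("ensemble standard errors shrink like one over root reps", {
  p <- rate_parameters(0.3, 0.4, 0.05, 0.3)
  prot <- condition_protocol("1000")
  grid <- seq(2, 20, by = 2)
  e1 <- simulate_ensemble(p, prot, grid, n_reps = 40, base_seed = 100)
  e2 <- simulate_ensemble(p, prot, grid, n_reps = 80, base_seed = 300)
  m1 <- stats::median(e1$se[e1$se > 0])
  m2 <- stats::median(e2$se[e2$se > 0])
  expect_lt(abs(m2 / m1 - 1 / sqrt(2)), 0.2 * 1 / sqrt(2))
  # n_reps = 1: mean is the run itself, SE flagged as NA
  e0 <- simulate_ensemble(p, prot, grid, n_reps = 1, base_seed = 7)
  expect_true(all(is.na(e0$se)))
  # fixed base seed: bit-identical summaries
  e3 <- simulate_ensemble(p, prot, grid, n_reps = 40, base_seed = 100)
  expect_identical(e1$mean, e3$mean)
})

test_that("disjoint seeds give uncorrelated endpoints", {
  p <- rate_parameters(0.4, 0.4, 0.05, 0.3)
  prot <- condition_protocol("1000")
  ends <- vapply(1:60, function(s) {
    simulate_gillespie(p, prot, 16, n_cells = 200, seed = s)$positive
  }, numeric(1))
  lag1 <- stats::cor(ends[-1], ends[-length(ends)])
  expect_lt(abs(lag1), 0.35)
})

test_that("zero total propensity idles to the horizon without error", {
  p <- rate_parameters(alpha = 0, beta = 0.5)
  g <- simulate_gillespie(p, stimulation_protocol(0, 0), c(12, 24),
                          model_spec(2), n_cells = 100, seed = 1)
  expect_equal(g$negative, c(100, 100))
  expect_equal(attr(g, "n_events"), 0)
})
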