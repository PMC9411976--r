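test_that("prior draws respect support, seed and moments", {
  pr <- prior_spec()
  d <- sample_parameters(pr, model_spec(3)$free_parameters, 1000, seed = 2)
  expect_equal(dim(d), c(1000L, 4L))
  expect_true(all(d >= 0.01 & d <= 1))
  d2 <- sample_parameters(pr, model_spec(3)$free_parameters, 1000, seed = 2)
  expect_identical(d, d2)
  big <- sample_parameters(pr, "alpha", 1e5, seed = 3)$alpha
  expect_lt(abs(mean(big) - 0.505), 3 * 0.99 / sqrt(12) / sqrt(1e5))

  tn <- sample_parameters(prior_spec("normal"), "alpha", 5000, seed = 4)$alpha
  expect_true(all(tn >= 0))
  expect_lt(abs(mean(tn) - 0.03), 0.001)

  ga <- sample_parameters(prior_spec("gamma"), "alpha", 5000, seed = 5)$alpha
  expect_true(all(ga >= 0))
  expect_lt(abs(mean(ga) - 0.68 * 0.2), 0.02)
  # shape/rate parameterisation is selectable
  gr <- prior_spec("gamma", shape = 0.68, rate = 0.2)
  expect_equal(gr$scale, 5)
  expect_error(prior_spec("uniform", low = 1, high = 0.5), "low < high")
})

test_that("rmsd matches its definition on toy cases", {
  expect_equal(rmsd(c(0.5, 0.9), c(0.5, 0.9)), 0)
  expect_equal(rmsd(rep(0.3 + 0.05, 7), rep(0.3, 7)), 0.05)
  expect_equal(rmsd(c(0.5, 0.9), c(0.4, 0.7)), sqrt((0.01 + 0.04) / 2))
  expect_error(rmsd(numeric(0), numeric(0)), "empty")
  expect_error(rmsd(c(0.1, 0.2), c(0.1)), "align")
})

test_that("AIC has the Gaussian-residual closed form", {
  expect_equal(aic(0.02, 12, 4), 12 * log(0.02 / 12) + 2 * 4)
  # one extra parameter costs exactly 2
  expect_equal(aic(0.05, 10, 5) - aic(0.05, 10, 4), 2)
  # halving the RSS buys n ln 2
  expect_equal(aic(0.04, 9, 4) - aic(0.02, 9, 4), 9 * log(2))
  expect_warning(v <- aic(0, 5, 4), "degenerate")
  expect_identical(v, -Inf)
})

test_that("rejection fit honours its contract", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 1)
  fit <- rejection_fit(obs, model_spec(3), n_samples = 2000, top_k = 50,
                       seed = 3)
  s <- tidy(fit)
  expect_equal(nrow(s), 50)
  expect_true(!is.unsorted(s$aic))
  expect_equal(s$rank, 1:50)
  expect_true(all(s$aic >= min(s$aic)))
  g <- glance(fit)
  expect_equal(g$n_samples, 2000)
  expect_equal(g$best_rmsd, min(s$rmsd))
  expect_error(rejection_fit(obs, model_spec(3), n_samples = 10, top_k = 50),
               "n_samples")
})

test_that("scoring is joint across conditions and order-invariant", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 2)
  fit1 <- rejection_fit(obs, model_spec(3), n_samples = 500, seed = 7)
  perm <- obs[sample(nrow(obs)), ]
  fit2 <- rejection_fit(perm, model_spec(3), n_samples = 500, seed = 7)
  expect_equal(sort(tidy(fit1)$rmsd), sort(tidy(fit2)$rmsd), tolerance = 1e-12)
  expect_equal(sort(tidy(fit1)$aic), sort(tidy(fit2)$aic), tolerance = 1e-12)
})

test_that("a known 3-state truth is recovered inside the top-50 envelope", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 5)
  truth <- ground_truth(obs)
  fit <- rejection_fit(obs, model_spec(3), n_samples = 2e4, seed = 9)
  s <- tidy(fit)
  for (nm in c("alpha", "gamma1")) {
    env <- stats::quantile(s[[nm]], c(0.025, 0.975))
    expect_gte(truth[[nm]], env[[1]])
    expect_lte(truth[[nm]], env[[2]])
  }
})

test_that("model comparison penalises the unneeded fourth state", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 6)
  fit3 <- rejection_fit(obs, model_spec(3), n_samples = 2e4, seed = 11)
  fit4 <- rejection_fit(obs, model_spec(4), n_samples = 2e4, seed = 12)
  cmp <- compare_models(fit3, fit4)
  expect_equal(cmp$delta_aic, cmp$mean_aic_4 - cmp$mean_aic_3)
  expect_true(cmp$preferred %in% c(3L, 4L))
  # identical predictions differing only in parameter count: penalty = 2
  expect_equal(aic(0.01, 9, 5) - aic(0.01, 9, 4), 2)
  other <- generate_observations(experiment_design("bmdm_like", proteins = "IL6"),
                                 seed = 1)
  fit_other <- rejection_fit(other, model_spec(4), n_samples = 200, seed = 1)
  expect_error(compare_models(fit3, fit_other), "different observation")
})

test_that("the preferred model is robust to the prior family", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 8)
  pref <- vapply(list(prior_spec("uniform"),
                      prior_spec("normal", mean = 0.3, sd = 0.15),
                      prior_spec("gamma", shape = 2, scale = 0.15)),
                 function(pr) {
    f3 <- rejection_fit(obs, model_spec(3), pr, n_samples = 1e4, seed = 21)
    f4 <- rejection_fit(obs, model_spec(4), pr, n_samples = 1e4, seed = 22)
    compare_models(f3, f4)$preferred
  }, integer(1))
  expect_equal(length(unique(pref)), 1L)
})

test_that("binomial-likelihood AIC mode ranks coherently", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 9)
  fit <- rejection_fit(obs, model_spec(3), n_samples = 1000, seed = 13,
                       likelihood = "binomial")
  s <- tidy(fit)
  expect_true(!is.unsorted(s$aic))
  # better RMSD generally means better binomial likelihood on the same data
  expect_gt(stats::cor(s$rank, s$rmsd, method = "spearman"), 0.5)
})

test_that("the convergence curve is a non-increasing running best", {
  obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
                               seed = 10)
  cv <- rmsd_convergence(obs, model_spec(3), checkpoints = c(100, 1000, 5000),
                         seed = 15)
  expect_true(all(diff(cv$best_rmsd) <= 0))
  expect_true(all(diff(cv$topk_mean_rmsd) <= 0))
  expect_lte(cv$best_rmsd[3], cv$best_rmsd[1])
  expect_true(is.na(cv$rel_improvement[1]))
  expect_true(all(cv$rel_improvement[-1] >= 0))
})

test_that("noise-free observations admit near-zero RMSD as sampling grows", {
  des <- experiment_design("raw_like", proteins = "TNF",
                           cells_per_sample = 1e7)
  obs <- generate_observations(des, seed = 11)
  cv <- rmsd_convergence(obs, model_spec(3), checkpoints = c(100, 2000, 2e4),
                         seed = 16)
  expect_lt(cv$best_rmsd[3], 0.01)
})
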