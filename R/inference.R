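#' Prior specification for rejection sampling
#'
#' Each free transition rate is drawn independently from the chosen family,
#' truncated to non-negative values. The default is the uniform prior
#' U[0.01, 1] per rate used throughout the modelling workflow; truncated
#' normal N(0.03, 0.01) and gamma G(0.68, 0.2) alternatives are provided to
#' check that the prior family does not drive the model comparison.
#'
#' @param family `"uniform"`, `"normal"` or `"gamma"`.
#' @param low,high Uniform support (defaults 0.01, 1).
#' @param mean,sd Normal location and scale (defaults 0.03, 0.01), truncated
#'   to `[0, Inf)` by rejection.
#' @param shape Gamma shape (default 0.68).
#' @param scale,rate Gamma scale (default 0.2) or rate; supply exactly one.
#'   The scale parameterisation is the default reading of "G(0.68, 0.2)".
#' @return An object of class `norm_prior`.
#' @examples
#' prior_spec()                       # U[0.01, 1]
#' prior_spec("gamma", shape = 0.68, rate = 0.2)
#' @export
prior_spec <- function(family = c("uniform", "normal", "gamma"),
                       low = 0.01, high = 1, mean = 0.03, sd = 0.01,
                       shape = 0.68, scale = 0.2, rate = NULL) {
  family <- match.arg(family)
  pr <- switch(family,
    uniform = {
      if (!(low < high)) stop("uniform prior needs low < high", call. = FALSE)
      list(family = "uniform", low = low, high = high)
    },
    normal = {
      if (sd <= 0) stop("normal prior needs sd > 0", call. = FALSE)
      list(family = "normal", mean = mean, sd = sd)
    },
    gamma = {
      if (!is.null(rate)) scale <- 1 / rate
      if (shape <= 0 || scale <= 0) stop("gamma prior needs positive shape and scale", call. = FALSE)
      list(family = "gamma", shape = shape, scale = scale)
    })
  structure(pr, class = "norm_prior")
}

#' @export
print.norm_prior <- function(x, ...) {
  cat("<norm_prior>", x$family,
      paste(sprintf("%s=%g", setdiff(names(x), "family"),
                    unlist(x[setdiff(names(x), "family")])), collapse = " "),
      "\n")
  invisible(x)
}

#' Draw independent parameter sets from a prior
#'
#' @param prior A [prior_spec()].
#' @param free_names Names of the free rates (e.g.
#'   `model_spec(3)$free_parameters`).
#' @param n Number of parameter sets.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with `n` rows and one column per free rate; all values
#'   within the prior support (non-negative).
#' @examples
#' sample_parameters(prior_spec(), model_spec(3)$free_parameters, 5, seed = 1)
#' @export
sample_parameters <- function(prior, free_names, n, seed = NULL) {
  stopifnot(inherits(prior, "norm_prior"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(m) {
    switch(prior$family,
      uniform = stats::runif(m, prior$low, prior$high),
      normal = {
        # truncate to [0, Inf) by rejection; acceptance ~ 1 for the defaults
        x <- stats::rnorm(m, prior$mean, prior$sd)
        while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), prior$mean, prior$sd)
        x
      },
      gamma = stats::rgamma(m, shape = prior$shape, scale = prior$scale))
  }
  out <- tibble::as_tibble(stats::setNames(
    lapply(free_names, function(nm) draw(n)), free_names))
  out
}

#' Root-mean-square deviation between predictions and observations
#'
#' @param predicted Numeric vector of predicted positive fractions, aligned
#'   one-to-one with the rows of `observed`.
#' @param observed A tibble with a `fraction_positive` column (an
#'   observation set), or a plain numeric vector.
#' @return The RMSD; 0 iff the prediction matches exactly.
#' @examples
#' rmsd(c(0.5, 0.9), c(0.4, 0.7)) # sqrt((0.01 + 0.04) / 2)
#' @export
rmsd <- function(predicted, observed) {
  obs <- if (is.data.frame(observed)) observed$fraction_positive else observed
  if (length(obs) == 0L) stop("empty observation set", call. = FALSE)
  if (length(predicted) != length(obs)) {
    stop("`predicted` and `observed` must align one-to-one", call. = FALSE)
  }
  sqrt(mean((predicted - obs)^2))
}

#' Akaike information criterion from a residual sum of squares
#'
#' Gaussian-residual form `n * ln(RSS / n) + 2k`, with `k` the number of
#' free transition rates (4 for the 3-state model, 5 for the 4-state
#' model). Monotone increasing in RSS at fixed `n` and `k`, so within one
#' model it ranks parameter sets identically to RMSD; across models it adds
#' the parameter-count penalty.
#'
#' @param rss Residual sum of squares (> 0; `rss = 0` is degenerate and
#'   returns `-Inf` with a warning).
#' @param n_obs Number of observations.
#' @param k_params Number of free parameters.
#' @return The AIC value.
#' @examples
#' aic(0.02, n_obs = 12, k_params = 4)
#' @export
aic <- function(rss, n_obs, k_params) {
  if (n_obs < 1) stop("`n_obs` must be >= 1", call. = FALSE)
  if (any(rss < 0)) stop("`rss` must be non-negative", call. = FALSE)
  out <- n_obs * log(rss / n_obs) + 2 * k_params
  if (any(rss == 0)) {
    warning("rss = 0: degenerate (perfect) fit, AIC is -Inf", call. = FALSE)
  }
  out
}

#' Binomial-likelihood AIC for positive-count observations
#'
#' Alternative AIC mode treating each observed positive fraction as a
#' binomial draw of `n_cells` cells: `-2 log L + 2k` with
#' `L = prod Binom(round(frac * n), n, p_pred)`.
#'
#' @param predicted Predicted positive fractions (clamped away from 0/1 by
#'   machine epsilon for the log-likelihood).
#' @param observed Observation tibble with `fraction_positive` and `n_cells`.
#' @param k_params Number of free parameters.
#' @return The AIC value.
#' @export
aic_binomial <- function(predicted, observed, k_params) {
  p <- pmin(pmax(predicted, 1e-12), 1 - 1e-12)
  x <- round(observed$fraction_positive * observed$n_cells)
  ll <- sum(stats::dbinom(x, observed$n_cells, p, log = TRUE))
  -2 * ll + 2 * k_params
}

# Predict positive fractions for every row of `par` at every observation
# record, jointly across conditions. Returns an nrow(par) x nrow(obs) matrix.
predict_obs_matrix <- function(par, observations, mu = 10, delta = 0.5,
                               dt_h = 0.25, challenge_time_h = 24) {
  conds <- split(seq_len(nrow(observations)), observations$condition)
  out <- matrix(NA_real_, nrow(par), nrow(observations))
  for (cond in names(conds)) {
    idx <- conds[[cond]]
    prot <- condition_protocol(cond, challenge_time_h)
    offset <- condition_clock_offset(cond, challenge_time_h)
    t_abs <- observations$time_h[idx] + offset
    pf <- batch_state_fractions(par, prot, t_abs, mu = mu, delta = delta,
                                dt_h = dt_h)$positive
    out[, idx] <- pf
  }
  out
}

#' Rejection-sampling parameter estimation
#'
#' Draws `n_samples` candidate parameter sets from the prior, simulates
#' each under every observed condition's stimulation protocol, scores the
#' root-mean-square deviation of predicted vs observed positive fractions
#' jointly across all records, converts to AIC, and retains the `top_k`
#' best (lowest-AIC) sets.
#'
#' The default engine propagates the mean-field equations for all candidate
#' sets at once (see [batch_state_fractions()]); the mean field is the
#' expectation of the stochastic model, so it is the natural fitting
#' target. The `"gillespie"` engine instead averages stochastic replicates
#' per candidate set (slow; mainly for spot checks).
#'
#' @param observations An observation tibble with columns `condition`,
#'   `time_h`, `fraction_positive` (and `n_cells` for the binomial AIC
#'   mode), e.g. from [generate_observations()]. Measurement times are
#'   post-challenge (see [condition_clock_offset()]).
#' @param spec A [model_spec()] (3- or 4-state).
#' @param prior A [prior_spec()].
#' @param n_samples Number of prior draws (>= `top_k`).
#' @param top_k Number of retained sets (default 50).
#' @param engine `"ode"` (default) or `"gillespie"`.
#' @param seed Integer seed for the prior draws (and stochastic engine).
#' @param mu,delta Fixed LPS constants.
#' @param dt_h Batch propagator step (hours).
#' @param n_cells_sim,n_reps_gillespie Stochastic-engine population size and
#'   replicates per candidate set.
#' @param likelihood `"gaussian"` (RSS-based AIC, default) or `"binomial"`.
#' @return An object of class `norm_fit`: a list with `samples` (tibble of
#'   the retained sets, ascending AIC, with `rmsd`, `rss`, `aic`, `rank`),
#'   `spec`, `prior`, `n_samples`, `top_k`, `seed`, `n_failed`, and the
#'   observations that were fit. Use [tidy()] / [glance()] to extract tidy
#'   summaries.
#' @examples
#' \donttest{
#' obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
#'                              seed = 1)
#' fit <- rejection_fit(obs, model_spec(3), n_samples = 2000, seed = 1)
#' glance(fit)
#' }
#' @export
rejection_fit <- function(observations, spec = model_spec(3),
                          prior = prior_spec(), n_samples = 1e5, top_k = 50,
                          engine = c("ode", "gillespie"), seed = 1,
                          mu = 10, delta = 0.5, dt_h = 0.25,
                          n_cells_sim = 1000, n_reps_gillespie = 3,
                          likelihood = c("gaussian", "binomial")) {
  engine <- match.arg(engine)
  likelihood <- match.arg(likelihood)
  stopifnot(inherits(spec, "norm_model_spec"))
  observations <- validate_observations(observations)
  if (n_samples < top_k) stop("`n_samples` must be >= `top_k`", call. = FALSE)
  par <- sample_parameters(prior, spec$free_parameters, n_samples, seed = seed)
  n_obs <- nrow(observations)

  if (engine == "ode") {
    pred <- predict_obs_matrix(par, observations, mu, delta, dt_h)
  } else {
    pred <- matrix(NA_real_, n_samples, n_obs)
    conds <- split(seq_len(n_obs), observations$condition)
    for (i in seq_len(n_samples)) {
      p_i <- rate_parameters(alpha = par$alpha[i], beta = par$beta[i],
                             beta2 = par$beta2[i] %||% 0,
                             gamma1 = par$gamma1[i] %||% 0,
                             gamma2 = par$gamma2[i] %||% 0,
                             mu = mu, delta = delta)
      for (cond in names(conds)) {
        idx <- conds[[cond]]
        prot <- condition_protocol(cond)
        t_abs <- observations$time_h[idx] + condition_clock_offset(cond)
        ens <- simulate_ensemble(p_i, prot, t_abs, spec, n_cells_sim,
                                 n_reps = n_reps_gillespie,
                                 base_seed = seed + i, keep_runs = FALSE)
        pos <- ens$mean[ens$state == "positive"][match(t_abs, sort(unique(t_abs)))]
        pred[i, idx] <- pos / n_cells_sim
      }
    }
  }

  ok <- stats::complete.cases(pred) & apply(is.finite(pred), 1L, all)
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    message(n_failed, " candidate set(s) failed to simulate and were discarded")
  }
  resid2 <- (pred[ok, , drop = FALSE] -
               matrix(observations$fraction_positive, sum(ok), n_obs, byrow = TRUE))^2
  rss <- rowSums(resid2)
  rmsd_v <- sqrt(rss / n_obs)
  aic_v <- if (likelihood == "gaussian") {
    suppressWarnings(n_obs * log(rss / n_obs) + 2 * spec$k)
  } else {
    vapply(seq_along(rss), function(i) {
      aic_binomial(pred[ok, , drop = FALSE][i, ], observations, spec$k)
    }, numeric(1))
  }
  ord <- order(aic_v)[seq_len(min(top_k, length(aic_v)))]
  samples <- tibble::as_tibble(par[which(ok)[ord], , drop = FALSE])
  samples$rmsd <- rmsd_v[ord]
  samples$rss <- rss[ord]
  samples$aic <- aic_v[ord]
  samples$rank <- seq_len(nrow(samples))
  structure(list(samples = samples, spec = spec, prior = prior,
                 n_samples = n_samples, top_k = top_k, seed = seed,
                 engine = engine, likelihood = likelihood,
                 n_failed = n_failed, mu = mu, delta = delta,
                 observations = observations),
            class = "norm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.norm_fit <- function(x, ...) {
  cat(sprintf("<norm_fit> %d-state model, %d/%g sets retained (engine: %s)\n",
              x$spec$n_states, nrow(x$samples), x$n_samples, x$engine))
  cat(sprintf("  best RMSD %.4g | mean AIC (top %d) %.4g | seed %s\n",
              min(x$samples$rmsd), nrow(x$samples), mean(x$samples$aic),
              format(x$seed)))
  invisible(x)
}

#' Compare 3- and 4-state fits by mean AIC over retained sets
#'
#' Both fits must target the same observation set. Reports the mean AIC
#' over the retained (top-k) sets per model, their difference, and the
#' preferred (lower mean AIC) model. A lower mean AIC for the 3-state
#' model indicates that the reversible non-responsive state alone explains
#' the data and the permanent state is not needed.
#'
#' @param fit3,fit4 `norm_fit` objects for the 3- and 4-state models.
#' @return An object of class `norm_model_comparison` (a one-row tibble with
#'   `mean_aic_3`, `mean_aic_4`, `delta_aic`, `preferred`).
#' @export
compare_models <- function(fit3, fit4) {
  stopifnot(inherits(fit3, "norm_fit"), inherits(fit4, "norm_fit"))
  same <- isTRUE(all.equal(
    fit3$observations[c("condition", "time_h", "fraction_positive")],
    fit4$observations[c("condition", "time_h", "fraction_positive")]))
  if (!same) stop("fits target different observation sets", call. = FALSE)
  m3 <- mean(fit3$samples$aic); m4 <- mean(fit4$samples$aic)
  out <- tibble::tibble(
    mean_aic_3 = m3, mean_aic_4 = m4, delta_aic = m4 - m3,
    preferred = if (m3 <= m4) 3L else 4L,
    n_states_3 = fit3$spec$n_states, n_states_4 = fit4$spec$n_states)
  class(out) <- c("norm_model_comparison", class(out))
  out
}

#' Best-so-far RMSD as a function of samples drawn
#'
#' Draws a single prior stream of `max(checkpoints)` candidate sets and
#' reports, at each checkpoint, the running best RMSD and the mean RMSD of
#' the `top_k` best sets so far. Both curves are non-increasing by
#' construction; a plateau indicates that further sampling no longer
#' improves the fit, which is how the sampling budget is justified.
#'
#' @inheritParams rejection_fit
#' @param checkpoints Increasing vector of sample counts.
#' @return A tibble of class `norm_convergence` with columns `n_sampled`,
#'   `best_rmsd`, `topk_mean_rmsd` and `rel_improvement` (relative change
#'   of `best_rmsd` from the previous checkpoint).
#' @export
rmsd_convergence <- function(observations, spec = model_spec(3),
                             prior = prior_spec(),
                             checkpoints = c(100, 1000, 10000),
                             top_k = 50, seed = 1, mu = 10, delta = 0.5,
                             dt_h = 0.25) {
  checkpoints <- as.numeric(checkpoints)
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop("`checkpoints` must be strictly increasing", call. = FALSE)
  }
  observations <- validate_observations(observations)
  n_max <- max(checkpoints)
  par <- sample_parameters(prior, spec$free_parameters, n_max, seed = seed)
  pred <- predict_obs_matrix(par, observations, mu, delta, dt_h)
  n_obs <- nrow(observations)
  rmsd_all <- sqrt(rowSums((pred - matrix(observations$fraction_positive,
                                          n_max, n_obs, byrow = TRUE))^2) / n_obs)
  best <- vapply(checkpoints, function(m) min(rmsd_all[seq_len(m)]), numeric(1))
  topk <- vapply(checkpoints, function(m) {
    r <- sort(rmsd_all[seq_len(m)])
    mean(r[seq_len(min(top_k, length(r)))])
  }, numeric(1))
  out <- tibble::tibble(
    n_sampled = checkpoints, best_rmsd = best, topk_mean_rmsd = topk,
    rel_improvement = c(NA_real_, 1 - best[-1] / best[-length(best)]))
  class(out) <- c("norm_convergence", class(out))
  out
}
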