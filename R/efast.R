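#' eFAST sampling design with resample curves and a dummy parameter
#'
#' Builds the extended Fourier Amplitude Sensitivity Test design: for each
#' parameter of interest, `n_samples` points are placed along a sinusoidal
#' space-filling curve on which that parameter oscillates at a distinguished
#' high frequency while all others oscillate at low, interference-free
#' frequencies. Repeating the curve `n_curves` times with independent random
#' phase shifts gives the resample curves used to average (and test) the
#' indices. A dummy parameter that feeds nothing provides the estimator's
#' noise floor.
#'
#' The maximum frequency is `floor((n_samples - 1) / (2 * M))` with `M = 4`
#' harmonics (so 8 for the default 65 samples per curve), and complementary
#' parameters are assigned frequencies at most `max_freq / (2 * M)`, the
#' standard interference-free assignment. The default design — 3 curves,
#' 65 samples per curve, 7 model parameters plus one dummy — comprises
#' 3 x 65 x 8 = 1560 parameter sets.
#'
#' @param ranges Named list of `c(min, max)` ranges, one per parameter
#'   (include the dummy). Default: the five transition rates plus `mu`,
#'   `delta` and `dummy`, rates and dummy on `[0.01, 1]`, `mu` on `[1, 20]`,
#'   `delta` on `[0.1, 1]`.
#' @param n_curves Number of resample curves (default 3).
#' @param n_samples Samples per curve (default 65).
#' @param M Number of harmonics used by the estimator (default 4).
#' @param seed Integer seed for the random phases.
#' @return An object of class `norm_efast_design`: a list with `sets` (a
#'   tibble of `n_curves * n_samples * n_params` parameter sets with
#'   bookkeeping columns `poi`, `curve`, `s_index`), `parameters`, `ranges`,
#'   `n_curves`, `n_samples`, `M`, `omega_max`.
#' @examples
#' d <- efast_design(n_curves = 3, n_samples = 65, seed = 11)
#' nrow(d$sets) # 1560
#' @export
efast_design <- function(ranges = efast_default_ranges(), n_curves = 3,
                         n_samples = 65, M = 4, seed = 11) {
  pars <- names(ranges)
  k <- length(pars)
  if (k < 1) stop("need at least one parameter", call. = FALSE)
  if (any(!vapply(ranges, function(r) length(r) == 2L && is.finite(r[1]) &&
                    is.finite(r[2]) && r[1] <= r[2], logical(1)))) {
    stop("each range must be a finite c(min, max)", call. = FALSE)
  }
  omega_max <- floor((n_samples - 1) / (2 * M))
  if (omega_max < 1) {
    stop("`n_samples` too small for M = ", M,
         " harmonics: need at least ", 2 * M + 1, " samples", call. = FALSE)
  }
  # complementary frequencies: at most omega_max / (2M), spread or cycled
  m_comp <- max(1, floor(omega_max / (2 * M)))
  comp_freqs <- if (k == 1L) integer(0) else if (m_comp >= k - 1) {
    floor(seq(1, m_comp, length.out = k - 1))
  } else {
    rep_len(seq_len(m_comp), k - 1)
  }
  if (!is.null(seed)) set.seed(seed)
  s <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  blocks <- vector("list", n_curves * k)
  b <- 0L
  for (curve in seq_len(n_curves)) {
    for (i in seq_len(k)) {
      omega <- integer(k)
      omega[i] <- omega_max
      omega[-i] <- comp_freqs
      phase <- stats::runif(k, 0, 2 * pi)
      x <- vapply(seq_len(k), function(j) {
        0.5 + asin(sin(omega[j] * s + phase[j])) / pi
      }, numeric(n_samples))
      x <- sweep(sweep(x, 2, vapply(ranges, diff, numeric(1)), "*"),
                 2, vapply(ranges, `[`, numeric(1), 1), "+")
      colnames(x) <- pars
      df <- tibble::as_tibble(x)
      df$poi <- pars[i]
      df$curve <- curve
      df$s_index <- seq_len(n_samples)
      b <- b + 1L
      blocks[[b]] <- df
    }
  }
  sets <- dplyr::bind_rows(blocks)
  structure(list(sets = sets, parameters = pars, ranges = ranges,
                 n_curves = n_curves, n_samples = n_samples, M = M,
                 omega_max = omega_max, seed = seed),
            class = "norm_efast_design")
}

#' Default eFAST parameter ranges for the cell-state model
#'
#' The five transition rates and the dummy span the prior support
#' `[0.01, 1]`; the LPS coefficient `mu` spans `[1, 20]` around its fixed
#' value 10 and the decay rate `delta` spans `[0.1, 1]` around 0.5, so all
#' seven model parameters plus the dummy are perturbed.
#' @return A named list of ranges.
#' @export
efast_default_ranges <- function() {
  list(alpha = c(0.01, 1), beta = c(0.01, 1), beta2 = c(0.01, 1),
       gamma1 = c(0.01, 1), gamma2 = c(0.01, 1),
       mu = c(1, 20), delta = c(0.1, 1), dummy = c(0.01, 1))
}

#' @export
print.norm_efast_design <- function(x, ...) {
  cat(sprintf("<norm_efast_design> %d params x %d curves x %d samples = %d sets (omega_max=%d, M=%d)\n",
              length(x$parameters), x$n_curves, x$n_samples, nrow(x$sets),
              x$omega_max, x$M))
  invisible(x)
}

#' Evaluate a function over every design point
#'
#' Applies `f` to the design's parameter table and returns the outputs
#' aligned with the design rows. `f` receives the full tibble of parameter
#' columns and must return a data frame (or named vector per row) of
#' numeric outputs; it should be vectorised over rows.
#'
#' @param design A [efast_design()].
#' @param f Function of a tibble of parameter columns returning a
#'   data.frame of outputs with `nrow(design$sets)` rows.
#' @return A tibble of outputs.
#' @export
efast_evaluate <- function(design, f) {
  stopifnot(inherits(design, "norm_efast_design"))
  out <- f(design$sets[design$parameters])
  out <- tibble::as_tibble(out)
  if (nrow(out) != nrow(design$sets)) {
    stop("`f` must return one output row per design row", call. = FALSE)
  }
  out
}

#' Run the cell-state model over an eFAST design
#'
#' Evaluates the four state counts at a readout time for every design point.
#' The stochastic engine averages `n_replicates` Doob-Gillespie runs per
#' parameter set (accounting for simulation noise, 30 by default); the ODE
#' engine evaluates the mean field directly and is deterministic.
#'
#' @param design A [efast_design()] whose parameters are a subset of
#'   `alpha, beta, beta2, gamma1, gamma2, mu, delta, dummy`.
#' @param protocol A [stimulation_protocol()].
#' @param readout_time_h Readout time in hours (default 16, the end of the
#'   primary-challenge observation window).
#' @param spec A [model_spec()]; default 4-state so all rates act.
#' @param n_cells Cells per simulation (default 1000).
#' @param engine `"gillespie"` (default) or `"ode"`.
#' @param n_replicates Stochastic replicates per set (default 30).
#' @param base_seed Seed for the stochastic engine.
#' @param mu,delta Values used when the design does not vary them.
#' @return A tibble with columns `negative`, `positive`, `nrs`, `nrps`
#'   (mean counts at readout), aligned with `design$sets`.
#' @export
efast_run <- function(design, protocol, readout_time_h = 16,
                      spec = model_spec(4), n_cells = 1000,
                      engine = c("gillespie", "ode"), n_replicates = 30,
                      base_seed = 1, mu = 10, delta = 0.5) {
  engine <- match.arg(engine)
  stopifnot(inherits(design, "norm_efast_design"))
  sets <- design$sets
  get_col <- function(nm, default) sets[[nm]] %||% rep(default, nrow(sets))
  if (engine == "ode") {
    par <- data.frame(alpha = get_col("alpha", 0.1), beta = get_col("beta", 0.1),
                      beta2 = get_col("beta2", 0), gamma1 = get_col("gamma1", 0),
                      gamma2 = get_col("gamma2", 0))
    mu_v <- get_col("mu", mu); de_v <- get_col("delta", delta)
    # mu/delta may vary per row: group rows sharing (mu, delta)
    key <- paste(signif(mu_v, 12), signif(de_v, 12))
    out <- matrix(NA_real_, nrow(sets), 4)
    for (kk in unique(key)) {
      idx <- which(key == kk)
      fr <- batch_state_fractions(par[idx, , drop = FALSE], protocol,
                                  readout_time_h, mu = mu_v[idx[1]],
                                  delta = de_v[idx[1]])
      out[idx, ] <- cbind(fr$negative[, 1], fr$positive[, 1],
                          fr$nrs[, 1], fr$nrps[, 1]) * n_cells
    }
  } else {
    out <- matrix(NA_real_, nrow(sets), 4)
    for (i in seq_len(nrow(sets))) {
      p_i <- rate_parameters(alpha = get_col("alpha", 0.1)[i],
                             beta = get_col("beta", 0.1)[i],
                             beta2 = get_col("beta2", 0)[i],
                             gamma1 = get_col("gamma1", 0)[i],
                             gamma2 = get_col("gamma2", 0)[i],
                             mu = get_col("mu", mu)[i],
                             delta = get_col("delta", delta)[i])
      acc <- numeric(4)
      for (r in seq_len(n_replicates)) {
        tr <- simulate_gillespie(p_i, protocol, readout_time_h, spec, n_cells,
                                 seed = base_seed + (i - 1L) * n_replicates + r)
        acc <- acc + c(tr$negative[1], tr$positive[1], tr$nrs[1], tr$nrps[1])
      }
      out[i, ] <- acc / n_replicates
    }
  }
  colnames(out) <- c("negative", "positive", "nrs", "nrps")
  tibble::as_tibble(out)
}

#' First- and total-order eFAST sensitivity indices
#'
#' For each output and each parameter of interest, computes the first-order
#' index Si as the fraction of output variance at the distinguished
#' frequency and its first `M` harmonics, and the total-order index STi as
#' one minus the fraction at the complementary (low) frequencies, averaged
#' over the resample curves. `0 <= Si <= STi <= 1` up to estimator noise;
#' the dummy parameter's indices estimate the noise floor.
#'
#' @param design A [efast_design()].
#' @param outputs A data frame of numeric outputs aligned row-by-row with
#'   `design$sets` (e.g. from [efast_run()] or [efast_evaluate()]).
#' @return A tibble of class `norm_sensitivity` with columns `output`,
#'   `parameter`, `Si`, `STi`, `Si_sd`, `STi_sd` (across curves) and
#'   `n_curves`; the per-curve indices are kept in attribute `per_curve`.
#' @examples
#' d <- efast_design(list(x1 = c(0, 1), x2 = c(0, 1)), n_samples = 65, seed = 1)
#' y <- efast_evaluate(d, function(p) data.frame(y = 2 * p$x1 + 0.1 * p$x2))
#' efast_analyze(d, y)
#' @export
efast_analyze <- function(design, outputs) {
  stopifnot(inherits(design, "norm_efast_design"))
  outputs <- as.data.frame(outputs)
  if (nrow(outputs) != nrow(design$sets)) {
    stop("`outputs` must align with the design rows", call. = FALSE)
  }
  NS <- design$n_samples; M <- design$M; wmax <- design$omega_max
  s <- 2 * pi * (seq_len(NS) - 1) / NS
  p_all <- seq_len((NS - 1) %/% 2)
  cosb <- outer(s, p_all, function(si, p) cos(p * si))
  sinb <- outer(s, p_all, function(si, p) sin(p * si))
  harm <- wmax * seq_len(M)
  harm <- harm[harm <= max(p_all)]
  comp <- seq_len(max(1, floor(wmax / 2)))

  rows <- list()
  per_curve <- list()
  for (out_nm in names(outputs)) {
    for (poi in design$parameters) {
      si_c <- sti_c <- numeric(design$n_curves)
      for (curve in seq_len(design$n_curves)) {
        idx <- which(design$sets$poi == poi & design$sets$curve == curve)
        y <- outputs[[out_nm]][idx][order(design$sets$s_index[idx])]
        A <- colMeans(y * cosb); B <- colMeans(y * sinb)
        spec_p <- A^2 + B^2
        V <- 2 * sum(spec_p)
        if (V <= .Machine$double.eps * max(1, mean(y)^2)) {
          si_c[curve] <- NA_real_; sti_c[curve] <- NA_real_
          next
        }
        si_c[curve] <- 2 * sum(spec_p[harm]) / V
        sti_c[curve] <- 1 - 2 * sum(spec_p[comp]) / V
      }
      if (all(is.na(si_c))) {
        warning("zero output variance for output '", out_nm,
                "', poi '", poi, "': indices undefined", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        output = out_nm, parameter = poi,
        Si = mean(si_c, na.rm = TRUE), STi = mean(sti_c, na.rm = TRUE),
        Si_sd = stats::sd(si_c), STi_sd = stats::sd(sti_c),
        n_curves = design$n_curves)
      per_curve[[length(per_curve) + 1L]] <- tibble::tibble(
        output = out_nm, parameter = poi, curve = seq_len(design$n_curves),
        Si = si_c, STi = sti_c)
    }
  }
  res <- dplyr::bind_rows(rows)
  attr(res, "per_curve") <- dplyr::bind_rows(per_curve)
  attr(res, "design") <- list(n_curves = design$n_curves,
                              n_samples = design$n_samples,
                              M = M, omega_max = wmax)
  class(res) <- c("norm_sensitivity", class(res))
  res
}

#' Test a parameter's indices against the dummy's noise floor
#'
#' Two-sided Welch t-test of a parameter's per-curve Si (and STi) against
#' the dummy parameter's, across resample curves — the conventional check
#' that a sensitivity is distinguishable from estimator noise.
#'
#' @param result A [efast_analyze()] result.
#' @param dummy Name of the dummy parameter (default `"dummy"`).
#' @return A tibble with `output`, `parameter`, `p_Si`, `p_STi`.
#' @export
efast_dummy_test <- function(result, dummy = "dummy") {
  pc <- attr(result, "per_curve")
  if (is.null(pc)) stop("result lacks per-curve indices", call. = FALSE)
  if (!dummy %in% pc$parameter) stop("no '", dummy, "' parameter", call. = FALSE)
  outs <- unique(pc$output)
  rows <- list()
  for (o in outs) {
    d <- pc[pc$output == o & pc$parameter == dummy, ]
    for (p in setdiff(unique(pc$parameter), dummy)) {
      x <- pc[pc$output == o & pc$parameter == p, ]
      p_si <- tryCatch(stats::t.test(x$Si, d$Si)$p.value, error = function(e) NA_real_)
      p_sti <- tryCatch(stats::t.test(x$STi, d$STi)$p.value, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        output = o, parameter = p, p_Si = p_si, p_STi = p_sti)
    }
  }
  dplyr::bind_rows(rows)
}
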