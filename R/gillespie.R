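#' Exact stochastic simulation of the cell-state model
#'
#' Simulates the continuous-time Markov jump process whose mean field is the
#' deterministic model of [simulate_ode()], using the Doob-Gillespie
#' algorithm. The LPS-dependent activation propensity varies continuously
#' in time; it is handled exactly by thinning against the propensity at the
#' current time, which bounds the future propensity because the LPS level
#' decays monotonically between stimulation events. All cells start
#' negative. Total cell number is conserved exactly (every reaction moves
#' one cell).
#'
#' Reproducibility: the run draws from R's RNG, so a fixed `seed` gives an
#' identical trajectory.
#'
#' @param params A [rate_parameters()] object.
#' @param protocol A [stimulation_protocol()].
#' @param t_grid_h Reporting times in hours (the jump process is sampled
#'   piecewise-constant: state just before each grid time).
#' @param spec A [model_spec()]; default 3-state.
#' @param n_cells Total number of simulated cells (default 1000).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return A `norm_trajectory` tibble (as [simulate_ode()]) with attributes
#'   `seed` and `n_events` (total reactions fired).
#' @examples
#' tr <- simulate_gillespie(rate_parameters(0.2, 0.3, 0.05, 0.2),
#'                          condition_protocol("1000"), 0:16, seed = 1)
#' attr(tr, "n_events")
#' @export
simulate_gillespie <- function(params, protocol, t_grid_h,
                               spec = model_spec(3), n_cells = 1000,
                               seed = NULL) {
  stopifnot(inherits(params, "norm_rates"), inherits(protocol, "norm_protocol"))
  check_spec_params(spec, params)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  t_grid_h <- sort(as.numeric(t_grid_h))
  if (any(t_grid_h < 0)) stop("`t_grid_h` must be non-negative", call. = FALSE)
  t_max <- max(t_grid_h, 1e-9)
  if (!is.null(seed)) set.seed(seed)
  segs <- protocol_segments(protocol, t_max, params$delta)
  res <- norm_gillespie_cpp(
    c(params$alpha, params$beta, params$beta2, params$gamma1, params$gamma2,
      params$mu, params$delta),
    cbind(segs$t0_h / 24, segs$t1_h / 24, segs$L0),
    c(n_cells, 0L, 0L, 0L),
    t_grid_h / 24)
  st <- res$states
  out <- tibble::tibble(time_h = t_grid_h,
                        lps = lps_concentration(protocol, t_grid_h, params$delta),
                        negative = st[, 1], positive = st[, 2],
                        nrs = st[, 3], nrps = st[, 4])
  out <- new_trajectory(out, params, spec, n_cells)
  attr(out, "seed") <- seed
  attr(out, "n_events") <- res$n_events
  out
}

#' Ensemble of stochastic runs with mean and standard-error summaries
#'
#' Runs [simulate_gillespie()] `n_reps` times with per-replicate seeds
#' derived from `base_seed` (replicate `i` uses `base_seed + i`, so the
#' ensemble is order-independent and reproducible) and summarises the state
#' counts per reporting time.
#'
#' @inheritParams simulate_gillespie
#' @param n_reps Number of independent replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param keep_runs Keep the per-replicate long table (default TRUE).
#' @return A tibble of class `norm_ensemble`: one row per (time, state) with
#'   columns `mean`, `se` (NA when `n_reps = 1`) and `n_reps`. The
#'   per-replicate table, if kept, is in attribute `runs`.
#' @examples
#' ens <- simulate_ensemble(rate_parameters(0.2, 0.3, 0.05, 0.2),
#'                          condition_protocol("1000"), c(8, 16),
#'                          n_reps = 5, base_seed = 1)
#' @export
simulate_ensemble <- function(params, protocol, t_grid_h,
                              spec = model_spec(3), n_cells = 1000,
                              n_reps = 30, base_seed = 1, keep_runs = TRUE) {
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  runs <- purrr::map_dfr(seq_len(n_reps), function(i) {
    tr <- simulate_gillespie(params, protocol, t_grid_h, spec, n_cells,
                             seed = base_seed + i)
    tibble::tibble(rep = i, seed = base_seed + i, time_h = tr$time_h,
                   negative = tr$negative, positive = tr$positive,
                   nrs = tr$nrs, nrps = tr$nrps)
  })
  long <- tidyr::pivot_longer(runs, c("negative", "positive", "nrs", "nrps"),
                              names_to = "state", values_to = "count")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$time_h, .data$state),
    mean = mean(.data$count),
    se = if (dplyr::n() > 1) stats::sd(.data$count) / sqrt(dplyr::n()) else NA_real_,
    n_reps = dplyr::n(),
    .groups = "drop")
  summ$state <- factor(summ$state, levels = c("negative", "positive", "nrs", "nrps"))
  summ <- dplyr::arrange(summ, .data$time_h, .data$state)
  attr(summ, "params") <- params
  attr(summ, "base_seed") <- base_seed
  attr(summ, "n_cells") <- n_cells
  if (keep_runs) attr(summ, "runs") <- runs
  class(summ) <- c("norm_ensemble", class(summ))
  summ
}
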