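#' Ground-truth rate presets for the synthetic observation generator
#'
#' Named illustrative parameter sets, one per protein, drawn from the
#' support of the fitting prior (U[0.01, 1] per rate). They are synthetic
#' defaults for exercising the inference workflow with a known ground
#' truth, not fitted values. The `raw_like` presets give slower kinetics
#' than the `bmdm_like` ones, echoing the slower responses of the cell
#' line relative to primary macrophages.
#'
#' @param cell_type `"raw_like"` or `"bmdm_like"`.
#' @return A named list of [rate_parameters()] objects, one per protein
#'   (TNF, IL6, proIL1b, NOS2).
#' @export
synthetic_truth_presets <- function(cell_type = c("raw_like", "bmdm_like")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "raw_like") {
    list(
      TNF     = rate_parameters(alpha = 0.15, beta = 0.45, beta2 = 0.10, gamma1 = 0.60),
      IL6     = rate_parameters(alpha = 0.08, beta = 0.30, beta2 = 0.05, gamma1 = 0.35),
      proIL1b = rate_parameters(alpha = 0.25, beta = 0.20, beta2 = 0.08, gamma1 = 0.25),
      NOS2    = rate_parameters(alpha = 0.12, beta = 0.10, beta2 = 0.15, gamma1 = 0.15))
  } else {
    list(
      TNF     = rate_parameters(alpha = 0.40, beta = 0.80, beta2 = 0.10, gamma1 = 0.90),
      IL6     = rate_parameters(alpha = 0.20, beta = 0.50, beta2 = 0.05, gamma1 = 0.50),
      proIL1b = rate_parameters(alpha = 0.50, beta = 0.35, beta2 = 0.08, gamma1 = 0.40),
      NOS2    = rate_parameters(alpha = 0.30, beta = 0.15, beta2 = 0.15, gamma1 = 0.20))
  }
}

#' Synthetic flow-cytometry experiment design
#'
#' Describes the design the synthetic generator emulates: per-condition
#' stimulation protocols (media or LPS pre-treatment for 24 h followed by a
#' 1000 ng/ml challenge), measurement times relative to the challenge, the
#' number of cells acquired per sample, and per-protein ground-truth rates.
#' The `raw_like` design measures at 8/12/16 h post-challenge, the
#' `bmdm_like` design at 4/8/12 h, matching the faster kinetics of primary
#' cells.
#'
#' @param cell_type `"raw_like"` or `"bmdm_like"`.
#' @param conditions Condition labels (see [condition_protocol()]).
#' @param times_h Measurement times (hours post-challenge); defaults depend
#'   on `cell_type`.
#' @param cells_per_sample Cells acquired per sample (default 10000).
#' @param proteins Which proteins to include (subset of the preset names).
#' @param truth Named list of [rate_parameters()] overriding the presets.
#' @return An object of class `norm_design`.
#' @examples
#' experiment_design("bmdm_like", proteins = c("TNF", "IL6"))
#' @export
experiment_design <- function(cell_type = c("raw_like", "bmdm_like"),
                              conditions = c("Media/1000", "10/1000", "1000/1000"),
                              times_h = NULL, cells_per_sample = 10000,
                              proteins = c("TNF", "IL6", "proIL1b", "NOS2"),
                              truth = NULL) {
  cell_type <- match.arg(cell_type)
  if (is.null(times_h)) {
    times_h <- if (cell_type == "raw_like") c(8, 12, 16) else c(4, 8, 12)
  }
  if (cells_per_sample < 1) stop("`cells_per_sample` must be >= 1", call. = FALSE)
  presets <- synthetic_truth_presets(cell_type)
  proteins <- match.arg(proteins, names(presets), several.ok = TRUE)
  truth_all <- presets[proteins]
  if (!is.null(truth)) {
    stopifnot(all(names(truth) %in% proteins))
    truth_all[names(truth)] <- truth
  }
  structure(list(cell_type = cell_type, conditions = conditions,
                 times_h = times_h, cells_per_sample = cells_per_sample,
                 proteins = proteins, truth = truth_all),
            class = "norm_design")
}

#' @export
print.norm_design <- function(x, ...) {
  cat(sprintf("<norm_design> %s: %d proteins x %d conditions x %d times, %d cells/sample\n",
              x$cell_type, length(x$proteins), length(x$conditions),
              length(x$times_h), x$cells_per_sample))
  invisible(x)
}

#' Generate a synthetic observation set with known ground truth
#'
#' For every protein, condition and measurement time, propagates the
#' ground-truth model to the true positive fraction, then draws the
#' observed number of positive cells as a binomial sample of
#' `cells_per_sample` cells — the statistical structure of a
#' fraction-positive flow-cytometry readout. Observation noise is binomial
#' only (no instrument or gating noise).
#'
#' @param design An [experiment_design()].
#' @param spec A [model_spec()] the truth is propagated under (default
#'   3-state; ground-truth `gamma2` is ignored unless the 4-state spec is
#'   used).
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A tibble of class `norm_observations` with columns `protein`,
#'   `cell_type`, `condition`, `time_h` (post-challenge), `fraction_positive`,
#'   `n_cells`, and the sealed ground truth in attribute `ground_truth`
#'   (retrievable with [ground_truth()]).
#' @examples
#' obs <- generate_observations(experiment_design("raw_like", proteins = "TNF"),
#'                              seed = 3)
#' obs
#' @export
generate_observations <- function(design, spec = model_spec(3), seed = 1) {
  stopifnot(inherits(design, "norm_design"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (prot in design$proteins) {
    pp <- design$truth[[prot]]
    if (spec$n_states < 4) {
      pp <- rate_parameters(pp$alpha, pp$beta,
                            if (spec$n_states >= 3) pp$beta2 else 0,
                            if (spec$n_states >= 3) pp$gamma1 else 0, 0,
                            pp$mu, pp$delta)
    }
    for (cond in design$conditions) {
      prot_l <- condition_protocol(cond)
      offset <- condition_clock_offset(cond)
      t_abs <- design$times_h + offset
      tr <- simulate_ode(pp, prot_l, sort(unique(t_abs)), spec, n_cells = 1)
      p_true <- tr$f_positive[match(t_abs, tr$time_h)]
      x <- stats::rbinom(length(p_true), design$cells_per_sample, p_true)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        protein = prot, cell_type = design$cell_type, condition = cond,
        time_h = design$times_h, fraction_positive = x / design$cells_per_sample,
        n_cells = design$cells_per_sample, .true = p_true)
    }
  }
  out <- dplyr::bind_rows(rows)
  truth_frac <- out[c("protein", "condition", "time_h")]
  truth_frac$true_fraction <- out$.true
  out$.true <- NULL
  truth_tab <- dplyr::bind_rows(lapply(design$truth, as_tibble.norm_rates))
  truth_tab <- dplyr::bind_cols(tibble::tibble(protein = names(design$truth)), truth_tab)
  attr(out, "ground_truth") <- truth_tab
  attr(out, "true_fractions") <- truth_frac
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  class(out) <- c("norm_observations", class(out))
  out
}

#' Ground truth sealed in a synthetic observation set
#' @param observations A [generate_observations()] result.
#' @return A tibble of the true rates, one row per protein.
#' @export
ground_truth <- function(observations) {
  gt <- attr(observations, "ground_truth")
  if (is.null(gt)) stop("no sealed ground truth on this observation set", call. = FALSE)
  gt
}

OBS_COLUMNS <- c("protein", "cell_type", "condition", "time_h",
                 "fraction_positive", "n_cells")

validate_observations <- function(observations) {
  observations <- tibble::as_tibble(observations)
  need <- c("condition", "time_h", "fraction_positive")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("observations lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(observations) == 0L) stop("empty observation set", call. = FALSE)
  if (any(observations$fraction_positive < 0 | observations$fraction_positive > 1)) {
    stop("`fraction_positive` must lie in [0, 1]", call. = FALSE)
  }
  if (any(observations$time_h < 0)) stop("`time_h` must be non-negative", call. = FALSE)
  observations
}

#' Read / write observation tables
#'
#' Plain-CSV serialisation of an observation set with the schema
#' `protein, cell_type, condition, time_h, fraction_positive, n_cells`
#' (extra columns are preserved). Round-trips losslessly.
#'
#' @param path File path.
#' @return `read_observations()` returns the observation tibble.
#' @export
read_observations <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  validate_observations(out)
}

#' @param observations The observation tibble to write.
#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  validate_observations(observations)
  readr::write_csv(observations, path)
  invisible(path)
}

#' Sixteen-subset community composition from four marginal fractions
#'
#' Expands the four per-protein positive fractions into the frequencies of
#' the 2^4 = 16 positive/negative combination subsets (the SPICE-style
#' community chart), assuming independence across proteins — a reporting
#' convenience, not a claim about the underlying biology. Frequencies are
#' products of marginals and sum to 1; summing over a protein's positive
#' patterns recovers its marginal.
#'
#' @param marginals Named numeric vector of four positive fractions in
#'   `[0, 1]` (names become the pattern columns).
#' @return A tibble with one row per subset: a logical column per protein,
#'   a `pattern` label such as `"TNF+IL6-proIL1b+NOS2-"`, and `frequency`.
#' @examples
#' community_composition(c(TNF = 0.5, IL6 = 0.5, proIL1b = 0.5, NOS2 = 0.5))
#' @export
community_composition <- function(marginals) {
  if (is.null(names(marginals)) || any(!nzchar(names(marginals)))) {
    stop("`marginals` must be named", call. = FALSE)
  }
  if (any(marginals < 0 | marginals > 1)) {
    stop("marginals must lie in [0, 1]", call. = FALSE)
  }
  k <- length(marginals)
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(grid) <- names(marginals)
  freq <- apply(grid, 1L, function(sgn) {
    prod(ifelse(sgn, marginals, 1 - marginals))
  })
  pattern <- apply(grid, 1L, function(sgn) {
    paste0(names(marginals), ifelse(sgn, "+", "-"), collapse = "")
  })
  out <- tibble::as_tibble(grid)
  out$pattern <- pattern
  out$frequency <- freq
  dplyr::arrange(out, dplyr::desc(.data$frequency))
}

#' Cell-state composition at stated readout times
#'
#' Mean-field fractions of cells in each of the four states under a
#' protocol, at one or more readout times — the composition summary used
#' to compare single- and two-dose stimulations (readouts at 12 h for
#' BMDM-like or 16 h for RAW-like kinetics). Under a 3-state spec the NRPS
#' fraction is identically 0.
#'
#' @param params A [rate_parameters()] object.
#' @param protocol A [stimulation_protocol()].
#' @param readout_times_h Readout times in hours.
#' @param spec A [model_spec()].
#' @return A tibble with columns `time_h`, `state`, `fraction` (fractions
#'   sum to 1 at each readout).
#' @examples
#' state_composition_report(rate_parameters(0.2, 0.3, 0.05, 0.3),
#'                          condition_protocol("1000"), 16)
#' @export
state_composition_report <- function(params, protocol, readout_times_h,
                                     spec = model_spec(3)) {
  tr <- simulate_ode(params, protocol, sort(unique(readout_times_h)), spec,
                     n_cells = 1)
  long <- tidyr::pivot_longer(
    tr[c("time_h", "f_negative", "f_positive", "f_nrs", "f_nrps")],
    -"time_h", names_to = "state", values_to = "fraction")
  long$state <- factor(sub("^f_", "", long$state),
                       levels = c("negative", "positive", "nrs", "nrps"))
  tibble::as_tibble(long)
}
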