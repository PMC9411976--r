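#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the retained parameter sets of a rejection fit
#'
#' One row per retained parameter set (ascending AIC) with the sampled
#' rates, `rmsd`, `rss`, `aic` and `rank`.
#'
#' @param x A `norm_fit` from [rejection_fit()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.norm_fit <- function(x, ...) {
  x$samples
}

#' One-row summary of a rejection fit
#'
#' @param x A `norm_fit` from [rejection_fit()].
#' @param ... Unused.
#' @return A one-row tibble with `n_states`, `n_samples`, `top_k`,
#'   `best_rmsd`, `mean_rmsd`, `min_aic`, `mean_aic`, `n_failed`, `seed`.
#' @export
glance.norm_fit <- function(x, ...) {
  tibble::tibble(
    n_states = x$spec$n_states,
    n_samples = x$n_samples,
    top_k = nrow(x$samples),
    best_rmsd = min(x$samples$rmsd),
    mean_rmsd = mean(x$samples$rmsd),
    min_aic = min(x$samples$aic),
    mean_aic = mean(x$samples$aic),
    n_failed = x$n_failed,
    seed = x$seed)
}

#' Tidy eFAST indices into long format
#'
#' @param x A `norm_sensitivity` from [efast_analyze()].
#' @param ... Unused.
#' @return A long tibble (`output`, `parameter`, `index` in Si/STi, `value`,
#'   `sd`).
#' @export
tidy.norm_sensitivity <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c("output", "parameter", "Si", "STi")],
    c("Si", "STi"), names_to = "index", values_to = "value")
  sds <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c("output", "parameter", "Si_sd", "STi_sd")],
    c("Si_sd", "STi_sd"), names_to = "index", values_to = "sd")
  long$sd <- sds$sd
  long
}
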