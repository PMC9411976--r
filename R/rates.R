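#' Transition-rate parameters for the macrophage cell-state model
#'
#' Bundles the five transition rates of the four-state activation model
#' together with the two fixed LPS constants. All rates are expressed per
#' day; user-facing time arguments elsewhere in the package are in hours
#' and converted internally (24 h = 1 rate-time unit).
#'
#' The states are: negative (not producing the protein), positive
#' (producing), NRS (reversibly non-responsive) and NRPS (permanently
#' non-responsive). Transitions are
#' negative -> positive at `alpha * (1 + mu * L)` where `L` is the ambient
#' LPS concentration (normalized so 1000 ng/ml = 1), positive -> negative
#' at `beta`, positive -> NRS at `gamma1`, NRS -> negative at `beta2`, and
#' NRS -> NRPS at `gamma2`.
#'
#' Setting `gamma2 = 0` collapses the four-state model to the three-state
#' model; additionally setting `gamma1 = 0` collapses to the two-state
#' (negative/positive) switch.
#'
#' @param alpha Base negative -> positive rate in the absence of LPS (per day).
#' @param beta Positive -> negative rate (per day).
#' @param beta2 NRS -> negative recovery rate (per day).
#' @param gamma1 Positive -> NRS rate (per day).
#' @param gamma2 NRS -> NRPS absorption rate (per day).
#' @param mu Dimensionless LPS response coefficient (fixed at 10 by default).
#' @param delta LPS decay rate (per day; 0.5 by default, i.e. roughly a
#'   one-day effective decay at the highest dose).
#'
#' @return An object of class `norm_rates`: a named list of the seven values.
#' @examples
#' rate_parameters(alpha = 0.1, beta = 0.3, gamma1 = 0.2)
#' @export
rate_parameters <- function(alpha, beta, beta2 = 0, gamma1 = 0, gamma2 = 0,
                            mu = 10, delta = 0.5) {
  p <- list(alpha = alpha, beta = beta, beta2 = beta2,
            gamma1 = gamma1, gamma2 = gamma2, mu = mu, delta = delta)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("`", nm, "` must be non-negative", call. = FALSE)
  }
  structure(p, class = "norm_rates")
}

#' @export
print.norm_rates <- function(x, ...) {
  cat("<norm_rates> (per day)\n")
  cat(sprintf("  alpha=%.4g beta=%.4g beta2=%.4g gamma1=%.4g gamma2=%.4g\n",
              x$alpha, x$beta, x$beta2, x$gamma1, x$gamma2))
  cat(sprintf("  mu=%.4g (fixed)  delta=%.4g/d (fixed)\n", x$mu, x$delta))
  invisible(x)
}

#' Convert a rates object to a one-row tibble
#' @param x A `norm_rates` object.
#' @param ... Unused.
#' @export
as_tibble.norm_rates <- function(x, ...) {
  tibble::as_tibble(unclass(x)[RATE_NAMES_ALL])
}

RATE_NAMES_FREE <- c("alpha", "beta", "beta2", "gamma1", "gamma2")
RATE_NAMES_ALL <- c(RATE_NAMES_FREE, "mu", "delta")

#' Model specification: number of cell states and free parameters
#'
#' The two-state model frees `alpha` and `beta`; the three-state model adds
#' `beta2` and `gamma1`; the four-state model adds `gamma2`. The LPS
#' constants `mu` and `delta` are never estimated.
#'
#' @param n_states 2, 3 or 4.
#' @return An object of class `norm_model_spec` with elements `n_states`,
#'   `free_parameters` and `k` (the number of free rates, used in the AIC
#'   penalty).
#' @examples
#' model_spec(3)$free_parameters
#' @export
model_spec <- function(n_states = 3) {
  if (!n_states %in% c(2, 3, 4)) stop("`n_states` must be 2, 3 or 4", call. = FALSE)
  free <- switch(as.character(n_states),
                 "2" = c("alpha", "beta"),
                 "3" = c("alpha", "beta", "beta2", "gamma1"),
                 "4" = c("alpha", "beta", "beta2", "gamma1", "gamma2"))
  structure(list(n_states = n_states, free_parameters = free, k = length(free)),
            class = "norm_model_spec")
}

#' @export
print.norm_model_spec <- function(x, ...) {
  cat(sprintf("<norm_model_spec> %d states; free: %s (k=%d)\n",
              x$n_states, paste(x$free_parameters, collapse = ", "), x$k))
  invisible(x)
}

# A params/spec pair is inconsistent when the params switch on a transition
# the spec's state space cannot represent.
check_spec_params <- function(spec, params) {
  if (spec$n_states < 4 && params$gamma2 > 0) {
    stop("gamma2 > 0 requires the 4-state model", call. = FALSE)
  }
  if (spec$n_states < 3 && (params$gamma1 > 0 || params$beta2 > 0)) {
    stop("gamma1/beta2 > 0 require at least the 3-state model", call. = FALSE)
  }
  invisible(TRUE)
}

#' LPS-boosted forward activation rate
#'
#' The negative -> positive rate is modelled as a linear function of the
#' ambient LPS concentration: `alpha * (1 + mu * L)`. With no LPS it
#' reduces to the base rate `alpha`.
#'
#' @param params A [rate_parameters()] object.
#' @param L LPS concentration in normalized units (1000 ng/ml = 1); may be a
#'   vector.
#' @return The effective rate(s), per day.
#' @examples
#' effective_alpha(rate_parameters(0.1, 0.3), L = 1) # 0.1 * (1 + 10)
#' @export
effective_alpha <- function(params, L) {
  stopifnot(inherits(params, "norm_rates"))
  if (any(L < 0)) stop("LPS concentration must be non-negative", call. = FALSE)
  params$alpha * (1 + params$mu * L)
}
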