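#' Mean-field derivative of the cell-state model
#'
#' Right-hand side of the deterministic (mean-field) ODE system at a given
#' LPS concentration. States are ordered negative, positive, NRS, NRPS;
#' derivatives are per day and always sum to zero (the total cell number is
#' conserved).
#'
#' @param spec A [model_spec()].
#' @param params A [rate_parameters()] object, consistent with `spec`.
#' @param state Numeric vector `c(negative, positive, nrs, nrps)` (counts or
#'   fractions).
#' @param L Ambient LPS concentration (normalized units).
#' @return Named numeric derivative vector of length 4.
#' @examples
#' ode_rhs(model_spec(3), rate_parameters(0.2, 0.1, 0.05, 0.3),
#'         c(negative = 1000, positive = 0, nrs = 0, nrps = 0), L = 1)
#' @export
ode_rhs <- function(spec, params, state, L) {
  stopifnot(inherits(spec, "norm_model_spec"), inherits(params, "norm_rates"))
  check_spec_params(spec, params)
  if (length(state) != 4L) stop("`state` must have 4 components", call. = FALSE)
  if (L < 0) stop("LPS concentration must be non-negative", call. = FALSE)
  a <- params$alpha * (1 + params$mu * L)
  N <- state[[1]]; P <- state[[2]]; NR <- state[[3]]
  c(negative = -N * a + params$beta * P + params$beta2 * NR,
    positive = N * a - params$beta * P - params$gamma1 * P,
    nrs      = params$gamma1 * P - (params$beta2 + params$gamma2) * NR,
    nrps     = params$gamma2 * NR)
}

new_trajectory <- function(df, params, spec, n_cells) {
  df <- tibble::as_tibble(df)
  tot <- df$negative + df$positive + df$nrs + df$nrps
  df$f_negative <- df$negative / tot
  df$f_positive <- df$positive / tot
  df$f_nrs <- df$nrs / tot
  df$f_nrps <- df$nrps / tot
  attr(df, "params") <- params
  attr(df, "spec") <- spec
  attr(df, "n_cells") <- n_cells
  class(df) <- c("norm_trajectory", class(df))
  df
}

#' Deterministic trajectory of the cell-state model
#'
#' Integrates the mean-field ODE system under a stimulation protocol with a
#' stiff-capable adaptive integrator (`deSolve::lsoda`, relative tolerance
#' 1e-8, absolute 1e-10). Integration restarts at every stimulation event,
#' where the LPS concentration is discontinuous. All cells start negative.
#'
#' @param params A [rate_parameters()] object.
#' @param protocol A [stimulation_protocol()].
#' @param t_grid_h Increasing output times in hours (from 0).
#' @param spec A [model_spec()]; default 3-state.
#' @param n_cells Total number of cells (conserved; default 1000).
#' @return A tibble of class `norm_trajectory` with columns `time_h`, `lps`,
#'   the four state counts and the four state fractions (`f_*`).
#' @examples
#' tr <- simulate_ode(rate_parameters(0.2, 0.3, 0.05, 0.2),
#'                    condition_protocol("1000"), t_grid_h = 0:24)
#' head(tr)
#' @export
simulate_ode <- function(params, protocol, t_grid_h, spec = model_spec(3),
                         n_cells = 1000) {
  stopifnot(inherits(params, "norm_rates"), inherits(protocol, "norm_protocol"))
  check_spec_params(spec, params)
  t_grid_h <- as.numeric(t_grid_h)
  if (is.unsorted(t_grid_h) || any(t_grid_h < 0)) {
    stop("`t_grid_h` must be non-negative and increasing", call. = FALSE)
  }
  t_max <- max(t_grid_h)
  segs <- protocol_segments(protocol, max(t_max, 1e-9), params$delta)
  delta <- params$delta

  deriv <- function(t_d, y, parms) {
    L <- parms$L0 * exp(-delta * (t_d - parms$t0_d))
    a <- params$alpha * (1 + params$mu * L)
    dN <- -y[1] * a + params$beta * y[2] + params$beta2 * y[3]
    dP <- y[1] * a - (params$beta + params$gamma1) * y[2]
    dNR <- params$gamma1 * y[2] - (params$beta2 + params$gamma2) * y[3]
    dNRPS <- params$gamma2 * y[3]
    list(c(dN, dP, dNR, dNRPS))
  }

  y <- c(n_cells, 0, 0, 0)
  rows <- vector("list", nrow(segs) + 1L)
  if (any(t_grid_h == 0)) {
    rows[[1]] <- data.frame(time_h = 0, negative = y[1], positive = y[2],
                            nrs = y[3], nrps = y[4])
  }
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$t0_h[i]; t1 <- segs$t1_h[i]
    inner <- sort(unique(t_grid_h[t_grid_h > t0 & t_grid_h <= t1]))
    times_h_seg <- sort(unique(c(t0, inner, t1)))
    sol <- deSolve::lsoda(y, times_h_seg / 24, deriv,
                          parms = list(L0 = segs$L0[i], t0_d = t0 / 24),
                          rtol = 1e-8, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed on segment [", t0, ", ", t1, "] h: ",
           "istate = ", attr(sol, "istate")[1], call. = FALSE)
    }
    keep <- times_h_seg %in% inner
    if (any(keep)) {
      rows[[i + 1L]] <- data.frame(time_h = times_h_seg[keep],
                                   negative = sol[keep, 2], positive = sol[keep, 3],
                                   nrs = sol[keep, 4], nrps = sol[keep, 5])
    }
    y <- as.numeric(sol[nrow(sol), -1])
  }
  out <- dplyr::bind_rows(rows)
  out <- out[match(t_grid_h, out$time_h), , drop = FALSE]
  out$lps <- lps_concentration(protocol, out$time_h, params$delta)
  out <- out[, c("time_h", "lps", "negative", "positive", "nrs", "nrps")]
  new_trajectory(out, params, spec, n_cells)
}

#' No-LPS equilibrium of the two-state switch
#'
#' With no LPS the negative/positive switch relaxes to
#' `P* = T * alpha / (alpha + beta)` (equivalently `P*/N* = alpha/beta`).
#'
#' @param params A [rate_parameters()] object; `alpha + beta` must be > 0.
#' @param n_cells Total cell count `T`.
#' @return The equilibrium positive count.
#' @examples
#' equilibrium_positive(rate_parameters(0.2, 0.1), 900) # 600
#' @export
equilibrium_positive <- function(params, n_cells = 1000) {
  stopifnot(inherits(params, "norm_rates"))
  if (params$alpha + params$beta <= 0) {
    stop("degenerate input: alpha + beta must be positive", call. = FALSE)
  }
  n_cells * params$alpha / (params$alpha + params$beta)
}

#' Quasi-equilibrium positive count under decaying LPS
#'
#' When LPS dynamics are slow relative to the negative/positive switch, the
#' positive count tracks the instantaneous equilibrium obtained by setting
#' dP/dt = 0 with `L = L0 * exp(-delta * t)`:
#' `P_q(t) = T * a / (a + beta/alpha)` with `a = 1 + mu * L0 * exp(-delta t)`.
#' At `L0 = 0` this reduces to [equilibrium_positive()].
#'
#' @param params A [rate_parameters()] object.
#' @param L0 Initial LPS concentration (normalized units).
#' @param t_h Time(s) since the dose, in hours.
#' @param n_cells Total cell count.
#' @return Quasi-equilibrium positive count(s).
#' @export
quasi_equilibrium_positive <- function(params, L0, t_h, n_cells = 1000) {
  stopifnot(inherits(params, "norm_rates"))
  if (L0 < 0) stop("`L0` must be non-negative", call. = FALSE)
  if (any(t_h < 0)) stop("`t_h` must be non-negative", call. = FALSE)
  a <- params$alpha * (1 + params$mu * L0 * exp(-params$delta * t_h / 24))
  n_cells * a / (a + params$beta)
}

#' Closed-form positive count of the two-state model under decaying LPS
#'
#' Exact solution of the two-state mean-field equation
#' `dP/dt = (T - P) alpha (1 + mu L) - beta P` with `L = L0 exp(-delta t)`
#' and `P(0) = 0`, evaluated by adaptive quadrature of its integral term.
#' The integrand is computed in a form whose exponent is always
#' non-positive, so the evaluation cannot overflow even for large `t` or
#' stiff rate combinations.
#'
#' @param params A [rate_parameters()] object (used with `gamma1 = gamma2 = 0`).
#' @param L0 Initial LPS concentration (normalized units).
#' @param t_h Evaluation time(s) in hours, >= 0.
#' @param n_cells Total cell count `T`.
#' @return Positive count(s) `P(t)`, with `P(0) = 0` and `0 <= P <= T`.
#' @examples
#' p <- rate_parameters(0.3, 0.6)
#' closed_form_two_state(p, L0 = 1, t_h = 12)
#' @export
closed_form_two_state <- function(params, L0, t_h, n_cells = 1000) {
  stopifnot(inherits(params, "norm_rates"))
  if (L0 < 0) stop("`L0` must be non-negative", call. = FALSE)
  if (any(t_h < 0)) stop("`t_h` must be non-negative", call. = FALSE)
  al <- params$alpha; be <- params$beta; mu <- params$mu; de <- params$delta
  vapply(t_h / 24, function(t_d) {
    if (t_d == 0) return(0)
    if (de == 0 || L0 == 0) {
      # constant LPS: plain linear relaxation at the boosted rate
      a <- al * (1 + mu * L0)
      return(n_cells * a / (a + be) * (1 - exp(-(a + be) * t_d)))
    }
    # P(t) = int_0^t T a (1 + mu L0 e^{-de s})
    #          exp(-(a+b)(t-s) + a mu L0 (e^{-de t} - e^{-de s}) / de) ds;
    # the exponent is <= 0 for all s in [0, t].
    integrand <- function(s) {
      n_cells * al * (1 + mu * L0 * exp(-de * s)) *
        exp(-(al + be) * (t_d - s) +
              al * mu * L0 * (exp(-de * t_d) - exp(-de * s)) / de)
    }
    q <- stats::integrate(integrand, 0, t_d, abs.tol = 1e-10, rel.tol = 1e-10,
                          subdivisions = 500L)
    if (q$message != "OK") {
      stop("quadrature failed: ", q$message, call. = FALSE)
    }
    min(q$value, n_cells)
  }, numeric(1))
}
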