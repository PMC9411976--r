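# Shared fixtures and independent oracles for the test suite.

# Random rate sets drawn from the fitting-prior support.
random_rates <- function(n, n_states = 4, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    rate_parameters(
      alpha = runif(1, 0.01, 1), beta = runif(1, 0.01, 1),
      beta2 = if (n_states >= 3) runif(1, 0.01, 1) else 0,
      gamma1 = if (n_states >= 3) runif(1, 0.01, 1) else 0,
      gamma2 = if (n_states >= 4) runif(1, 0.01, 1) else 0)
  })
}

# Single-cell CTMC generator for the 4-state model at fixed LPS level.
ctmc_generator <- function(params, L) {
  a <- params$alpha * (1 + params$mu * L)
  Q <- matrix(0, 4, 4,
              dimnames = list(c("N", "P", "NR", "NRPS"),
                              c("N", "P", "NR", "NRPS")))
  Q["N", "P"] <- a
  Q["P", "N"] <- params$beta; Q["P", "NR"] <- params$gamma1
  Q["NR", "N"] <- params$beta2; Q["NR", "NRPS"] <- params$gamma2
  diag(Q) <- -rowSums(Q)
  Q
}

# Occupation probabilities at time t (days) from the all-negative start,
# by matrix exponential of the master equation (independent of the
# Gillespie path being tested).
ctmc_probs <- function(params, L, t_d) {
  Q <- ctmc_generator(params, L)
  as.numeric(c(1, 0, 0, 0) %*% as.matrix(Matrix::expm(Q * t_d)))
}

ishigami <- function(x1, x2, x3, a = 7, b = 0.1) {
  sin(x1) + a * sin(x2)^2 + b * x3^4 * sin(x1)
}

# Monte-Carlo Sobol pick-freeze oracle (Saltelli estimators) for the
# Ishigami function on U(-pi, pi)^3. Independent of the Fourier-based
# estimator it is used to check.
sobol_mc_ishigami <- function(n = 2^17, seed = 99) {
  set.seed(seed)
  A <- matrix(runif(3 * n, -pi, pi), n, 3)
  B <- matrix(runif(3 * n, -pi, pi), n, 3)
  yA <- ishigami(A[, 1], A[, 2], A[, 3])
  yB <- ishigami(B[, 1], B[, 2], B[, 3])
  V <- stats::var(c(yA, yB))
  Si <- STi <- numeric(3)
  for (i in 1:3) {
    ABi <- A; ABi[, i] <- B[, i]
    yABi <- ishigami(ABi[, 1], ABi[, 2], ABi[, 3])
    Si[i] <- mean(yB * (yABi - yA)) / V
    STi[i] <- mean((yA - yABi)^2) / (2 * V)
  }
  list(Si = Si, STi = STi)
}

# Peak response amplitude within [t_from, t_to] hours: the maximum rise of
# the positive fraction above its value at window entry, per parameter row.
# For a first stimulation from the all-negative start the baseline is 0 and
# this is simply the peak positive fraction.
peak_response <- function(par, protocol, t_from, t_to, by = 0.5) {
  grid <- seq(t_from, t_to, by = by)
  pf <- batch_state_fractions(par, protocol, grid)$positive
  apply(pf - pf[, 1], 1, max)
}
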