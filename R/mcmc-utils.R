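## Shared MCMC infrastructure: split-chain convergence diagnostics, effective
## sample sizes, adaptive random-walk helpers, and small-matrix samplers used
## by both hierarchical models.

#' Split-chain potential scale reduction factor
#'
#' Computes the split-chain Rhat statistic for each parameter of a draws
#' array. Chains are split in half so that within-chain trends inflate the
#' statistic.
#'
#' @param x Numeric array of dimension (iterations, chains, parameters) or a
#'   matrix (iterations, chains) for a single parameter.
#' @return Numeric vector of Rhat values, one per parameter.
#' @export
split_rhat <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[1]; m <- dim(x)[2]; p <- dim(x)[3]
  half <- n %/% 2L
  ## stack the two halves of every chain as separate chains
  y <- array(NA_real_, c(half, 2L * m, p))
  y[, seq_len(m), ] <- x[seq_len(half), , , drop = FALSE]
  y[, m + seq_len(m), ] <- x[(n - half + 1L):n, , , drop = FALSE]
  cm <- apply(y, c(2L, 3L), mean)            # chain means: (2m, p)
  cv <- apply(y, c(2L, 3L), stats::var)      # chain vars:  (2m, p)
  W <- colMeans(cv)
  B <- half * apply(cm, 2L, stats::var)
  vplus <- (half - 1) / half * W + B / half
  r <- sqrt(vplus / W)
  r[W < .Machine$double.eps] <- 1            # degenerate (constant) parameters
  r
}

#' Effective sample size via initial positive autocorrelation sums
#'
#' @param x Matrix (iterations, chains) of draws for one parameter.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::var(as.vector(x)) < .Machine$double.eps) return(n * m)
  maxlag <- min(n - 2L, 200L)
  rho <- rowMeans(sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = maxlag, plot = FALSE)$acf[-1]
    as.vector(a)
  }))
  ## Geyer-style truncation at the first negative paired sum
  s <- 0
  k <- 1L
  while (k < length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, n * m / (1 + 2 * s))
}

## Robbins-Monro style log-scale adaptation for random-walk proposals.
adapt_scale <- function(log_scale, accepted, iter, target = 0.35) {
  log_scale + (accepted - target) / max(5, iter)^0.6
}

## log density of a half-Student-t distribution (x > 0)
dhalf_t <- function(x, df, scale, log = TRUE) {
  ld <- log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

## log density of a half-normal distribution (x > 0)
dhalf_norm <- function(x, scale) {
  ld <- log(2) + stats::dnorm(x / scale, log = TRUE) - log(scale)
  ld[x <= 0] <- -Inf
  ld
}

## Build a 3x3 correlation matrix from canonical partial correlations
## p = (rho12, rho13, rho23|1), each in (-1, 1).
cpc_to_corr <- function(p) {
  r12 <- p[1]; r13 <- p[2]
  r23 <- p[3] * sqrt((1 - r12^2) * (1 - r13^2)) + r12 * r13
  matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
}

## log prior density of unconstrained hyperparameters (log tau, atanh cpc)
## under independent half-t priors on tau and an LKJ(eta) prior on the
## correlation matrix, including all transform Jacobians.
lp_hyper <- function(log_tau, x_cpc, tau_df, tau_scale, eta) {
  tau <- exp(log_tau)
  p <- tanh(x_cpc)
  det_omega <- (1 - p[1]^2) * (1 - p[2]^2) * (1 - p[3]^2)
  sum(dhalf_t(tau, tau_df, tau_scale)) + sum(log_tau) +
    (eta - 1) * log(det_omega) +
    0.5 * log((1 - p[1]^2) * (1 - p[2]^2)) +
    sum(log(1 - p^2))
}

## Vectorized sampler for G independent trivariate normals with precision
## matrices sharing the sparsity P = [P11 P12 P13; P12 P22 0; P13 0 P33] + S
## (S a dense 3x3 added to all genes). Arguments are length-G vectors of the
## gene-specific precision entries and right-hand sides; returns list with the
## posterior means (m1..m3) and one draw (u1..u3).
mvn3_gibbs <- function(P11, P12, P13, P22, P23, P33, r1, r2, r3) {
  L11 <- sqrt(P11)
  L21 <- P12 / L11
  L31 <- P13 / L11
  L22 <- sqrt(P22 - L21^2)
  L32 <- (P23 - L31 * L21) / L22
  L33 <- sqrt(P33 - L31^2 - L32^2)
  ## solve P m = r
  y1 <- r1 / L11
  y2 <- (r2 - L21 * y1) / L22
  y3 <- (r3 - L31 * y1 - L32 * y2) / L33
  m3 <- y3 / L33
  m2 <- (y2 - L32 * m3) / L22
  m1 <- (y1 - L21 * m2 - L31 * m3) / L11
  n <- length(P11)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
  w3 <- z3 / L33
  w2 <- (z2 - L32 * w3) / L22
  w1 <- (z1 - L21 * w2 - L31 * w3) / L11
  list(m1 = m1, m2 = m2, m3 = m3,
       u1 = m1 + w1, u2 = m2 + w2, u3 = m3 + w3)
}
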