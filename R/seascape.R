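#' Priors and settings for the geometric seascape model
#'
#' @param z_scale Sd of the Normal(0, z_scale) prior on latent gene
#'   coordinates; anchors the scale of the latent axis (default 2).
#' @param alpha_scale Sd of the Normal(0, .) prior on interval peak selection
#'   rates (default 1; peaks may be negative).
#' @param kappa_scale Scale of the half-Normal prior on interval curvatures
#'   (default 1).
#' @param phi_scale Scale of the half-Normal prior on the
#'   Ornstein-Uhlenbeck reversion rate linking adjacent interval optima
#'   (default 1).
#' @param innovation_scale Scale of the half-Normal prior on the OU
#'   stationary sd of the moving optimum (default 2).
#' @param extra_sd_scale Scale of the half-Normal prior on the residual sd
#'   beyond the propagated per-gene measurement sd (default 0.5).
#' @param midpoints Interval midpoints (days) used for OU time gaps
#'   (default \code{c(0.5, 2.5, 7)}, i.e. gaps 2 and 4.5 days).
#' @param chains,warmup,draws MCMC layout (defaults 4 x 750 + 750).
#' @param seed Integer RNG seed.
#' @return A \code{seascape_priors} list.
#' @export
seascape_priors <- function(z_scale = 2, alpha_scale = 1, kappa_scale = 1,
                            phi_scale = 1, innovation_scale = 2,
                            extra_sd_scale = 0.5,
                            midpoints = c(0.5, 2.5, 7),
                            chains = 4, warmup = 750, draws = 750,
                            seed = 1L) {
  stopifnot(z_scale > 0, alpha_scale > 0, kappa_scale > 0, phi_scale > 0,
            innovation_scale > 0, extra_sd_scale > 0,
            length(midpoints) == 3, all(diff(midpoints) > 0))
  structure(as.list(environment()), class = "seascape_priors")
}

## Quadratic interval landscape
seascape_mu <- function(alpha, kappa, theta, z) {
  alpha - 0.5 * kappa * (z - theta)^2
}

## truncated-normal draw on [0, Inf)
rtnorm0 <- function(mean, sd) {
  p0 <- stats::pnorm(0, mean, sd)
  if (p0 > 1 - 1e-12) return(abs(stats::rnorm(1, 0, sd * 1e-3)))
  x <- stats::qnorm(stats::runif(1, p0, 1), mean, sd)
  if (!is.finite(x) || x < 0) x <- max(mean, 0)
  x
}

## log OU prior for the optimum sequence
lp_theta_ou <- function(theta, phi, sinn, dt) {
  decay <- exp(-phi * dt)
  sd_tr <- pmax(sinn * sqrt(1 - decay^2), 1e-8)
  stats::dnorm(theta[1], 0, sinn, log = TRUE) +
    sum(stats::dnorm(theta[-1], theta[-3] * decay, sd_tr, log = TRUE))
}

.run_seachain <- function(m, sd2, pr, init, n_iter, n_keep) {
  G <- nrow(m)
  z <- init$z; alpha <- init$alpha; kappa <- init$kappa; theta <- init$theta
  log_phi <- init$log_phi; log_sinn <- init$log_sinn; log_sx <- init$log_sx
  dt <- diff(pr$midpoints)
  ls_z <- log(0.4); ls_theta <- rep(log(0.2), 3)
  ls_ou <- log(0.3); ls_sx <- log(0.2); ls_resc <- log(0.1)
  ls_shift <- log(0.1)
  keep_at <- n_iter - n_keep

  z_draws <- matrix(NA_real_, n_keep, G)
  par_draws <- matrix(NA_real_, n_keep, 12,
                      dimnames = list(NULL, c(paste0("alpha", 1:3),
                                              paste0("kappa", 1:3),
                                              paste0("theta", 1:3),
                                              "phi", "innovation_sd",
                                              "extra_sd")))

  loglik_rows <- function(z, alpha, kappa, theta, v) {
    ll <- 0
    for (d in 1:3) {
      r <- m[, d] - seascape_mu(alpha[d], kappa[d], theta[d], z)
      ll <- ll + (-0.5) * (r^2 / v[, d] + log(v[, d]))
    }
    ll
  }

  v <- sd2 + exp(2 * log_sx)

  for (it in seq_len(n_iter)) {
    ## --- latent coordinates: vectorized single-site random walks ---
    for (rep_z in 1:2) {
      zp <- z + exp(ls_z) * stats::rnorm(G)
      ll_cur <- loglik_rows(z, alpha, kappa, theta, v) -
        z^2 / (2 * pr$z_scale^2)
      ll_prop <- loglik_rows(zp, alpha, kappa, theta, v) -
        zp^2 / (2 * pr$z_scale^2)
      acc <- log(stats::runif(G)) < ll_prop - ll_cur
      z[acc] <- zp[acc]
      if (it <= keep_at)
        ls_z <- adapt_scale(ls_z, mean(acc), it, target = 0.44)
    }
    ## mirror proposal: each gene conditional can be bimodal (the quadratics
    ## are symmetric about their optima), so reflect z about the
    ## curvature-weighted optimum (a deterministic involution)
    if (sum(kappa) > 0) {
      zc <- sum(kappa * theta) / sum(kappa)
      zp <- 2 * zc - z
      ll_cur <- loglik_rows(z, alpha, kappa, theta, v) -
        z^2 / (2 * pr$z_scale^2)
      ll_prop <- loglik_rows(zp, alpha, kappa, theta, v) -
        zp^2 / (2 * pr$z_scale^2)
      acc <- log(stats::runif(G)) < ll_prop - ll_cur
      z[acc] <- zp[acc]
    }

    ## --- peaks and curvatures: conjugate normal updates per interval ---
    for (d in 1:3) {
      q <- 0.5 * (z - theta[d])^2
      w <- 1 / v[, d]
      prec_a <- sum(w) + 1 / pr$alpha_scale^2
      mean_a <- sum(w * (m[, d] + kappa[d] * q)) / prec_a
      alpha[d] <- stats::rnorm(1, mean_a, 1 / sqrt(prec_a))
      prec_k <- sum(w * q^2) + 1 / pr$kappa_scale^2
      mean_k <- sum(w * q * (alpha[d] - m[, d])) / prec_k
      kappa[d] <- rtnorm0(mean_k, 1 / sqrt(prec_k))
    }

    ## --- interval optima: scalar MH with OU prior ---
    phi <- exp(log_phi); sinn <- exp(log_sinn)
    for (d in 1:3) {
      lp_d <- function(th_d) {
        th <- theta; th[d] <- th_d
        r <- m[, d] - seascape_mu(alpha[d], kappa[d], th_d, z)
        -0.5 * sum(r^2 / v[, d]) + lp_theta_ou(th, phi, sinn, dt)
      }
      prop <- theta[d] + exp(ls_theta[d]) * stats::rnorm(1)
      a <- 0
      if (log(stats::runif(1)) < lp_d(prop) - lp_d(theta[d])) {
        theta[d] <- prop; a <- 1
      }
      if (it <= keep_at) ls_theta[d] <- adapt_scale(ls_theta[d], a, it)
    }

    ## --- OU hyperparameters ---
    lp_ou <- function(lphi, lsinn) {
      lp_theta_ou(theta, exp(lphi), exp(lsinn), dt) +
        dhalf_norm(exp(lphi), pr$phi_scale) + lphi +
        dhalf_norm(exp(lsinn), pr$innovation_scale) + lsinn
    }
    prop <- c(log_phi, log_sinn) + exp(ls_ou) * stats::rnorm(2)
    a <- 0
    if (log(stats::runif(1)) < lp_ou(prop[1], prop[2]) -
        lp_ou(log_phi, log_sinn)) {
      log_phi <- prop[1]; log_sinn <- prop[2]; a <- 1
    }
    if (it <= keep_at) ls_ou <- adapt_scale(ls_ou, a, it, target = 0.25)

    ## --- residual sd beyond propagated uncertainty ---
    lp_sx <- function(lsx) {
      vv <- sd2 + exp(2 * lsx)
      sum(loglik_rows(z, alpha, kappa, theta, vv)) +
        dhalf_norm(exp(lsx), pr$extra_sd_scale) + lsx
    }
    prop <- log_sx + exp(ls_sx) * stats::rnorm(1)
    a <- 0
    if (prop > log(1e-6) && log(stats::runif(1)) < lp_sx(prop) - lp_sx(log_sx)) {
      log_sx <- prop; a <- 1
    }
    if (it <= keep_at) ls_sx <- adapt_scale(ls_sx, a, it)
    v <- sd2 + exp(2 * log_sx)

    ## --- translation move: the likelihood is invariant under
    ## (z, theta) -> (z + a, theta + a); shift the whole axis jointly ---
    aa <- exp(ls_shift) * stats::rnorm(1)
    dlp <- sum(stats::dnorm(z + aa, 0, pr$z_scale, log = TRUE) -
                 stats::dnorm(z, 0, pr$z_scale, log = TRUE)) +
      lp_theta_ou(theta + aa, exp(log_phi), exp(log_sinn), dt) -
      lp_theta_ou(theta, exp(log_phi), exp(log_sinn), dt)
    a <- 0
    if (log(stats::runif(1)) < dlp) {
      z <- z + aa; theta <- theta + aa; a <- 1
    }
    if (it <= keep_at) ls_shift <- adapt_scale(ls_shift, a, it, target = 0.3)

    ## --- rescale move: the likelihood is invariant under
    ## (z, theta) -> (c z, c theta), kappa -> kappa / c^2; traverse this
    ## ridge jointly, accepting on the prior ratio and Jacobian ---
    lc <- exp(ls_resc) * stats::rnorm(1)
    cc <- exp(lc)
    dlp <- sum(stats::dnorm(cc * z, 0, pr$z_scale, log = TRUE) -
                 stats::dnorm(z, 0, pr$z_scale, log = TRUE)) +
      lp_theta_ou(cc * theta, exp(log_phi), exp(log_sinn), dt) -
      lp_theta_ou(theta, exp(log_phi), exp(log_sinn), dt) +
      sum(dhalf_norm(kappa / cc^2, pr$kappa_scale) -
            dhalf_norm(kappa, pr$kappa_scale)) +
      (G - 3) * lc
    a <- 0
    if (log(stats::runif(1)) < dlp) {
      z <- cc * z; theta <- cc * theta; kappa <- kappa / cc^2
      a <- 1
    }
    if (it <= keep_at) ls_resc <- adapt_scale(ls_resc, a, it, target = 0.3)

    if (it > keep_at) {
      k <- it - keep_at
      z_draws[k, ] <- z
      par_draws[k, ] <- c(alpha, kappa, theta, exp(log_phi), exp(log_sinn),
                          exp(log_sx))
    }
  }
  list(z = z_draws, pars = par_draws)
}

## Least-squares warm start: the leading principal axis of the gene summaries
## orders genes along a provisional z; per-interval quadratic regressions of
## m on that z give starting peaks, curvatures and optima.
.seascape_init <- function(m) {
  sds <- pmax(apply(m, 2L, stats::sd), 1e-8)
  ms <- scale(m, center = TRUE, scale = sds)
  sc <- stats::prcomp(ms)$x[, 1]
  z0 <- if (stats::sd(sc) > 1e-10) 1.5 * sc / stats::sd(sc)
        else stats::rnorm(nrow(m))
  alpha0 <- kappa0 <- theta0 <- numeric(3)
  for (d in 1:3) {
    cf <- stats::coef(stats::lm(m[, d] ~ z0 + I(z0^2)))
    k <- max(-2 * cf[3], 0.02)
    th <- cf[2] / k
    th <- max(min(th, 4), -4)
    kappa0[d] <- k
    theta0[d] <- th
    alpha0[d] <- cf[1] + 0.5 * k * th^2
  }
  list(z = z0, alpha = alpha0, kappa = kappa0, theta = theta0,
       log_phi = log(0.2), log_sinn = log(max(stats::sd(theta0), 0.5)),
       log_sx = log(0.1))
}

#' Fit the one-dimensional Fisher's geometric seascape
#'
#' Treats gene-level interval selection-rate posterior summaries (median m and
#' sd) from the longitudinal model as noisy observations of a latent quadratic
#' landscape per interval:
#' \deqn{m_{g,d} ~ Normal(\alpha_d - \kappa_d (z_g - \theta_d)^2 / 2,
#'   \sqrt{sd_{g,d}^2 + \sigma_{extra}^2})}
#' Each gene receives one latent coordinate \code{z_g}; each interval has a
#' peak rate \code{alpha_d}, curvature \code{kappa_d >= 0}, and optimum
#' \code{theta_d}, with adjacent optima tied by a discretized
#' Ornstein-Uhlenbeck process over the gaps between interval midpoints. The
#' likelihood is invariant to the reflection (z, theta) -> (-z, -theta);
#' draws are deterministically aligned so that the interval-2 (death phase)
#' optimum lies to the right of the interval-1 (growth) optimum.
#' Sampling is Metropolis-within-Gibbs (conjugate peak/curvature updates,
#' vectorized single-site walks for z) under the same split-chain convergence
#' gate as the longitudinal model.
#'
#' @param obs Either a data frame with columns \code{gene}, \code{interval},
#'   \code{median}, \code{sd} (e.g. derived from a \code{tnfit} summary), or a
#'   list with matrices \code{m} and \code{sd} (genes x 3, gene row names).
#' @param priors A \code{\link{seascape_priors}}.
#' @return A \code{seascape_fit}: posterior draws of z (draws x genes) and of
#'   the landscape/OU parameters, per-gene z summaries, convergence
#'   diagnostics, and an unidentified-axis flag (curvature posterior
#'   concentrated at zero).
#' @export
fit_seascape <- function(obs, priors = seascape_priors()) {
  stopifnot(inherits(priors, "seascape_priors"))
  if (is.data.frame(obs)) {
    stopifnot(all(c("gene", "interval", "median", "sd") %in% names(obs)))
    genes <- sort(unique(obs$gene))
    m <- sdm <- matrix(NA_real_, length(genes), 3,
                       dimnames = list(genes, NULL))
    m[cbind(match(obs$gene, genes), obs$interval)] <- obs$median
    sdm[cbind(match(obs$gene, genes), obs$interval)] <- obs$sd
  } else {
    m <- as.matrix(obs$m); sdm <- as.matrix(obs$sd)
    genes <- rownames(m)
    if (is.null(genes)) genes <- sprintf("g%04d", seq_len(nrow(m)))
  }
  if (anyNA(m) || anyNA(sdm)) stop("every gene needs all three interval summaries")
  if (any(sdm <= 0)) stop("posterior sds must be positive")
  if (nrow(m) < 10) stop("need at least 10 genes")
  G <- nrow(m)
  sd2 <- sdm^2

  set.seed(priors$seed)
  base_init <- .seascape_init(m)
  n_iter <- priors$warmup + priors$draws
  chains <- vector("list", priors$chains)
  for (ch in seq_len(priors$chains)) {
    init <- base_init
    init$z <- init$z * sample(c(-1, 1), 1) + stats::rnorm(G, 0, 0.2)
    init$alpha <- init$alpha + stats::rnorm(3, 0, 0.05)
    init$theta <- init$theta + stats::rnorm(3, 0, 0.2)
    chains[[ch]] <- .run_seachain(m, sd2, priors, init, n_iter, priors$draws)
  }

  n_keep <- priors$draws
  z_all <- do.call(rbind, lapply(chains, `[[`, "z"))
  par_all <- do.call(rbind, lapply(chains, `[[`, "pars"))
  colnames(z_all) <- genes

  ## reflection alignment: theta2 >= theta1 in every draw
  flip <- par_all[, "theta2"] < par_all[, "theta1"]
  z_all[flip, ] <- -z_all[flip, ]
  par_all[flip, paste0("theta", 1:3)] <- -par_all[flip, paste0("theta", 1:3)]

  ca <- function(mat) array(mat, c(n_keep, priors$chains, ncol(mat)))
  rhat <- c(split_rhat(ca(par_all)), split_rhat(ca(z_all)))
  frac_ok <- mean(rhat < 1.01, na.rm = TRUE)
  diagnostics <- list(rhat_pars = stats::setNames(
    split_rhat(ca(par_all)), colnames(par_all)),
    frac_rhat_ok = frac_ok, rhat_max = max(rhat, na.rm = TRUE),
    converged = frac_ok >= 0.99)
  if (!diagnostics$converged)
    warning(sprintf("convergence gate failed: only %.1f%% of parameters have Rhat < 1.01",
                    100 * frac_ok))
  kappa_med <- apply(par_all[, paste0("kappa", 1:3)], 2L, stats::median)
  unidentified <- all(kappa_med < 0.02)
  if (unidentified)
    warning("curvature posterior concentrated near zero: latent axis unidentified")

  a <- 0.05
  zq <- apply(z_all, 2L, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  structure(list(genes = genes, z = z_all, pars = par_all,
                 z_summary = data.frame(gene = genes, median = zq[2, ],
                                        lower = zq[1, ], upper = zq[3, ]),
                 data = list(m = m, sd = sdm),
                 priors = priors, diagnostics = diagnostics,
                 unidentified_axis = unidentified),
            class = "seascape_fit")
}

#' @export
print.seascape_fit <- function(x, ...) {
  cat(sprintf("seascape_fit: %d genes, %d draws (%d chains), seed %d\n",
              length(x$genes), nrow(x$pars), x$priors$chains, x$priors$seed))
  med <- apply(x$pars, 2L, stats::median)
  cat(sprintf("convergence: %s (%.1f%% of parameters with Rhat < 1.01)\n",
              if (x$diagnostics$converged) "passed" else "FAILED",
              100 * x$diagnostics$frac_rhat_ok))
  cat("posterior medians:\n")
  print(round(med, 3))
  invisible(x)
}

#' @export
summary.seascape_fit <- function(object, ...) {
  q <- apply(object$pars, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
             names = FALSE)
  data.frame(parameter = colnames(object$pars),
             median = q[2, ], lower = q[1, ], upper = q[3, ],
             row.names = NULL)
}

#' @export
coef.seascape_fit <- function(object, ...) {
  apply(object$pars, 2L, stats::median)
}

#' Predicted selection rate on an interval landscape
#'
#' Evaluates \code{alpha_d - kappa_d (z - theta_d)^2 / 2} for the posterior
#' draws of a fitted seascape (default: posterior median prediction).
#'
#' @param object A \code{seascape_fit}.
#' @param z Latent coordinate(s).
#' @param interval Interval index 1..3.
#' @param draws If TRUE return the draws x z matrix instead of medians.
#' @param ... Unused.
#' @return Predicted selection rates (days^-1).
#' @export
predict.seascape_fit <- function(object, z, interval = 1, draws = FALSE, ...) {
  stopifnot(interval %in% 1:3)
  al <- object$pars[, paste0("alpha", interval)]
  ka <- object$pars[, paste0("kappa", interval)]
  th <- object$pars[, paste0("theta", interval)]
  pred <- outer(seq_along(al), seq_along(z),
                function(i, j) seascape_mu(al[i], ka[i], th[i], z[j]))
  if (draws) pred else apply(pred, 2L, stats::median)
}

#' Quadratic landscape value for explicit parameters
#'
#' @param alpha Peak selection rate.
#' @param kappa Curvature (>= 0).
#' @param theta Optimum coordinate.
#' @param z Latent coordinate(s).
#' @return \code{alpha - kappa * (z - theta)^2 / 2}.
#' @export
seascape_rate <- function(alpha, kappa, theta, z) {
  seascape_mu(alpha, kappa, theta, z)
}

#' Integrated (time-weighted) seascape and its cumulative optimum
#'
#' Sums the interval landscapes with duration weights,
#' \code{cumulative(z) = sum_d w_d (alpha_d - kappa_d (z - theta_d)^2 / 2)},
#' and computes the closed-form cumulative optimum
#' \code{z* = sum_d w_d kappa_d theta_d / sum_d w_d kappa_d} per posterior
#' draw (undefined in draws where the total curvature is zero).
#'
#' @param fit A \code{seascape_fit}.
#' @param weights Interval duration weights summing to 1
#'   (default \code{c(0.1, 0.3, 0.6)}).
#' @param z_grid Grid on which to summarize the cumulative curve.
#' @return List with \code{curve} (z, median, lower, upper of the cumulative
#'   landscape), \code{zstar_draws}, \code{zstar} (median and 90\% CI),
#'   and \code{n_undefined}.
#' @export
integrate_seascape <- function(fit, weights = c(0.1, 0.3, 0.6),
                               z_grid = seq(-6, 6, length.out = 241)) {
  stopifnot(inherits(fit, "seascape_fit"),
            abs(sum(weights) - 1) < 1e-8, all(weights >= 0))
  al <- fit$pars[, paste0("alpha", 1:3), drop = FALSE]
  ka <- fit$pars[, paste0("kappa", 1:3), drop = FALSE]
  th <- fit$pars[, paste0("theta", 1:3), drop = FALSE]
  n <- nrow(al)
  curve <- matrix(0, n, length(z_grid))
  for (d in 1:3) {
    curve <- curve + weights[d] *
      (al[, d] - 0.5 * ka[, d] * (outer(-th[, d], z_grid, `+`))^2)
  }
  denom <- as.vector(ka %*% weights)
  num <- rowSums(sweep(ka * th, 2L, weights, `*`))
  zstar <- ifelse(denom > 0, num / denom, NA_real_)
  q <- apply(curve, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
             names = FALSE)
  list(curve = data.frame(z = z_grid, median = q[2, ], lower = q[1, ],
                          upper = q[3, ]),
       zstar_draws = zstar,
       zstar = stats::quantile(zstar, c(0.05, 0.5, 0.95), na.rm = TRUE,
                               names = FALSE)[c(2, 1, 3)],
       n_undefined = sum(is.na(zstar)))
}

#' Regulon signed-sum predictions of regulator coordinates
#'
#' Under an additive reading of the latent axis, an activator's coordinate
#' should equal the sum of its targets' coordinates and a repressor's the
#' negative sum. Signed sums are computed draw-wise to propagate posterior
#' uncertainty.
#'
#' @param fit A \code{seascape_fit}.
#' @param regulons Data frame with columns \code{regulator}, \code{mode}
#'   ("activator" or "repressor"), and \code{targets} (comma-separated locus
#'   tags or a list column).
#' @param level Credible level for summaries (default 0.90).
#' @return Data frame per retained regulator: observed and predicted z
#'   (median and credible bounds), draw-wise discrepancy summary, and regulon
#'   size used.
#' @export
regulon_prediction <- function(fit, regulons, level = 0.90) {
  stopifnot(inherits(fit, "seascape_fit"),
            all(c("regulator", "mode", "targets") %in% names(regulons)))
  a <- (1 - level) / 2
  rows <- list()
  for (i in seq_len(nrow(regulons))) {
    reg <- regulons$regulator[i]
    mode <- match.arg(regulons$mode[i], c("activator", "repressor"))
    tg <- regulons$targets[[i]]
    if (length(tg) == 1 && is.character(tg))
      tg <- trimws(strsplit(tg, ",")[[1]])
    tg <- setdiff(tg, reg)
    if (!reg %in% fit$genes) {
      warning("regulator ", reg, " absent from fit; skipped")
      next
    }
    missing <- setdiff(tg, fit$genes)
    if (length(missing)) {
      warning("dropping ", length(missing), " target(s) of ", reg,
              " absent from fit")
      tg <- intersect(tg, fit$genes)
    }
    if (!length(tg)) {
      warning("regulon of ", reg, " empty after filtering; skipped")
      next
    }
    sgn <- if (mode == "activator") 1 else -1
    pred <- sgn * rowSums(fit$z[, tg, drop = FALSE])
    obs <- fit$z[, reg]
    dd <- obs - pred
    qq <- function(v) stats::quantile(v, c(a, 0.5, 1 - a), names = FALSE)
    qo <- qq(obs); qp <- qq(pred); qd <- qq(dd)
    rows[[length(rows) + 1L]] <- data.frame(
      regulator = reg, mode = mode, n_targets = length(tg),
      observed_z = qo[2], observed_lo = qo[1], observed_hi = qo[3],
      predicted_z = qp[2], predicted_lo = qp[1], predicted_hi = qp[3],
      discrepancy = qd[2], discrepancy_lo = qd[1], discrepancy_hi = qd[3],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no regulator could be evaluated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate gene-level observations from a known seascape
#'
#' Generates posterior-summary-style inputs (medians and sds) from explicit
#' landscape parameters, for parameter-recovery checks.
#'
#' @param n_genes Number of genes.
#' @param alpha,kappa,theta Length-3 landscape parameters.
#' @param z Optional true coordinates (default drawn from Normal(0, 2)).
#' @param noise_sd Observation noise sd, also reported as the per-cell sd.
#' @param seed RNG seed.
#' @return List with \code{truth} (z, alpha, kappa, theta) and \code{obs}
#'   (list of matrices \code{m}, \code{sd} suitable for
#'   \code{\link{fit_seascape}}).
#' @export
simulate_seascape <- function(n_genes = 300,
                              alpha = c(0.3, 0.1, 0.05),
                              kappa = c(0.6, 0.3, 0.15),
                              theta = c(-1.5, 1.0, -0.5),
                              z = NULL, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  if (is.null(z)) z <- stats::rnorm(n_genes, 0, 2)
  genes <- sprintf("g%04d", seq_along(z))
  m <- sapply(1:3, function(d)
    seascape_mu(alpha[d], kappa[d], theta[d], z) +
      stats::rnorm(length(z), 0, noise_sd))
  rownames(m) <- genes
  sdm <- matrix(noise_sd, length(z), 3, dimnames = list(genes, NULL))
  list(truth = list(z = stats::setNames(z, genes), alpha = alpha,
                    kappa = kappa, theta = theta),
       obs = list(m = m, sd = sdm))
}
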