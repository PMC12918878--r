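#' Specification for the hierarchical longitudinal selection-rate model
#'
#' Collects priors and inference settings for \code{\link{fit_longitudinal}}.
#' The observation model is
#' \deqn{rate(b, r, d) ~ Normal(\beta_d + u_{g(b),d}, \sigma_d)}
#' in a contrast parameterization: the interval-1 effect is the "intercept"
#' and later intervals are contrasts against it, so the LKJ prior acts on the
#' correlation between the intercept and the slopes. Gene effect vectors are
#' multivariate normal with per-coordinate scales \code{tau} and correlation
#' matrix \code{Omega ~ LKJ(eta)}. All hyperpriors are (half-)Student-t.
#'
#' @param beta_df,beta_scale Student-t prior on population effects
#'   (default t(3, 0, 0.2), weakly informative on the days^-1 scale).
#' @param tau_df,tau_scale Half-Student-t prior on gene-effect sds
#'   (default half-t(3, 0, 0.3)).
#' @param sigma_df,sigma_scale Half-Student-t prior on per-interval residual
#'   sds (default half-t(3, 0, 0.5)).
#' @param lkj_eta Shape of the LKJ prior on the gene-effect correlation matrix
#'   (default 2, mildly favouring moderate correlations).
#' @param chains,warmup,draws MCMC layout: number of chains, warmup
#'   iterations, and retained post-warmup draws per chain (defaults 4, 500,
#'   1000).
#' @param seed Integer RNG seed recorded in all outputs.
#' @param ci_level Central credible-interval level for summaries (default
#'   0.90, matching the coverage benchmark).
#' @return A \code{tn_model_spec} list.
#' @export
model_spec <- function(beta_df = 3, beta_scale = 0.2,
                       tau_df = 3, tau_scale = 0.3,
                       sigma_df = 3, sigma_scale = 0.5,
                       lkj_eta = 2,
                       chains = 4, warmup = 500, draws = 1000,
                       seed = 1L, ci_level = 0.90) {
  stopifnot(beta_scale > 0, tau_scale > 0, sigma_scale > 0, lkj_eta > 0,
            chains >= 1, warmup >= 50, draws >= 50,
            ci_level > 0, ci_level < 1)
  structure(list(beta_df = beta_df, beta_scale = beta_scale,
                 tau_df = tau_df, tau_scale = tau_scale,
                 sigma_df = sigma_df, sigma_scale = sigma_scale,
                 lkj_eta = lkj_eta, chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), ci_level = ci_level),
            class = "tn_model_spec")
}

## Sufficient statistics per gene x interval: counts, means, within-cell SSE.
.suffstats <- function(rates) {
  ok <- !is.na(rates$gene) & is.finite(rates$rate)
  dropped <- unique(rates$gene[is.na(rates$gene)])
  rates <- rates[ok, , drop = FALSE]
  if (!nrow(rates)) stop("no gene-mapped observations")
  if (!all(rates$interval %in% 1:3))
    stop("the longitudinal model expects interval indices 1, 2, 3")
  genes <- sort(unique(rates$gene))
  gi <- match(rates$gene, genes)
  G <- length(genes)
  N <- YB <- SSE <- matrix(0, G, 3)
  for (d in 1:3) {
    sel <- rates$interval == d
    if (!any(sel)) next
    t_n <- tabulate(gi[sel], nbins = G)
    t_s <- rowsum(rates$rate[sel], gi[sel], reorder = FALSE)
    idx <- as.integer(rownames(t_s))
    N[idx, d] <- t_n[idx]
    YB[idx, d] <- t_s / t_n[idx]
    mu_row <- YB[gi[sel], d]
    t_ss <- rowsum((rates$rate[sel] - mu_row)^2, gi[sel], reorder = FALSE)
    SSE[idx, d] <- t_ss
  }
  list(genes = genes, N = N, YB = YB, SSE = SSE, rates = rates)
}

## Moment-matching Gaussian approximation used as chain warm start.
.moment_init <- function(ss, spec) {
  YB <- ss$YB; N <- ss$N
  m <- YB
  for (d in 1:3) {
    cm <- stats::weighted.mean(YB[, d], N[, d])
    m[N[, d] == 0, d] <- cm
  }
  v <- cbind(m[, 1], m[, 2] - m[, 1], m[, 3] - m[, 1])
  beta0 <- colMeans(v)
  u0 <- sweep(v, 2L, beta0) * 0.8
  tau0 <- pmax(apply(u0, 2L, stats::sd), 0.05)
  co <- suppressWarnings(stats::cor(u0))
  co[!is.finite(co)] <- 0
  p1 <- max(min(co[1, 2], 0.9), -0.9)
  p2 <- max(min(co[1, 3], 0.9), -0.9)
  p3 <- (co[2, 3] - p1 * p2) / sqrt((1 - p1^2) * (1 - p2^2))
  p3 <- max(min(p3, 0.9), -0.9)
  dof <- pmax(colSums(N) - colSums(N > 0), 1)
  sigma0 <- pmax(sqrt(colSums(ss$SSE) / dof), 0.05)
  list(beta = beta0, u = u0, log_tau = log(tau0),
       x_cpc = atanh(c(p1, p2, p3)), log_sigma = log(sigma0),
       lambda = rep(1, 3))
}

.run_lchain <- function(ss, spec, init, n_iter, n_keep) {
  G <- length(ss$genes)
  N <- ss$N; YB <- ss$YB
  SSEsum <- colSums(ss$SSE)
  Nd <- colSums(N)
  beta <- init$beta; u <- init$u
  log_tau <- init$log_tau; x_cpc <- init$x_cpc
  log_sigma <- init$log_sigma; lambda <- init$lambda
  ls_sigma <- rep(log(0.1), 3)
  ls_hyper <- log(0.08)
  ls_trans <- log(0.05)
  prior_prec_beta <- 1 / spec$beta_scale^2

  s_draws <- array(NA_real_, c(n_keep, G, 3))
  sc_draws <- matrix(NA_real_, n_keep, 12,
                     dimnames = list(NULL, c(paste0("beta", 1:3),
                                             paste0("tau", 1:3),
                                             paste0("omega", c("12", "13", "23")),
                                             paste0("sigma", 1:3))))
  keep_at <- n_iter - n_keep

  lp_hyper_full <- function(log_tau, x_cpc, S) {
    tau <- exp(log_tau)
    Om <- cpc_to_corr(tanh(x_cpc))
    Sig <- Om * (tau %o% tau)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(list(lp = -Inf))
    Sinv <- chol2inv(ch)
    lp <- -G * sum(log(diag(ch))) - 0.5 * sum(Sinv * S) +
      lp_hyper(log_tau, x_cpc, spec$tau_df, spec$tau_scale, spec$lkj_eta)
    list(lp = lp, Sinv = Sinv)
  }

  S_u <- crossprod(u)
  cur <- lp_hyper_full(log_tau, x_cpc, S_u)
  Sinv <- cur$Sinv

  for (it in seq_len(n_iter)) {
    sigma2 <- exp(2 * log_sigma)
    c1 <- N[, 1] / sigma2[1]; c2 <- N[, 2] / sigma2[2]; c3 <- N[, 3] / sigma2[3]

    ## --- gene effects: conjugate trivariate normal draws, vectorized ---
    r1 <- c1 * YB[, 1] + c2 * YB[, 2] + c3 * YB[, 3] -
      ((c1 + c2 + c3) * beta[1] + c2 * beta[2] + c3 * beta[3])
    r2 <- c2 * (YB[, 2] - beta[1] - beta[2])
    r3 <- c3 * (YB[, 3] - beta[1] - beta[3])
    g <- mvn3_gibbs(Sinv[1, 1] + c1 + c2 + c3,
                    Sinv[1, 2] + c2,
                    Sinv[1, 3] + c3,
                    Sinv[2, 2] + c2,
                    Sinv[2, 3],
                    Sinv[3, 3] + c3,
                    r1, r2, r3)
    u <- cbind(g$u1, g$u2, g$u3)

    ## --- population effects: conjugate given t-prior mixing weights ---
    e1 <- YB[, 1] - u[, 1]
    e2 <- YB[, 2] - u[, 1] - u[, 2]
    e3 <- YB[, 3] - u[, 1] - u[, 3]
    C1 <- sum(c1); C2 <- sum(c2); C3 <- sum(c3)
    Pb <- matrix(c(C1 + C2 + C3, C2, C3,
                   C2, C2, 0,
                   C3, 0, C3), 3, 3) +
      diag(lambda * prior_prec_beta, 3)
    rhs <- c(sum(c1 * e1) + sum(c2 * e2) + sum(c3 * e3),
             sum(c2 * e2), sum(c3 * e3))
    ch <- chol(Pb)
    beta <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE)) +
      backsolve(ch, stats::rnorm(3))
    lambda <- stats::rgamma(3, (spec$beta_df + 1) / 2,
                            (spec$beta_df + beta^2 / spec$beta_scale^2) / 2)

    ## --- translation move: shift mass between beta and the gene effects ---
    ## (likelihood-invariant, accepted on the prior ratio; decorrelates the
    ## population effects from the gene-effect mean)
    for (rep_t in 1:4) {
      eps <- exp(ls_trans) * stats::rnorm(3)
      usum <- colSums(u)
      dlp <- sum(eps * (Sinv %*% usum)) -
        G / 2 * sum(eps * (Sinv %*% eps)) +
        sum(stats::dnorm(beta + eps, 0,
                         spec$beta_scale / sqrt(lambda), log = TRUE)) -
        sum(stats::dnorm(beta, 0, spec$beta_scale / sqrt(lambda), log = TRUE))
      acc <- 0
      if (log(stats::runif(1)) < dlp) {
        beta <- beta + eps
        u <- sweep(u, 2L, eps)
        acc <- 1
      }
      if (it <= keep_at)
        ls_trans <- adapt_scale(ls_trans, acc, (it - 1) * 4 + rep_t,
                                target = 0.3)
    }

    ## --- residual sds: random-walk MH on log sigma_d ---
    mu1 <- beta[1] + u[, 1]
    mu2 <- beta[1] + beta[2] + u[, 1] + u[, 2]
    mu3 <- beta[1] + beta[3] + u[, 1] + u[, 3]
    SS <- c(SSEsum[1] + sum(N[, 1] * (YB[, 1] - mu1)^2),
            SSEsum[2] + sum(N[, 2] * (YB[, 2] - mu2)^2),
            SSEsum[3] + sum(N[, 3] * (YB[, 3] - mu3)^2))
    for (d in 1:3) {
      lp_s <- function(ls) {
        s2 <- exp(2 * ls)
        -Nd[d] * ls - SS[d] / (2 * s2) +
          dhalf_t(exp(ls), spec$sigma_df, spec$sigma_scale) + ls
      }
      prop <- log_sigma[d] + exp(ls_sigma[d]) * stats::rnorm(1)
      acc <- 0
      if (prop > log(1e-8) &&
          log(stats::runif(1)) < lp_s(prop) - lp_s(log_sigma[d])) {
        log_sigma[d] <- prop; acc <- 1
      }
      if (it <= keep_at) ls_sigma[d] <- adapt_scale(ls_sigma[d], acc, it)
    }

    ## --- gene-effect covariance: blocked MH with LKJ/half-t priors ---
    ## the block is O(1) per proposal, so several sweeps per iteration keep
    ## the hypercovariance mixing in step with the conjugate updates
    S_u <- crossprod(u)
    cur <- lp_hyper_full(log_tau, x_cpc, S_u)
    for (rep_h in 1:8) {
      prop_lt <- log_tau + exp(ls_hyper) * stats::rnorm(3)
      prop_xc <- x_cpc + exp(ls_hyper) * stats::rnorm(3)
      prop <- lp_hyper_full(prop_lt, prop_xc, S_u)
      acc <- 0
      if (is.finite(prop$lp) &&
          log(stats::runif(1)) < prop$lp - cur$lp) {
        log_tau <- prop_lt; x_cpc <- prop_xc; cur <- prop; acc <- 1
      }
      if (it <= keep_at)
        ls_hyper <- adapt_scale(ls_hyper, acc, (it - 1) * 8 + rep_h,
                                target = 0.25)
    }
    Sinv <- cur$Sinv

    if (it > keep_at) {
      k <- it - keep_at
      s_draws[k, , 1] <- beta[1] + u[, 1]
      s_draws[k, , 2] <- beta[1] + beta[2] + u[, 1] + u[, 2]
      s_draws[k, , 3] <- beta[1] + beta[3] + u[, 1] + u[, 3]
      p <- tanh(x_cpc)
      Om <- cpc_to_corr(p)
      sc_draws[k, ] <- c(beta, exp(log_tau), Om[1, 2], Om[1, 3], Om[2, 3],
                         exp(log_sigma))
    }
  }
  list(s = s_draws, scalars = sc_draws)
}

#' Fit the hierarchical Bayesian longitudinal selection-rate model
#'
#' Models per-barcode interval selection rates with gene-level random effects
#' across the three sampling intervals. Observations are normal around the
#' gene-by-interval mean with per-interval residual sds; gene effect vectors
#' (intercept and two slope contrasts) are multivariate normal with
#' half-Student-t scale priors and an LKJ-distributed correlation matrix.
#' Sampling is blocked Gibbs/Metropolis (conjugate gene- and population-effect
#' updates; adaptive random-walk updates for variance and correlation
#' hyperparameters), with every chain initialized from a moment-matching
#' Gaussian approximation of the posterior. Results are gated on split-chain
#' convergence: the fit is flagged unconverged unless Rhat < 1.01 for at
#' least 99\% of parameters.
#'
#' @param rates Selection-rate data frame (see
#'   \code{\link{compute_selection_rates}}): columns \code{gene},
#'   \code{interval} (1..3), \code{rate}; rows without a gene are dropped
#'   with a message.
#' @param spec A \code{\link{model_spec}}.
#' @param weights Interval duration weights used for the net selection rate;
#'   taken from the table's \code{intervals} attribute when present, else
#'   \code{c(0.1, 0.3, 0.6)} (days 0-1, 1-4, 4-10 of a 10-day experiment).
#' @return A \code{tnfit} object with posterior draw arrays (\code{draws$s}:
#'   draws x gene x interval; \code{draws$snet}; \code{draws$scalars}),
#'   per-quantity summaries (median, central credible bounds, Pr(s>0),
#'   Pr(s<0)), and convergence diagnostics.
#' @export
fit_longitudinal <- function(rates, spec = model_spec(), weights = NULL) {
  stopifnot(inherits(spec, "tn_model_spec"))
  if (is.null(weights)) {
    iv <- attr(rates, "intervals")
    weights <- if (!is.null(iv)) {
      len <- iv$end - iv$start
      len / sum(len)
    } else c(0.1, 0.3, 0.6)
  }
  stopifnot(length(weights) == 3, all(weights > 0),
            abs(sum(weights) - 1) < 1e-8)
  if (any(is.na(rates$gene)))
    message(sum(is.na(rates$gene)), " observations without a gene excluded")
  ss <- .suffstats(rates)
  G <- length(ss$genes)
  if (G < 2) stop("need at least two genes")

  set.seed(spec$seed)
  base_init <- .moment_init(ss, spec)
  n_iter <- spec$warmup + spec$draws
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    init <- base_init
    init$beta <- init$beta + stats::rnorm(3, 0, 0.02)
    init$u <- init$u + matrix(stats::rnorm(3 * G, 0, 0.02), G, 3)
    init$log_tau <- init$log_tau + stats::rnorm(3, 0, 0.1)
    init$log_sigma <- init$log_sigma + stats::rnorm(3, 0, 0.1)
    chains[[ch]] <- .run_lchain(ss, spec, init, n_iter, spec$draws)
  }

  n_keep <- spec$draws
  s_all <- array(NA_real_, c(n_keep * spec$chains, G, 3))
  sc_all <- matrix(NA_real_, n_keep * spec$chains, 12)
  colnames(sc_all) <- colnames(chains[[1]]$scalars)
  chain_id <- rep(seq_len(spec$chains), each = n_keep)
  for (ch in seq_len(spec$chains)) {
    idx <- (ch - 1L) * n_keep + seq_len(n_keep)
    s_all[idx, , ] <- chains[[ch]]$s
    sc_all[idx, ] <- chains[[ch]]$scalars
  }

  ## convergence diagnostics over all scalar and gene-level parameters
  to_chain_array <- function(m) {
    array(m, c(n_keep, spec$chains, ncol(m)))
  }
  rhat_sc <- split_rhat(to_chain_array(sc_all))
  s_flat <- matrix(s_all, nrow = dim(s_all)[1])
  rhat_s <- split_rhat(to_chain_array(s_flat))
  rhat <- c(rhat_sc, rhat_s)
  frac_ok <- mean(rhat < 1.01, na.rm = TRUE)
  ess <- apply(sc_all, 2L, function(v)
    ess_basic(matrix(v, n_keep, spec$chains)))
  diagnostics <- list(rhat_scalars = stats::setNames(rhat_sc, colnames(sc_all)),
                      rhat_max = max(rhat, na.rm = TRUE),
                      frac_rhat_ok = frac_ok,
                      converged = frac_ok >= 0.99,
                      ess_scalars = ess)
  if (!diagnostics$converged)
    warning(sprintf("convergence gate failed: only %.1f%% of parameters have Rhat < 1.01",
                    100 * frac_ok))

  fit <- structure(list(genes = ss$genes, weights = weights,
                        draws = list(s = s_all, scalars = sc_all),
                        chain = chain_id, spec = spec,
                        data = ss$rates, N = ss$N, YB = ss$YB,
                        diagnostics = diagnostics),
                   class = "tnfit")
  fit$draws$snet <- compute_snet(fit)$draws
  fit$summaries <- .summarize_tnfit(fit)
  fit
}

.post_summary <- function(draws, level) {
  a <- (1 - level) / 2
  q <- apply(draws, 2L, stats::quantile, probs = c(a, 0.5, 1 - a),
             names = FALSE)
  data.frame(median = q[2, ], lower = q[1, ], upper = q[3, ],
             sd = apply(draws, 2L, stats::sd),
             pr_pos = colMeans(draws > 0), pr_neg = colMeans(draws < 0))
}

.summarize_tnfit <- function(fit) {
  level <- fit$spec$ci_level
  out <- vector("list", 4L)
  labs <- c("s1", "s2", "s3")
  for (d in 1:3) {
    sm <- .post_summary(fit$draws$s[, , d, drop = TRUE], level)
    out[[d]] <- cbind(data.frame(gene = fit$genes, quantity = labs[d],
                                 stringsAsFactors = FALSE), sm)
  }
  sm <- .post_summary(fit$draws$snet, level)
  out[[4]] <- cbind(data.frame(gene = fit$genes, quantity = "snet",
                               stringsAsFactors = FALSE), sm)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Net selection rate draws (time-weighted average of interval rates)
#'
#' The net selection rate is the integral of the per-interval step function of
#' selection rate over the experiment, divided by its duration:
#' \code{snet = sum_d w_d * s_d} with duration weights \code{w}. Ten times
#' \code{snet} is the cumulative log relative-abundance change over a 10-day
#' experiment.
#'
#' @param fit A \code{tnfit} object.
#' @param weights Duration weights (default: those stored in the fit).
#' @return List with \code{draws} (draws x gene matrix) and \code{summary}
#'   (per gene median, credible bounds, tail probabilities).
#' @export
compute_snet <- function(fit, weights = NULL) {
  stopifnot(inherits(fit, "tnfit"))
  w <- if (is.null(weights)) fit$weights else weights
  stopifnot(length(w) == 3)
  draws <- fit$draws$s[, , 1, drop = TRUE] * w[1] +
    fit$draws$s[, , 2, drop = TRUE] * w[2] +
    fit$draws$s[, , 3, drop = TRUE] * w[3]
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(fit$genes))
  colnames(draws) <- fit$genes
  sm <- .post_summary(draws, fit$spec$ci_level)
  list(draws = draws, summary = cbind(data.frame(gene = fit$genes), sm))
}

#' Classify genes as beneficial, deleterious, or neutral
#'
#' A gene-quantity is beneficial when the posterior probability that its
#' selection rate is positive reaches \code{threshold}, deleterious when the
#' probability of a negative rate does, and neutral otherwise.
#'
#' @param x A \code{tnfit} object or a data frame with columns \code{pr_pos}
#'   and \code{pr_neg}.
#' @param threshold Posterior probability cutoff in (0.5, 1); default 0.9,
#'   with 0.975 as the stricter variant.
#' @return The summary data frame with an added \code{label} factor.
#' @export
classify <- function(x, threshold = 0.9) {
  stopifnot(threshold > 0.5, threshold < 1)
  df <- if (inherits(x, "tnfit")) x$summaries else x
  stopifnot(all(c("pr_pos", "pr_neg") %in% names(df)))
  lab <- ifelse(df$pr_pos >= threshold, "beneficial",
                ifelse(df$pr_neg >= threshold, "deleterious", "neutral"))
  df$label <- factor(lab, levels = c("beneficial", "deleterious", "neutral"))
  df
}

#' Beneficial/deleterious counts and skew per quantity
#'
#' Tabulates beneficial (B) and deleterious (D) classifications and the
#' normalized skew (B - D) / (B + D) for each quantity (interval or net rate).
#' Accepts either a classified summary table (from \code{\link{classify}}) or
#' a data frame of pre-tabulated counts with columns \code{B} and \code{D}.
#'
#' @param x Data frame with columns \code{quantity} and \code{label}, or with
#'   columns \code{B} and \code{D} (and optionally \code{quantity}).
#' @return Data frame with columns \code{quantity}, \code{B}, \code{D},
#'   \code{total}, \code{skew} (NA when B + D = 0).
#' @export
interval_summary <- function(x) {
  if (all(c("B", "D") %in% names(x))) {
    out <- data.frame(quantity = if ("quantity" %in% names(x)) x$quantity
                      else seq_len(nrow(x)),
                      B = x$B, D = x$D)
  } else {
    stopifnot(all(c("quantity", "label") %in% names(x)))
    qs <- unique(x$quantity)
    out <- data.frame(quantity = qs,
                      B = sapply(qs, function(q)
                        sum(x$label[x$quantity == q] == "beneficial")),
                      D = sapply(qs, function(q)
                        sum(x$label[x$quantity == q] == "deleterious")))
  }
  out$total <- out$B + out$D
  out$skew <- ifelse(out$total > 0, (out$B - out$D) / out$total, NA_real_)
  rownames(out) <- NULL
  out
}

#' Persist posterior draws to a columnar on-disk table
#'
#' Writes the gene-by-interval selection-rate draws (and optionally the net
#' rate) in long format keyed by (gene, interval, draw), as a plain TSV.
#'
#' @param fit A \code{tnfit}.
#' @param path Output TSV path.
#' @param snet Include net-rate draws as interval code "snet" (default TRUE).
#' @return The path, invisibly.
#' @export
write_gene_draws <- function(fit, path, snet = TRUE) {
  stopifnot(inherits(fit, "tnfit"))
  n <- dim(fit$draws$s)[1]
  G <- length(fit$genes)
  blocks <- lapply(1:3, function(d) {
    data.frame(gene = rep(fit$genes, each = n),
               interval = as.character(d),
               draw = rep(seq_len(n), G),
               value = as.vector(fit$draws$s[, , d]))
  })
  if (snet)
    blocks <- c(blocks, list(
      data.frame(gene = rep(fit$genes, each = n), interval = "snet",
                 draw = rep(seq_len(n), G),
                 value = as.vector(fit$draws$snet))))
  utils::write.table(do.call(rbind, blocks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standard count-table tests on classification summaries
#'
#' Thin wrappers around \code{stats::fisher.test} (beneficial/deleterious
#' composition across quantities) and per-quantity \code{stats::chisq.test}
#' goodness-of-fit against an even beneficial/deleterious split, with BH
#' correction across quantities.
#'
#' @param counts Output of \code{\link{interval_summary}}.
#' @return List with \code{fisher} (htest over the B/D x quantity table) and
#'   \code{chisq} (data frame of per-quantity statistics and BH-adjusted
#'   p-values).
#' @export
classification_tests <- function(counts) {
  stopifnot(all(c("quantity", "B", "D") %in% names(counts)))
  keep <- counts$total > 0
  tab <- t(as.matrix(counts[keep, c("B", "D")]))
  colnames(tab) <- counts$quantity[keep]
  fisher <- stats::fisher.test(tab, simulate.p.value = ncol(tab) > 2,
                               B = 10000)
  chi <- do.call(rbind, lapply(which(keep), function(i) {
    ct <- stats::chisq.test(c(counts$B[i], counts$D[i]))
    data.frame(quantity = counts$quantity[i],
               statistic = unname(ct$statistic), p = ct$p.value)
  }))
  chi$p_adj <- stats::p.adjust(chi$p, method = "BH")
  list(fisher = fisher, chisq = chi)
}

#' @export
print.tnfit <- function(x, ...) {
  cat(sprintf("tnfit: %d genes, %d draws (%d chains x %d), seed %d\n",
              length(x$genes), nrow(x$draws$scalars), x$spec$chains,
              x$spec$draws, x$spec$seed))
  cat(sprintf("convergence: %s (%.1f%% of parameters with Rhat < 1.01, max Rhat %.3f)\n",
              if (x$diagnostics$converged) "passed" else "FAILED",
              100 * x$diagnostics$frac_rhat_ok, x$diagnostics$rhat_max))
  invisible(x)
}

#' @export
summary.tnfit <- function(object, threshold = 0.9, ...) {
  cls <- classify(object, threshold)
  out <- list(fit = object, counts = interval_summary(cls),
              threshold = threshold)
  class(out) <- "summary.tnfit"
  out
}

#' @export
print.summary.tnfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nclassification at threshold %.3f:\n", x$threshold))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tnfit <- function(object, ...) {
  med <- apply(object$draws$s, c(2, 3), stats::median)
  dimnames(med) <- list(object$genes, c("s1", "s2", "s3"))
  cbind(med, snet = apply(object$draws$snet, 2L, stats::median))
}

#' @export
fitted.tnfit <- function(object, ...) {
  med <- apply(object$draws$s, c(2, 3), stats::median)
  med[cbind(match(object$data$gene, object$genes), object$data$interval)]
}

#' @export
residuals.tnfit <- function(object, ...) {
  object$data$rate - fitted(object)
}

#' Posterior predictive simulation from a fitted longitudinal model
#'
#' Draws new selection-rate observations for the observed design (same genes,
#' intervals and per-cell observation counts), each replicate using one
#' posterior draw of the gene means and residual sds.
#'
#' @param object A \code{tnfit}.
#' @param nsim Number of replicate datasets.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of \code{nsim} data frames shaped like the input rates.
#' @export
simulate.tnfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_draws <- dim(object$draws$s)[1]
  gi <- match(object$data$gene, object$genes)
  di <- object$data$interval
  lapply(seq_len(nsim), function(i) {
    k <- sample.int(n_draws, 1)
    mu <- object$draws$s[k, , ][cbind(gi, di)]
    sig <- object$draws$scalars[k, paste0("sigma", 1:3)][di]
    out <- object$data
    out$rate <- stats::rnorm(length(mu), mu, sig)
    out
  })
}

#' @export
plot.tnfit <- function(x, quantity = "snet", ...) {
  sm <- x$summaries[x$summaries$quantity == quantity, ]
  sm <- sm[order(sm$median), ]
  n <- nrow(sm)
  plot(seq_len(n), sm$median, type = "n", xlab = "gene rank",
       ylab = sprintf("%s (days^-1)", quantity),
       ylim = range(sm$lower, sm$upper), ...)
  segments(seq_len(n), sm$lower, seq_len(n), sm$upper, col = "grey70")
  points(seq_len(n), sm$median, pch = 16, cex = 0.4)
  abline(h = 0, lty = 2)
  invisible(x)
}
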