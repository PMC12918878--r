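#' Configuration for the longitudinal RB-TnSeq benchmark simulator
#'
#' The simulator emulates a pseudo-longitudinal barcoded fitness assay: genes
#' carry latent per-interval selection rates correlated across time, each
#' insertion (barcode) deviates from its gene's rate (intragenic fitness
#' variation), barcode log-abundances are integrated forward through the
#' sampling days, and each destructively-sampled replicate culture receives a
#' directional batch offset plus undirected per-observation measurement error.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_replicates Replicate cultures per sampling day (default 3).
#' @param timepoints Strictly increasing sampling days
#'   (default \code{c(0, 1, 4, 10)}).
#' @param sd_intra Intragenic (barcode-level) rate sd, days^-1.
#' @param sd_meas Measurement-error sd added to every log-abundance
#'   observation.
#' @param sd_batch Sd of the directional offset shared by all observations of
#'   one replicate sample.
#' @param effect_sd Marginal sd of latent gene rates (default 0.3 days^-1).
#' @param effect_cor Cross-interval correlation of latent gene rates
#'   (default 0.5).
#' @param barcode_median Median insertions per gene for the geometric-like
#'   barcode-count sampler (default 16, minimum draw 1).
#' @param seed Integer RNG seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 1000, n_replicates = 3,
                       timepoints = c(0, 1, 4, 10),
                       sd_intra = 0.1, sd_meas = 0.1, sd_batch = 0,
                       effect_sd = 0.3, effect_cor = 0.5,
                       barcode_median = 16, seed = 1L) {
  stopifnot(n_genes >= 1, n_replicates >= 1, length(timepoints) >= 2,
            all(diff(timepoints) > 0), sd_intra >= 0, sd_meas >= 0,
            sd_batch >= 0, effect_sd > 0, effect_cor > -1, effect_cor < 1,
            barcode_median >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a longitudinal RB-TnSeq dataset with known truth
#'
#' Draws latent gene selection rates from a multivariate normal (marginal sd
#' \code{effect_sd}, cross-interval correlation \code{effect_cor}), barcode
#' rates around them (\code{sd_intra}), integrates barcode log-abundances
#' through the timepoints, adds one shared batch offset per replicate sample
#' (\code{sd_batch}) and independent measurement error (\code{sd_meas}) to
#' every observation, then derives observed per-barcode interval rates exactly
#' as the preprocessing chain does: each later-day replicate paired against
#' the mean over the earlier day's replicates.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{tn_sim} object: list with \code{truth} (gene x interval
#'   latent rates), \code{barcode_truth}, \code{abund} (barcode x sample
#'   observed log-abundances), \code{samples}, \code{rates} (selection-rate
#'   table as from \code{\link{compute_selection_rates}}), and \code{config}.
#' @export
simulate_tnseq <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  tp <- config$timepoints
  D <- length(tp) - 1L
  delta <- diff(tp)
  R <- config$n_replicates

  ## latent gene rates: compound-symmetric correlation across intervals
  Sig <- config$effect_sd^2 *
    (diag(1 - config$effect_cor, D) + config$effect_cor)
  L <- chol(Sig)
  truth <- matrix(stats::rnorm(G * D), G, D) %*% L
  genes <- sprintf("g%04d", seq_len(G))
  rownames(truth) <- genes
  colnames(truth) <- paste0("s", seq_len(D))

  ## barcodes per gene: 1 + geometric, median barcode_median
  p_geom <- 1 - 2^(-1 / (config$barcode_median - 0.5))
  nb <- 1L + stats::rgeom(G, p_geom)
  B <- sum(nb)
  bgene <- rep(seq_len(G), nb)
  barcodes <- sprintf("b%06d", seq_len(B))

  ## barcode-level rates around the gene rate
  brate <- truth[bgene, , drop = FALSE] +
    matrix(stats::rnorm(B * D, 0, config$sd_intra), B, D)

  ## integrate log-abundance forward: a(t_k) = sum_{d<=k} s_d * delta_d
  a <- cbind(0, brate %*% diag(delta, D))
  a <- t(apply(a, 1L, cumsum))

  samples <- data.frame(
    sample = paste0("d", rep(tp, each = R), "_r", rep(seq_len(R), length(tp))),
    day = rep(tp, each = R),
    replicate = as.character(rep(seq_len(R), length(tp))),
    stringsAsFactors = FALSE)
  batch <- stats::rnorm(nrow(samples), 0, config$sd_batch)

  abund <- matrix(NA_real_, B, nrow(samples),
                  dimnames = list(barcodes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    k <- match(samples$day[j], tp)
    abund[, j] <- a[, k] + batch[j] +
      stats::rnorm(B, 0, config$sd_meas)
  }

  ## derive observed rates with the mean-baseline replicate pairing
  out <- vector("list", D)
  for (d in seq_len(D)) {
    i0 <- which(samples$day == tp[d])
    i1 <- which(samples$day == tp[d + 1L])
    base <- rowMeans(abund[, i0, drop = FALSE])
    out[[d]] <- do.call(rbind, lapply(i1, function(j) {
      data.frame(barcode = barcodes, gene = genes[bgene],
                 interval = d, t_start = tp[d], t_end = tp[d + 1L],
                 replicate = samples$replicate[j],
                 rate = (abund[, j] - base) / delta[d],
                 stringsAsFactors = FALSE)
    }))
  }
  rates <- do.call(rbind, out)
  rownames(rates) <- NULL
  attr(rates, "intervals") <- data.frame(start = tp[-length(tp)], end = tp[-1])

  structure(list(truth = truth, barcode_truth = brate, abund = abund,
                 samples = samples, rates = rates, config = config),
            class = "tn_sim")
}

#' @export
print.tn_sim <- function(x, ...) {
  cat(sprintf("tn_sim: %d genes, %d barcodes, days %s, sds (intra %.2g, meas %.2g, batch %.2g), seed %d\n",
              x$config$n_genes, nrow(x$abund),
              paste(x$config$timepoints, collapse = "/"),
              x$config$sd_intra, x$config$sd_meas, x$config$sd_batch,
              x$config$seed))
  invisible(x)
}

#' Simulate observations directly from the longitudinal model
#'
#' Generates data under the hierarchical model's own observation process:
#' gene effect vectors from a multivariate normal (marginal sd \code{tau},
#' compound-symmetric correlation \code{rho}) around population means
#' \code{beta}, and iid normal observations around the gene-interval mean with
#' per-interval residual sds. Used for calibration checks where the fitted
#' model matches the generating process.
#'
#' @param n_genes Number of genes.
#' @param n_obs Observations per gene per interval (barcodes x replicates).
#' @param beta Population interval means (length 3).
#' @param tau Gene-effect sds (length 3 or scalar).
#' @param rho Cross-interval gene-effect correlation.
#' @param sigma Residual sds per interval (length 3 or scalar).
#' @param seed RNG seed.
#' @return List with \code{truth} (gene x interval means) and \code{rates}
#'   (observation table suitable for \code{\link{fit_longitudinal}}).
#' @export
simulate_from_model <- function(n_genes = 200, n_obs = 12,
                                beta = c(0, 0, 0), tau = 0.3, rho = 0.5,
                                sigma = 0.3, seed = 1L) {
  set.seed(seed)
  tau <- rep(tau, length.out = 3)
  sigma <- rep(sigma, length.out = 3)
  Sig <- (diag(1 - rho, 3) + rho) * (tau %o% tau)
  s <- matrix(stats::rnorm(n_genes * 3), n_genes, 3) %*% chol(Sig) +
    matrix(beta, n_genes, 3, byrow = TRUE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  rownames(s) <- genes
  rates <- do.call(rbind, lapply(1:3, function(d) {
    data.frame(gene = rep(genes, each = n_obs),
               interval = d,
               replicate = as.character(rep(seq_len(n_obs), n_genes)),
               rate = stats::rnorm(n_genes * n_obs,
                                   rep(s[, d], each = n_obs), sigma[d]),
               stringsAsFactors = FALSE)
  }))
  attr(rates, "intervals") <- data.frame(start = c(0, 1, 4), end = c(1, 4, 10))
  list(truth = s, rates = rates)
}
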