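#' BarSeq-style baseline estimator with t-based intervals
#'
#' Estimates each gene-by-interval selection rate as the plain mean of its
#' barcode-by-replicate observed rates, with a 90\% t interval
#' \code{mean +/- t(0.95, n-1) * sd/sqrt(n)}. Cells with a single observation
#' get an undefined interval and are excluded from coverage computations.
#'
#' @param rates Selection-rate table (from \code{\link{simulate_tnseq}} or
#'   \code{\link{compute_selection_rates}}) with columns \code{gene},
#'   \code{interval}, \code{rate}.
#' @param level Interval confidence level (default 0.90).
#' @return Data frame: \code{gene}, \code{interval}, \code{n},
#'   \code{estimate}, \code{lower}, \code{upper}.
#' @export
barseq_estimate <- function(rates, level = 0.90) {
  ok <- !is.na(rates$gene) & is.finite(rates$rate)
  rates <- rates[ok, , drop = FALSE]
  f <- factor(paste(rates$gene, rates$interval, sep = "\r"))
  n <- tabulate(f, nbins = nlevels(f))
  s1 <- rowsum(rates$rate, f)[levels(f), 1]
  s2 <- rowsum(rates$rate^2, f)[levels(f), 1]
  mean_ <- s1 / n
  var_ <- pmax(s2 - n * mean_^2, 0) / pmax(n - 1L, 1L)
  parts <- strsplit(levels(f), "\r", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  interval <- as.integer(vapply(parts, `[`, "", 2L))
  hw <- stats::qt(1 - (1 - level) / 2, pmax(n - 1L, 1L)) * sqrt(var_ / n)
  hw[n < 2] <- NA_real_
  data.frame(gene = gene, interval = interval, n = n, estimate = mean_,
             lower = mean_ - hw, upper = mean_ + hw,
             stringsAsFactors = FALSE)
}

#' Gene-by-interval estimates with credible intervals from a tnfit
#'
#' Extracts posterior medians and central credible intervals in the same
#' format as \code{\link{barseq_estimate}}, for benchmark comparisons.
#'
#' @param fit A \code{tnfit}.
#' @param level Credible level (default 0.90).
#' @return Data frame: \code{gene}, \code{interval}, \code{estimate},
#'   \code{lower}, \code{upper}.
#' @export
bayes_estimate <- function(fit, level = 0.90) {
  stopifnot(inherits(fit, "tnfit"))
  a <- (1 - level) / 2
  out <- vector("list", 3L)
  for (d in 1:3) {
    q <- apply(fit$draws$s[, , d, drop = TRUE], 2L, stats::quantile,
               probs = c(a, 0.5, 1 - a), names = FALSE)
    out[[d]] <- data.frame(gene = fit$genes, interval = d,
                           estimate = q[2, ], lower = q[1, ], upper = q[3, ],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Evaluate estimates against simulation truth
#'
#' @param truth Gene x interval matrix of true rates (gene row names), as in
#'   \code{tn_sim$truth}.
#' @param estimates Data frame with \code{gene}, \code{interval},
#'   \code{estimate}, \code{lower}, \code{upper}.
#' @return List with \code{rmse} (over all cells with estimates),
#'   \code{coverage} (fraction of defined intervals containing the truth),
#'   \code{n_rmse}, \code{n_coverage}, \code{n_covered}, and the per-cell
#'   \code{errors}/\code{covered} vectors with gene index attribute for
#'   bootstrap resampling.
#' @export
evaluate_estimates <- function(truth, estimates) {
  gi <- match(estimates$gene, rownames(truth))
  if (all(is.na(gi))) stop("no estimates align to truth")
  ok <- !is.na(gi)
  est <- estimates[ok, , drop = FALSE]
  tru <- truth[cbind(gi[ok], est$interval)]
  err <- est$estimate - tru
  covered <- est$lower <= tru & tru <= est$upper
  list(rmse = sqrt(mean(err^2)),
       coverage = mean(covered, na.rm = TRUE),
       n_rmse = length(err),
       n_coverage = sum(!is.na(covered)),
       n_covered = sum(covered, na.rm = TRUE),
       errors = err, covered = covered,
       gene_index = gi[ok])
}

## percentile bootstrap CI for per-condition RMSE and coverage, resampling
## genes (cells are dependent within gene)
.boot_condition <- function(ev, reps, seed) {
  set.seed(seed)
  genes <- unique(ev$gene_index)
  idx_by_gene <- split(seq_along(ev$gene_index), ev$gene_index)
  stats_ <- matrix(NA_real_, reps, 2)
  for (b in seq_len(reps)) {
    take <- unlist(idx_by_gene[as.character(sample(genes, replace = TRUE))],
                   use.names = FALSE)
    stats_[b, 1] <- sqrt(mean(ev$errors[take]^2))
    stats_[b, 2] <- mean(ev$covered[take], na.rm = TRUE)
  }
  list(rmse_ci = stats::quantile(stats_[, 1], c(0.025, 0.975), names = FALSE),
       cov_ci = stats::quantile(stats_[, 2], c(0.025, 0.975), names = FALSE))
}

#' Run the noise-grid benchmark of Bayesian vs BarSeq-style estimation
#'
#' Simulates one dataset per noise condition (by default the full Cartesian
#' grid of intragenic, measurement, and batch sds over \code{sd_levels}),
#' estimates gene-by-interval selection rates with the hierarchical Bayesian
#' model and/or the BarSeq-style t-interval baseline, and scores each method
#' by RMSE against the latent truth and by the coverage of its 90\% intervals.
#' Per-condition bootstrap CIs resample genes; grid-median CIs resample
#' conditions.
#'
#' @param n_genes Genes per condition (default 1000).
#' @param sd_levels Noise sd levels crossed over the three channels
#'   (default \code{c(0, 0.1, 1)} days^-1).
#' @param grid Optional explicit condition data frame with columns
#'   \code{sd_intra}, \code{sd_meas}, \code{sd_batch} (overrides
#'   \code{sd_levels}).
#' @param methods Subset of \code{c("bayes", "barseq")}.
#' @param bootstrap_reps Bootstrap resamples (default 1000).
#' @param seed Master seed; per-condition simulation seeds are derived from
#'   it.
#' @param fit_chains,fit_warmup,fit_draws MCMC layout for the per-condition
#'   Bayesian fits (defaults 2 chains x 300 warmup + 500 draws, sized for a
#'   27-condition grid).
#' @param ... Further arguments passed to \code{\link{sim_config}} (e.g.
#'   \code{n_replicates}, \code{effect_sd}).
#' @return A \code{benchmark_result}: list with \code{conditions} (per
#'   condition x method metrics with bootstrap CIs) and \code{medians} (grid
#'   medians per method with bootstrap CIs).
#' @export
run_benchmark_grid <- function(n_genes = 1000, sd_levels = c(0, 0.1, 1),
                               grid = NULL,
                               methods = c("bayes", "barseq"),
                               bootstrap_reps = 1000, seed = 1L,
                               fit_chains = 2, fit_warmup = 300,
                               fit_draws = 500, ...) {
  methods <- match.arg(methods, c("bayes", "barseq"), several.ok = TRUE)
  if (is.null(grid))
    grid <- expand.grid(sd_intra = sd_levels, sd_meas = sd_levels,
                        sd_batch = sd_levels)
  set.seed(seed)
  cond_seeds <- sample.int(2^30, nrow(grid))
  boot_seeds <- sample.int(2^30, nrow(grid) * length(methods) + 1L)

  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    cfg <- sim_config(n_genes = n_genes, sd_intra = grid$sd_intra[i],
                      sd_meas = grid$sd_meas[i], sd_batch = grid$sd_batch[i],
                      seed = cond_seeds[i], ...)
    sim <- simulate_tnseq(cfg)
    for (m in methods) {
      k <- k + 1L
      ev <- tryCatch({
        est <- if (m == "barseq") {
          barseq_estimate(sim$rates)
        } else {
          spec <- model_spec(chains = fit_chains, warmup = fit_warmup,
                             draws = fit_draws, seed = cond_seeds[i])
          fit <- suppressWarnings(fit_longitudinal(sim$rates, spec))
          bayes_estimate(fit)
        }
        evaluate_estimates(sim$truth, est)
      }, error = function(e) {
        message(sprintf("condition %d method %s failed: %s", i, m,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(ev)) {
        rows[[k]] <- data.frame(grid[i, , drop = FALSE], method = m,
                                rmse = NA_real_, coverage = NA_real_,
                                rmse_lo = NA, rmse_hi = NA,
                                cov_lo = NA, cov_hi = NA,
                                n_cells = NA, n_coverage = NA)
        next
      }
      bci <- .boot_condition(ev, bootstrap_reps, boot_seeds[k])
      rows[[k]] <- data.frame(grid[i, , drop = FALSE], method = m,
                              rmse = ev$rmse, coverage = ev$coverage,
                              rmse_lo = bci$rmse_ci[1], rmse_hi = bci$rmse_ci[2],
                              cov_lo = bci$cov_ci[1], cov_hi = bci$cov_ci[2],
                              n_cells = ev$n_rmse,
                              n_coverage = ev$n_coverage)
    }
  }
  conditions <- do.call(rbind, rows)
  rownames(conditions) <- NULL

  ## grid medians with bootstrap over conditions
  set.seed(boot_seeds[length(boot_seeds)])
  med_rows <- lapply(methods, function(m) {
    sub <- conditions[conditions$method == m & !is.na(conditions$rmse), ]
    bs <- matrix(NA_real_, bootstrap_reps, 2)
    for (b in seq_len(bootstrap_reps)) {
      take <- sample(nrow(sub), replace = TRUE)
      bs[b, ] <- c(stats::median(sub$rmse[take]),
                   stats::median(sub$coverage[take]))
    }
    data.frame(method = m,
               median_rmse = stats::median(sub$rmse),
               rmse_lo = stats::quantile(bs[, 1], 0.025, names = FALSE),
               rmse_hi = stats::quantile(bs[, 1], 0.975, names = FALSE),
               median_coverage = stats::median(sub$coverage),
               cov_lo = stats::quantile(bs[, 2], 0.025, names = FALSE),
               cov_hi = stats::quantile(bs[, 2], 0.975, names = FALSE),
               n_conditions = nrow(sub))
  })
  structure(list(conditions = conditions,
                 medians = do.call(rbind, med_rows),
                 n_genes = n_genes, seed = seed,
                 bootstrap_reps = bootstrap_reps),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d conditions x %d genes (seed %d)\n",
              nrow(x$conditions) / length(unique(x$conditions$method)),
              x$n_genes, x$seed))
  cat("\ngrid medians (95% bootstrap CIs over conditions):\n")
  print(x$medians, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pooled coverage over a subset of benchmark conditions
#'
#' Averages per-condition coverage over the conditions selected by the
#' predicate, e.g. the high-noise regime
#' \code{sd_intra == 1 & sd_meas == 1} marginalized over batch levels.
#'
#' @param result A \code{benchmark_result}.
#' @param method One of \code{"bayes"}, \code{"barseq"}.
#' @param subset Logical vector or expression-result over
#'   \code{result$conditions} rows.
#' @return Mean coverage over the selected conditions.
#' @export
coverage_subset <- function(result, method, subset) {
  sub <- result$conditions[result$conditions$method == method & subset, ]
  mean(sub$coverage, na.rm = TRUE)
}
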