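#' Read and validate a declarative run configuration
#'
#' The configuration is a YAML file with nested sections: \code{paths}
#' (poolcount, metadata, neutral, optionally regulons, output),
#' \code{preprocess} (min_total, window, pseudocount), \code{model} (prior and
#' sampler settings passed to \code{\link{model_spec}}), \code{seascape}
#' (settings for \code{\link{seascape_priors}}), \code{cluster}
#' (threshold, k, restarts), \code{benchmark} (settings for
#' \code{\link{run_benchmark_grid}}), and \code{seed}.
#'
#' @param path YAML config path, or a pre-built list.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  if (is.null(config$paths)) stop("config validation failed at key: paths")
  for (key in c("poolcount", "metadata", "neutral")) {
    p <- config$paths[[key]]
    if (is.null(p)) stop("config validation failed at key: paths.", key)
    if (!file.exists(p))
      stop("config validation failed at key: paths.", key,
           " (file not found: ", p, ")")
  }
  if (!is.null(config$paths$regulons) && !file.exists(config$paths$regulons))
    stop("config validation failed at key: paths.regulons (file not found)")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.log_msg <- function(logfile, level, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the analysis pipeline end-to-end
#'
#' Orchestrates the stages \code{preprocess} (count table to selection
#' rates), \code{fit} (hierarchical longitudinal model), \code{seascape}
#' (latent-axis model on the gene summaries), and \code{cluster} (PCA and
#' trajectory k-means of non-neutral genes). Each stage writes TSV artifacts
#' plus a manifest JSON recording the config, seeds, package version, and an
#' md5 hash of every output file. Reruns with identical config and seeds
#' reproduce deterministic stages byte-identically.
#'
#' @param config Config list or YAML path (see \code{\link{read_run_config}}).
#' @param stages Subset of c("preprocess", "fit", "seascape", "cluster").
#' @param out_dir Output directory (default \code{config$paths$output} or
#'   "tnseascape_out").
#' @return (Invisibly) the manifest list.
#' @export
run_pipeline <- function(config,
                         stages = c("preprocess", "fit", "seascape", "cluster"),
                         out_dir = NULL) {
  config <- read_run_config(config)
  stages <- match.arg(stages, c("preprocess", "fit", "seascape", "cluster"),
                      several.ok = TRUE)
  if (is.null(out_dir))
    out_dir <- if (!is.null(config$paths$output)) config$paths$output
               else "tnseascape_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run.log")
  artifacts <- character(0)
  manifest <- list(package = "tnseascape",
                   version = as.character(utils::packageVersion("tnseascape")),
                   seed = config$seed, stages = stages, config = config,
                   started = format(Sys.time()), completed_stages = character(0))
  pp <- config$preprocess
  getd <- function(x, d) if (is.null(x)) d else x

  rates_path <- file.path(out_dir, "selection_rates.tsv")
  summ_path <- file.path(out_dir, "gene_summaries.tsv")

  if ("preprocess" %in% stages) {
    .log_msg(logfile, "INFO", "preprocess: reading ", config$paths$poolcount)
    metadata <- utils::read.delim(config$paths$metadata,
                                  stringsAsFactors = FALSE)
    metadata$replicate <- as.character(metadata$replicate)
    pc <- read_poolcount(config$paths$poolcount, metadata)
    neutral <- readLines(config$paths$neutral)
    neutral <- trimws(neutral[nzchar(trimws(neutral))])
    pc <- filter_day0(pc, getd(pp$min_total, 3))
    pc <- positional_correction(pc, getd(pp$window, 251),
                                getd(pp$pseudocount, 0.5))
    ab <- clr_transform(pc, neutral, getd(pp$pseudocount, 0.5))
    rates <- compute_selection_rates(ab)
    artifacts <- c(artifacts,
                   .write_tsv(rates, rates_path),
                   write_abundance(ab, file.path(out_dir, "abundance.tsv")))
    manifest$completed_stages <- c(manifest$completed_stages, "preprocess")
    .log_msg(logfile, "INFO", sprintf("preprocess: %d rate observations", nrow(rates)))
  }

  fit <- NULL
  if ("fit" %in% stages) {
    if (!file.exists(rates_path))
      stop("fit stage requires preprocess output at ", rates_path)
    rates <- read_selection_rates(rates_path)
    ms <- config$model
    spec <- model_spec(chains = getd(ms$chains, 4),
                       warmup = getd(ms$warmup, 500),
                       draws = getd(ms$draws, 1000),
                       seed = getd(ms$seed, config$seed))
    .log_msg(logfile, "INFO", "fit: sampling the longitudinal model")
    fit <- fit_longitudinal(rates, spec)
    threshold <- getd(config$cluster$threshold, 0.9)
    summ <- classify(fit, threshold)
    diag_df <- data.frame(parameter = names(fit$diagnostics$rhat_scalars),
                          rhat = fit$diagnostics$rhat_scalars,
                          ess = fit$diagnostics$ess_scalars)
    artifacts <- c(artifacts,
                   .write_tsv(summ, summ_path),
                   .write_tsv(diag_df, file.path(out_dir, "diagnostics.tsv")),
                   .write_tsv(interval_summary(summ),
                              file.path(out_dir, "interval_summary.tsv")))
    manifest$completed_stages <- c(manifest$completed_stages, "fit")
    if (!fit$diagnostics$converged)
      .log_msg(logfile, "WARN", "fit: convergence gate failed")
  }

  if ("seascape" %in% stages) {
    if (is.null(fit) && !file.exists(summ_path))
      stop("seascape stage requires fit output at ", summ_path)
    summ <- if (!is.null(fit)) fit$summaries
            else utils::read.delim(summ_path, stringsAsFactors = FALSE)
    obs <- summ[summ$quantity %in% c("s1", "s2", "s3"), ]
    obs$interval <- match(obs$quantity, c("s1", "s2", "s3"))
    sp <- config$seascape
    pr <- seascape_priors(chains = getd(sp$chains, 4),
                          warmup = getd(sp$warmup, 750),
                          draws = getd(sp$draws, 750),
                          seed = getd(sp$seed, config$seed))
    .log_msg(logfile, "INFO", "seascape: sampling the latent-axis model")
    sfit <- fit_seascape(obs[, c("gene", "interval", "median", "sd")], pr)
    integ <- integrate_seascape(sfit)
    artifacts <- c(artifacts,
                   .write_tsv(sfit$z_summary, file.path(out_dir, "z_coordinates.tsv")),
                   .write_tsv(summary(sfit), file.path(out_dir, "seascape_params.tsv")),
                   .write_tsv(integ$curve, file.path(out_dir, "integrated_landscape.tsv")))
    if (!is.null(config$paths$regulons)) {
      reg <- utils::read.delim(config$paths$regulons, stringsAsFactors = FALSE)
      rp <- regulon_prediction(sfit, reg)
      artifacts <- c(artifacts,
                     .write_tsv(rp, file.path(out_dir, "regulon_predictions.tsv")))
    }
    manifest$completed_stages <- c(manifest$completed_stages, "seascape")
  }

  if ("cluster" %in% stages) {
    if (is.null(fit) && !file.exists(summ_path))
      stop("cluster stage requires fit output at ", summ_path)
    summ <- if (!is.null(fit)) classify(fit, getd(config$cluster$threshold, 0.9))
            else utils::read.delim(summ_path, stringsAsFactors = FALSE)
    wide <- stats::reshape(
      summ[summ$quantity %in% c("s1", "s2", "s3"), c("gene", "quantity", "median")],
      direction = "wide", idvar = "gene", timevar = "quantity")
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- wide$gene
    colnames(mat) <- c("s1", "s2", "s3")
    nn <- unique(summ$gene[summ$label != "neutral" &
                           summ$quantity %in% c("s1", "s2", "s3")])
    mat_nn <- mat[rownames(mat) %in% nn, , drop = FALSE]
    cl_cfg <- config$cluster
    .log_msg(logfile, "INFO", sprintf("cluster: %d non-neutral genes", nrow(mat_nn)))
    pca <- pca_trajectories(mat_nn)
    cl <- cluster_trajectories(mat_nn, k = getd(cl_cfg$k, 4),
                               restarts = getd(cl_cfg$restarts, 25),
                               seed = config$seed)
    artifacts <- c(artifacts,
                   .write_tsv(data.frame(gene = names(cl$cluster),
                                         cluster = as.character(cl$cluster)),
                              file.path(out_dir, "clusters.tsv")),
                   .write_tsv(data.frame(gene = rownames(pca$scores),
                                         pca$scores),
                              file.path(out_dir, "pca_scores.tsv")),
                   .write_tsv(data.frame(component = seq_along(pca$variance_fraction),
                                         variance_fraction = pca$variance_fraction),
                              file.path(out_dir, "pca_variance.tsv")))
    manifest$completed_stages <- c(manifest$completed_stages, "cluster")
  }

  manifest$finished <- format(Sys.time())
  manifest$files <- data.frame(path = basename(artifacts),
                               md5 = unname(tools::md5sum(artifacts)),
                               stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .log_msg(logfile, "INFO", "pipeline complete: ", length(artifacts), " artifacts")
  invisible(manifest)
}

#' Run the simulation benchmark from a config
#'
#' Wraps \code{\link{run_benchmark_grid}}: reads the \code{benchmark} section
#' of the config, runs the grid, and writes per-condition and grid-median TSVs
#' plus a provenance JSON.
#'
#' @param config Config list or YAML path with a \code{benchmark} section.
#' @param out_dir Output directory.
#' @return (Invisibly) the \code{benchmark_result}.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bm <- config$benchmark
  if (is.null(bm)) stop("config validation failed at key: benchmark")
  if (is.null(out_dir))
    out_dir <- if (!is.null(config$paths$output)) config$paths$output
               else "tnseascape_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  getd <- function(x, d) if (is.null(x)) d else x
  grid <- if (!is.null(bm$grid)) as.data.frame(bm$grid) else NULL
  res <- run_benchmark_grid(
    n_genes = getd(bm$n_genes, 1000),
    sd_levels = getd(bm$sd_levels, c(0, 0.1, 1)),
    grid = grid,
    methods = getd(bm$methods, c("bayes", "barseq")),
    bootstrap_reps = getd(bm$bootstrap_reps, 1000),
    seed = getd(bm$seed, getd(config$seed, 1L)),
    fit_chains = getd(bm$fit_chains, 2),
    fit_warmup = getd(bm$fit_warmup, 300),
    fit_draws = getd(bm$fit_draws, 500))
  .write_tsv(res$conditions, file.path(out_dir, "benchmark_conditions.tsv"))
  .write_tsv(res$medians, file.path(out_dir, "benchmark_medians.tsv"))
  jsonlite::write_json(list(n_genes = res$n_genes, seed = res$seed,
                            bootstrap_reps = res$bootstrap_reps,
                            config = bm),
                       file.path(out_dir, "benchmark_provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
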