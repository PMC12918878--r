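#' PCA of gene selection-rate trajectories
#'
#' Centered (optionally scaled) principal component analysis of the genes x
#' intervals matrix of posterior-median selection rates.
#'
#' @param mat Numeric genes x intervals matrix (gene row names recommended).
#' @param scale. Scale columns to unit variance before rotation
#'   (default FALSE).
#' @return List with \code{loadings} (unit-norm columns), \code{scores}
#'   (per-gene component scores), and \code{variance_fraction} (sums to 1).
#' @export
pca_trajectories <- function(mat, scale. = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stop("need at least 3 genes for PCA")
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation, scores = pc$x, variance_fraction = vf)
}

.roman <- function(i) as.character(utils::as.roman(i))

#' Cluster fitness trajectories with spherical k-means
#'
#' Rows are unit-length normalized before Euclidean k-means, which makes the
#' clustering equivalent to cosine-distance clustering on trajectory shapes;
#' the best of \code{restarts} random starts (by within-cluster sum of
#' squares) is kept. Clusters are then relabeled deterministically by the sign
#' pattern of the cluster-mean early and late rates (s1, s3):
#' (+,+) -> I, (-,+) -> II, (-,-) -> III, (+,-) -> IV, with ties broken by
#' cluster-mean s1 descending.
#'
#' @param mat Numeric genes x 3 matrix of posterior-median interval rates.
#' @param k Number of clusters (default 4).
#' @param restarts Random restarts (default 25).
#' @param seed RNG seed.
#' @param normalize "cosine" (default: unit-normalize rows) or "euclidean"
#'   (raw rows).
#' @return A \code{trajectory_clusters} object: list with \code{cluster}
#'   (named vector of labels), \code{centers} (cluster means of the raw
#'   rows, in label order), \code{sizes}, and \code{k}.
#' @export
cluster_trajectories <- function(mat, k = 4, restarts = 25, seed = 1L,
                                 normalize = c("cosine", "euclidean")) {
  normalize <- match.arg(normalize)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(mat)) stop("k exceeds the number of genes")
  x <- mat
  if (normalize == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) {
      warning(sum(nrm == 0), " all-zero trajectories dropped before clustering")
      x <- x[nrm > 0, , drop = FALSE]
      mat <- mat[nrm > 0, , drop = FALSE]
      nrm <- nrm[nrm > 0]
    }
    x <- x / nrm
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)

  ## deterministic relabeling by sign pattern of raw-space cluster means
  raw_centers <- rowsum(mat, km$cluster) / as.vector(table(km$cluster))
  pat_rank <- function(m1, m3) {
    if (m1 >= 0 && m3 >= 0) 1L
    else if (m1 < 0 && m3 >= 0) 2L
    else if (m1 < 0 && m3 < 0) 3L
    else 4L
  }
  ranks <- mapply(pat_rank, raw_centers[, 1], raw_centers[, 3])
  ord <- order(ranks, -raw_centers[, 1])
  labels <- .roman(seq_len(k))
  relabel <- stats::setNames(labels, rownames(raw_centers)[ord])
  cluster <- factor(relabel[as.character(km$cluster)], levels = labels)
  names(cluster) <- rownames(mat)
  centers <- raw_centers[ord, , drop = FALSE]
  rownames(centers) <- labels
  structure(list(cluster = cluster, centers = centers,
                 sizes = as.vector(table(cluster)), k = k,
                 tot_withinss = km$tot.withinss),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf("trajectory_clusters: k = %d, sizes %s\n", x$k,
              paste(x$sizes, collapse = "/")))
  print(round(x$centers, 3))
  invisible(x)
}

.new_permnull <- function(observed, null, seed, exact) {
  structure(list(observed = observed, null = null,
                 exceedance = mean(null < observed),
                 n_replicates = length(null), seed = seed, exact = exact),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: observed %.4g, Pr[observed > null] = %.4g (%s, %d replicates)\n",
              x$observed, x$exceedance,
              if (x$exact) "exhaustive" else "Monte Carlo", x$n_replicates))
  invisible(x)
}

#' Size-matched random-gene-set null for regulon deleterious burden
#'
#' The observed statistic is the expected number of deleterious genes in the
#' regulon, computed as the sum over its members of each gene's posterior
#' probability of being deleterious. Null replicates draw uniform random gene
#' sets of the same size from the universe and compute the same sum. The
#' exceedance probability Pr[observed > null] is the fraction of null
#' replicates strictly below the observed value (ties count against
#' exceedance).
#'
#' @param probs Named numeric vector of per-gene deleterious probabilities in
#'   [0, 1] (the gene universe).
#' @param regulon Character vector of regulon members.
#' @param n_draws Monte Carlo replicates (default 10000).
#' @param seed RNG seed.
#' @param exact If TRUE, enumerate all size-matched subsets exhaustively
#'   (universe must be small).
#' @return A \code{permutation_null} object.
#' @export
regulon_enrichment_null <- function(probs, regulon, n_draws = 10000,
                                    seed = 1L, exact = FALSE) {
  stopifnot(is.numeric(probs), !is.null(names(probs)),
            all(probs >= 0 & probs <= 1))
  missing <- setdiff(regulon, names(probs))
  if (length(missing)) {
    warning("dropping ", length(missing), " regulon gene(s) absent from universe")
    regulon <- intersect(regulon, names(probs))
  }
  if (!length(regulon)) stop("regulon empty after filtering")
  m <- length(regulon)
  observed <- sum(probs[regulon])
  if (exact) {
    if (choose(length(probs), m) > 2e5)
      stop("too many subsets for exhaustive enumeration")
    null <- as.vector(utils::combn(unname(probs), m, FUN = sum))
    seed <- NA_integer_
  } else {
    set.seed(seed)
    null <- replicate(n_draws, sum(sample(unname(probs), m)))
  }
  .new_permnull(observed, null, seed, exact)
}

## all permutations of 1..n (n small)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Permutation null for mutation counts by fitness bin
#'
#' For each fitness bin the observed statistic is the total mutation count of
#' its genes. Null replicates permute the gene-to-bin assignment (equivalently
#' shuffle the counts across genes) and recompute the bin totals, giving a
#' per-bin null distribution; exceedance is Pr[observed > null] under strict
#' inequality.
#'
#' @param bins Factor or character vector assigning each gene to a fitness
#'   bin.
#' @param counts Nonnegative numeric vector of per-gene mutation counts,
#'   aligned with \code{bins}.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param exact If TRUE, enumerate all permutations exhaustively (at most 7
#'   genes).
#' @return A \code{bin_permutation_null} object: per-bin observed totals, null
#'   summaries (median, 80\% and 95\% intervals), exceedance probabilities,
#'   and the null matrix.
#' @export
mutation_count_permutation <- function(bins, counts, n_perm = 10000,
                                       seed = 1L, exact = FALSE) {
  stopifnot(length(bins) == length(counts), all(counts >= 0),
            !anyNA(bins), !anyNA(counts))
  ## keep caller-supplied levels so empty bins stay reported
  if (!is.factor(bins)) bins <- factor(bins)
  bin_sum <- function(cnt) as.vector(tapply(cnt, bins, sum, default = 0))
  observed <- bin_sum(counts)
  names(observed) <- levels(bins)
  if (exact) {
    n <- length(counts)
    if (n > 7) stop("exhaustive enumeration limited to 7 genes")
    P <- .all_perms(n)
    null <- do.call(rbind, lapply(seq_len(nrow(P)),
                                  function(i) bin_sum(counts[P[i, ]])))
    seed <- NA_integer_
  } else {
    set.seed(seed)
    null <- do.call(rbind, lapply(seq_len(n_perm),
                                  function(i) bin_sum(sample(counts))))
  }
  colnames(null) <- levels(bins)
  summ <- data.frame(
    bin = levels(bins),
    observed = observed,
    null_median = apply(null, 2L, stats::median),
    null_lo80 = apply(null, 2L, stats::quantile, 0.10, names = FALSE),
    null_hi80 = apply(null, 2L, stats::quantile, 0.90, names = FALSE),
    null_lo95 = apply(null, 2L, stats::quantile, 0.025, names = FALSE),
    null_hi95 = apply(null, 2L, stats::quantile, 0.975, names = FALSE),
    exceedance = vapply(seq_along(observed),
                        function(i) mean(null[, i] < observed[i]), 0),
    row.names = NULL)
  structure(list(summary = summ, null = null, seed = seed, exact = exact,
                 n_replicates = nrow(null)),
            class = "bin_permutation_null")
}

#' @export
print.bin_permutation_null <- function(x, ...) {
  cat(sprintf("bin_permutation_null: %d bins, %d %s replicates\n",
              nrow(x$summary), x$n_replicates,
              if (x$exact) "exhaustive" else "Monte Carlo"))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
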