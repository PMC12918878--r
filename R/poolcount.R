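#' Read a poolcount-style barcode count table
#'
#' Reads the tab-separated "poolcount" format produced by the standard
#' RB-TnSeq counting pipeline: leading columns \code{barcode}, \code{rcbarcode},
#' \code{scaffold}, \code{strand}, \code{pos}, followed by one nonnegative
#' integer count column per sequenced sample. Barcodes are ordered by
#' (scaffold, position) on load; unmapped barcodes (no gene annotation) are
#' retained with \code{NA} gene.
#'
#' @param path Path to the poolcount TSV (header required).
#' @param metadata Data frame of per-sample metadata with columns
#'   \code{sample}, \code{day}, \code{replicate}, and optionally \code{batch}
#'   and \code{condition}. Every count column of the file must appear exactly
#'   once in \code{metadata$sample}.
#' @param annotation Optional gene annotation: either \code{NULL} (use a
#'   \code{gene}/\code{locusId} column in the file if present), or a data
#'   frame with columns \code{gene}, \code{scaffold}, \code{begin}, \code{end}
#'   used to assign each insertion position to a locus tag.
#'
#' @return A \code{poolcount} object: a list with elements \code{info}
#'   (barcode records: barcode, rcbarcode, scaffold, strand, pos, gene),
#'   \code{counts} (barcode x sample numeric matrix), and \code{samples}
#'   (the metadata, ordered as the count columns).
#' @export
read_poolcount <- function(path, metadata, annotation = NULL) {
  if (!file.exists(path)) stop("poolcount file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  fixed <- c("barcode", "rcbarcode", "scaffold", "strand", "pos")
  missing_fixed <- setdiff(fixed, names(raw))
  if (length(missing_fixed))
    stop("poolcount header lacks required column(s): ",
         paste(missing_fixed, collapse = ", "))
  gene_col <- intersect(c("gene", "locusId"), names(raw))[1]
  sample_cols <- setdiff(names(raw), c(fixed, gene_col))
  if (!length(sample_cols)) stop("poolcount file has no count columns")

  if (!is.data.frame(metadata) ||
      !all(c("sample", "day", "replicate") %in% names(metadata)))
    stop("metadata must be a data frame with columns sample, day, replicate")
  if (anyDuplicated(metadata$sample))
    stop("duplicate sample metadata for: ",
         paste(unique(metadata$sample[duplicated(metadata$sample)]), collapse = ", "))
  uncovered <- setdiff(sample_cols, metadata$sample)
  if (length(uncovered))
    stop("metadata missing for sample column(s): ",
         paste(uncovered, collapse = ", "))
  metadata <- metadata[match(sample_cols, metadata$sample), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.numeric(metadata$day) || any(is.na(metadata$day)) || any(metadata$day < 0))
    stop("metadata day must be nonnegative numeric")

  counts <- matrix(NA_real_, nrow(raw), length(sample_cols),
                   dimnames = list(NULL, sample_cols))
  for (sc in sample_cols) {
    v <- suppressWarnings(as.numeric(raw[[sc]]))
    bad <- which(is.na(v) | v != round(v) | v < 0)
    if (length(bad))
      stop(sprintf("non-integer count '%s' in column '%s' at line %d",
                   raw[[sc]][bad[1]], sc, bad[1] + 1L))
    counts[, sc] <- v
  }

  pos <- suppressWarnings(as.integer(raw$pos))
  if (any(is.na(pos) | pos < 1)) stop("pos column must be 1-based positive integers")
  if (!all(raw$strand %in% c("+", "-")))
    stop("strand column must be '+' or '-'")
  if (any(!nzchar(raw$barcode))) stop("empty barcode encountered")

  gene <- if (!is.na(gene_col)) {
    g <- raw[[gene_col]]
    g[!nzchar(g)] <- NA_character_
    g
  } else rep(NA_character_, nrow(raw))
  info <- data.frame(barcode = raw$barcode, rcbarcode = raw$rcbarcode,
                     scaffold = raw$scaffold, strand = raw$strand,
                     pos = pos, gene = gene, stringsAsFactors = FALSE)
  if (is.data.frame(annotation)) {
    stopifnot(all(c("gene", "scaffold", "begin", "end") %in% names(annotation)))
    for (i in seq_len(nrow(info))) {
      hit <- which(annotation$scaffold == info$scaffold[i] &
                   annotation$begin <= info$pos[i] &
                   annotation$end >= info$pos[i])
      if (length(hit)) info$gene[i] <- annotation$gene[hit[1]]
    }
  }

  ord <- order(info$scaffold, info$pos)
  new_poolcount(info[ord, , drop = FALSE], counts[ord, , drop = FALSE], metadata)
}

new_poolcount <- function(info, counts, samples) {
  rownames(info) <- NULL
  rownames(counts) <- info$barcode
  structure(list(info = info, counts = counts, samples = samples),
            class = "poolcount")
}

#' @export
print.poolcount <- function(x, ...) {
  cat(sprintf("poolcount: %d barcodes x %d samples (%d genes, %d unmapped barcodes)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(stats::na.omit(x$info$gene))), sum(is.na(x$info$gene))))
  cat("days:", paste(sort(unique(x$samples$day)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.poolcount <- function(x) dim(x$counts)

#' Drop barcodes with insufficient day-0 representation
#'
#' Removes barcodes whose summed counts across all day-0 samples (library-only
#' and co-culture replicates combined) fall below \code{min_total}. The sample
#' set is unchanged.
#'
#' @param x A \code{poolcount} object.
#' @param min_total Minimum summed day-0 count to retain a barcode (default 3,
#'   i.e. barcodes with fewer than three total day-0 counts are removed).
#' @return A filtered \code{poolcount} object.
#' @export
filter_day0 <- function(x, min_total = 3) {
  stopifnot(inherits(x, "poolcount"))
  day0 <- which(x$samples$day == 0)
  if (!length(day0)) stop("no day-0 samples present; cannot apply day-0 filter")
  keep <- rowSums(x$counts[, day0, drop = FALSE]) >= min_total
  new_poolcount(x$info[keep, , drop = FALSE], x$counts[keep, , drop = FALSE],
                x$samples)
}

## Rolling median over truncated windows. For vectors shorter than the window
## every truncated window spans the whole vector, so the global median is used.
rolling_median <- function(v, k) {
  n <- length(v)
  h <- (k - 1L) %/% 2L
  if (n < k) return(rep(stats::median(v), n))
  med <- stats::runmed(v, k, endrule = "keep")
  edge <- c(seq_len(h), seq(n - h + 1L, n))
  for (i in edge) med[i] <- stats::median(v[max(1L, i - h):min(n, i + h)])
  med
}

#' Correct positional sequencing bias with a sliding median
#'
#' Mitigates position-dependent coverage artefacts (e.g. replication-associated
#' copy-number gradients) by recentring each barcode's count against the median
#' of a window of neighbouring insertions on the same scaffold. The correction
#' operates on log(count + pseudocount): the local window median is subtracted
#' and the scaffold-wide median added back, preserving positivity and overall
#' scale, then values are back-transformed to (real-valued) counts. Windows are
#' truncated at scaffold edges.
#'
#' @param x A \code{poolcount} object with records ordered by
#'   (scaffold, position) (as returned by \code{\link{read_poolcount}}).
#' @param window Odd window width in barcodes (default 251).
#' @param pseudocount Added before the log transform (default 0.5).
#' @return A \code{poolcount} object with corrected, nonnegative real counts.
#' @export
positional_correction <- function(x, window = 251, pseudocount = 0.5) {
  stopifnot(inherits(x, "poolcount"))
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  counts <- x$counts
  for (sc in unique(x$info$scaffold)) {
    idx <- which(x$info$scaffold == sc)
    if (is.unsorted(x$info$pos[idx]))
      stop("records not ordered by position within scaffold ", sc)
    for (j in seq_len(ncol(counts))) {
      l <- log(counts[idx, j] + pseudocount)
      lc <- l - rolling_median(l, window) + stats::median(l)
      counts[idx, j] <- pmax(exp(lc) - pseudocount, 0)
    }
  }
  new_poolcount(x$info, counts, x$samples)
}

#' Centered log-ratio transform against a neutral gene set
#'
#' Converts counts to natural-log abundance ratios relative to the mean
#' log-count of barcodes mapping to an empirically neutral gene set, per
#' sample: \code{value(b, j) = ln(count(b,j) + pc) - mean_k ln(count(k,j) + pc)}
#' over neutral-set barcodes k. By construction the per-sample mean over
#' neutral barcodes is zero, anchoring the fitness zero-point.
#'
#' @param x A \code{poolcount} object.
#' @param neutral Character vector of neutral locus tags (or an object with a
#'   \code{genes} element).
#' @param pseudocount Added to every count before the log (default 0.5).
#' @return A \code{tn_abundance} object: list with \code{values} (barcode x
#'   sample matrix, natural-log units), \code{info}, \code{samples},
#'   \code{neutral} (tags used), and \code{neutral_barcodes} (logical index).
#' @export
clr_transform <- function(x, neutral, pseudocount = 0.5) {
  stopifnot(inherits(x, "poolcount"))
  if (is.list(neutral) && !is.null(neutral$genes)) neutral <- neutral$genes
  neutral <- as.character(neutral)
  nb <- !is.na(x$info$gene) & x$info$gene %in% neutral
  if (!any(nb))
    stop("no barcodes map to the neutral gene set after filtering")
  lv <- log(x$counts + pseudocount)
  values <- sweep(lv, 2L, colMeans(lv[nb, , drop = FALSE]))
  structure(list(values = values, info = x$info, samples = x$samples,
                 neutral = neutral, neutral_barcodes = nb),
            class = "tn_abundance")
}

#' @export
print.tn_abundance <- function(x, ...) {
  cat(sprintf("tn_abundance: %d barcodes x %d samples, %d neutral barcodes\n",
              nrow(x$values), ncol(x$values), sum(x$neutral_barcodes)))
  invisible(x)
}

#' Per-barcode interval selection rates
#'
#' Computes, for each barcode and each interval between adjacent sampling
#' days, the change in log-ratio abundance divided by the elapsed time in
#' days. The design is pseudo-longitudinal (independent replicate cultures are
#' destructively sampled at each day), so each later-day replicate is paired
#' against the mean abundance over the earlier day's replicates.
#'
#' @param abund A \code{tn_abundance} object whose samples span at least two
#'   distinct days.
#' @return A data frame with columns \code{barcode}, \code{gene},
#'   \code{interval} (1-based index of the day pair), \code{t_start},
#'   \code{t_end}, \code{replicate}, \code{rate} (days^-1), carrying an
#'   \code{intervals} attribute (data frame of start/end days).
#' @export
compute_selection_rates <- function(abund) {
  stopifnot(inherits(abund, "tn_abundance"))
  days <- sort(unique(abund$samples$day))
  if (length(days) < 2) stop("samples must span at least two distinct days")
  out <- vector("list", length(days) - 1L)
  for (d in seq_len(length(days) - 1L)) {
    t0 <- days[d]; t1 <- days[d + 1L]
    i0 <- which(abund$samples$day == t0)
    i1 <- which(abund$samples$day == t1)
    if (!length(i0) || !length(i1))
      stop("interval ", t0, "->", t1, " lacks samples at an endpoint")
    base <- rowMeans(abund$values[, i0, drop = FALSE])
    per_rep <- lapply(i1, function(j) {
      data.frame(barcode = abund$info$barcode,
                 gene = abund$info$gene,
                 interval = d, t_start = t0, t_end = t1,
                 replicate = as.character(abund$samples$replicate[j]),
                 rate = (abund$values[, j] - base) / (t1 - t0),
                 stringsAsFactors = FALSE)
    })
    out[[d]] <- do.call(rbind, per_rep)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(!is.finite(res$rate))) stop("non-finite selection rate computed")
  attr(res, "intervals") <- data.frame(start = days[-length(days)],
                                       end = days[-1])
  res
}

#' Derive an empirically neutral gene set from a fitness compendium
#'
#' Selects genes whose disruption shows minimal fitness variation across many
#' conditions: absolute row mean at most \code{max_abs_mean} and row standard
#' deviation at most \code{max_sd}.
#'
#' @param compendium Numeric gene x condition fitness matrix with gene row
#'   names and at least two condition columns.
#' @param max_abs_mean Threshold on |row mean| (default 0.1).
#' @param max_sd Threshold on row sd (default 0.25).
#' @return Character vector of neutral locus tags.
#' @export
derive_neutral_set <- function(compendium, max_abs_mean = 0.1, max_sd = 0.25) {
  compendium <- as.matrix(compendium)
  if (ncol(compendium) < 2) stop("compendium needs >= 2 conditions")
  if (is.null(rownames(compendium))) stop("compendium needs gene row names")
  m <- rowMeans(compendium)
  s <- apply(compendium, 1L, stats::sd)
  tags <- rownames(compendium)[abs(m) <= max_abs_mean & s <= max_sd]
  if (!length(tags))
    stop("no genes pass the neutrality thresholds; consider loosening them")
  tags
}

#' Write / read selection-rate tables
#'
#' Round-trippable TSV serialization of the per-barcode selection-rate table.
#' @param rates Selection-rate data frame from
#'   \code{\link{compute_selection_rates}}.
#' @param path Output/input TSV path.
#' @return \code{read_selection_rates} returns the data frame with its
#'   \code{intervals} attribute restored.
#' @export
write_selection_rates <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_selection_rates
#' @export
read_selection_rates <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  res$replicate <- as.character(res$replicate)
  iv <- unique(res[order(res$interval), c("interval", "t_start", "t_end")])
  attr(res, "intervals") <- data.frame(start = iv$t_start, end = iv$t_end)
  res
}

#' Write a log-ratio abundance matrix to TSV
#' @param abund A \code{tn_abundance} object.
#' @param path Output TSV path.
#' @export
write_abundance <- function(abund, path) {
  df <- data.frame(barcode = abund$info$barcode, gene = abund$info$gene,
                   abund$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
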