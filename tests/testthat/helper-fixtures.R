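## shared fixture helpers

fixture_path <- function(name) {
  system.file("extdata", name, package = "tnseascape", mustWork = TRUE)
}

toy_metadata <- function() {
  md <- read.delim(fixture_path("toy_metadata.tsv"), stringsAsFactors = FALSE)
  md$replicate <- as.character(md$replicate)
  md
}

toy_pool <- function() {
  read_poolcount(fixture_path("toy_poolcount.tsv"), toy_metadata())
}

toy_neutral <- function() readLines(fixture_path("toy_neutral.txt"))

## build a small poolcount object in code
make_poolcount <- function(counts, gene = NULL, days = NULL,
                           scaffold = NULL, pos = NULL) {
  n <- nrow(counts)
  if (is.null(gene)) gene <- sprintf("g%02d", seq_len(n))
  if (is.null(scaffold)) scaffold <- rep("sc1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(days)) days <- rep(0, ncol(counts))
  info <- data.frame(barcode = sprintf("BC%03d", seq_len(n)),
                     rcbarcode = sprintf("RC%03d", seq_len(n)),
                     scaffold = scaffold, strand = rep("+", n),
                     pos = pos, gene = gene, stringsAsFactors = FALSE)
  samples <- data.frame(sample = paste0("s", seq_len(ncol(counts))),
                        day = days,
                        replicate = as.character(seq_len(ncol(counts))),
                        stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample
  tnseascape:::new_poolcount(info, counts, samples)
}

## independent naive rolling median (truncated windows)
naive_rolling_median <- function(v, k) {
  h <- (k - 1) %/% 2
  n <- length(v)
  if (n < k) return(rep(median(v), n))
  sapply(seq_len(n), function(i) median(v[max(1, i - h):min(n, i + h)]))
}
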