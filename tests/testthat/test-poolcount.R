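test_that("poolcount files parse, sort by position, and validate counts", {
  pc <- toy_pool()
  expect_s3_class(pc, "poolcount")
  expect_equal(dim(pc), c(30L, 12L))
  ## records ordered by (scaffold, position)
  expect_false(is.unsorted(order(pc$info$scaffold, pc$info$pos)))
  by_sc <- split(pc$info$pos, pc$info$scaffold)
  for (v in by_sc) expect_false(is.unsorted(v))

  ## a 3-barcode, 2-sample toy file parses verbatim
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("barcode\trcbarcode\tscaffold\tstrand\tpos\ts1\ts2",
               "AAA\tTTT\tsc1\t+\t10\t5\t7",
               "CCC\tGGG\tsc1\t-\t20\t0\t2",
               "GGG\tCCC\tsc1\t+\t30\t1\t1"), tf)
  md <- data.frame(sample = c("s1", "s2"), day = c(0, 1),
                   replicate = c("1", "1"))
  pc2 <- read_poolcount(tf, md)
  expect_equal(unname(pc2$counts[, "s1"]), c(5, 0, 1))
  expect_equal(unname(pc2$counts[, "s2"]), c(7, 2, 1))

  ## non-integer count cell errors with the line number
  writeLines(c("barcode\trcbarcode\tscaffold\tstrand\tpos\ts1",
               "AAA\tTTT\tsc1\t+\t10\t5",
               "CCC\tGGG\tsc1\t-\t20\t1.5"), tf)
  md1 <- data.frame(sample = "s1", day = 0, replicate = "1")
  expect_error(read_poolcount(tf, md1), "1\\.5.*line 3")

  ## metadata gaps and duplicates are configuration errors
  expect_error(read_poolcount(fixture_path("toy_poolcount.tsv"),
                              toy_metadata()[-1, ]), "missing")
  expect_error(read_poolcount(fixture_path("toy_poolcount.tsv"),
                              rbind(toy_metadata(), toy_metadata()[1, ])),
               "duplicate")

  ## out-of-order input matches a hand-sorted copy
  raw <- read.delim(fixture_path("toy_poolcount.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  raw_sorted <- raw[order(raw$scaffold, raw$pos), ]
  expect_equal(pc$info$barcode, raw_sorted$barcode)
})

test_that("day-0 filtering keeps exactly the well-covered barcodes", {
  counts <- matrix(c(0, 1, 2, 3, 4, 10,   # day-0 sample A
                     0, 0, 0, 0, 0, 0,    # day-0 sample B
                     9, 9, 9, 9, 9, 9),   # day-1 sample
                   ncol = 3)
  pc <- make_poolcount(counts, days = c(0, 0, 1))
  kept <- filter_day0(pc, min_total = 3)
  expect_equal(nrow(kept$counts), 3L)              # totals {3,4,10} survive
  expect_equal(kept$info$gene, sprintf("g%02d", 4:6))
  expect_equal(ncol(kept$counts), 3L)              # sample set unchanged

  ## totals are summed across all day-0 samples: (1,1,0) over two day-0
  ## samples totals 2 and is removed; all-zero barcodes likewise
  counts2 <- matrix(c(1, 0, 1, 0, 0, 0, 5, 5), ncol = 4)
  pc2 <- make_poolcount(counts2, days = c(0, 0, 1, 1))
  expect_equal(nrow(filter_day0(pc2)$counts), 0L)
  expect_error(filter_day0(make_poolcount(counts2, days = c(1, 1, 4, 4))),
               "day-0")
})

test_that("positional correction matches an independent rolling median", {
  set.seed(3)
  n <- 1000
  counts <- matrix(rpois(n, 100), ncol = 1)
  ## a 10x positional bump spanning 301..600: wider than the window
  ## half-width, so the local median tracks it and the correction removes it
  counts[301:600, 1] <- rpois(300, 1000)
  pc <- make_poolcount(counts, days = 0)
  corr <- positional_correction(pc, window = 251)

  l <- log(counts[, 1] + 0.5)
  expect_med <- naive_rolling_median(l, 251)
  manual <- pmax(exp(l - expect_med + median(l)) - 0.5, 0)
  expect_equal(unname(corr$counts[, 1]), manual, tolerance = 1e-12)

  ## bump interior flattened toward the scaffold-wide level
  expect_lt(median(corr$counts[430:470, 1]), 300)
  expect_gt(median(counts[430:470, 1]), 900)

  ## constant signal is a fixed point; short scaffolds recentre globally
  flat <- make_poolcount(matrix(rep(50, 20), ncol = 1), days = 0)
  expect_equal(positional_correction(flat, 251)$counts, flat$counts)
  short <- make_poolcount(matrix(rpois(40, 80), ncol = 1), days = 0)
  expect_equal(positional_correction(short, 251)$counts, short$counts,
               tolerance = 1e-12)
  expect_error(positional_correction(pc, window = 250), "odd")
})

test_that("CLR values center the neutral set and match hand-computed logs", {
  ## counts + pseudocount of exactly {10, 100, 1000} (corrected counts may be
  ## non-integer): focal value = ln(1000) - (ln 10 + ln 100)/2
  counts <- matrix(c(9.5, 99.5, 999.5), ncol = 1)
  pc <- make_poolcount(counts, gene = c("n1", "n2", "x"), days = 0)
  ab <- clr_transform(pc, c("n1", "n2"))
  expect_equal(ab$values[3, 1], log(1000) - (log(10) + log(100)) / 2,
               tolerance = 1e-12)
  expect_equal(mean(ab$values[1:2, 1]), 0, tolerance = 1e-9)

  ## uniform composition gives all zeros
  pc2 <- make_poolcount(matrix(rep(42, 8), ncol = 2),
                        gene = rep(c("n1", "x"), 2), days = c(0, 1))
  ab2 <- clr_transform(pc2, "n1")
  expect_true(all(abs(ab2$values) < 1e-12))

  expect_error(clr_transform(pc, c("absent")), "neutral")
})

test_that("selection rates divide abundance changes by interval length", {
  ## two barcodes, days 0/1/4/10, single replicate per day
  vals <- matrix(0, 2, 4)
  vals[1, ] <- c(0, 0.5, 1.1, -0.1)   # deltas 0.5, 0.6, -1.2
  counts <- round(exp(vals + 5))
  pc <- make_poolcount(counts, gene = c("x", "n1"), days = c(0, 1, 4, 10))
  ab <- clr_transform(pc, "n1")
  rates <- compute_selection_rates(ab)
  x <- rates[rates$gene == "x", ]
  v <- ab$values[1, ]
  expect_equal(x$rate[x$interval == 1], unname(v[2] - v[1]) / 1)
  expect_equal(x$rate[x$interval == 2], unname(v[3] - v[2]) / 3)
  expect_equal(x$rate[x$interval == 3], unname(v[4] - v[3]) / 6)
  expect_equal(attr(rates, "intervals"),
               data.frame(start = c(0, 1, 4), end = c(1, 4, 10)))

  ## identical abundances at both endpoints give rate zero
  pcz <- make_poolcount(matrix(c(10, 20, 10, 20), 2), gene = c("x", "n1"),
                        days = c(0, 1))
  expect_equal(compute_selection_rates(clr_transform(pcz, "n1"))$rate,
               c(0, 0))
  expect_error(compute_selection_rates(
    clr_transform(make_poolcount(matrix(1:2, 2), days = 0), "g01")),
    "two distinct days")
})

test_that("later-day replicates pair against the earlier-day replicate mean", {
  ## 2 replicates at day 0, 2 at day 1
  counts <- matrix(c(10, 12, 30, 40), nrow = 1)
  pc <- make_poolcount(counts, gene = "n1", days = c(0, 0, 1, 1))
  ab <- clr_transform(pc, "n1")
  ## with one barcode all CLR values are 0; use two genes instead
  counts <- rbind(c(10, 12, 30, 40), c(10, 10, 10, 10))
  pc <- make_poolcount(counts, gene = c("x", "n1"), days = c(0, 0, 1, 1))
  ab <- clr_transform(pc, "n1")
  rates <- compute_selection_rates(ab)
  x <- rates[rates$gene == "x", ]
  base <- mean(ab$values[1, 1:2])
  expect_equal(x$rate, unname(ab$values[1, 3:4]) - base)
  expect_equal(x$replicate, c("3", "4"))
})

test_that("interval-weighted rate sums reconstruct the total abundance change", {
  pc <- toy_pool()
  pc <- filter_day0(pc)
  ab <- clr_transform(positional_correction(pc, window = 251), toy_neutral())
  rates <- compute_selection_rates(ab)
  iv <- attr(rates, "intervals")
  len <- iv$end - iv$start
  ## replicate-averaged rates telescope to day0 -> day10
  agg <- aggregate(rate ~ barcode + interval, rates, mean)
  wide <- reshape(agg, direction = "wide", idvar = "barcode",
                  timevar = "interval")
  total <- as.matrix(wide[, -1]) %*% len
  d0 <- rowMeans(ab$values[, ab$samples$day == 0, drop = FALSE])
  d10 <- rowMeans(ab$values[, ab$samples$day == 10, drop = FALSE])
  expect_equal(unname(total[, 1]),
               unname((d10 - d0)[wide$barcode]), tolerance = 1e-9)
})

test_that("neutral sets derive from row statistics and tables round-trip", {
  fit <- rbind(c(0, 0, 0, 0), c(0.05, -0.05, 0.08, 0), c(0.5, 0.5, 0.5, 0.5),
               c(0, 1, -1, 0), c(-0.09, 0.09, 0.02, -0.02))
  rownames(fit) <- paste0("g", 1:5)
  ## brute-force row statistics
  expected <- rownames(fit)[abs(rowMeans(fit)) <= 0.1 &
                            apply(fit, 1, sd) <= 0.25]
  expect_equal(derive_neutral_set(fit), expected)
  expect_equal(derive_neutral_set(fit), c("g1", "g2", "g5"))
  ## with the perfectly neutral gene removed, impossible thresholds error
  expect_error(derive_neutral_set(fit[-1, ], max_abs_mean = 1e-9,
                                  max_sd = 1e-9), "loosen")
  expect_error(derive_neutral_set(fit[, 1, drop = FALSE]), "2 conditions")

  rates <- compute_selection_rates(clr_transform(filter_day0(toy_pool()),
                                                 toy_neutral()))
  tf <- tempfile(fileext = ".tsv")
  write_selection_rates(rates, tf)
  back <- read_selection_rates(tf)
  expect_equal(back$rate, rates$rate, tolerance = 1e-12)
  expect_equal(attr(back, "intervals"), attr(rates, "intervals"))
})

test_that("preprocessing is deterministic and shape-preserving", {
  pc <- toy_pool()
  expect_lte(nrow(filter_day0(pc)$counts), nrow(pc$counts))
  corr1 <- positional_correction(pc, 11)
  corr2 <- positional_correction(pc, 11)
  expect_identical(corr1, corr2)
  expect_equal(dim(corr1$counts), dim(pc$counts))
  ab <- clr_transform(pc, toy_neutral())
  expect_equal(dim(ab$values), dim(pc$counts))
  ## CLR neutral-centering holds on every sample
  nb <- ab$neutral_barcodes
  expect_true(all(abs(colMeans(ab$values[nb, ])) < 1e-9))
})
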