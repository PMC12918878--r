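test_that("the simulator hits its noise-free and distributional contracts", {
  ## noise-free limit: observed barcode rates equal latent gene rates exactly
  sim0 <- simulate_tnseq(sim_config(n_genes = 50, sd_intra = 0, sd_meas = 0,
                                    sd_batch = 0, seed = 3))
  truth_rows <- sim0$truth[cbind(match(sim0$rates$gene, rownames(sim0$truth)),
                                 sim0$rates$interval)]
  expect_equal(sim0$rates$rate, unname(truth_rows), tolerance = 1e-9)

  ## intragenic channel: empirical sd of (barcode rate - gene rate) near 1
  sim1 <- simulate_tnseq(sim_config(n_genes = 1000, sd_intra = 1, sd_meas = 0,
                                    sd_batch = 0, seed = 4))
  dev <- sim1$barcode_truth - sim1$truth[rownames(sim1$barcode_truth), ]
  expect_equal(sd(as.vector(dev)), 1, tolerance = 0.02)

  ## determinism: same config gives bit-identical output
  cfg <- sim_config(n_genes = 30, sd_intra = 0.1, sd_meas = 0.1,
                    sd_batch = 0.1, seed = 7)
  expect_identical(simulate_tnseq(cfg), simulate_tnseq(cfg))

  ## barcode sampler: median insertions per gene is 16, minimum 1
  big <- simulate_tnseq(sim_config(n_genes = 4000, seed = 8))
  nb <- table(big$rates$gene[big$rates$interval == 1 &
                             big$rates$replicate == "1"])
  expect_equal(median(as.vector(nb)), 16)
  expect_gte(min(nb), 1)
})

test_that("stored rates recompute exactly from stored abundances", {
  sim <- simulate_tnseq(sim_config(n_genes = 40, sd_intra = 0.3,
                                   sd_meas = 0.5, sd_batch = 0.2, seed = 12))
  tp <- sim$config$timepoints
  for (d in 1:3) {
    i0 <- sim$samples$day == tp[d]
    i1 <- which(sim$samples$day == tp[d + 1])
    base <- rowMeans(sim$abund[, i0])
    for (j in i1) {
      manual <- (sim$abund[, j] - base) / (tp[d + 1] - tp[d])
      got <- sim$rates$rate[sim$rates$interval == d &
                            sim$rates$replicate == sim$samples$replicate[j]]
      expect_equal(got, unname(manual), tolerance = 0)
    }
  }
})

test_that("the baseline computes textbook t intervals", {
  rates <- data.frame(gene = c("a", "a", "a", "b", rep("c", 3)),
                      interval = c(1, 1, 1, 1, 1, 1, 1),
                      rate = c(0.1, 0.2, 0.3, 0.5, 0.4, 0.4, 0.4))
  est <- barseq_estimate(rates)
  a <- est[est$gene == "a", ]
  expect_equal(a$estimate, 0.2)
  hw <- qt(0.95, 2) * 0.1 / sqrt(3)
  expect_equal(c(a$lower, a$upper), c(0.2 - hw, 0.2 + hw), tolerance = 1e-12)
  ## single observation: estimate defined, interval undefined
  b <- est[est$gene == "b", ]
  expect_equal(b$estimate, 0.5)
  expect_true(is.na(b$lower) && is.na(b$upper))
  ## identical observations: zero-width interval at the common value
  cc <- est[est$gene == "c", ]
  expect_equal(c(cc$lower, cc$estimate, cc$upper), rep(0.4, 3))
})

test_that("evaluation scores RMSE and coverage as defined", {
  truth <- matrix(c(0.1, 0.2, 0.3, -0.1, -0.2, -0.3), 2, 3, byrow = TRUE,
                  dimnames = list(c("a", "b"), NULL))
  perfect <- data.frame(gene = rep(c("a", "b"), 3),
                        interval = rep(1:3, each = 2),
                        estimate = as.vector(truth),
                        lower = as.vector(truth) - 0.1,
                        upper = as.vector(truth) + 0.1)
  ev <- evaluate_estimates(truth, perfect)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$coverage, 1)

  ## two cells with errors 0.3 and 0.4
  est2 <- data.frame(gene = "a", interval = c(1, 2),
                     estimate = c(0.4, 0.6), lower = -Inf, upper = Inf)
  ev2 <- evaluate_estimates(truth, est2)
  expect_equal(ev2$rmse, sqrt((0.09 + 0.16) / 2), tolerance = 1e-12)
  expect_equal(ev2$coverage, 1)  # vacuous infinite-width intervals

  expect_error(evaluate_estimates(truth,
                                  data.frame(gene = "zz", interval = 1,
                                             estimate = 0, lower = 0,
                                             upper = 0)),
               "align")
})

test_that("baseline RMSE degrades monotonically in each noise channel", {
  ## vary one channel at a time with the others silent, so the comparison is
  ## not swamped by single-realization batch draws in crossed conditions
  for (ch in c("sd_intra", "sd_meas", "sd_batch")) {
    grid <- data.frame(sd_intra = 0, sd_meas = 0, sd_batch = 0)
    grid <- grid[rep(1, 3), ]
    grid[[ch]] <- c(0, 0.1, 1)
    res <- run_benchmark_grid(n_genes = 300, grid = grid,
                              methods = "barseq", bootstrap_reps = 50,
                              seed = 31)
    expect_true(all(diff(res$conditions$rmse) > -0.01), info = ch)
  }
})

test_that("the full grid reports bracketing bootstrap intervals", {
  res <- run_benchmark_grid(n_genes = 150, methods = "barseq",
                            bootstrap_reps = 50, seed = 31)
  expect_equal(nrow(res$conditions), 27L)
  md <- res$medians
  expect_true(md$rmse_lo <= md$median_rmse & md$median_rmse <= md$rmse_hi)
  expect_true(md$cov_lo <= md$median_coverage &
                md$median_coverage <= md$cov_hi)
  expect_true(all(res$conditions$coverage >= 0 &
                    res$conditions$coverage <= 1, na.rm = TRUE))
  ok <- !is.na(res$conditions$rmse)
  expect_true(all(res$conditions$rmse_lo[ok] <= res$conditions$rmse[ok] &
                    res$conditions$rmse[ok] <= res$conditions$rmse_hi[ok]))
})

test_that("single-condition grids and coverage subsets work", {
  res <- run_benchmark_grid(n_genes = 120,
                            grid = data.frame(sd_intra = 0.1, sd_meas = 0.1,
                                              sd_batch = 0),
                            methods = "barseq", bootstrap_reps = 50,
                            seed = 13)
  expect_equal(nrow(res$conditions), 1L)
  expect_equal(coverage_subset(res, "barseq",
                               res$conditions$sd_batch == 0),
               res$conditions$coverage)
})
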