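test_that("net selection rate is the exact duration-weighted combination", {
  sim <- simulate_from_model(n_genes = 30, n_obs = 6, seed = 2)
  fit <- suppressWarnings(fit_longitudinal(
    sim$rates, model_spec(chains = 2, warmup = 100, draws = 100, seed = 2)))
  sn <- compute_snet(fit)
  manual <- fit$draws$s[, , 1] * 0.1 + fit$draws$s[, , 2] * 0.3 +
    fit$draws$s[, , 3] * 0.6
  expect_equal(unname(sn$draws), unname(manual), tolerance = 0)

  ## arithmetic of the weighted average
  w <- c(0.1, 0.3, 0.6)
  expect_equal(sum(w * c(1, 0, 0)), 0.1)
  expect_equal(sum(w * c(0.1, 0.2, -0.05)), 0.04)
  expect_equal(sum(w * c(0.3, 0.3, 0.3)), 0.3)
})

test_that("posterior medians recover the truth in the noise-free limit", {
  sim <- simulate_tnseq(sim_config(n_genes = 80, sd_intra = 0, sd_meas = 0,
                                   sd_batch = 0, seed = 9))
  fit <- suppressWarnings(fit_longitudinal(
    sim$rates, model_spec(chains = 2, warmup = 200, draws = 300, seed = 9)))
  med <- coef(fit)[, 1:3]
  expect_lt(max(abs(med[rownames(sim$truth), ] - sim$truth)), 0.02)
})

test_that("hierarchical fits shrink extreme single-barcode genes toward the mean", {
  set.seed(4)
  ## many well-measured genes plus one single-observation outlier gene
  rates <- simulate_from_model(n_genes = 100, n_obs = 9, tau = 0.2,
                               sigma = 0.3, seed = 4)$rates
  outlier <- data.frame(gene = "zoutlier", interval = 1:3,
                        replicate = "1", rate = c(3, 3, 3))
  fit <- suppressWarnings(fit_longitudinal(
    rbind(rates, outlier),
    model_spec(chains = 2, warmup = 200, draws = 300, seed = 4)))
  med <- coef(fit)["zoutlier", 1:3]
  beta_med <- apply(fit$draws$scalars[, 1:3], 2L, median)
  pop <- c(beta_med[1], beta_med[1] + beta_med[2], beta_med[1] + beta_med[3])
  ## shrunk strictly toward the population mean relative to the raw rate
  expect_true(all(med < 3))
  expect_true(all(abs(med - pop) < abs(3 - pop)))

  ## across genes, posterior medians are less dispersed than raw means
  raw <- with(rates, tapply(rate, list(gene, interval), mean))
  expect_lt(var(coef(fit)[rownames(raw), "s1"]), var(raw[, 1]))
})

test_that("classification thresholds behave and are monotone", {
  df <- data.frame(gene = c("a", "b", "c"), quantity = "s1",
                   pr_pos = c(0.95, 0.5, 0.05), pr_neg = c(0.05, 0.5, 0.95))
  lab <- classify(df, 0.9)$label
  expect_equal(as.character(lab), c("beneficial", "neutral", "deleterious"))
  expect_error(classify(df, 0.4))

  ## raising the threshold never increases the non-neutral count
  set.seed(11)
  sim_pr <- runif(500)
  df2 <- data.frame(gene = paste0("g", 1:500), quantity = "snet",
                    pr_pos = sim_pr, pr_neg = 1 - sim_pr)
  n_nonneutral <- function(th) sum(classify(df2, th)$label != "neutral")
  expect_lte(n_nonneutral(0.975), n_nonneutral(0.9))
})

test_that("beneficial/deleterious skew tabulates counts and handles edge cases", {
  labels <- data.frame(quantity = rep(c("s1", "snet"), each = 4),
                       label = c("beneficial", "beneficial", "deleterious",
                                 "neutral",
                                 "neutral", "neutral", "neutral", "neutral"))
  out <- interval_summary(labels)
  expect_equal(out$B, c(2, 0))
  expect_equal(out$D, c(1, 0))
  expect_equal(out$skew, c(1 / 3, NA))
  ## B = D gives zero skew
  expect_equal(interval_summary(data.frame(B = 7, D = 7))$skew, 0)
})

test_that("fits are reproducible, diagnosable, and expose methods", {
  sim <- simulate_from_model(n_genes = 40, n_obs = 6, seed = 5)
  spec <- model_spec(chains = 2, warmup = 100, draws = 120, seed = 5)
  f1 <- suppressWarnings(fit_longitudinal(sim$rates, spec))
  f2 <- suppressWarnings(fit_longitudinal(sim$rates, spec))
  expect_identical(f1$draws, f2$draws)

  expect_named(f1$diagnostics$rhat_scalars)
  expect_true(all(is.finite(f1$diagnostics$rhat_scalars)))
  expect_equal(length(f1$diagnostics$ess_scalars), 12L)

  ## tail probabilities are complementary up to draw resolution
  sm <- f1$summaries
  expect_true(all(abs(sm$pr_pos + sm$pr_neg - 1) <=
                    1 / nrow(f1$draws$scalars) + 1e-12))
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))

  expect_output(print(f1), "tnfit")
  expect_output(print(summary(f1)), "classification")
  expect_equal(dim(coef(f1)), c(40L, 4L))
  expect_equal(length(fitted(f1)), nrow(f1$data))
  expect_equal(residuals(f1), f1$data$rate - fitted(f1))
  pp <- simulate(f1, nsim = 2, seed = 1)
  expect_equal(nrow(pp[[1]]), nrow(f1$data))
})

test_that("posterior draws persist to a keyed long-format table", {
  sim <- simulate_from_model(n_genes = 12, n_obs = 4, seed = 6)
  fit <- suppressWarnings(fit_longitudinal(
    sim$rates, model_spec(chains = 2, warmup = 100, draws = 100, seed = 6)))
  tf <- tempfile(fileext = ".tsv")
  write_gene_draws(fit, tf)
  dr <- read.delim(tf, colClasses = c(interval = "character"))
  n <- nrow(fit$draws$scalars)
  expect_equal(nrow(dr), 12L * n * 4L)
  one <- dr[dr$gene == fit$genes[3] & dr$interval == "2", ]
  expect_equal(one$value[order(one$draw)], fit$draws$s[, 3, 2])
})

test_that("count-table test wrappers run on classification summaries", {
  counts <- interval_summary(data.frame(quantity = c("s1", "snet"),
                                        B = c(30, 10), D = c(20, 40)))
  out <- classification_tests(counts)
  expect_s3_class(out$fisher, "htest")
  ## 2x2 case agrees with calling fisher.test directly
  direct <- fisher.test(matrix(c(30, 20, 10, 40), 2))
  expect_equal(out$fisher$p.value, direct$p.value)
  expect_equal(out$chisq$p,
               c(chisq.test(c(30, 20))$p.value, chisq.test(c(10, 40))$p.value))
  expect_true(all(out$chisq$p_adj >= out$chisq$p))
})

test_that("a neutral subset with true rate zero is anchored near zero", {
  set.seed(21)
  n_zero <- 60; n_other <- 120; n_obs <- 9
  truth <- rbind(matrix(0, n_zero, 3),
                 matrix(rnorm(n_other * 3, 0, 0.3), n_other, 3))
  genes <- sprintf("g%04d", seq_len(nrow(truth)))
  rates <- do.call(rbind, lapply(1:3, function(d) {
    data.frame(gene = rep(genes, each = n_obs), interval = d,
               replicate = "1",
               rate = rnorm(length(genes) * n_obs,
                            rep(truth[, d], each = n_obs), 0.3))
  }))
  fit <- suppressWarnings(fit_longitudinal(
    rates, model_spec(chains = 2, warmup = 200, draws = 300, seed = 21)))
  med <- coef(fit)[genes[1:n_zero], 1:3]
  ## Monte-Carlo error of the neutral-subset mean includes the shared
  ## population-effect term (~ tau / sqrt(G) = 0.022 here); allow ~3 sd
  expect_lt(max(abs(colMeans(med))), 0.07)
})
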