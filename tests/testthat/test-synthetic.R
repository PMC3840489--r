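test_that("zero-noise expression has exact planted group means", {
  cfg <- array_sim_config(n_mirnas = 30, n_up = 1, n_down = 1,
                          planted_fc = 3, noise_cv = 0, seed = 42)
  sim <- gen_expression(cfg)
  vals <- sim$matrix$values
  d <- sim$matrix$design
  sham <- rowMeans(vals[, d$array_id[d$group == "sham"]])
  tum <- rowMeans(vals[, d$array_id[d$group == "tumour"]])
  up <- sim$truth$planted_up
  dn <- sim$truth$planted_down
  expect_equal(tum[up], 3 * sham[up])
  expect_equal(tum[dn], sham[dn] / 3)
  null <- setdiff(rownames(vals), c(up, dn))
  expect_equal(tum[null], sham[null])
  expect_true(all(vals > 0))
})

test_that("expression generation is deterministic under a fixed seed", {
  cfg <- array_sim_config(n_mirnas = 100, seed = 9)
  a <- gen_expression(cfg)
  b <- gen_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  c <- gen_expression(array_sim_config(n_mirnas = 100, seed = 10))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("invalid array configs name the offending field", {
  expect_error(array_sim_config(n_up = 400, n_down = 400), "n_up/n_down")
  expect_error(array_sim_config(planted_fc = 1), "planted_fc")
  expect_error(array_sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(array_sim_config(n_per_group = 1), "n_per_group")
})

test_that("lognormal noise keeps linear-scale means unbiased", {
  # with many replicates the empirical group mean approaches the planted mean
  cfg <- array_sim_config(n_mirnas = 5, n_per_group = 2000, n_up = 1,
                          n_down = 0, planted_fc = 3, noise_cv = 0.3,
                          seed = 1)
  sim <- gen_expression(cfg)
  d <- sim$matrix$design
  sham <- rowMeans(sim$matrix$values[, d$array_id[d$group == "sham"]])
  tum <- rowMeans(sim$matrix$values[, d$array_id[d$group == "tumour"]])
  up <- sim$truth$planted_up
  expect_equal(unname(tum[up] / sham[up]), 3, tolerance = 0.05)
})

test_that("zero-noise Ct tables recover planted fold changes exactly", {
  ct <- gen_ct(c("t1", "t2"), c(t1 = 4, t2 = 1), ct_noise_sd = 0, seed = 2)
  r1 <- ddct(ct, "t1", "sno202", "tumour", "sham")
  expect_equal(r1$ddct, -2)
  expect_equal(r1$fold_change, 4)
  r2 <- ddct(ct, "t2", "sno202", "tumour", "sham")
  expect_equal(r2$fold_change, 1)
  expect_equal(r2$dct_treatment, r2$dct_control)
  expect_error(gen_ct("t1", c(t1 = -2)), "positive")
})

test_that("noisy Ct recovery stays within 3 SE of truth (Monte Carlo)", {
  true_fc <- 4
  sd_ct <- 0.2
  n_bio <- 3
  errs <- vapply(1:100, function(s) {
    ct <- gen_ct("t1", c(t1 = true_fc), n_bio = n_bio, n_tech = 3,
                 ct_noise_sd = sd_ct, seed = s)
    -ddct(ct, "t1", "sno202", "tumour", "sham")$ddct - log2(true_fc)
  }, 0)
  # ddCt variance: 2 groups x (target + reference Ct means over 3 tech reps)
  se <- sqrt(2 * 2 * sd_ct^2 / 3 / n_bio)
  expect_lt(abs(mean(errs)), 3 * se / sqrt(100))
  expect_lt(stats::sd(errs), 2 * se)
})

test_that("prediction tables plant exact support counts", {
  planted <- list("miR-x" = c("G1", "G2", "G3"))
  support <- c(G1 = 2L, G2 = 1L, G3 = 14L)
  tab <- gen_predictions(n_algorithms = 14, genes = sprintf("BG%02d", 1:20),
                         planted = planted, support = support,
                         background_rate = 0, seed = 4)
  # background_rate 0: only planted genes appear
  expect_setequal(unique(tab$gene), c("G1", "G2", "G3"))
  counts <- tapply(tab$algorithm, tab$gene, function(a) length(unique(a)))
  expect_equal(counts[["G1"]], 2L)
  expect_equal(counts[["G2"]], 1L)
  expect_equal(counts[["G3"]], 14L)
  expect_error(gen_predictions(planted = planted,
                               support = c(G1 = 15L, G2 = 1L, G3 = 2L)),
               "n_algorithms")
})

test_that("background predictions match an independent tally", {
  planted <- list("miR-x" = c("G1", "G2"))
  tab <- gen_predictions(n_algorithms = 14,
                         genes = sprintf("BG%03d", 1:100),
                         planted = planted, support = c(G1 = 2L, G2 = 5L),
                         background_rate = 0.05, seed = 8)
  cons <- tally(tab, min_algorithms = 2)
  orc <- oracle_tally(tab)
  expect_equal(cons$n_algorithms[order(cons$gene)],
               orc$n_algorithms[order(orc$gene)])
  expect_equal(sum(cons$consensus), sum(orc$n_algorithms >= 2))
})

test_that("zero-dispersion counts give exact responder ratios", {
  genes <- sprintf("G%02d", 1:10)
  hk <- c("Cltc", "Gapdh", "Gusb", "Hprt", "Tubb5")
  cnt <- gen_counts(genes, hk, responders = genes[1:3], response_ratio = 1.5,
                    dispersion = 0, seed = 6)
  norm <- normalize_counts(cnt$counts, cnt$housekeeping)
  resp <- response_filter(norm, cnt$design, min_ratio = 1.5)
  expect_setequal(resp$gene[resp$responder], genes[1:3])
  expect_equal(resp$response_ratio[match(genes[1:3], resp$gene)],
               rep(1.5, 3))
  # housekeeping genes are unchanged between conditions
  expect_equal(resp$response_ratio[match(hk, resp$gene)], rep(1, 5))
  # empty responders flag nothing
  cnt0 <- gen_counts(genes, hk, responders = character(), dispersion = 0,
                     seed = 6)
  norm0 <- normalize_counts(cnt0$counts, cnt0$housekeeping)
  resp0 <- response_filter(norm0, cnt0$design, min_ratio = 1.5)
  expect_equal(sum(resp0$responder), 0L)
  expect_error(gen_counts(genes, hk, responders = "Gapdh"), "disjoint")
})

test_that("per-sample scaling leaves normalized ratios unchanged", {
  genes <- sprintf("G%02d", 1:6)
  hk <- c("Cltc", "Gapdh")
  cnt <- gen_counts(genes, hk, responders = genes[1], response_ratio = 2,
                    dispersion = 0, seed = 3)
  doubled <- cnt$counts
  doubled[, 1] <- doubled[, 1] * 2
  n1 <- normalize_counts(cnt$counts, cnt$housekeeping)
  n2 <- normalize_counts(doubled, cnt$housekeeping)
  expect_equal(n1, n2, ignore_attr = TRUE)
})

test_that("behavioral psychometric has its logistic midpoint and step limit", {
  # floor 0, ceiling 1, force == threshold: probability exactly 0.5
  expect_equal(psychometric_p(0.16, 0.16, slope = 4), 0.5)
  # slope -> infinity: step at the threshold (times ceiling)
  expect_equal(psychometric_p(0.4, 0.16, slope = 1e6, ceiling = 0.9), 0.9)
  expect_equal(psychometric_p(0.02, 0.16, slope = 1e6), 0)
})

test_that("behavior generation is deterministic, bounded and truth-recorded", {
  cfg <- behavior_sim_config(n_mice_per_group = 3, seed = 12)
  a <- gen_behavior(cfg)
  b <- gen_behavior(cfg)
  expect_identical(a$data, b$data)
  expect_true(all(a$data$n_withdrawals >= 0 &
                    a$data$n_withdrawals <= a$data$n_trials))
  # sham truth constant, tumour truth follows the configured trajectory
  sham_thr <- a$truth$threshold_g[a$truth$group == "sham"]
  expect_true(all(sham_thr == cfg$baseline_threshold_g))
  tum <- a$truth[a$truth$group == "tumour", ]
  expect_equal(tum$threshold_g[match(c(0, 8), tum$day)], c(0.6, 0.05))
  expect_error(behavior_sim_config(floor = 0.5, ceiling = 0.4),
               "floor/ceiling")
  expect_error(behavior_sim_config(filaments = c(0.4, 0.16)), "filaments")
})

test_that("large-n behavior recovers the planted threshold trajectory", {
  cfg <- behavior_sim_config(n_mice_per_group = 1000,
                             days = c(0, 4, 8), seed = 99)
  sim <- gen_behavior(cfg)
  tc <- group_timecourse(sim$data, q = 50)
  tum <- tc$summary[tc$summary$group == "tumour", ]
  truth <- sim$truth[sim$truth$group == "tumour", ]
  for (d in c(0, 4, 8)) {
    est <- tum$mean_threshold_g[tum$day == d]
    tru <- truth$threshold_g[truth$day == d]
    expect_equal(est, tru, tolerance = 0.10)
  }
})
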