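test_that("quantile normalization reproduces the hand-worked example", {
  x <- cbind(A = c(2, 4, 6), B = c(9, 5, 1))
  rownames(x) <- paste0("m", 1:3)
  qn <- quantile_normalize(x)
  expect_equal(unname(qn[, "A"]), c(1.5, 4.5, 7.5))
  expect_equal(unname(qn[, "B"]), c(7.5, 4.5, 1.5))
})

test_that("quantile normalization is idempotent, sum- and rank-preserving", {
  set.seed(7)
  x <- matrix(rlnorm(50 * 6, 5, 1), 50, 6,
              dimnames = list(paste0("m", 1:50), paste0("a", 1:6)))
  qn <- quantile_normalize(x)
  expect_equal(sum(qn), sum(x))
  for (j in 1:6) {
    expect_equal(rank(qn[, j]), rank(x[, j]))
    expect_equal(sort(qn[, j]), sort(qn[, 1]), ignore_attr = TRUE)
  }
  expect_equal(quantile_normalize(qn), qn)
})

test_that("quantile normalization matches the brute-force oracle (20 seeds)", {
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rlnorm(50 * 6, 5, 1), 50, 6,
                dimnames = list(paste0("m", 1:50), paste0("a", 1:6)))
    expect_equal(quantile_normalize(x), oracle_quantile_normalize(x))
  }
})

test_that("single-array matrices are returned unchanged and ties average", {
  x <- matrix(c(3, 1, 2), dimnames = list(paste0("m", 1:3), "a1"))
  expect_identical(quantile_normalize(x), x)
  # ties in one column span two reference slots and take their mean
  y <- cbind(A = c(1, 1, 5), B = c(2, 4, 6))
  rownames(y) <- paste0("m", 1:3)
  qn <- quantile_normalize(y)
  ref <- c(1.5, 2.5, 5.5)
  expect_equal(unname(qn[, "A"]), c(2, 2, 5.5))
  expect_equal(sum(qn[, "A"]), sum(ref))
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(11)
  x <- matrix(rlnorm(80 * 5, 6, 1.2), 80, 5,
              dimnames = list(paste0("m", 1:80), paste0("a", 1:5)))
  expect_equal(unname(quantile_normalize(x)),
               unname(limma::normalizeQuantiles(x)), tolerance = 1e-12)
})

test_that("non-finite intensities are rejected with cell coordinates", {
  x <- cbind(A = c(1, NA), B = c(2, 3))
  rownames(x) <- c("m1", "m2")
  expect_error(quantile_normalize(x), "\\(2,1\\)")
})

test_that("group_stats computes means and sample SDs per group", {
  vals <- rbind("m1" = c(90, 100, 110, 280, 300, 320),
                "m2" = c(50, 50, 50, 50, 50, 50))
  design <- data.frame(array_id = paste0("a", 1:6),
                       group = rep(c("sham", "tumour"), each = 3),
                       replicate = rep(1:3, 2), timepoint = "PID-8")
  colnames(vals) <- design$array_id
  em <- expression_matrix(vals, design)
  st <- group_stats(em)
  expect_equal(st$mean_sham[1], 100)
  expect_equal(st$sd_sham[1], 10)
  expect_equal(st$mean_tumour[1], 300)
  expect_equal(st$sd_sham[2], 0)
  # population mode uses the n denominator
  stp <- group_stats(em, sd_mode = "population")
  expect_equal(stp$sd_sham[1], sqrt(mean((c(90, 100, 110) - 100)^2)))
  # permuting array order leaves statistics unchanged
  perm <- sample(1:6)
  em2 <- expression_matrix(vals[, perm], design[perm, ])
  expect_equal(group_stats(em2), st)
})

test_that("group_stats errors when a group is missing", {
  vals <- matrix(1:4, 2, 2,
                 dimnames = list(c("m1", "m2"), c("a1", "a2")))
  design <- data.frame(array_id = c("a1", "a2"), group = "sham",
                       replicate = 1:2, timepoint = "PID-8")
  em <- expression_matrix(vals, design)
  expect_error(group_stats(em), "tumour")
})

test_that("screen applies the worked consistency and fold-change examples", {
  stats <- data.frame(
    mirna_id = c("a", "b", "c"),
    mean_sham = c(100, 100, 100), sd_sham = c(10, 2, 5),
    mean_tumour = c(300, 220, 100), sd_tumour = c(20, 2, 5))
  res <- screen(stats, screen_config())
  # |200| >= 5*30 and FC 3 >= 2.5: selected, up
  expect_true(res$selected[1])
  expect_equal(res$direction[1], "up")
  expect_equal(res$fold_change[1], 3)
  # consistency holds (120 >= 20) but FC 2.2 < 2.5: secondary tier only
  expect_true(res$passes_consistency[2])
  expect_false(res$selected[2])
  expect_true(res$passes_fc_secondary[2])
  # equal means: FC 1, no direction
  expect_equal(res$fold_change[3], 1)
  expect_false(res$selected[3])
  expect_equal(res$direction[3], "none")
})

test_that("boundary comparisons are inclusive", {
  stats <- data.frame(mirna_id = c("up", "dn"),
                      mean_sham = c(100, 250), sd_sham = c(10, 10),
                      mean_tumour = c(250, 100), sd_tumour = c(20, 20))
  # |150| == 5 * 30 exactly; FC exactly 2.5 and 0.4
  res <- screen(stats, screen_config())
  expect_true(all(res$selected))
  expect_equal(res$direction, c("up", "down"))
})

test_that("screen matches the brute-force oracle on random small instances", {
  for (s in 1:10) {
    set.seed(s)
    n <- 20
    stats <- data.frame(
      mirna_id = paste0("m", 1:n),
      mean_sham = runif(n, 10, 300), sd_sham = runif(n, 0, 30),
      mean_tumour = runif(n, 10, 300), sd_tumour = runif(n, 0, 30))
    res <- screen(stats, screen_config())
    orc <- oracle_screen(stats$mean_sham, stats$sd_sham,
                         stats$mean_tumour, stats$sd_tumour)
    expect_equal(res$selected, orc$selected)
    expect_equal(res$direction, orc$direction)
  }
})

test_that("screen decisions are invariant to global intensity scaling", {
  set.seed(3)
  n <- 50
  stats <- data.frame(
    mirna_id = paste0("m", 1:n),
    mean_sham = runif(n, 10, 300), sd_sham = runif(n, 0, 30),
    mean_tumour = runif(n, 10, 300), sd_tumour = runif(n, 0, 30))
  res <- screen(stats, screen_config())
  for (c_scale in c(0.01, 7, 1e4)) {
    scaled <- stats
    scaled[-1] <- scaled[-1] * c_scale
    res2 <- screen(scaled, screen_config())
    expect_equal(res2$selected, res$selected)
    expect_equal(res2$passes_consistency, res$passes_consistency)
    expect_equal(res2$passes_fc_primary, res$passes_fc_primary)
    expect_equal(res2$fold_change, res$fold_change)
  }
})

test_that("nonpositive group means are flagged unevaluable, not dropped", {
  stats <- data.frame(mirna_id = c("ok", "zero"),
                      mean_sham = c(100, 0), sd_sham = c(1, 0),
                      mean_tumour = c(300, 50), sd_tumour = c(1, 1))
  res <- screen(stats, screen_config())
  expect_equal(nrow(res), 2)
  expect_false(res$evaluable[2])
  expect_false(res$selected[2])
  expect_true(is.na(res$fold_change[2]))
})

test_that("implied_t_bound gives the closed-form worst case", {
  b <- implied_t_bound(k = 5, n = 3)
  expect_equal(b$t_min, 5 * sqrt(3))
  expect_equal(b$df, 4)
  expect_equal(b$p_value, 2 * pt(-5 * sqrt(3), 4))
  expect_lt(b$p_value, 0.001)
  expect_gt(b$p_value, 9e-4)  # "roughly" 0.001, not orders smaller
  expect_error(implied_t_bound(5, 1), ">= 2")
})

test_that("implied_t_bound dominates the SD-configuration grid and is
           monotone in k", {
  b <- implied_t_bound(5, 3)
  expect_gte(b$p_value, oracle_t_bound_grid(5, 3, grid = 100))
  # equal SDs give t = k * sqrt(2n), hence a smaller p
  k <- 5; n <- 3
  t_equal <- k * 2 / sqrt(2 / n * 2 / 2)  # s_S = s_T = 1: delta = 2k, sp = 1
  expect_equal(t_equal, k * sqrt(2 * n))
  expect_lt(2 * pt(-k * sqrt(2 * n), 2 * n - 2), b$p_value)
  # p strictly decreasing in k
  ps <- sapply(c(2, 3, 5, 8), function(k) implied_t_bound(k, 3)$p_value)
  expect_true(all(diff(ps) < 0))
})

test_that("screen_report counts nest and order the heatmap by direction", {
  set.seed(5)
  sim <- gen_expression(array_sim_config(n_mirnas = 60, n_up = 4, n_down = 3,
                                         noise_cv = 0, seed = 5))
  st <- group_stats(quantile_normalize(sim$matrix))
  res <- screen(st, screen_config())
  rep <- screen_report(res, screen_config(), matrix = sim$matrix)
  expect_gte(rep$counts[["n_fc_secondary"]], rep$counts[["n_fc_primary"]])
  expect_equal(rep$counts[["n_selected"]],
               rep$counts[["n_selected_up"]] + rep$counts[["n_selected_down"]])
  expect_equal(nrow(rep$heatmap), rep$counts[["n_selected"]])
  # empty selection gives zero counts and no heatmap
  res0 <- screen(data.frame(mirna_id = "m", mean_sham = 100, sd_sham = 50,
                            mean_tumour = 110, sd_tumour = 50))
  rep0 <- screen_report(res0)
  expect_equal(rep0$counts[["n_selected"]], 0L)
  expect_null(rep0$heatmap)
})
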