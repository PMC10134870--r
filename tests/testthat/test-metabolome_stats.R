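make_series <- function(metabolite, condition, times, means, reps = 1,
                        noise = 0) {
  do.call(rbind, lapply(seq_len(reps), function(rr) {
    data.frame(metabolite_id = metabolite, condition = condition,
               time_h = times, replicate = rr,
               value = means * exp(stats::rnorm(length(times), 0, noise)))
  }))
}

test_that("trajectory normalization rescales to the first time point", {
  s <- make_series("m1", "0C", c(0, 1, 2), c(2, 4, 6))
  n <- normalize_trajectory(s)
  expect_equal(n$value, c(1, 2, 3))
  s2 <- make_series("m1", "0C", c(0, 1, 2), c(5, 5, 5))
  expect_equal(normalize_trajectory(s2)$value, c(1, 1, 1))
  s3 <- make_series("m1", "0C", c(0, 1), c(0, 1))
  expect_error(normalize_trajectory(s3), "zero baseline")
  # scale normalization leaves Pearson correlations untouched
  set.seed(7)
  a <- make_series("m1", "0C", 0:4, exp(runif(5, 0, 2)))
  b <- make_series("m1", "15C", 0:4, exp(runif(5, 0, 2)))
  r_raw <- cor(a$value, b$value)
  nn <- normalize_trajectory(rbind(a, b))
  r_norm <- cor(nn$value[nn$condition == "0C"], nn$value[nn$condition == "15C"])
  expect_equal(r_norm, r_raw, tolerance = 1e-12)
})

test_that("trend correlation handles perfect, reversed and constant series", {
  a <- make_series("m", "0C", 0:4, c(1, 2, 3, 4, 5))
  b <- make_series("m", "15C", 0:4, c(2, 4, 6, 8, 10))
  tc <- trend_correlation(a, b)
  expect_equal(tc$pearson_r, 1)
  expect_true(tc$defined)

  rev <- make_series("m", "15C", 0:4, c(5, 4, 3, 2, 1))
  tr <- trend_correlation(a, rev)
  expect_equal(tr$pearson_r, -1)
  expect_equal(tr$spearman_rho, -1)
  expect_equal(tr$spearman_p, 2 / 120)   # both extreme rank orders

  flat <- make_series("m", "15C", 0:4, rep(3, 5))
  tf <- trend_correlation(a, flat)
  expect_false(tf$defined)
  expect_true(is.na(tf$pearson_r))
})

test_that("exact Spearman p matches the independent reference and is k/120", {
  set.seed(11)
  for (i in 1:15) {
    x <- sample(100, 5)     # distinct values: tie-free exact null applies
    y <- sample(100, 5)
    st <- spearman_test(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(st$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(st$p, min(1, ref$p.value), tolerance = 1e-9)
    expect_equal(st$p * 120, round(st$p * 120), tolerance = 1e-9)
  }
})

test_that("correlation matrices are symmetric with unit diagonal", {
  set.seed(3)
  s <- rbind(make_series("m1", "0C", 0:4, c(1, 2, 3, 4, 5)),
             make_series("m2", "0C", 0:4, c(2, 4, 6, 8, 10)),
             make_series("m3", "0C", 0:4, exp(runif(5, 0, 1))))
  cm <- correlation_matrix(s, "0C")
  expect_identical(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r["m1", "m2"], 1, tolerance = 1e-12)  # identical trends
  expect_error(correlation_matrix(s[s$metabolite_id == "m1", ]), "2 metabolites")
})

test_that("matrix comparison is a Welch test on upper triangles", {
  set.seed(5)
  X <- matrix(rnorm(50), 10)
  r1 <- cor(X)
  cmp_same <- compare_matrices(r1, r1)
  expect_equal(cmp_same$statistic, 0)
  expect_equal(cmp_same$p, 1)
  r2 <- cor(matrix(rnorm(50), 10))
  cmp <- compare_matrices(r1, r2)
  ref <- stats::t.test(r1[upper.tri(r1)], r2[upper.tri(r2)])
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-12)
  expect_error(compare_matrices(r1, cor(matrix(rnorm(36), 6))), "dimensions")
})

test_that("matrix comparison holds its size under the null", {
  # same generative process, independent noise: rejections should be rare
  rejections <- 0L
  for (seed in 1:24) {
    t1 <- make_synthetic_truth(seed)
    t2 <- make_synthetic_truth(seed + 1000)
    m1 <- correlation_matrix(simulate_metabolome(t1), "0C")
    m2 <- correlation_matrix(simulate_metabolome(t2), "0C")
    if (compare_matrices(m1, m2)$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)
})

test_that("per-metabolite mean tests apply Bonferroni over metabolites tested", {
  set.seed(9)
  n_met <- 34
  rows <- list()
  for (i in seq_len(n_met)) {
    for (cond in c("0C", "15C")) {
      shift <- if (i == 1 && cond == "15C") 3 else 0   # one planted 3-sd shift
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite_id = sprintf("m%02d", i), condition = cond,
        time_h = rep(1:5, each = 3), replicate = rep(1:3, 5),
        value = 10 + stats::rnorm(15) + shift)
    }
  }
  series <- do.call(rbind, rows)
  out <- mean_difference_tests(series)
  expect_equal(out$p_bonferroni, pmin(1, out$p_raw * n_met))
  # a raw p of 0.01 cannot survive m = 34 correction
  expect_false(any(out$significant[out$p_raw > 0.05 / n_met]))
  expect_true(out$significant[out$metabolite_id == "m01"])
})

test_that("a planted 3-sd mean shift survives Bonferroni in most seeds", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    rows <- list()
    for (i in 1:34) {
      for (cond in c("0C", "15C")) {
        shift <- if (i == 1 && cond == "15C") 3 else 0
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite_id = sprintf("m%02d", i), condition = cond,
          time_h = rep(1:5, each = 3), replicate = rep(1:3, 5),
          value = 10 + stats::rnorm(15) + shift)
      }
    }
    out <- mean_difference_tests(do.call(rbind, rows))
    if (out$significant[out$metabolite_id == "m01"] &&
        sum(out$significant) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("log2 fold-change contrast flags and summarizes correctly", {
  rows <- list()
  for (i in 1:34) {
    alt_mean <- if (i <= 8) 4 else 1    # 8 metabolites at log2FC = 2
    rows[[length(rows) + 1L]] <- make_series(sprintf("m%02d", i), "0C",
                                             c(10, 20), c(1, 1), reps = 3)
    rows[[length(rows) + 1L]] <- make_series(sprintf("m%02d", i), "15C",
                                             c(5, 8), c(1, alt_mean), reps = 3)
  }
  ct <- contrast_log2fc(do.call(rbind, rows), time_index = 2)
  expect_equal(attr(ct, "n_flagged"), 8L)
  expect_equal(attr(ct, "pct_below"), 76)   # round(26/34 * 100)
  expect_equal(ct$log2fc[ct$metabolite_id == "m01"], 2)
  expect_equal(ct$log2fc[ct$metabolite_id == "m20"], 0)
})
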