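test_that("paired t matches hand arithmetic and flags degenerate inputs", {
  res <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$statistic, -2 / (1 / sqrt(3)), tolerance = 1e-6)  # -3.46
  expect_equal(round(res$statistic, 2), -3.46)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)
  shift <- paired_t(c(1, 2, 3), c(3, 4, 5))
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p_value))
})

test_that("unpaired t separates shifted groups and matches a permutation oracle", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- unpaired_t(rnorm(10, 1000, 0.1), rnorm(10, 0, 0.1))
  expect_lt(far$p_value, 1e-6)
  # small two-group case against an exhaustive permutation p on the t statistic
  x <- c(1.1, 2.3, 3.2, 4.1); y <- c(2.9, 4.4, 5.1, 6.2)
  res <- unpaired_t(x, y)
  pooled <- c(x, y)
  combos <- utils::combn(8, 4)
  tstats <- apply(combos, 2, function(idx) {
    unpaired_t(pooled[idx], pooled[-idx])$statistic
  })
  perm_p <- mean(abs(tstats) >= abs(res$statistic) - 1e-9)
  expect_lt(abs(res$p_value - perm_p), 0.05)   # t approximation error band
})

test_that("exact Wilcoxon p equals brute-force enumeration for small samples", {
  res <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 2 * (1 / 6))      # two-sided, most extreme of C(4,2)
  cases <- list(
    list(x = c(1.2, 3.5, 2.2), y = c(4.1, 5.0, 6.3)),
    list(x = c(10, 30, 22, 41), y = c(15, 12, 8)),
    list(x = c(0.3, 1.9, 2.8, 3.3, 4.4), y = c(1.1, 2.1, 5.5, 6.6, 7.7, 0.1)),
    list(x = c(5, 1), y = c(2, 3, 4, 6, 7, 8, 9, 10))
  )
  for (cs in cases) {
    got <- wilcoxon_ranksum(cs$x, cs$y)
    expect_match(got$method, "exact")
    expect_equal(got$p_value, enumerate_ranksum_p(cs$x, cs$y),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum is invariant to monotone transforms and flags constants", {
  x <- c(1, 5, 9, 13); y <- c(2, 4, 20, 30)
  a <- wilcoxon_ranksum(x, y)
  b <- wilcoxon_ranksum(exp(x / 5), exp(y / 5))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  same <- wilcoxon_ranksum(c(2, 2), c(2, 2, 2))
  expect_true(same$degenerate)
  ident <- wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 0.05)
})

test_that("t-test type-I error is calibrated on Gaussian nulls", {
  set.seed(2024)
  rejections <- vapply(seq_len(2000), function(i) {
    paired_t(rnorm(8), rnorm(8))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("the per-channel screen flags injected effects and respects alpha", {
  set.seed(7)
  cells <- expand.grid(channel = sprintf("ch%02d", 1:6),
                       band = c("delta", "alpha"), stringsAsFactors = FALSE)
  df <- purrr::map_dfr(1:8, function(unit) {
    purrr::map_dfr(c("before", "after"), function(cond) {
      v <- rnorm(nrow(cells))
      v[cells$channel == "ch03" & cells$band == "alpha"] <-
        v[cells$channel == "ch03" & cells$band == "alpha"] +
        ifelse(cond == "after", 8, 0)
      dplyr::mutate(cells, unit = unit, condition = cond, value = v)
    })
  })
  scr <- per_channel_screen(df, value = "value", condition = "condition",
                            unit = "unit", test = "paired_t")
  hit <- scr[scr$channel == "ch03" & scr$band == "alpha", ]
  expect_true(hit$significant)
  expect_lt(mean(scr$significant[!(scr$channel == "ch03" & scr$band == "alpha")]),
            0.3)
  # tiny alpha empties the mask
  scr0 <- per_channel_screen(df, value = "value", condition = "condition",
                             unit = "unit", test = "paired_t", alpha = 1e-12)
  expect_equal(sum(scr0$significant), 0)
  # FDR mode is labelled
  scr_bh <- per_channel_screen(df, value = "value", condition = "condition",
                               unit = "unit", test = "wilcoxon", adjust = "BH")
  expect_true(all(scr_bh$adjust == "BH"))
  expect_true(all(scr_bh$p_adjusted >= scr_bh$p_value - 1e-12))
})

test_that("the screen's false-positive rate under the null is near alpha", {
  set.seed(99)
  rates <- vapply(seq_len(30), function(r) {
    df <- purrr::map_dfr(1:8, function(unit) {
      purrr::map_dfr(c("a", "b"), function(cond) {
        tibble::tibble(channel = sprintf("ch%02d", rep(1:14, each = 5)),
                       band = rep(c("delta", "theta", "alpha", "beta", "gamma"), 14),
                       unit = unit, condition = cond, value = rnorm(70))
      })
    })
    scr <- per_channel_screen(df, value = "value", condition = "condition",
                              unit = "unit", test = "paired_t")
    mean(scr$significant)
  }, numeric(1))
  # binomial band around 0.05 for 30 x 70 cells
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})
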