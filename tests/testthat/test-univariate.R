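# independent hand oracle for the Welch statistic
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

test_that("Welch t statistic, df and p match the closed-form oracle", {
  set.seed(8)
  for (rep in 1:25) {
    x <- rlnorm(sample(3:30, 1), sdlog = runif(1, 0.3, 1.5))
    y <- rlnorm(sample(3:30, 1), sdlog = runif(1, 0.3, 1.5))
    got <- welch_t(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # antisymmetry under sample swap
    swapped <- welch_t(y, x)
    expect_equal(swapped$t, -got$t, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
})

test_that("Welch degenerate cases follow the stated conventions", {
  expect_message(got <- welch_t(c(2, 2, 2), c(2, 2)), "constant")
  expect_equal(got$p, 1)
  expect_equal(got$t, 0)
  expect_error(welch_t(c(1, 1), c(2, 2)), "constant")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  # identical samples: exact symmetry
  x <- c(1.3, 2.2, 5.9)
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("sqrt-transform test composes the two published steps", {
  set.seed(9)
  x <- rlnorm(20); y <- rlnorm(25)
  got <- sqrt_transform_then_test(x, y)
  want <- welch_t(sqrt(x), sqrt(y))
  expect_equal(got, want, tolerance = 1e-12)
  # t is invariant to scaling both samples by s^2
  s2 <- 5.7^2
  expect_equal(sqrt_transform_then_test(x * s2, y * s2)$t, got$t,
               tolerance = 1e-10)
  expect_error(sqrt_transform_then_test(c(-1, 2, 3), y), "non-negative")
})

test_that("BH q-values reproduce the hand-evaluated step-up and dominate p", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand evaluation of the step-up: q_(i) = min_{k>=i} m p_(k) / k, i.e. a
  # cumulative minimum from the largest p downwards
  p <- c(0.04, 0.001, 0.9, 0.02, 0.3)
  q <- bh_fdr(p)
  m <- length(p)
  ord <- order(p)
  sorted <- sort(p)
  qs <- rev(cummin(rev(m * sorted / seq_len(m))))
  expect_equal(q[ord], pmin(1, qs), tolerance = 1e-12)

  set.seed(10)
  for (rep in 1:20) {
    p <- runif(sample(2:40, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("AUROC rank formula equals brute-force pair counting, with ties", {
  expect_equal(auroc(c(5, 6, 7), c(1, 2, 3)), 1)     # complete separation
  expect_equal(auroc(c(1, 2), c(1, 2)), 0.5)         # tie symmetry
  set.seed(12)
  for (rep in 1:100) {
    # discretised values force ties
    x <- sample(1:8, sample(2:15, 1), replace = TRUE)
    y <- sample(1:8, sample(2:15, 1), replace = TRUE)
    pairs <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
    expect_equal(auroc(x, y), mean(pairs), tolerance = 1e-12)
  }
  # null orientation: identically drawn large samples sit near 1/2
  set.seed(13)
  expect_equal(auroc(rnorm(4000), rnorm(4000)), 0.5, tolerance = 0.03)
})

test_that("percent difference reproduces the published worked rows", {
  expect_equal(round(percent_difference(2564, 1072)), 139)
  expect_equal(round(percent_difference(7.95, 3.77)), 111)
  expect_equal(percent_difference(5, 5), 0)
  expect_warning(out <- percent_difference(3, 0), "undefined")
  expect_true(is.na(out))
  # invariant to joint positive rescaling
  expect_equal(percent_difference(2564e3, 1072e3),
               percent_difference(2564, 1072))
})

test_that("percent above reference agrees with the scoring indicators", {
  sim <- small_sim(seed = 19, n_asd = 20, n_td = 15, n_met = 4,
                   elevation_prob = 0.4)
  res <- score_cohort(sim$cohort)
  g <- cohort_groups(sim$cohort)
  vals <- res$norm$values
  for (j in seq_len(ncol(vals))) {
    ri <- match(colnames(vals)[j], res$ranges$metabolite_id)
    got <- pct_above_reference(vals[g == "ASD", j],
                               res$ranges$lower[ri], res$ranges$upper[ri])
    expect_equal(got, 100 * mean(res$indicators[g == "ASD", j]))
  }
  expect_equal(pct_above_reference(c(1, 2), lower = 0, upper = 10), 0)
})

test_that("percent below LOD pools both groups and matches generator truth", {
  expect_equal(pct_below_lod(c(TRUE, TRUE)), 100)
  expect_equal(pct_below_lod(c(FALSE, FALSE, FALSE)), 0)
  sim <- small_sim(seed = 29, n_asd = 50, n_td = 50, elevation_prob = 0,
                   lod_quantile = 0.3)
  norm <- normalize_by_creatinine(sim$cohort)
  tab <- univariate_table(norm)
  expect_equal(mean(tab$pct_below_lod), 30, tolerance = 3)
})

test_that("correlation matrix matches the textbook formula on a hand fixture", {
  vals <- cbind(a = c(1, 2, 3, 4, 5),
                b = c(2, 1, 4, 3, 6),
                c = c(5, 4, 3, 2, 1))
  got <- correlation_matrix(vals)
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(got["a", "b"], pearson(vals[, "a"], vals[, "b"]),
               tolerance = 1e-12)
  expect_equal(diag(got), c(a = 1, b = 1, c = 1))
  expect_equal(got["a", "c"], -1)                      # negated column
  expect_equal(correlation_matrix(cbind(vals, d = vals[, "a"]))["a", "d"], 1)
  expect_true(isSymmetric(got))
})

test_that("univariate table assembles all columns coherently", {
  sim <- small_sim(seed = 37, n_asd = 20, n_td = 15, n_met = 5,
                   elevation_prob = 0.4, lod_quantile = 0.1)
  norm <- normalize_by_creatinine(sim$cohort)
  tab <- univariate_table(norm)
  expect_equal(nrow(tab), 5)
  expect_true(all(c("mean_asd", "mean_td", "pct_difference", "p_raw",
                    "p_sqrt", "q_value", "auroc", "pct_asd_above_td",
                    "pct_below_lod") %in% names(tab)))
  expect_true(all(tab$q_value >= tab$p_raw - 1e-15))
  expect_true(all(tab$auroc >= 0 & tab$auroc <= 1))
  g <- cohort_groups(sim$cohort)
  expect_equal(tab$mean_asd[1], mean(norm$values[g == "ASD", 1], na.rm = TRUE))
  # report formatting: integer percents, 2-decimal AUROC
  rep <- format_report(tab)
  expect_true(all(rep$pct_asd_above_td == round(rep$pct_asd_above_td)))
  expect_equal(rep$auroc, round(rep$auroc, 2))
})

test_that("Welch test keeps nominal type-I error under the null generator", {
  # identical groups, no elevations: rejection rate at alpha = 0.05 stays
  # within Monte-Carlo error; BH then controls FDR trivially under the null
  set.seed(555)
  n_rep <- 5000
  pvals <- vapply(seq_len(n_rep), function(r) {
    welch_t(rlnorm(15), rlnorm(15))$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  # Welch on skewed lognormal n=15 is approximate; allow modest slack
  expect_lt(abs(rate - 0.05), 0.02)
  expect_lt(mean(bh_fdr(pvals[1:200]) < 0.05), 0.05)
})
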