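test_that("same seed and config give bit-identical cohorts", {
  a <- small_sim(seed = 101)
  b <- small_sim(seed = 101)
  expect_identical(a$cohort$raw, b$cohort$raw)
  expect_identical(a$cohort$lod_flags, b$cohort$lod_flags)
  expect_identical(a$truth, b$truth)
  expect_identical(a$multipliers, b$multipliers)
  c <- small_sim(seed = 102)
  expect_false(identical(a$cohort$raw, c$cohort$raw))
})

test_that("per-metabolite substreams: adding a metabolite leaves others' draws alone", {
  p5 <- tiny_panel(5)
  p6 <- tiny_panel(6)
  cfg5 <- sim_config(10, 8, p5, log_mean = 0, elevation_prob = 0.3, seed = 7)
  cfg6 <- sim_config(10, 8, p6, log_mean = 0, elevation_prob = 0.3, seed = 7)
  s5 <- generate_cohort(cfg5)
  s6 <- generate_cohort(cfg6)
  shared <- p5$metabolite_id
  expect_identical(s6$cohort$raw[, shared], s5$cohort$raw[, shared])
  expect_identical(s6$multipliers[, shared], s5$multipliers[, shared])
})

test_that("null configuration produces no truth and TD-exchangeable ASD", {
  sim <- small_sim(seed = 5, elevation_prob = 0)
  expect_true(all(lengths(sim$truth) == 0))
  expect_true(all(sim$multipliers == 1))
  # groups are exchangeable: Welch p on a couple of metabolites is not tiny
  norm <- normalize_by_creatinine(sim$cohort)
  g <- cohort_groups(sim$cohort)
  p1 <- welch_t(norm$values[g == "ASD", 1], norm$values[g == "TD", 1])$p
  expect_gt(p1, 1e-4)
})

test_that("forced large elevations land in truth and dominate the TD scale", {
  panel <- tiny_panel(3)
  cfg <- sim_config(20, 15, panel, log_mean = 0, log_sd = 0.5,
                    elevation_prob = c(met01 = 1, met02 = 0, met03 = 0),
                    fold_range = c(500, 1000), seed = 31)
  sim <- generate_cohort(cfg)
  expect_true(all(vapply(sim$truth, function(t) "met01" %in% t, logical(1))))
  # applied multipliers are recorded and within the configured fold range
  expect_true(all(sim$multipliers[, "met01"] >= 500 &
                  sim$multipliers[, "met01"] <= 1000))
  norm <- normalize_by_creatinine(sim$cohort)
  g <- cohort_groups(sim$cohort)
  ratio <- median(norm$values[g == "ASD", "met01"]) /
    median(norm$values[g == "TD", "met01"])
  expect_gte(ratio, 100)
})

test_that("truth is consistent: fired events only, ASD only, multiplier != 1", {
  for (seed in c(3, 17, 59)) {
    sim <- small_sim(seed = seed, elevation_prob = 0.4)
    for (pid in names(sim$truth)) {
      fired <- sim$truth[[pid]]
      expect_setequal(fired,
                      colnames(sim$multipliers)[sim$multipliers[pid, ] != 1])
      expect_true(all(sim$multipliers[pid, fired] > 1))
    }
    expect_true(all(startsWith(names(sim$truth), "ASD")))
  }
})

test_that("low-direction markers are suppressed, not elevated, when they fire", {
  panel <- tiny_panel(2, directions = c("high", "low"))
  cfg <- sim_config(10, 8, panel, log_mean = 0,
                    elevation_prob = c(met01 = 0, met02 = 1),
                    fold_range = c(10, 100), seed = 13)
  sim <- generate_cohort(cfg)
  expect_true(all(sim$multipliers[, "met02"] < 1))
  expect_true(all(sim$multipliers[, "met02"] >= 1 / 100))
})

test_that("LOD censoring hits the requested fraction and flags match values", {
  sim <- small_sim(seed = 23, n_asd = 60, n_td = 60, elevation_prob = 0,
                   lod_quantile = 0.4)
  frac <- mean(sim$cohort$lod_flags)
  expect_equal(frac, 0.4, tolerance = 0.05)
  expect_true(all(is.na(sim$cohort$raw[sim$cohort$lod_flags])))
  # realized LODs are recorded on the panel for downstream imputation
  expect_true(all(!is.na(sim$cohort$panel$lod)))
})

test_that("family coupling drives co-elevation within families", {
  panel <- tiny_panel(4, directions = rep("high", 4))
  # two metabolites per family (tiny_panel cycles families)
  probs <- stats::setNames(rep(0.5, 4), panel$metabolite_id)
  fire_cor <- function(coupling) {
    fires <- sapply(1:40, function(s) {
      cfg <- sim_config(30, 10, panel, log_mean = 0, elevation_prob = probs,
                        family_coupling = coupling, seed = 1000 + s)
      m <- generate_cohort(cfg)$multipliers
      # met01 and met04 share a family under the cycling layout
      stats::cor(m[, "met01"] != 1, m[, "met04"] != 1)
    })
    mean(fires, na.rm = TRUE)
  }
  expect_lt(abs(fire_cor(0)), 0.12)     # independent events
  expect_gt(fire_cor(1), 0.8)           # all-or-none per family
})

test_that("calibration inverts the exceedance model", {
  panel <- tiny_panel(3)
  # all-zero targets give elevation probability zero everywhere
  cfg0 <- calibrate_to_table(
    stats::setNames(rep(0, 3), panel$metabolite_id),
    n_asd = 10, n_td = 20, panel = panel, log_mean = 0, seed = 1)
  expect_true(all(cfg0$elevation_prob == 0))

  # infeasible target: no fold range reaches exceedance 1
  expect_error(
    calibrate_to_table(stats::setNames(c(1, 0, 0), panel$metabolite_id),
                       n_asd = 10, n_td = 20, panel = panel, log_mean = 0),
    "infeasible")

  # achieved expected exceedance is the invert of the measured mixture
  cfg <- calibrate_to_table(
    stats::setNames(c(0.44, 0.1, 0), panel$metabolite_id),
    n_asd = 50, n_td = 47, panel = panel, log_mean = 0, seed = 1)
  expect_equal(unname(cfg$calibration$achieved[1:2]), c(0.44, 0.1),
               tolerance = 1e-10)
  expect_equal(unname(cfg$calibration$achieved[3]), 1 / 48, tolerance = 1e-12)
})

test_that("calibrated exceedance is realized empirically (Monte Carlo)", {
  # one strongly-elevated metabolite, target 0.44: over many simulated
  # cohorts the strict-exceedance fraction among ASD matches the target
  panel <- tiny_panel(1)
  cfg <- calibrate_to_table(c(met01 = 0.44), n_asd = 50, n_td = 47,
                            panel = panel, log_mean = 0, seed = 1)
  rates <- vapply(1:200, function(s) {
    cfg$seed <- 50000L + s
    sim <- generate_cohort(cfg)
    res <- score_cohort(sim$cohort)
    g <- cohort_groups(sim$cohort)
    mean(res$indicators[g == "ASD", "met01"])
  }, numeric(1))
  expect_equal(mean(rates), 0.44, tolerance = 0.05)

  # linearity of expectation: expected total score is the sum of the
  # achieved per-metabolite fractions
  panel3 <- tiny_panel(3)
  cfg3 <- calibrate_to_table(
    stats::setNames(c(0.3, 0.15, 0.05), panel3$metabolite_id),
    n_asd = 50, n_td = 47, panel = panel3, log_mean = 0,
    family_coupling = 0, seed = 1)
  totals <- vapply(1:200, function(s) {
    cfg3$seed <- 60000L + s
    sim <- generate_cohort(cfg3)
    res <- score_cohort(sim$cohort)
    mean(res$scores$total[cohort_groups(sim$cohort) == "ASD"])
  }, numeric(1))
  expect_equal(mean(totals), sum(cfg3$calibration$achieved),
               tolerance = 0.05)
})

test_that("synthetic cohort writes the cohort CSV dialect plus truth sidecar", {
  sim <- small_sim(seed = 77, elevation_prob = 0.5, lod_quantile = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_synthetic_cohort(sim, path)
  back <- load_cohort(path, sim$cohort$panel)
  expect_equal(back$raw, sim$cohort$raw)
  expect_identical(back$lod_flags, sim$cohort$lod_flags)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"))
  expect_equal(truth$seed, 77)
  expect_setequal(unlist(truth$truth[["ASD001"]]), sim$truth[["ASD001"]])
})
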