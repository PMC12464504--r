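test_that("ICER values and quadrants classify correctly", {
  ne <- icer(23.3, 2.8)
  expect_equal(ne$value, 23.3 / 2.8)
  expect_identical(ne$quadrant, "NE")
  expect_true(ne$interpretable)

  dom <- icer(-10, 0.1)
  expect_identical(dom$quadrant, "SE")
  expect_true(dom$dominant)
  expect_lt(dom$value, 0)

  bad <- icer(10, -0.1)
  expect_identical(bad$quadrant, "NW")
  expect_true(bad$dominated)
  expect_false(bad$interpretable)

  zero <- icer(10, 0)
  expect_true(is.na(zero$value))
  expect_false(zero$interpretable)
})

test_that("zero-variance data bootstrap to the point estimate", {
  fr <- frame_with_means(130, 100, noise_sd = 0)
  fr$sbp_reduction <- ifelse(fr$arm == "intervention", 7.1, 4.3)
  fr$baseline_sbp <- 145
  bs <- cluster_bootstrap(fr, "sbp_reduction", baseline = "baseline_sbp",
                          B = 25, seed = 4)
  expect_true(all(abs(bs$draws$d_cost - 30) < 1e-8))
  expect_true(all(abs(bs$draws$d_effect - 2.8) < 1e-8))
  expect_equal(unname(bs$point), c(30, 2.8), tolerance = 1e-8)
})

test_that("bootstrap draws are seed-reproducible and centered", {
  cfg <- run_config()
  fr <- build_analysis_frame(simulate_trial(small_sim()), cfg)
  a <- cluster_bootstrap(fr, "sbp_reduction", baseline = "baseline_sbp",
                         B = 400, seed = 7)
  b <- cluster_bootstrap(fr, "sbp_reduction", baseline = "baseline_sbp",
                         B = 400, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_error(cluster_bootstrap(fr, "sbp_reduction", B = 0), "B")
  # bootstrap consistency: draw mean within 2 MC SE of the OLS center
  center <- adjusted_difference(fr, "sbp_reduction",
                                baseline = "baseline_sbp",
                                method = "ols")$delta
  mc_se <- stats::sd(a$draws$d_effect) / sqrt(a$B)
  expect_lt(abs(mean(a$draws$d_effect) - center),
            2 * mc_se + 0.05 * abs(center) + 0.05)
  # REML replication path agrees with the OLS path in expectation
  r <- cluster_bootstrap(fr, "sbp_reduction", baseline = "baseline_sbp",
                         B = 40, seed = 7, method = "reml")
  expect_lt(abs(mean(r$draws$d_effect) - mean(a$draws$d_effect)),
            3 * stats::sd(a$draws$d_effect) / sqrt(40))
})

test_that("stratified cluster resampling preserves the design", {
  # resampling respects township x arm strata: with one village per
  # stratum the resample is the identity, so draws repeat the point
  fr <- frame_with_means(120, 100, noise_sd = 30, seed = 2,
                         n_villages_per_arm = 2)
  fr$township <- ifelse(fr$village %in% c(1, 3), 1, 2)
  bs <- cluster_bootstrap(fr, "total_cost", baseline = NULL,
                          cost_outcome = "total_cost", B = 10, seed = 1)
  expect_true(all(abs(bs$draws$d_cost - bs$draws$d_cost[1]) < 1e-8))
})

test_that("CEAC is the NMB exceedance fraction with its invariants", {
  draws <- data.frame(d_cost = c(-5, -1, -2), d_effect = c(0.1, 0.2, 0.3))
  expect_true(all(ceac(draws, c(0, 100, 1000))$p_ce == 1))

  set.seed(1)
  draws <- data.frame(d_cost = stats::rnorm(500, 20, 30),
                      d_effect = stats::rexp(500, 10))
  grid <- seq(0, 4e4, length.out = 41)
  curve <- ceac(draws, grid)
  expect_equal(curve$p_ce[1], mean(draws$d_cost <= 0))
  expect_true(all(diff(curve$p_ce) >= 0))  # all d_effect >= 0
  expect_true(all(curve$p_ce >= 0 & curve$p_ce <= 1))
  # limit: fraction with positive effect (plus free zero-effect draws)
  expect_equal(ceac(draws, 1e12)$p_ce, mean(draws$d_effect > 0))
  expect_error(ceac(draws, c(-1, 10)), "negative")
})

test_that("draw summaries report quadrants and percentile intervals", {
  all_ne <- data.frame(d_cost = c(1, 2, 3), d_effect = c(1, 1, 2))
  s <- ce_summary(all_ne)
  expect_equal(unname(s$quadrants[["NE"]]), 1)
  expect_equal(sum(s$quadrants), 1)
  expect_equal(s$interpretable_fraction, 1)

  set.seed(2)
  sym <- data.frame(d_cost = stats::rnorm(4000),
                    d_effect = stats::rnorm(4000))
  s2 <- ce_summary(sym)
  expect_equal(sum(s2$quadrants), 1)
  expect_lt(abs(sum(s2$quadrants[c("NE", "SE")]) - 0.5), 0.05)
  expect_equal(s2$ci_d_cost,
               unname(stats::quantile(sym$d_cost, c(0.025, 0.975))),
               tolerance = 1e-9)
  # order invariance of percentile endpoints
  s3 <- ce_summary(sym[rev(seq_len(nrow(sym))), ])
  expect_equal(s3$ci_d_effect, s2$ci_d_effect, tolerance = 1e-12)
})

test_that("one-way DSA recomputes the ICER parameter by parameter", {
  expect_identical(nrow(one_way_dsa(list(a = 1), list(), identity)), 0L)

  evalr <- function(p) (p$c_fixed + p$x) / p$effect
  base <- list(c_fixed = 10, x = 10, effect = 0.03, ignored = 1)
  rows <- one_way_dsa(base, list(x = c(5, 15), ignored = c(0, 2)), evalr)
  xrow <- rows[rows$parameter == "x", ]
  expect_equal(xrow$icer_low, 500)
  expect_equal(xrow$icer_high, 833.33, tolerance = 1e-4)
  irow <- rows[rows$parameter == "ignored", ]
  expect_equal(irow$icer_low, irow$icer_high)
  # tornado order: largest swing first
  expect_identical(rows$parameter[1], "x")
  expect_error(one_way_dsa(base, list(zz = c(0, 1)), evalr), "zz")
  expect_error(one_way_dsa(base, list(x = c(2, 1)), evalr), "low < high")
})

test_that("run_cea bundles point, draws, CEAC and summary consistently", {
  cfg <- run_config(n_bootstrap = 300, rng_seed = 5)
  fr <- build_analysis_frame(simulate_trial(small_sim()), cfg)
  res <- run_cea(fr, "qaly", baseline = "baseline_utility", cfg = cfg)
  expect_s3_class(res, "ce_result")
  expect_identical(nrow(res$draws), 300L)
  expect_equal(res$icer$value, res$point$d_cost / res$point$d_effect)
  expect_identical(nrow(res$ceac), length(cfg$wtp_grid))
  expect_output(print(res), "ICER")
})
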