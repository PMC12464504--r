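test_that("default design reproduces the trial structure", {
  tt <- generate_trial(sim_config(seed = 1))
  oc <- tt$outcomes
  vt <- unique(oc[, c("village", "township", "arm")])
  expect_identical(nrow(vt), 50L)
  expect_identical(n_participants(tt), 1299L)
  expect_identical(unname(table(vt$arm)[["intervention"]]), 25L)
  # stratified 1:1 balance within every township
  tab <- table(vt$township, vt$arm)
  expect_true(all(tab[, "intervention"] == tab[, "control"]))
  expect_identical(nrow(tab), 5L)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  cfg <- small_sim()
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a, b)
  cfg2 <- small_sim(); cfg2$seed <- 43
  expect_false(identical(simulate_trial(cfg2)$outcomes$sbp,
                         a$outcomes$sbp))
})

test_that("utilities honor the truncation bounds and deaths are terminal", {
  cfg <- small_sim(mortality_year1 = 0.2, include_posttrial = TRUE)
  tt <- generate_trial(cfg)
  oc <- tt$outcomes
  u <- oc$utility[!is.na(oc$utility)]
  expect_true(all(u <= 1))
  expect_true(all(u >= cfg$utility_floor))
  dead <- !is.na(oc$death_time)
  expect_false(any(dead & oc$time_years > oc$death_time &
                     (!is.na(oc$sbp) | !is.na(oc$utility))))
  expect_gt(sum(!is.na(unique(oc[, c("pid", "death_time")])$death_time)), 0)
})

test_that("degenerate cost settings behave as configured", {
  # no hospitalization risk at all -> no inpatient items; the cost target
  # must then be attainable from program + medication components alone
  cfg <- small_sim(inpatient_prob = c(inpatient_stroke = 0,
                                      inpatient_cvd_nonstroke = 0,
                                      inpatient_other = 0),
                   med_uptake_intervention = c(med_antiplatelet = 0.60,
                                               med_statin = 0.30,
                                               med_antihypertensive = 0.62),
                   target_cost_increment = 50.8)
  tt <- simulate_trial(cfg)
  expect_false(any(grepl("^inpatient", tt$cost_items$category)))
  # hospitalization certain in the control arm
  cfg2 <- small_sim(inpatient_prob = c(inpatient_stroke = 1,
                                       inpatient_cvd_nonstroke = 0,
                                       inpatient_other = 0),
                    target_cost_increment = 23.3)
  tt2 <- simulate_trial(cfg2)
  ctl <- unique(tt2$outcomes$pid[tt2$outcomes$arm == "control"])
  stroke <- tt2$cost_items[tt2$cost_items$category == "inpatient_stroke", ]
  expect_true(all(ctl %in% stroke$pid))
})

test_that("an unattainable cost target is rejected at config time", {
  expect_error(small_sim(target_cost_increment = 1e6),
               "target_cost_increment")
  expect_error(sim_config(villages_per_township = 3), "even")
  expect_error(sim_config(mortality_year1 = 1.5), "probabilities")
})

test_that("the utility ceiling attenuates the configured gain predictably", {
  # additive utility gains are clipped at full health, so the realized
  # arm contrast sits a little below the configured +0.06 (and the QALY
  # contrast below +0.03); the SBP effect has no such bound
  scfg <- sim_config(seed = 1)
  cfg <- run_config()
  d <- vapply(1:40, function(s) {
    scfg$seed <- s
    fr <- build_analysis_frame(simulate_trial(scfg), cfg)
    adjusted_difference(fr, "utility_change",
                        baseline = "baseline_utility")$delta
  }, numeric(1))
  expect_lt(mean(d), 0.06)
  expect_gt(mean(d), 0.75 * 0.06)
})

test_that("with no true effects the estimated differences center on zero", {
  cfg0 <- small_sim(true_effect_sbp = 0, true_effect_utility = 0,
                    target_cost_increment = 0, program_cost_pp = 0,
                    med_uptake_intervention = c(med_antiplatelet = 0.60,
                                                med_statin = 0.30,
                                                med_antihypertensive = 0.62))
  rcfg <- run_config()
  est <- vapply(1:40, function(s) {
    cfg0$seed <- s
    fr <- build_analysis_frame(simulate_trial(cfg0), rcfg)
    c(adjusted_difference(fr, "sbp_reduction",
                          baseline = "baseline_sbp")$delta,
      adjusted_difference(fr, "total_cost")$delta)
  }, numeric(2))
  mc_se_sbp <- stats::sd(est[1, ]) / sqrt(ncol(est))
  mc_se_cost <- stats::sd(est[2, ]) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ])), 3 * mc_se_sbp)
  expect_lt(abs(mean(est[2, ])), 3 * mc_se_cost)
})
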