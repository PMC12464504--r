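test_that("first-year eligibility is prevalence times rural share", {
  p <- bia_params(base_population = 1e6)
  expect_equal(eligible_year1(p), round(1e6 * 0.0258 * 0.529))  # 13648
  p0 <- bia_params(stroke_prevalence = 0)
  expect_equal(eligible_year1(p0), 0)
  # default base population back-solves the published eligible count
  expect_equal(eligible_year1(bia_params()), 11676010, tolerance = 2)
})

test_that("the calibrated projection reproduces the published trajectory", {
  p <- bia_params()
  r <- (p$eligible_year5 / p$eligible_year1)^(1 / 4) - 1
  expect_equal(r, 4.099907e-4, tolerance = 1e-4)
  n <- p$eligible_year1
  for (k in 1:4) n <- project_eligible(n, p, "calibrated")
  expect_lte(abs(n - 11695170), 1)
  expect_equal(eligible_series(p, 5)[5], n)

  # zero rates leave the population unchanged in stated-rates mode
  p0 <- bia_params(population_growth = 0, death_rate = 0,
                   incidence_rate = 0)
  expect_equal(project_eligible(5000, p0, "stated_rates"), 5000)
  expect_error(project_eligible(0, p), "n_prev")
})

test_that("scenario costs follow the component schedule", {
  p <- bia_params()
  a <- bia_run(p, "A")
  b <- bia_run(p, "B")
  expect_equal(a$cost_per_participant[1], 16.93, tolerance = 0.01)
  expect_equal(a$cost_per_participant[5], 6.68, tolerance = 0.01)
  expect_equal(b$cost_per_participant[1], 9.90, tolerance = 0.01)
  expect_equal(b$cost_per_participant[5], 3.98, tolerance = 0.01)
  # integration and year-1-only components only ever remove cost
  expect_true(all(b$cost_per_participant <= a$cost_per_participant))
  expect_true(all(a$cost_per_participant <= a$cost_per_participant[1]))
  expect_true(all(b$cost_per_participant <= b$cost_per_participant[1]))
  # NBPH-covered headcount tracks the published split
  expect_equal(b$covered_by_nbph[1], 7125158)
  expect_lte(abs(b$covered_by_nbph[5] - 7136851), 10)
})

test_that("toy component schedules reproduce hand arithmetic", {
  comp <- data.frame(
    component = c("visits", "messages", "development"),
    cost = c(4 * 1.00, 2.00, 10.00),
    year1_only = c(FALSE, FALSE, TRUE),
    nbph_funded = c(TRUE, FALSE, FALSE))
  p <- bia_params(components = comp)
  y1 <- scenario_cost(1000, p, "A", year = 1)
  y2 <- scenario_cost(1000, p, "A", year = 2)
  expect_equal(y1$cost_per_participant, 16)
  expect_equal(y2$cost_per_participant, 6)
  # total budget is linear in the eligible population
  expect_equal(scenario_cost(2000, p, "A", 1)$total_budget,
               2 * y1$total_budget)
  zero <- bia_params(components = transform(comp, cost = 0))
  z <- scenario_cost(1000, zero, "A", 1)
  expect_equal(z$total_budget, 0)
  expect_equal(z$cost_per_capita, 0)
})

test_that("per-capita division matches the published table", {
  expect_equal(round(per_capita(197726357, 1411750000), 2), 0.14)
  expect_equal(round(per_capita(46592046, 1459785833), 2), 0.03)
  expect_equal(per_capita(0, 123), 0)
  expect_error(per_capita(100, 0), "population")
})

test_that("parameter validation rejects incoherent inputs", {
  expect_error(bia_params(stroke_prevalence = 1.2), "fractions")
  expect_error(bia_params(horizon_years = 0), "horizon")
  expect_error(bia_params(nbph_covered_year1 = 2e7), "exceed")
})
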