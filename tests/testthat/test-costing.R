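cfg_cpi <- run_config(cpi_table = c("2017" = 95, "2020" = 100,
                                    "2023" = 110),
                      exchange_rate = 7.08)

test_that("currency adjustment inflates by the CPI ratio and converts once", {
  expect_equal(adjust_currency(100, 2023, cfg_cpi, "USD"), 100)
  expect_equal(adjust_currency(100, 2020, cfg_cpi, "USD"), 110)
  expect_equal(adjust_currency(0, 2017, cfg_cpi, "USD"), 0)
  expect_equal(adjust_currency(708, 2023, cfg_cpi, "local"), 100)
  expect_error(adjust_currency(10, 1999, cfg_cpi), "1999")
})

test_that("currency adjustment is multiplicative-linear", {
  a <- stats::runif(20, 0, 500); b <- stats::runif(20, 0, 500)
  k <- 3.7
  expect_equal(adjust_currency(a + b, 2017, cfg_cpi),
               adjust_currency(a, 2017, cfg_cpi) +
                 adjust_currency(b, 2017, cfg_cpi))
  expect_equal(adjust_currency(k * a, 2017, cfg_cpi, "local"),
               k * adjust_currency(a, 2017, cfg_cpi, "local"))
})

test_that("medication cost is quantity x price x adherence", {
  expect_equal(medication_cost(30, 0.10, 0.8), 2.40)
  expect_equal(medication_cost(30, 0.10, 0), 0)
  expect_equal(medication_cost(30, 0.10, 1), 3)
  expect_error(medication_cost(30, 0.10, 1.2), "adherence")
  expect_error(medication_cost(-1, 0.10, 0.5), "quantity")
})

test_that("person totals include people with no recorded items", {
  cfg <- run_config()
  none <- data.frame(pid = character(0), amount = numeric(0),
                     source_year = integer(0))
  expect_equal(person_total_cost(none, 45.5, cfg), 45.5)
  items <- data.frame(pid = "a", amount = c(218.3, 37.3),
                      source_year = 2023)
  expect_equal(person_total_cost(items, 45.5, cfg), 301.1)
  expect_equal(person_total_cost(none, 0, cfg), 0)
  # permutation invariance and additivity over disjoint subsets
  expect_equal(person_total_cost(items[2:1, ], 45.5, cfg), 301.1)
  expect_equal(person_total_cost(items, 0, cfg),
               person_total_cost(items[1, , drop = FALSE], 0, cfg) +
                 person_total_cost(items[2, , drop = FALSE], 0, cfg))
  # unadjusted currency-years never silently sum
  mixed <- data.frame(pid = "a", amount = c(10, 10),
                      source_year = c(2023, 2018))
  expect_error(person_total_cost(mixed, 0, cfg), "2018")
})

test_that("program ledger amortizes its grand total per participant", {
  components <- data.frame(
    component = c("township_physicians", "village_doctors",
                  "project_manager", "county_specialists",
                  "voice_messages", "printing", "system_maintenance",
                  "development_fee"),
    unit_cost = c(228.9, 414.8, 740.7, 134.7, 0.02, 0.5, 1481.4, 16497.6),
    quantity = c(5, 25, 1, 2, 97000, 700, 1, 1),
    total = c(1144.7, 10369.9, 740.7, 269.3, 1548.8, 336.7, 1481.4,
              16497.6))
  led <- program_ledger(components, n_participants = 638)
  pp <- program_per_participant(led)
  expect_equal(pp$grand_total, 32389.1, tolerance = 1e-9)
  expect_equal(pp$per_participant, 32389.1 / 638, tolerance = 1e-9)

  single <- program_ledger(
    data.frame(component = "maintenance", unit_cost = 1481.4,
               quantity = 1, total = 1481.4), 1)
  expect_equal(program_per_participant(single)$per_participant, 1481.4)

  zero <- program_ledger(
    data.frame(component = "x", unit_cost = 0, quantity = 0, total = 0), 10)
  expect_equal(unlist(program_per_participant(zero)),
               c(grand_total = 0, per_participant = 0))
  none <- program_ledger(components, 0)
  expect_error(program_per_participant(none), "n_participants")
})

test_that("post-trial inpatient costs are counts times within-trial means", {
  expect_equal(estimate_posttrial_inpatient(c(stroke = 1),
                                            c(stroke = 639.8)), 639.8)
  expect_equal(estimate_posttrial_inpatient(c(stroke = 0, other = 0),
                                            c(stroke = 600, other = 300)),
               0)
  expect_equal(estimate_posttrial_inpatient(c(stroke = 2, other = 1),
                                            c(stroke = 600, other = 300)),
               1500)
  expect_error(estimate_posttrial_inpatient(c(unknown_cause = 1),
                                            c(stroke = 600)),
               "unknown_cause")
  # data.frame interface agrees with the vector interface
  df <- data.frame(cause = c("stroke", "other"), count = c(2, 1))
  expect_equal(estimate_posttrial_inpatient(
    df, c(stroke = 600, other = 300)), 1500)
})

test_that("within-trial per-cause episode means are plain averages", {
  ci <- data.frame(
    pid = c("a", "b", "c"),
    category = c("inpatient_stroke", "inpatient_stroke",
                 "inpatient_other"),
    amount = c(500, 700, 300), period = "within")
  m <- inpatient_cause_means(ci)
  expect_equal(unname(m[["inpatient_stroke"]]), 600)
  expect_equal(unname(m[["inpatient_other"]]), 300)
})
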