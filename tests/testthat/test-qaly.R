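vs <- pkg_value_set()

test_that("profile scoring matches the additive value-set form", {
  expect_equal(profile_to_utility("11111", vs), 1.0)
  # one level-2 dimension: 1 minus that dimension's level-2 decrement
  tab <- utils::read.csv(system.file("extdata", "valueset_synthetic.csv",
                                     package = "strokecea"))
  mo2 <- tab$decrement[tab$dimension == "MO" & tab$level == 2]
  expect_equal(profile_to_utility("21111", vs), 1 - mo2)
  # worst state hits the table floor
  worst <- 1 - sum(tapply(tab$decrement, tab$dimension, max))
  expect_equal(profile_to_utility("55555", vs), worst)
  expect_equal(vs$floor, worst)
  expect_error(profile_to_utility("11116", vs), "1..5")
})

test_that("profile scoring agrees with a brute-force lookup on all 3125 profiles", {
  tab <- utils::read.csv(system.file("extdata", "valueset_synthetic.csv",
                                     package = "strokecea"))
  grid <- expand.grid(MO = 1:5, SC = 1:5, UA = 1:5, PD = 1:5, AD = 1:5)
  profiles <- apply(grid, 1, paste0, collapse = "")
  # independent oracle: per-dimension merge against the raw CSV
  oracle <- 1 - rowSums(sapply(c("MO", "SC", "UA", "PD", "AD"), function(d) {
    sub <- tab[tab$dimension == d, ]
    sub$decrement[match(grid[[d]], sub$level)]
  }))
  expect_equal(profile_to_utility(profiles, vs), unname(oracle),
               tolerance = 1e-12)
})

test_that("trajectories follow the death and imputation rules", {
  flat <- build_trajectory(c(0, 1), c(0.8, 0.8), horizon = 1)
  expect_equal(qaly_auc(flat, c(0, 1)), 0.8)

  died <- build_trajectory(0, 0.8, death_time = 0.5, horizon = 1)
  expect_equal(died$points[, "utility"], c(0.8, 0, 0),
               ignore_attr = TRUE)
  expect_equal(qaly_auc(died, c(0, 1)), 0.5 * 0.5 * 0.8)

  # interior missing wave: linear between flanking observations
  imput <- build_trajectory(c(0, 2), c(0.9, 0.5), horizon = 2)
  expect_equal(qaly_auc(imput, c(0.999, 1.001)) / 0.002, 0.7,
               tolerance = 1e-6)

  expect_error(build_trajectory(c(0.5, 1), c(0.8, 0.8)), "baseline")
  expect_error(build_trajectory(0, 0.8, death_time = -0.1, horizon = 1),
               "death")
  expect_error(build_trajectory(c(0, 1), c(0.8, 1.2)), "utilities")
})

test_that("last-value-carried-forward death handling is available", {
  tr <- build_trajectory(0, 0.8, death_time = 0.5, horizon = 1,
                         death_method = "lvcf")
  # plateau at 0.8 until death, then 0: area = 0.5 * 0.8
  expect_equal(qaly_auc(tr, c(0, 1)), 0.4, tolerance = 1e-6)
})

test_that("QALY AUC closed forms and window properties hold", {
  tri <- build_trajectory(c(0, 1), c(1, 0), horizon = 1)
  expect_equal(qaly_auc(tri, c(0, 1)), 0.5)
  expect_error(qaly_auc(tri, c(0.5, 0.5)), "window")

  set.seed(7)
  for (i in 1:20) {
    times <- c(0, sort(stats::runif(3, 0.1, 4.9)), 5)
    u <- stats::runif(5, 0, 1)
    tr <- build_trajectory(times, u, horizon = 5)
    a <- stats::runif(1, 0, 2); b <- stats::runif(1, 2, 4)
    c_ <- stats::runif(1, 4, 5)
    expect_equal(qaly_auc(tr, c(a, c_)),
                 qaly_auc(tr, c(a, b)) + qaly_auc(tr, c(b, c_)),
                 tolerance = 1e-9)
    expect_gte(qaly_auc(tr, c(a, c_)), 0)
    expect_lte(qaly_auc(tr, c(a, c_)), (c_ - a) * 1)
  }
  # annual split sums back to the window total
  tr <- build_trajectory(c(0, 1.5, 3.7), c(0.9, 0.6, 0.8), horizon = 3.7)
  expect_equal(sum(annual_qalys(tr, c(0.3, 3.6))),
               qaly_auc(tr, c(0.3, 3.6)), tolerance = 1e-9)
})

test_that("discounting follows the closed form and is linear", {
  expect_equal(discount_stream(100, 0.05), 100 / 1.05)
  expect_equal(discount_stream(numeric(0), 0.05), 0)
  expect_equal(discount_stream(c(10, 20, 30), 0), 60)
  expect_error(discount_stream(10, -0.01), "negative")

  v <- c(50, 60, 70); w <- c(5, 0, 15)
  expect_equal(discount_stream(v + w, 0.05),
               discount_stream(v, 0.05) + discount_stream(w, 0.05))
  expect_lt(discount_stream(v, 0.05), sum(v))
  # anchor-year offsets: a year-0 element is undiscounted
  expect_equal(discount_stream(100, 0.08, years = 0), 100)
})
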