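#' EQ-5D-5L value set
#'
#' Additive-decrement value set converting 5-digit EQ-5D-5L profiles to a
#' utility index: `utility = anchor - sum(decrement[dimension, level])`.
#' Full health (11111) must map to the anchor of 1.0 and all decrements
#' must be nonnegative. Country value-set coefficients are an external
#' input supplied by the user; a synthetic example ships in
#' `inst/extdata/valueset_synthetic.csv`.
#'
#' @param decrements Data.frame with columns `dimension` (MO, SC, UA, PD,
#'   AD), `level` (1-5) and `decrement` (>= 0; level 1 must be 0).
#' @param anchor Utility of full health (1.0 by convention).
#' @return An object of class `value_set`.
#' @export
value_set <- function(decrements, anchor = 1.0) {
  stopifnot_msg(all(c("dimension", "level", "decrement") %in%
                      names(decrements)),
                "value set needs columns dimension, level, decrement")
  dims <- c("MO", "SC", "UA", "PD", "AD")
  stopifnot_msg(setequal(unique(decrements$dimension), dims),
                "value set must cover dimensions MO, SC, UA, PD, AD")
  stopifnot_msg(all(decrements$level %in% 1:5), "levels must be in 1..5")
  key <- paste(decrements$dimension, decrements$level)
  stopifnot_msg(!anyDuplicated(key), "duplicate dimension-level coefficient")
  stopifnot_msg(all(table(decrements$dimension) == 5),
                "each dimension needs all 5 levels")
  stopifnot_msg(all(decrements$decrement >= 0), "decrements must be >= 0")
  lvl1 <- decrements$decrement[decrements$level == 1]
  stopifnot_msg(all(lvl1 == 0),
                "level-1 decrements must be 0 so 11111 maps to the anchor")
  # lookup matrix [dimension, level]
  m <- matrix(0, nrow = 5, ncol = 5, dimnames = list(dims, 1:5))
  m[cbind(match(decrements$dimension, dims), decrements$level)] <-
    decrements$decrement
  structure(list(decrements = m, anchor = anchor,
                 floor = anchor - sum(apply(m, 1, max))),
            class = "value_set")
}

#' @rdname value_set
#' @param path CSV with columns `dimension`, `level`, `decrement`.
#' @export
read_value_set <- function(path, anchor = 1.0) {
  stopifnot_msg(file.exists(path), sprintf("file not found: %s", path))
  value_set(utils::read.csv(path, stringsAsFactors = FALSE), anchor)
}

#' Convert EQ-5D-5L profiles to utility indexes
#'
#' @param profile Character or integer vector of 5-digit profiles (e.g.
#'   `"21132"` or `21132`), digits in 1..5 ordered MO, SC, UA, PD, AD.
#' @param vs A [value_set()].
#' @return Numeric utility index per profile.
#' @examples
#' vs <- value_set(data.frame(
#'   dimension = rep(c("MO", "SC", "UA", "PD", "AD"), each = 5),
#'   level = rep(1:5, 5),
#'   decrement = rep(c(0, .05, .10, .20, .30), 5)))
#' profile_to_utility("11111", vs)  # 1.0
#' @export
profile_to_utility <- function(profile, vs) {
  stopifnot_msg(inherits(vs, "value_set"), "vs must be a value_set")
  p <- as.character(profile)
  stopifnot_msg(all(grepl("^[1-5]{5}$", p)),
                "profiles must be 5 digits, each in 1..5")
  digits <- matrix(as.integer(unlist(strsplit(p, ""))),
                   ncol = 5, byrow = TRUE)
  dec <- vapply(seq_len(nrow(digits)), function(i) {
    sum(vs$decrements[cbind(1:5, digits[i, ])])
  }, numeric(1))
  vs$anchor - dec
}

#' Build a piecewise-linear utility trajectory
#'
#' Observed waves are interpolated linearly (missing interior waves are
#' thereby filled by linear imputation). If the participant dies, the
#' trajectory runs linearly from the last observed utility down to 0 at the
#' death time and stays 0 up to the horizon (the value is 0 from the date
#' of death onward); with `death_method = "lvcf"` the last observed value
#' is carried forward to the death time, then drops to 0.
#'
#' @param times Observation times in years since baseline; must include
#'   baseline `t = 0` and be strictly increasing.
#' @param utilities Utility index at each time (<= 1).
#' @param death_time Years since baseline, or `NA` if alive.
#' @param horizon Trajectory end, years since baseline.
#' @param death_method `"linear"` (default) or `"lvcf"`.
#' @return An object of class `utility_trajectory` with a `points` matrix
#'   (`time`, `utility`), `death_time` and `horizon`.
#' @export
build_trajectory <- function(times, utilities, death_time = NA,
                             horizon = max(times),
                             death_method = c("linear", "lvcf")) {
  death_method <- match.arg(death_method)
  stopifnot_msg(length(times) == length(utilities),
                "times and utilities differ in length")
  keep <- !is.na(utilities)
  times <- times[keep]; utilities <- utilities[keep]
  stopifnot_msg(length(times) >= 1 && min(times) == 0,
                "a baseline (t = 0) utility measurement is required")
  stopifnot_msg(all(diff(times) > 0), "times must be strictly increasing")
  stopifnot_msg(all(utilities <= 1), "utilities must be <= 1")
  if (!is.na(death_time)) {
    stopifnot_msg(death_time > 0, "death before baseline")
    stopifnot_msg(all(times <= death_time),
                  "observed utilities after death time")
  }
  pts <- cbind(time = times, utility = utilities)
  if (!is.na(death_time) && death_time <= horizon) {
    last <- pts[nrow(pts), ]
    if (death_method == "lvcf" && death_time > last["time"]) {
      pts <- rbind(pts, c(death_time - 1e-9, last["utility"]))
    }
    if (death_time > pts[nrow(pts), "time"]) {
      pts <- rbind(pts, c(death_time, 0))
    } else {
      pts[nrow(pts), "utility"] <- 0
    }
    if (horizon > death_time) pts <- rbind(pts, c(horizon, 0))
  } else if (horizon > pts[nrow(pts), "time"]) {
    # survivors are not extrapolated past the last wave; trajectory ends
    # at the last observation and integration windows must respect it
    horizon <- pts[nrow(pts), "time"]
  }
  structure(list(points = pts, death_time = death_time, horizon = horizon),
            class = "utility_trajectory")
}

# linear interpolation of the trajectory at arbitrary times
trajectory_at <- function(traj, t) {
  stats::approx(traj$points[, "time"], traj$points[, "utility"],
                xout = t, rule = 2)$y
}

#' QALYs by the area-under-the-curve method
#'
#' Trapezoidal area of the piecewise-linear utility trajectory over a
#' window.
#'
#' @param traj A [build_trajectory()] result.
#' @param window `c(t0, t1)` in years; must lie within `[0, horizon]`.
#' @return QALYs accrued over the window.
#' @examples
#' tr <- build_trajectory(c(0, 1), c(0.8, 0.8), horizon = 1)
#' qaly_auc(tr, c(0, 1))  # 0.8
#' @export
qaly_auc <- function(traj, window = c(0, traj$horizon)) {
  stopifnot_msg(length(window) == 2 && window[2] > window[1],
                "window must be c(t0, t1) with t1 > t0")
  stopifnot_msg(window[1] >= 0 && window[2] <= traj$horizon + 1e-9,
                "window must lie within [0, horizon]")
  knots <- traj$points[, "time"]
  grid <- sort(unique(c(window, knots[knots > window[1] & knots < window[2]])))
  u <- trajectory_at(traj, grid)
  sum(diff(grid) * (utils::head(u, -1) + utils::tail(u, -1)) / 2)
}

#' @rdname qaly_auc
#' @description `annual_qalys` splits the window into calendar years from
#'   baseline, pro-rating fractional first/last years by the trapezoid.
#' @export
annual_qalys <- function(traj, window = c(0, traj$horizon)) {
  edges <- sort(unique(c(window,
                         seq(ceiling(window[1]), floor(window[2]), by = 1))))
  edges <- edges[edges >= window[1] & edges <= window[2]]
  vapply(seq_len(length(edges) - 1), function(i) {
    qaly_auc(traj, c(edges[i], edges[i + 1]))
  }, numeric(1))
}

#' Present value of an annual stream
#'
#' Discounts a per-year stream at a constant annual rate:
#' `sum(v_t / (1 + rate)^t)` with `t` whole years since the discounting
#' anchor. Within-trial quantities are left undiscounted by the pipeline;
#' discounting applies to the post-trial period only.
#'
#' @param values Numeric stream (money or QALYs per year).
#' @param rate Annual discount rate (>= 0).
#' @param years Whole years since the anchor for each element; defaults to
#'   `seq_along(values)` (first element one year out).
#' @return Present value at the anchor.
#' @examples
#' discount_stream(100, 0.05)  # 95.238...
#' @export
discount_stream <- function(values, rate, years = seq_along(values)) {
  stopifnot_msg(rate >= 0, "negative discount rate")
  stopifnot_msg(length(values) == length(years),
                "values and years differ in length")
  if (length(values) == 0) return(0)
  sum(values / (1 + rate)^years)
}
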