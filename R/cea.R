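#' Incremental cost-effectiveness ratio
#'
#' Ratio of incremental cost to incremental effect, with the effect
#' oriented so benefit is positive (e.g. SBP reduction entered as positive
#' mmHg reduced). The cost-effectiveness-plane quadrant is classified:
#' `NE` (costlier, more effective: the ratio is the price of the gain),
#' `SE` (cheaper, more effective: dominant), `NW` (costlier, less
#' effective: dominated), `SW` (cheaper, less effective). The ratio is
#' flagged non-interpretable when the incremental effect is not positive;
#' a zero effect yields an undefined ratio, not an exception.
#'
#' @param d_cost Incremental cost (USD, intervention - control).
#' @param d_effect Incremental effect (benefit-positive units).
#' @return List: `value` (USD per effect unit, `NA` when `d_effect` = 0),
#'   `quadrant`, `dominant`, `dominated`, `interpretable`.
#' @examples
#' icer(23.3, 2.8)  # 8.32 USD per mmHg reduced, NE
#' @export
icer <- function(d_cost, d_effect) {
  quadrant <- if (d_effect > 0 && d_cost > 0) "NE"
  else if (d_effect > 0) "SE"
  else if (d_cost > 0) "NW"
  else "SW"
  value <- if (d_effect == 0) NA_real_ else d_cost / d_effect
  list(value = value,
       quadrant = quadrant,
       dominant = quadrant == "SE",
       dominated = quadrant == "NW",
       interpretable = d_effect > 0)
}

# --- stratified cluster bootstrap ------------------------------------------

# fast arm-coefficient estimate: fixed-effects adjusted model via .lm.fit
fast_arm_coef <- function(X, y) {
  ok <- !is.na(y)
  fit <- stats::.lm.fit(X[ok, , drop = FALSE], y[ok])
  fit$coefficients[2]  # arm column is second by construction
}

build_design <- function(frame, baseline) {
  tw <- factor(frame$township)
  Xt <- if (nlevels(tw) > 1) {
    stats::model.matrix(~tw)[, -1, drop = FALSE]
  } else NULL
  sexnum <- as.integer(factor(frame$sex))
  X <- cbind(1, as.integer(frame$arm == "intervention"), Xt,
             if (!is.null(baseline)) frame[[baseline]], frame$age, sexnum)
  X
}

#' Stratified cluster bootstrap of incremental cost and effect
#'
#' Resamples villages with replacement within township-by-arm strata
#' (respecting both the cluster randomization unit and the stratified
#' design) and re-estimates the adjusted arm differences in cost and
#' effect on each replication. The per-replication estimator is the
#' fixed-effects version of the adjusted model (arm + township + baseline
#' + age + sex); the cluster resampling itself carries the within-village
#' correlation. `method = "reml"` refits the full mixed model on every
#' replication instead. An individual-level (unclustered) resampling
#' option is provided for comparison.
#'
#' @param frame Analysis frame from [build_analysis_frame()].
#' @param effect_outcome Benefit-positive effect column (e.g.
#'   `"sbp_reduction"` or `"qaly"`).
#' @param baseline Baseline covariate for the effect model (e.g.
#'   `"baseline_sbp"`), or `NULL`.
#' @param cost_outcome Cost column (default `"total_cost"`).
#' @param B Number of replications (>= 1).
#' @param seed Integer RNG seed.
#' @param method Per-replication estimator: `"ols"` (default) or `"reml"`.
#' @param resample `"cluster"` (default) or `"individual"`.
#' @return A `ce_draws` object: data.frame `draws` (`replicate`, `d_cost`,
#'   `d_effect`), `point` estimates from the full sample (REML adjusted
#'   model), `seed`, `B`.
#' @export
cluster_bootstrap <- function(frame, effect_outcome, baseline = NULL,
                              cost_outcome = "total_cost", B = 5000,
                              seed = 1L, method = c("ols", "reml"),
                              resample = c("cluster", "individual")) {
  method <- match.arg(method)
  resample <- match.arg(resample)
  stopifnot_msg(B >= 1, "B must be >= 1")
  check_design(frame, effect_outcome)
  point_cost <- adjusted_difference(frame, cost_outcome, baseline = NULL)
  point_eff <- adjusted_difference(frame, effect_outcome,
                                   baseline = baseline)
  set.seed(seed)
  cea_log("cluster_bootstrap",
          sprintf("B=%d seed=%d method=%s resample=%s",
                  B, seed, method, resample))
  frame$.stratum <- paste(frame$township, frame$arm)
  idx_by_village <- split(seq_len(nrow(frame)), frame$village)
  villages_by_stratum <- lapply(
    split(frame$village, frame$.stratum), unique)
  d_cost <- d_eff <- numeric(B)
  for (b in seq_len(B)) {
    if (resample == "cluster") {
      vils <- unlist(lapply(villages_by_stratum, function(v) {
        v[sample.int(length(v), length(v), replace = TRUE)]
      }), use.names = FALSE)
      rows <- unlist(idx_by_village[as.character(vils)], use.names = FALSE)
      newvil <- rep(seq_along(vils),
                    lengths(idx_by_village[as.character(vils)]))
    } else {
      rows <- sample.int(nrow(frame), nrow(frame), replace = TRUE)
      newvil <- frame$village[rows]
    }
    fb <- frame[rows, ]
    fb$village <- newvil
    if (method == "ols") {
      d_cost[b] <- fast_arm_coef(build_design(fb, NULL),
                                 fb[[cost_outcome]])
      d_eff[b] <- fast_arm_coef(build_design(fb, baseline),
                                fb[[effect_outcome]])
    } else {
      d_cost[b] <- tryCatch(
        adjusted_difference(fb, cost_outcome, baseline = NULL)$delta,
        error = function(e) {
          cea_log("cluster_bootstrap", "replication fell back to OLS")
          fast_arm_coef(build_design(fb, NULL), fb[[cost_outcome]])
        })
      d_eff[b] <- tryCatch(
        adjusted_difference(fb, effect_outcome, baseline = baseline)$delta,
        error = function(e) {
          fast_arm_coef(build_design(fb, baseline), fb[[effect_outcome]])
        })
    }
  }
  structure(
    list(draws = data.frame(replicate = seq_len(B), d_cost = d_cost,
                            d_effect = d_eff),
         point = c(d_cost = point_cost$delta, d_effect = point_eff$delta),
         seed = seed, B = B,
         effect_outcome = effect_outcome),
    class = "ce_draws")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability the intervention is cost-effective as a function of the
#' willingness-to-pay threshold: the fraction of bootstrap draws with
#' nonnegative net monetary benefit `lambda * d_effect - d_cost`.
#'
#' @param draws A `ce_draws` object (or a data.frame with `d_cost`,
#'   `d_effect`).
#' @param grid Ascending, nonnegative WTP values.
#' @return Data.frame `lambda`, `p_ce`.
#' @export
ceac <- function(draws, grid) {
  d <- if (inherits(draws, "ce_draws")) draws$draws else draws
  stopifnot_msg(nrow(d) > 0, "no bootstrap draws")
  stopifnot_msg(all(grid >= 0), "negative willingness-to-pay in grid")
  stopifnot_msg(all(diff(grid) > 0), "wtp grid must be strictly increasing")
  p <- vapply(grid, function(l) {
    mean(l * d$d_effect - d$d_cost >= 0)
  }, numeric(1))
  data.frame(lambda = grid, p_ce = p)
}

#' Summarize bootstrap draws
#'
#' Quadrant proportions on the cost-effectiveness plane, percentile 95%
#' intervals for the incremental cost and effect, and a percentile 95%
#' interval for the ICER over the interpretable (positive-effect) draws,
#' reported with the interpretable fraction.
#'
#' @param draws A `ce_draws` object.
#' @return List: `quadrants` (named proportions, sum 1), `ci_d_cost`,
#'   `ci_d_effect`, `ci_icer`, `interpretable_fraction`.
#' @export
ce_summary <- function(draws) {
  d <- if (inherits(draws, "ce_draws")) draws$draws else draws
  stopifnot_msg(nrow(d) > 0, "no bootstrap draws")
  q <- ifelse(d$d_effect > 0,
              ifelse(d$d_cost > 0, "NE", "SE"),
              ifelse(d$d_cost > 0, "NW", "SW"))
  quadrants <- c(NE = mean(q == "NE"), SE = mean(q == "SE"),
                 NW = mean(q == "NW"), SW = mean(q == "SW"))
  interp <- d$d_effect > 0
  ratio <- d$d_cost[interp] / d$d_effect[interp]
  list(
    quadrants = quadrants,
    ci_d_cost = stats::quantile(d$d_cost, c(0.025, 0.975), names = FALSE),
    ci_d_effect = stats::quantile(d$d_effect, c(0.025, 0.975),
                                  names = FALSE),
    ci_icer = if (length(ratio) > 0) {
      stats::quantile(ratio, c(0.025, 0.975), names = FALSE)
    } else c(NA_real_, NA_real_),
    interpretable_fraction = mean(interp)
  )
}

#' Full cost-effectiveness analysis for one effect outcome
#'
#' Point adjusted differences (REML mixed model), stratified cluster
#' bootstrap, point ICER, CEAC on the configured WTP grid, and draw
#' summaries, bundled as a `ce_result` that [write_results()] serializes.
#'
#' @inheritParams cluster_bootstrap
#' @param cfg A [run_config()] (bootstrap size, WTP grid and seed defaults
#'   are taken from it).
#' @param B,seed Override `cfg$n_bootstrap` / `cfg$rng_seed`.
#' @return A `ce_result` list: `point`, `icer`, `draws`, `ceac`,
#'   `summary`, `seed`, `B`, `effect_outcome`.
#' @export
run_cea <- function(frame, effect_outcome, baseline = NULL, cfg,
                    cost_outcome = "total_cost",
                    B = cfg$n_bootstrap,
                    seed = if (!is.null(cfg$rng_seed)) cfg$rng_seed else 1L,
                    method = c("ols", "reml")) {
  bs <- cluster_bootstrap(frame, effect_outcome, baseline = baseline,
                          cost_outcome = cost_outcome, B = B, seed = seed,
                          method = match.arg(method))
  ic <- icer(bs$point[["d_cost"]], bs$point[["d_effect"]])
  structure(
    list(point = as.list(bs$point), icer = ic,
         draws = bs$draws, ceac = ceac(bs, cfg$wtp_grid),
         summary = ce_summary(bs), seed = seed, B = bs$B,
         effect_outcome = effect_outcome),
    class = "ce_result")
}

#' @exportS3Method base::print
print.ce_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness result (%s)\n", x$effect_outcome))
  cat(sprintf("  incremental cost:   %.2f USD\n", x$point$d_cost))
  cat(sprintf("  incremental effect: %.4f\n", x$point$d_effect))
  cat(sprintf("  ICER: %s USD per unit (%s)\n",
              ifelse(is.na(x$icer$value), "undefined",
                     sprintf("%.2f", x$icer$value)), x$icer$quadrant))
  cat(sprintf("  bootstrap: B = %d, seed = %d\n", x$B, x$seed))
  cat(sprintf("  ICER 95%% CI (percentile, interpretable draws): %.2f to %.2f\n",
              x$summary$ci_icer[1], x$summary$ci_icer[2]))
  invisible(x)
}

#' One-way deterministic sensitivity analysis
#'
#' Varies one parameter at a time between its low and high value, holding
#' all others at base, and recomputes the ICER through a user-supplied
#' deterministic evaluator. Rows come back in tornado order (largest ICER
#' swing first).
#'
#' @param base Named list of base-case parameter values.
#' @param ranges Named list of `c(low, high)` per parameter to vary
#'   (low < high); parameters absent from `base` are an error.
#' @param evaluator `function(params) -> ICER value`; must be
#'   deterministic in its parameters.
#' @return Data.frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `swing`; sorted by decreasing `swing`.
#' @export
one_way_dsa <- function(base, ranges, evaluator) {
  if (length(ranges) == 0) {
    return(data.frame(parameter = character(0), low = numeric(0),
                      high = numeric(0), icer_low = numeric(0),
                      icer_high = numeric(0), swing = numeric(0)))
  }
  stopifnot_msg(all(names(ranges) %in% names(base)),
                sprintf("range(s) for unknown parameter(s): %s",
                        paste(setdiff(names(ranges), names(base)),
                              collapse = ", ")))
  rows <- lapply(names(ranges), function(p) {
    rg <- ranges[[p]]
    stopifnot_msg(length(rg) == 2 && rg[1] < rg[2],
                  sprintf("range for %s must be c(low, high), low < high", p))
    vals <- vapply(rg, function(v) {
      pars <- base
      pars[[p]] <- v
      tryCatch(evaluator(pars), error = function(e) {
        stop(sprintf("evaluator failed for parameter '%s': %s",
                     p, conditionMessage(e)), call. = FALSE)
      })
    }, numeric(1))
    data.frame(parameter = p, low = rg[1], high = rg[2],
               icer_low = vals[1], icer_high = vals[2],
               swing = abs(vals[2] - vals[1]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), , drop = FALSE]
}
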