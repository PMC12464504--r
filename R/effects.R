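#' Per-participant analysis frame
#'
#' Collapses a long-format trial table into one row per participant with
#' the quantities the economic evaluation needs:
#'
#' * `sbp_change`, `sbp_reduction` (= -change, so benefit is positive),
#'   `utility_change` between baseline and the 1-year wave;
#' * `qaly`: area-under-the-curve QALYs (within-trial window `[0, 1]`,
#'   or the discounted post-trial window when `period = "post"`);
#' * `total_cost`: itemized costs plus the flat outpatient cost (within),
#'   or post-trial costs built from self-reported episode counts valued at
#'   within-trial per-episode means, post-trial medication items, and the
#'   flat post-trial outpatient cost, discounted annually (post).
#'
#' Death handling follows the trajectory rules (utility 0 from death
#' onward); participants alive but missing the closing wave keep `NA`
#' outcomes and are excluded from that outcome's model (complete-case
#' intention to treat).
#'
#' @param trial A [trial_table()] with cost items.
#' @param cfg A [run_config()].
#' @param period `"within"` or `"post"`.
#' @return A data.frame, one row per participant.
#' @export
build_analysis_frame <- function(trial, cfg, period = c("within", "post")) {
  period <- match.arg(period)
  validate_trial_table(trial)
  oc <- trial$outcomes
  ids <- unique(oc$pid)
  first <- oc[match(ids, oc$pid), ]
  fr <- data.frame(pid = ids, village = first$village,
                   township = first$township, arm = first$arm,
                   age = first$age, sex = first$sex,
                   death_time = first$death_time,
                   stringsAsFactors = FALSE)
  get_wave <- function(col, t) {
    sel <- oc$time_years == t
    oc[[col]][sel][match(ids, oc$pid[sel])]
  }
  fr$baseline_sbp <- get_wave("sbp", 0)
  fr$baseline_utility <- get_wave("utility", 0)
  fr$sbp_change <- get_wave("sbp", 1) - fr$baseline_sbp
  fr$sbp_reduction <- -fr$sbp_change
  fr$utility_change <- get_wave("utility", 1) - fr$baseline_utility

  ci <- trial$cost_items
  if (period == "within") {
    # survivors with both waves have the closed-form trapezoid; deaths and
    # irregular observation patterns go through the trajectory machinery
    u0 <- fr$baseline_utility
    u1 <- u0 + fr$utility_change
    fr$qaly <- (u0 + u1) / 2
    irregular <- which(!is.na(fr$death_time) & fr$death_time <= 1 |
                         (is.na(fr$qaly) & !is.na(u0)))
    if (length(irregular) > 0) {
      oc_split <- split(oc[, c("time_years", "utility")],
                        oc$pid)[fr$pid[irregular]]
      fr$qaly[irregular] <- vapply(seq_along(irregular), function(k) {
        within_qaly(oc_split[[k]], fr$death_time[irregular[k]])
      }, numeric(1))
    }
    wt <- ci[ci$period == "within", , drop = FALSE]
    itemized <- tapply(wt$amount, wt$pid, sum)
    fr$total_cost <- cfg$outpatient_flat +
      ifelse(is.na(itemized[fr$pid]), 0, itemized[fr$pid])
  } else {
    waves <- sort(unique(oc$time_years))
    stopifnot_msg(any(waves > 1),
                  "post-trial analysis needs waves after t = 1")
    horizon <- max(waves)
    oc_split <- split(oc[, c("time_years", "utility")], oc$pid)[fr$pid]
    fr$qaly <- vapply(seq_len(nrow(fr)), function(i) {
      post_qaly(oc_split[[i]], fr$death_time[i], horizon,
                cfg$discount_rate_annual)
    }, numeric(1))
    fr$total_cost <- posttrial_costs(trial, fr, cfg, horizon)
  }
  fr
}

# within-trial QALY over [0,1] for one participant; NA when alive but
# missing the 1-year wave (complete case)
within_qaly <- function(rows, death_time) {
  rows <- rows[rows$time_years <= 1, ]
  obs <- !is.na(rows$utility)
  if (!any(obs & rows$time_years == 0)) return(NA_real_)
  dead_in_year <- !is.na(death_time) && death_time <= 1
  if (!dead_in_year && !any(obs & rows$time_years == 1)) return(NA_real_)
  traj <- build_trajectory(rows$time_years[obs], rows$utility[obs],
                           death_time = death_time, horizon = 1)
  qaly_auc(traj, c(0, 1))
}

# discounted post-trial QALY over (1, horizon]; annual areas discounted
# with the end of the within-trial year as anchor
post_qaly <- function(rows, death_time, horizon, rate) {
  obs <- !is.na(rows$utility)
  if (!any(obs & rows$time_years == 0)) return(NA_real_)
  died <- !is.na(death_time)
  if (died && death_time <= 1) return(0)
  if (!died && !any(obs & rows$time_years > 1)) return(NA_real_)
  traj <- build_trajectory(rows$time_years[obs], rows$utility[obs],
                           death_time = death_time, horizon = horizon)
  end <- min(horizon, traj$horizon)
  if (died) end <- horizon
  if (end <= 1) return(0)
  ann <- annual_qalys(traj, c(1, end))
  discount_stream(ann, rate, years = seq_along(ann) - 1)
}

posttrial_costs <- function(trial, fr, cfg, horizon) {
  means <- inpatient_cause_means(trial$cost_items)
  pv <- trial$posttrial_visits
  inpat <- numeric(nrow(fr))
  if (!is.null(pv) && nrow(pv) > 0) {
    per_pid <- vapply(split(pv, pv$pid), estimate_posttrial_inpatient,
                      numeric(1), mean_cost_per_cause = means)
    hit <- match(names(per_pid), fr$pid)
    inpat[hit] <- per_pid
  }
  post <- trial$cost_items[trial$cost_items$period == "post", , drop = FALSE]
  meds <- tapply(post$amount, post$pid, sum)
  meds <- ifelse(is.na(meds[fr$pid]), 0, meds[fr$pid])
  span <- horizon - 1
  alive_frac <- ifelse(is.na(fr$death_time), 1,
                       pmax(0, (fr$death_time - 1) / span))
  outp <- cfg$outpatient_flat_posttrial * alive_frac
  # spread each participant's post-trial total evenly over the post-trial
  # years and discount annually (anchor: end of the within-trial year)
  total_nominal <- inpat + unname(meds) + outp
  years <- seq_len(ceiling(span))
  w <- pmin(1, pmax(0, span - (years - 1))) / span
  disc <- sum(w / (1 + cfg$discount_rate_annual)^(years - 1))
  total_nominal * disc
}

check_design <- function(frame, outcome) {
  ok <- !is.na(frame[[outcome]])
  d <- frame[ok, ]
  stopifnot_msg(nrow(d) > 0, sprintf("no observations for %s", outcome))
  stopifnot_msg(length(unique(d$arm)) == 2,
                "both arms are required to estimate an arm difference")
  vt <- unique(d[, c("village", "arm", "township")])
  per_arm <- table(vt$arm)
  stopifnot_msg(all(per_arm >= 2),
                sprintf("need >= 2 villages per arm for %s", outcome))
  tab <- table(vt$township, vt$arm)
  bad <- rownames(tab)[apply(tab, 1, function(x) any(x == 0))]
  stopifnot_msg(length(bad) == 0,
                sprintf("township stratum(s) with a single arm: %s",
                        paste(bad, collapse = ", ")))
  d
}

make_estimate <- function(outcome, delta, se, n_by_arm, method) {
  structure(
    list(outcome = outcome, delta = delta, se = se,
         ci95 = c(delta - stats::qnorm(0.975) * se,
                  delta + stats::qnorm(0.975) * se),
         n_by_arm = n_by_arm, method = method),
    class = "effect_estimate")
}

#' Covariate-adjusted between-arm difference
#'
#' Fits the trial's primary analysis model to a per-participant outcome: a
#' linear mixed model with an arm indicator, township fixed effects (the
#' stratification factor), the baseline value of the outcome, age and sex
#' as fixed effects, and a village random intercept, estimated by
#' restricted maximum likelihood. Intention to treat, complete case:
#' participants missing the outcome are dropped. When the random-intercept
#' variance is estimated on the boundary (singular fit) the function falls
#' back to the same fixed-effects model with a cluster-robust (village)
#' covariance and logs the event.
#'
#' @param frame An analysis frame from [build_analysis_frame()].
#' @param outcome Column to analyze (e.g. `"sbp_reduction"`, `"qaly"`,
#'   `"total_cost"`).
#' @param baseline Baseline covariate column, or `NULL` (costs have no
#'   baseline analogue).
#' @param covariates Additional fixed-effect columns.
#' @param method `"reml"` (default) or `"ols"` (fixed-effects model with
#'   cluster-robust standard errors throughout).
#' @return An `effect_estimate`: `outcome`, `delta`
#'   (intervention - control), `se`, `ci95`, `n_by_arm`, `method`.
#' @export
adjusted_difference <- function(frame, outcome, baseline = NULL,
                                covariates = c("age", "sex"),
                                method = c("reml", "ols")) {
  method <- match.arg(method)
  d <- check_design(frame, outcome)
  if (!is.null(baseline)) d <- d[!is.na(d[[baseline]]), ]
  d$.arm <- as.integer(d$arm == "intervention")
  d$.township <- factor(d$township)
  rhs <- c(".arm", if (nlevels(d$.township) > 1) ".township",
           baseline, covariates)
  n_by_arm <- c(intervention = sum(d$.arm == 1), control = sum(d$.arm == 0))
  if (method == "reml") {
    fml <- stats::reformulate(c(rhs, "(1 | village)"), response = outcome)
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      cea_log("adjusted_difference",
              sprintf("singular fit for %s; cluster-robust OLS fallback",
                      outcome))
      return(ols_difference(d, outcome, rhs, n_by_arm))
    }
    co <- summary(fit)$coefficients
    return(make_estimate(outcome, co[".arm", "Estimate"],
                         co[".arm", "Std. Error"], n_by_arm, "reml"))
  }
  ols_difference(d, outcome, rhs, n_by_arm)
}

# fixed-effects fit with cluster-robust (CR1, village) standard errors
ols_difference <- function(d, outcome, rhs, n_by_arm) {
  fml <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(fml, data = d)
  # degenerate (zero-residual) data make summary.lm warn inside vcovCL;
  # the cluster-robust variance is still exact there
  vc <- suppressWarnings(sandwich::vcovCL(fit, cluster = d$village))
  make_estimate(outcome, stats::coef(fit)[[".arm"]],
                sqrt(vc[".arm", ".arm"]), n_by_arm, "ols_cluster_robust")
}

#' Unadjusted between-arm difference
#'
#' Raw mean difference with a cluster-robust standard error (villages as
#' the independent units); audit baseline for the adjusted model.
#'
#' @inheritParams adjusted_difference
#' @return An `effect_estimate`.
#' @export
unadjusted_difference <- function(frame, outcome) {
  d <- check_design(frame, outcome)
  vt <- unique(d[, c("village", "arm")])
  stopifnot_msg(all(table(vt$arm) >= 2),
                "need >= 2 villages per arm for a cluster-robust SE")
  d$.arm <- as.integer(d$arm == "intervention")
  fit <- stats::lm(stats::reformulate(".arm", response = outcome), data = d)
  vc <- suppressWarnings(sandwich::vcovCL(fit, cluster = d$village))
  make_estimate(outcome, stats::coef(fit)[[".arm"]],
                sqrt(vc[".arm", ".arm"]),
                c(intervention = sum(d$.arm == 1),
                  control = sum(d$.arm == 0)),
                "unadjusted_cluster_robust")
}

#' Tabulate effect estimates
#'
#' @param ... `effect_estimate` objects.
#' @return Data.frame with one row per estimate (outcome, delta, se,
#'   ci_low, ci_high, n_int, n_ctl, method).
#' @export
effects_table <- function(...) {
  ests <- list(...)
  do.call(rbind, lapply(ests, function(e) {
    data.frame(outcome = e$outcome, delta = e$delta, se = e$se,
               ci_low = e$ci95[1], ci_high = e$ci95[2],
               n_int = e$n_by_arm[["intervention"]],
               n_ctl = e$n_by_arm[["control"]],
               method = e$method, stringsAsFactors = FALSE)
  }))
}
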