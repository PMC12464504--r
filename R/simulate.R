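#' Synthetic cluster-randomized trial configuration
#'
#' Defaults emulate a 1-year cluster-randomized stroke secondary-prevention
#' trial in rural China: 50 villages in 5 township strata randomized 1:1
#' within township, ~1299 participants, baseline SBP ~ N(145.9, 22.4) mmHg,
#' baseline EQ-5D utility mean 0.80 (SD 0.20, capped at 1, floored at the
#' value-set minimum), a -2.8 mmHg intervention effect on 1-year SBP
#' change, a +0.06 effect on 1-year utility change, 2% first-year
#' mortality, and zero-inflated right-skewed (Bernoulli x gamma) inpatient
#' costs with higher medication uptake in the intervention arm. The
#' intervention-arm hospitalization probability is calibrated internally so
#' the expected total incremental cost equals `target_cost_increment`.
#'
#' @param n_townships Number of township strata.
#' @param villages_per_township Villages per township (even, for 1:1
#'   allocation within stratum).
#' @param n_total Total participants, allocated as evenly as possible
#'   across villages.
#' @param baseline_sbp_mean,baseline_sbp_sd Baseline SBP moments (mmHg).
#' @param baseline_utility_mean,baseline_utility_sd Baseline utility
#'   moments; draws are truncated to `[utility_floor, 1]`.
#' @param utility_floor Value-set floor (worst health state).
#' @param age_mean,age_sd,prop_female Covariate distributions.
#' @param icc_sbp,icc_utility Intraclass correlation of the 1-year change
#'   outcomes (village random intercept).
#' @param sbp_change_sd,utility_change_sd Within-village SD of the 1-year
#'   change outcomes.
#' @param sbp_change_control,utility_change_control Mean 1-year change in
#'   the control arm.
#' @param true_effect_sbp Arm difference in 1-year SBP change (mmHg,
#'   negative = larger reduction under intervention).
#' @param true_effect_utility Arm difference in 1-year utility change.
#' @param mortality_year1 First-year mortality (both arms).
#' @param dropout_year1 Probability a survivor misses the 1-year wave.
#' @param program_cost_pp Program delivery cost per intervention
#'   participant (reference-year USD).
#' @param target_cost_increment Expected intervention-minus-control
#'   difference in total within-trial cost per participant (USD).
#' @param inpatient_prob Named per-cause annual hospitalization
#'   probabilities in the control arm.
#' @param inpatient_mean Named per-cause gamma mean episode costs (USD).
#' @param inpatient_shape Gamma shape of episode costs.
#' @param med_uptake_control,med_uptake_intervention Named per-class
#'   medication uptake probabilities.
#' @param med_unit_price Named per-class unit price (USD per tablet).
#' @param med_quantity Annual tablets for a user.
#' @param med_adherence_mean Mean adherence among users (beta-distributed).
#' @param include_posttrial Also simulate the ~6-year observational
#'   follow-up (waves at `posttrial_waves`, arm-specific mortality,
#'   self-reported inpatient episode counts, post-trial medication costs).
#' @param posttrial_waves Post-trial wave times (years since baseline).
#' @param posttrial_mortality_by_arm Named cumulative mortality over the
#'   post-trial window among 1-year survivors.
#' @param utility_change_post_control Mean utility change from 1 year to
#'   the last wave (control arm).
#' @param true_effect_utility_post Arm difference in that change.
#' @param posttrial_visit_rate Named per-cause expected episode counts over
#'   the post-trial window (control arm).
#' @param posttrial_visit_factor_intervention Multiplier on those rates in
#'   the intervention arm.
#' @param reference_year Currency year costs are emitted in (the generator
#'   emits reference-year USD directly; historical-year emission is
#'   exercised through [adjust_currency()] separately).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_townships = 5,
                       villages_per_township = 10,
                       n_total = 1299,
                       baseline_sbp_mean = 145.9,
                       baseline_sbp_sd = 22.4,
                       baseline_utility_mean = 0.80,
                       baseline_utility_sd = 0.20,
                       utility_floor = -0.391,
                       age_mean = 65.6,
                       age_sd = 8.2,
                       prop_female = 0.5,
                       icc_sbp = 0.05,
                       icc_utility = 0.05,
                       sbp_change_sd = 12,
                       utility_change_sd = 0.12,
                       sbp_change_control = -4.3,
                       utility_change_control = -0.06,
                       true_effect_sbp = -2.8,
                       true_effect_utility = 0.06,
                       mortality_year1 = 0.02,
                       dropout_year1 = 0.033,
                       program_cost_pp = 50.8,
                       target_cost_increment = 23.3,
                       inpatient_prob = c(inpatient_stroke = 0.12,
                                          inpatient_cvd_nonstroke = 0.08,
                                          inpatient_other = 0.20),
                       inpatient_mean = c(inpatient_stroke = 300,
                                          inpatient_cvd_nonstroke = 250,
                                          inpatient_other = 230),
                       inpatient_shape = 0.9,
                       med_uptake_control = c(med_antiplatelet = 0.60,
                                              med_statin = 0.30,
                                              med_antihypertensive = 0.62),
                       med_uptake_intervention = c(med_antiplatelet = 0.85,
                                                   med_statin = 0.33,
                                                   med_antihypertensive = 0.755),
                       med_unit_price = c(med_antiplatelet = 0.030,
                                          med_statin = 0.011,
                                          med_antihypertensive = 0.070),
                       med_quantity = 365,
                       med_adherence_mean = 0.85,
                       include_posttrial = FALSE,
                       posttrial_waves = c(5.3, 5.9),
                       posttrial_mortality_by_arm = c(intervention = 0.173,
                                                      control = 0.204),
                       utility_change_post_control = -0.23,
                       true_effect_utility_post = -0.01,
                       posttrial_visit_rate = c(inpatient_stroke = 0.20,
                                                inpatient_cvd_nonstroke = 0.15,
                                                inpatient_other = 0.35),
                       posttrial_visit_factor_intervention = 1.40,
                       reference_year = 2023,
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot_msg(inherits(cfg, "sim_config"), "not a sim_config")
  stopifnot_msg(cfg$villages_per_township %% 2 == 0,
                "villages_per_township must be even for 1:1 allocation")
  probs <- c(cfg$mortality_year1, cfg$dropout_year1, cfg$prop_female,
             cfg$inpatient_prob, cfg$med_uptake_control,
             cfg$med_uptake_intervention, cfg$med_adherence_mean,
             cfg$posttrial_mortality_by_arm)
  stopifnot_msg(all(probs >= 0 & probs <= 1),
                "probabilities must lie in [0, 1]")
  sds <- c(cfg$baseline_sbp_sd, cfg$baseline_utility_sd, cfg$sbp_change_sd,
           cfg$utility_change_sd, cfg$age_sd)
  stopifnot_msg(all(sds > 0), "standard deviations must be > 0")
  stopifnot_msg(cfg$icc_sbp >= 0 && cfg$icc_sbp < 1 &&
                  cfg$icc_utility >= 0 && cfg$icc_utility < 1,
                "icc must lie in [0, 1)")
  stopifnot_msg(cfg$inpatient_shape > 0, "gamma shape must be > 0")
  # calibrated intervention hospitalization factor must be a probability scale
  f <- inpatient_factor(cfg)
  stopifnot_msg(f >= 0 && all(f * cfg$inpatient_prob <= 1),
                "target_cost_increment incompatible with cost model (implied hospitalization factor outside [0, 1/max prob])")
  invisible(cfg)
}

# expected medication cost difference (intervention - control) implied by
# the uptake/price/adherence parameters
med_cost_increment <- function(cfg) {
  per_user <- cfg$med_quantity * cfg$med_unit_price * cfg$med_adherence_mean
  sum((cfg$med_uptake_intervention - cfg$med_uptake_control) *
        per_user[names(cfg$med_uptake_intervention)])
}

# multiplier on control hospitalization probabilities in the intervention
# arm, solved so E[total cost difference] = target_cost_increment
inpatient_factor <- function(cfg) {
  ctl_mean <- sum(cfg$inpatient_prob * cfg$inpatient_mean)
  gap <- cfg$target_cost_increment - cfg$program_cost_pp -
    med_cost_increment(cfg)
  if (ctl_mean == 0) {
    stopifnot_msg(abs(gap) < 1e-8,
                  "target_cost_increment unattainable: no inpatient risk to calibrate against")
    return(1)
  }
  1 + gap / ctl_mean
}

# truncated-exponential death time on (lo, hi] given cumulative risk p
rdeath_time <- function(n, p, lo, hi) {
  if (p <= 0) return(rep(NA_real_, n))
  lambda <- -log(1 - p) / (hi - lo)
  u <- stats::runif(n)
  lo + -log(1 - u * (1 - exp(-lambda * (hi - lo)))) / lambda
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a synthetic cluster-randomized trial
#'
#' Reproducible given the config seed: the same `sim_config` yields an
#' identical table. Villages are assigned 1:1 to arms within each township
#' stratum; outcome waves sit at t = 0 and 1 year (plus post-trial waves
#' when enabled); deaths carry a death time and no outcome observations
#' afterward.
#'
#' @param cfg A [sim_config()].
#' @return A [trial_table()] (outcomes only; add costs with
#'   [generate_cost_items()] or use [simulate_trial()]).
#' @export
generate_trial <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  cea_log("generate_trial", sprintf("seed=%d", cfg$seed))
  n_vil <- cfg$n_townships * cfg$villages_per_township
  village <- seq_len(n_vil)
  township <- rep(seq_len(cfg$n_townships), each = cfg$villages_per_township)
  # stratified 1:1 allocation within township
  arm_v <- character(n_vil)
  for (tw in seq_len(cfg$n_townships)) {
    idx <- which(township == tw)
    picked <- sample(idx, length(idx) / 2)
    arm_v[picked] <- "intervention"
    arm_v[setdiff(idx, picked)] <- "control"
  }
  # spread n_total as evenly as possible over villages
  base_n <- ceiling(cfg$n_total / n_vil)
  counts <- rep(base_n, n_vil)
  excess <- sum(counts) - cfg$n_total
  if (excess > 0) counts[seq_len(excess)] <- counts[seq_len(excess)] - 1L
  n <- sum(counts)
  vil <- rep(village, counts)
  twn <- rep(township, counts)
  arm <- rep(arm_v, counts)
  pid <- sprintf("P%04d", seq_len(n))
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n) < cfg$prop_female, "female", "male")
  sbp0 <- stats::rnorm(n, cfg$baseline_sbp_mean, cfg$baseline_sbp_sd)
  u0 <- rtrunc_norm(n, cfg$baseline_utility_mean, cfg$baseline_utility_sd,
                    cfg$utility_floor, 1)
  trt <- as.integer(arm == "intervention")

  # village random intercepts on the change scale, variance from the ICC
  sd_v_sbp <- cfg$sbp_change_sd * sqrt(cfg$icc_sbp / (1 - cfg$icc_sbp))
  sd_v_u <- cfg$utility_change_sd * sqrt(cfg$icc_utility / (1 - cfg$icc_utility))
  re_sbp <- stats::rnorm(n_vil, 0, sd_v_sbp)
  re_u <- stats::rnorm(n_vil, 0, sd_v_u)

  d_sbp <- cfg$sbp_change_control + cfg$true_effect_sbp * trt +
    re_sbp[vil] + stats::rnorm(n, 0, cfg$sbp_change_sd)
  d_u <- cfg$utility_change_control + cfg$true_effect_utility * trt +
    re_u[vil] + stats::rnorm(n, 0, cfg$utility_change_sd)
  sbp1 <- sbp0 + d_sbp
  u1 <- pmin(1, pmax(cfg$utility_floor, u0 + d_u))

  dies1 <- stats::runif(n) < cfg$mortality_year1
  dt <- rep(NA_real_, n)
  # truncated-exponential time conditional on dying within the year
  dt[dies1] <- rdeath_time(sum(dies1), cfg$mortality_year1, 0, 1)
  drop1 <- !dies1 & stats::runif(n) < cfg$dropout_year1
  sbp1[dies1 | drop1] <- NA_real_
  u1[dies1 | drop1] <- NA_real_

  base <- data.frame(pid = pid, village = vil, township = twn, arm = arm,
                     age = age, sex = sex, stringsAsFactors = FALSE)
  w0 <- cbind(base, wave = 0L, time_years = 0, sbp = sbp0, utility = u0)
  w1 <- cbind(base, wave = 1L, time_years = 1, sbp = sbp1, utility = u1)
  waves <- list(w0, w1)

  if (cfg$include_posttrial) {
    surv1 <- !dies1
    diesP <- rep(FALSE, n)
    horizon <- max(cfg$posttrial_waves)
    for (a in c("intervention", "control")) {
      sel <- surv1 & arm == a
      p <- cfg$posttrial_mortality_by_arm[[a]]
      hit <- stats::runif(sum(sel)) < p
      tP <- rep(NA_real_, sum(sel))
      tP[hit] <- rdeath_time(sum(hit), p, 1, horizon)
      dt[sel][hit] <- tP[hit]
      diesP[sel][hit] <- TRUE
    }
    n_pw <- length(cfg$posttrial_waves)
    span <- max(cfg$posttrial_waves) - 1
    for (k in seq_len(n_pw)) {
      tk <- cfg$posttrial_waves[k]
      frac <- (tk - 1) / span
      d_uP <- (cfg$utility_change_post_control +
                 cfg$true_effect_utility_post * trt) * frac +
        re_u[vil] + stats::rnorm(n, 0, cfg$utility_change_sd)
      uk <- pmin(1, pmax(cfg$utility_floor, u1 + d_uP))
      sk <- sbp1 + stats::rnorm(n, 0, cfg$sbp_change_sd)
      alive_k <- is.na(dt) | dt > tk
      observed <- alive_k & !dies1 & !drop1
      uk[!observed] <- NA_real_
      sk[!observed] <- NA_real_
      waves[[length(waves) + 1]] <-
        cbind(base, wave = 1L + k, time_years = tk, sbp = sk, utility = uk)
    }
  }
  oc <- do.call(rbind, waves)
  oc$death_time <- dt[match(oc$pid, pid)]
  oc <- oc[order(oc$pid, oc$time_years), ]
  rownames(oc) <- NULL
  cea_log("generate_trial", sprintf(
    "%d participants, %d villages, %d deaths year 1",
    n, n_vil, sum(dies1)))
  trial_table(oc)
}

#' Generate itemized costs for a synthetic trial
#'
#' Within-trial items: zero-inflated gamma inpatient episodes per cause,
#' adherence-discounted medication costs per class with higher uptake in
#' the intervention arm, and a program-component item for every
#' intervention participant. The intervention-arm hospitalization
#' probability is scaled so the expected total incremental cost equals
#' `cfg$target_cost_increment`. When post-trial waves are enabled the
#' generator also emits self-reported post-trial episode counts and
#' post-trial medication items, scaled by each participant's time alive.
#' Costs are emitted in reference-year USD directly.
#'
#' @param cfg The [sim_config()] used for [generate_trial()].
#' @param trial The resulting [trial_table()].
#' @return List with `cost_items` and (when enabled) `posttrial_visits`
#'   data.frames.
#' @export
generate_cost_items <- function(cfg, trial) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  oc <- trial$outcomes
  ppl <- unique(oc[, c("pid", "arm", "death_time")])
  n <- nrow(ppl)
  trt <- ppl$arm == "intervention"
  f <- inpatient_factor(cfg)
  items <- list()
  add <- function(pid, category, amount, quantity = NA_real_,
                  unit_price = NA_real_, adherence = NA_real_,
                  period = "within") {
    if (length(pid) == 0) return(invisible(NULL))
    items[[length(items) + 1L]] <<- data.frame(
      pid = pid, category = category, amount = amount,
      source_year = cfg$reference_year, currency = "USD",
      quantity = quantity, unit_price = unit_price, adherence = adherence,
      period = period, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  # within-trial inpatient episodes (at most one per cause here; amounts gamma)
  for (cause in names(cfg$inpatient_prob)) {
    p <- cfg$inpatient_prob[[cause]] * ifelse(trt, f, 1)
    hosp <- stats::runif(n) < p
    m <- cfg$inpatient_mean[[cause]]
    amt <- stats::rgamma(sum(hosp), shape = cfg$inpatient_shape,
                         scale = m / cfg$inpatient_shape)
    add(ppl$pid[hosp], cause, amt)
  }
  # medications: uptake by arm, beta adherence, price x quantity x adherence
  a_shape <- 10
  for (cls in names(cfg$med_uptake_control)) {
    p <- ifelse(trt, cfg$med_uptake_intervention[[cls]],
                cfg$med_uptake_control[[cls]])
    user <- stats::runif(n) < p
    adh <- stats::rbeta(sum(user), a_shape * cfg$med_adherence_mean,
                        a_shape * (1 - cfg$med_adherence_mean))
    price <- cfg$med_unit_price[[cls]]
    add(ppl$pid[user], cls,
        medication_cost(cfg$med_quantity, price, adh),
        quantity = cfg$med_quantity, unit_price = price, adherence = adh)
  }
  # program delivery cost, intervention participants only
  add(ppl$pid[trt], "program_component", rep(cfg$program_cost_pp, sum(trt)))

  visits <- NULL
  if (cfg$include_posttrial) {
    horizon <- max(cfg$posttrial_waves)
    span <- horizon - 1
    # fraction of the post-trial window alive (0 for within-trial deaths)
    alive_frac <- ifelse(is.na(ppl$death_time), 1,
                         pmax(0, (ppl$death_time - 1) / span))
    vrows <- list()
    for (cause in names(cfg$posttrial_visit_rate)) {
      rate <- cfg$posttrial_visit_rate[[cause]] *
        ifelse(trt, cfg$posttrial_visit_factor_intervention, 1) * alive_frac
      cnt <- stats::rpois(n, rate)
      keep <- cnt > 0
      if (any(keep)) {
        vrows[[length(vrows) + 1L]] <- data.frame(
          pid = ppl$pid[keep], cause = cause, count = cnt[keep],
          stringsAsFactors = FALSE)
      }
    }
    visits <- if (length(vrows)) do.call(rbind, vrows) else
      data.frame(pid = character(0), cause = character(0),
                 count = integer(0), stringsAsFactors = FALSE)
    for (cls in names(cfg$med_uptake_control)) {
      p <- ifelse(trt, cfg$med_uptake_intervention[[cls]],
                  cfg$med_uptake_control[[cls]])
      user <- stats::runif(n) < p & alive_frac > 0
      adh <- stats::rbeta(sum(user), a_shape * cfg$med_adherence_mean,
                          a_shape * (1 - cfg$med_adherence_mean))
      price <- cfg$med_unit_price[[cls]]
      qty <- cfg$med_quantity * span * alive_frac[user]
      add(ppl$pid[user], cls, medication_cost(qty, price, adh),
          quantity = qty, unit_price = price, adherence = adh,
          period = "post")
    }
  }
  ci <- do.call(rbind, items)
  rownames(ci) <- NULL
  cea_log("generate_cost_items", sprintf("%d cost items", nrow(ci)))
  list(cost_items = ci, posttrial_visits = visits)
}

#' @rdname generate_trial
#' @description `simulate_trial` runs [generate_trial()] and
#'   [generate_cost_items()] and returns the complete table.
#' @export
simulate_trial <- function(cfg) {
  tt <- generate_trial(cfg)
  cc <- generate_cost_items(cfg, tt)
  trial_table(tt$outcomes, cc$cost_items, cc$posttrial_visits)
}
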