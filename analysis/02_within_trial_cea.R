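#!/usr/bin/env Rscript
# Within-trial cost-effectiveness analysis: per-participant costs and
# QALYs, covariate-adjusted arm differences (REML mixed model with
# village random intercepts), ICERs per mmHg SBP reduction and per QALY,
# 5000-replication stratified cluster bootstrap, and CEACs.

suppressMessages(library(strokecea))

out_dir <- "results"
trial_path <- file.path(out_dir, "trial_outcomes.csv")
if (!file.exists(trial_path)) {
  stop("run analysis/01_simulate_trial.R first", call. = FALSE)
}
tt <- read_trial(trial_path,
                 cost_path = file.path(out_dir, "trial_cost_items.csv"),
                 visits_path = file.path(out_dir,
                                         "trial_posttrial_visits.csv"))
cfg <- run_config(rng_seed = 1)
fr <- build_analysis_frame(tt, cfg, period = "within")

est <- effects_table(
  adjusted_difference(fr, "sbp_reduction", baseline = "baseline_sbp"),
  adjusted_difference(fr, "utility_change", baseline = "baseline_utility"),
  adjusted_difference(fr, "qaly", baseline = "baseline_utility"),
  adjusted_difference(fr, "total_cost"),
  unadjusted_difference(fr, "total_cost"))
write_results(est, file.path(out_dir, "within_trial_effects.csv"))
print(est, digits = 4)

res_sbp <- run_cea(fr, "sbp_reduction", baseline = "baseline_sbp",
                   cfg = cfg, B = 5000)
res_qaly <- run_cea(fr, "qaly", baseline = "baseline_utility",
                    cfg = cfg, B = 5000)
write_results(res_sbp, file.path(out_dir, "within_trial_cea_sbp.json"))
write_results(res_qaly, file.path(out_dir, "within_trial_cea_qaly.json"))
write_results(res_qaly$ceac, file.path(out_dir, "within_trial_ceac_qaly.csv"))

cat("\n-- within-trial results --\n")
print(res_sbp)
print(res_qaly)
at_wtp <- res_qaly$ceac$p_ce[which.min(abs(res_qaly$ceac$lambda -
                                             cfg$wtp_threshold))]
cat(sprintf("P(cost-effective at %d USD/QALY): %.3f\n",
            cfg$wtp_threshold, at_wtp))
cat(sprintf("NE-quadrant share of bootstrap draws: %.3f\n",
            res_qaly$summary$quadrants[["NE"]]))
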