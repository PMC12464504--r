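#!/usr/bin/env Rscript
# Generate the default synthetic cluster-randomized trial (50 villages in
# 5 township strata, ~1299 participants, 1-year intervention plus ~6-year
# observational follow-up) and write the long-format CSVs downstream
# stages read.

suppressMessages(library(strokecea))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

scfg <- sim_config(include_posttrial = TRUE)  # default seed
tt <- simulate_trial(scfg)

write_trial(tt,
            file.path(out_dir, "trial_outcomes.csv"),
            cost_path = file.path(out_dir, "trial_cost_items.csv"),
            visits_path = file.path(out_dir, "trial_posttrial_visits.csv"))

oc <- tt$outcomes
per_pid <- unique(oc[, c("pid", "arm", "death_time")])
cat(sprintf("participants: %d (%d intervention / %d control)\n",
            nrow(per_pid), sum(per_pid$arm == "intervention"),
            sum(per_pid$arm == "control")))
cat(sprintf("villages: %d in %d townships\n",
            length(unique(oc$village)), length(unique(oc$township))))
cat(sprintf("deaths within trial year: %d; deaths by %.1f years: %d\n",
            sum(per_pid$death_time <= 1, na.rm = TRUE),
            max(oc$time_years), sum(!is.na(per_pid$death_time))))
cat(sprintf("cost items: %d\n", nrow(tt$cost_items)))
cat(sprintf("wrote %s/trial_*.csv\n", out_dir))
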