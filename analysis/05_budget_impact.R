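#!/usr/bin/env Rscript
# National budget-impact projection over a 5-year horizon: eligible rural
# stroke population (calibrated net-growth projection), per-participant
# and total program cost under scenario A (standalone scale-up) and
# scenario B (integrated with the national basic public health services,
# which already fund visit delivery for the covered ~61%).

suppressMessages(library(strokecea))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

p <- bia_params()
tab <- rbind(bia_run(p, "A"), bia_run(p, "B"))
write_results(tab, file.path(out_dir, "budget_impact.csv"))

fmt <- function(x) format(round(x), big.mark = ",", scientific = FALSE)
for (sc in c("A", "B")) {
  s <- tab[tab$scenario == sc, ]
  cat(sprintf("-- scenario %s --\n", sc))
  for (k in c(1, nrow(s))) {
    cat(sprintf(
      "  year %d: eligible %s, %.2f USD/participant, total %s USD, %.2f USD per capita\n",
      s$year[k], fmt(s$eligible[k]), s$cost_per_participant[k],
      fmt(s$total_budget[k]), s$cost_per_capita[k]))
  }
}
cat(sprintf("scenario B first-year saving vs A: %s USD (%.0f%%)\n",
            fmt(tab$total_budget[1] - tab$total_budget[6]),
            100 * (1 - tab$total_budget[6] / tab$total_budget[1])))
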