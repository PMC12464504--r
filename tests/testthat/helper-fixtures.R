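# Shared fixtures, built in code.

# Minimal hand-built trial: 2 townships x 2 villages each (one per arm),
# n participants per village, waves at 0 and 1.
tiny_trial <- function(n_per_village = 3, sbp1_shift = 0, cost_items = NULL) {
  villages <- data.frame(
    village = 1:4, township = c(1, 1, 2, 2),
    arm = c("intervention", "control", "intervention", "control"),
    stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(1:4, function(v) {
    n <- n_per_village
    pid <- sprintf("T%d_%02d", v, seq_len(n))
    base <- data.frame(
      pid = pid, village = v, township = villages$township[v],
      arm = villages$arm[v], age = 60 + seq_len(n), sex = "female",
      stringsAsFactors = FALSE)
    rbind(
      cbind(base, wave = 0L, time_years = 0, sbp = 140 + seq_len(n),
            utility = 0.8),
      cbind(base, wave = 1L, time_years = 1,
            sbp = 140 + seq_len(n) + sbp1_shift, utility = 0.8))
  }))
  rows$death_time <- NA_real_
  trial_table(rows, cost_items)
}

# Frame with prescribed per-arm outcome means and controllable noise.
frame_with_means <- function(mean_int, mean_ctl, outcome = "total_cost",
                             n_per_village = 10, n_villages_per_arm = 4,
                             noise_sd = 0, seed = 1) {
  set.seed(seed)
  vil <- seq_len(2 * n_villages_per_arm)
  arm <- rep(c("intervention", "control"), each = n_villages_per_arm)
  twn <- rep(rep(1:2, length.out = n_villages_per_arm), 2)
  fr <- do.call(rbind, lapply(seq_along(vil), function(i) {
    data.frame(
      pid = sprintf("V%d_%02d", vil[i], seq_len(n_per_village)),
      village = vil[i], township = twn[i], arm = arm[i],
      age = 60 + seq_len(n_per_village) %% 10,
      sex = rep(c("female", "male"), length.out = n_per_village),
      stringsAsFactors = FALSE)
  }))
  mu <- ifelse(fr$arm == "intervention", mean_int, mean_ctl)
  fr[[outcome]] <- mu + stats::rnorm(nrow(fr), 0, noise_sd)
  fr
}

# Small, fast simulation config for property tests.
small_sim <- function(...) {
  sim_config(n_townships = 3, villages_per_township = 4, n_total = 240,
             seed = 42, ...)
}

pkg_value_set <- function() {
  read_value_set(system.file("extdata", "valueset_synthetic.csv",
                             package = "strokecea"))
}
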