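#' Analysis run configuration
#'
#' Bundles the economic-evaluation settings shared by every pipeline stage:
#' the currency reference year, the annual discount rate applied to
#' post-trial costs and QALYs, the willingness-to-pay threshold, bootstrap
#' size, the WTP grid for acceptability curves, the rural consumer price
#' index table used to inflate historical amounts, and the local-currency
#' exchange rate at the reference year.
#'
#' @param reference_year Calendar year all monetary amounts are expressed in.
#' @param discount_rate_annual Annual discount rate (fraction); applied to
#'   post-trial streams only. Base case 0.05; deterministic sensitivity
#'   typically explores 0.03-0.08.
#' @param wtp_threshold Willingness to pay, USD per QALY. Base case 18766
#'   (1.5 times 2023 China GDP per capita).
#' @param n_bootstrap Number of bootstrap replications (base case 5000).
#' @param rng_seed Integer seed used by stochastic stages, or `NULL`.
#' @param wtp_grid Strictly increasing vector of WTP values for the CEAC.
#'   Default: 0 to twice `wtp_threshold` in 100 steps.
#' @param cpi_table Named numeric vector, names are calendar years, values
#'   the rural consumer price index (any positive base).
#' @param exchange_rate Local currency units per USD at `reference_year`.
#' @param outpatient_flat Flat per-participant annual outpatient cost (USD,
#'   excluding medication), taken from official statistics because trial
#'   outpatient records are unavailable.
#' @param outpatient_flat_posttrial Same, for the post-trial period (total
#'   over the post-trial window).
#' @return An object of class `run_config`.
#' @examples
#' cfg <- run_config(rng_seed = 1)
#' cfg$wtp_threshold
#' @export
run_config <- function(reference_year = 2023,
                       discount_rate_annual = 0.05,
                       wtp_threshold = 18766,
                       n_bootstrap = 5000,
                       rng_seed = NULL,
                       wtp_grid = NULL,
                       cpi_table = c("2023" = 100),
                       exchange_rate = 7.08,
                       outpatient_flat = 45.5,
                       outpatient_flat_posttrial = 124.2) {
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 2 * wtp_threshold, length.out = 101)
  }
  cfg <- structure(
    list(
      reference_year = as.integer(reference_year),
      discount_rate_annual = discount_rate_annual,
      wtp_threshold = wtp_threshold,
      n_bootstrap = as.integer(n_bootstrap),
      rng_seed = rng_seed,
      wtp_grid = wtp_grid,
      cpi_table = cpi_table,
      exchange_rate = exchange_rate,
      outpatient_flat = outpatient_flat,
      outpatient_flat_posttrial = outpatient_flat_posttrial
    ),
    class = "run_config"
  )
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A `run_config` object to validate.
#' @export
validate_run_config <- function(cfg) {
  stopifnot_msg(inherits(cfg, "run_config"), "not a run_config object")
  stopifnot_msg(cfg$discount_rate_annual >= 0,
                "discount_rate_annual must be >= 0")
  stopifnot_msg(cfg$n_bootstrap >= 1, "n_bootstrap must be >= 1")
  stopifnot_msg(all(diff(cfg$wtp_grid) > 0),
                "wtp_grid must be strictly increasing")
  stopifnot_msg(all(cfg$wtp_grid >= 0), "wtp_grid values must be >= 0")
  stopifnot_msg(all(cfg$cpi_table > 0), "cpi_table values must be > 0")
  stopifnot_msg(!is.null(names(cfg$cpi_table)) &&
                  !anyNA(suppressWarnings(as.integer(names(cfg$cpi_table)))),
                "cpi_table must be named by calendar year")
  stopifnot_msg(cfg$exchange_rate > 0, "exchange_rate must be > 0")
  invisible(cfg)
}

# Keys accepted in a YAML run-config file; anything else is an error so
# typos fail fast rather than silently taking a default.
run_config_keys <- function() {
  c("reference_year", "discount_rate_annual", "wtp_threshold",
    "n_bootstrap", "rng_seed", "wtp_grid", "cpi_table", "exchange_rate",
    "outpatient_flat", "outpatient_flat_posttrial")
}

#' Read a run configuration from YAML
#'
#' Fails on unknown keys; all invariants are checked before any computation.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()]. `cpi_table` is a mapping year -> index.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  stopifnot_msg(file.exists(path), sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), run_config_keys())
  stopifnot_msg(length(unknown) == 0,
                sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  if (!is.null(raw$cpi_table)) {
    raw$cpi_table <- unlist(raw$cpi_table)
  }
  if (!is.null(raw$wtp_grid)) raw$wtp_grid <- as.numeric(raw$wtp_grid)
  do.call(run_config, raw)
}
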