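#' Adjust a monetary amount to reference-year USD
#'
#' Historical amounts are inflated with the rural consumer price index to
#' the reference year and, when recorded in local currency, converted once
#' at the reference-year exchange rate. The operation is linear in the
#' amount.
#'
#' @param amount Numeric amount(s) in `source_year` money.
#' @param source_year Calendar year the amount was recorded in.
#' @param cfg A [run_config()] supplying `cpi_table` and `exchange_rate`.
#' @param currency `"USD"` (inflate only) or `"local"` (inflate, then
#'   divide by the exchange rate).
#' @return Amount(s) in reference-year USD.
#' @examples
#' cfg <- run_config(cpi_table = c("2020" = 100, "2023" = 110))
#' adjust_currency(100, 2020, cfg, currency = "USD")  # 110
#' @export
adjust_currency <- function(amount, source_year, cfg,
                            currency = c("USD", "local")) {
  currency <- match.arg(currency)
  stopifnot_msg(all(amount >= 0), "amount must be >= 0")
  yrs <- as.character(c(source_year, cfg$reference_year))
  missing_yr <- setdiff(unique(yrs), names(cfg$cpi_table))
  stopifnot_msg(length(missing_yr) == 0,
                sprintf("cpi_table has no entry for year(s): %s",
                        paste(missing_yr, collapse = ", ")))
  out <- amount * cfg$cpi_table[[as.character(cfg$reference_year)]] /
    cfg$cpi_table[as.character(source_year)]
  out <- unname(out)
  if (currency == "local") out <- out / cfg$exchange_rate
  out
}

#' Adherence-discounted medication cost
#'
#' Quantity used times unit price, discounted by the individual adherence
#' fraction.
#'
#' @param quantity Units of medication consumed (>= 0).
#' @param unit_price Price per unit (>= 0).
#' @param adherence Adherence fraction in \[0, 1\].
#' @return `quantity * unit_price * adherence`.
#' @examples
#' medication_cost(30, 0.10, 0.8)  # 2.40
#' @export
medication_cost <- function(quantity, unit_price, adherence) {
  stopifnot_msg(all(quantity >= 0), "quantity must be >= 0")
  stopifnot_msg(all(unit_price >= 0), "unit_price must be >= 0")
  stopifnot_msg(all(adherence >= 0 & adherence <= 1),
                "adherence must lie in [0, 1]")
  quantity * unit_price * adherence
}

#' Total cost for one participant
#'
#' Sums a participant's itemized costs (already adjusted to reference-year
#' USD) and adds the flat outpatient cost. Participants with no items
#' contribute the flat outpatient cost only, so population means include
#' participants without any hospitalization or medication use.
#'
#' @param items Data.frame of cost items for a single participant, with at
#'   least `amount` and `source_year`; may have zero rows.
#' @param outpatient_flat Flat outpatient cost (USD, reference year).
#' @param cfg A [run_config()]; items whose `source_year` differs from
#'   `cfg$reference_year` are rejected (mixing unadjusted currency-years in
#'   one aggregation is an error, not a silent sum).
#' @return Total cost in reference-year USD.
#' @export
person_total_cost <- function(items, outpatient_flat, cfg) {
  stopifnot_msg(outpatient_flat >= 0, "outpatient_flat must be >= 0")
  if (is.null(items) || nrow(items) == 0) return(outpatient_flat)
  if (length(unique(items$pid)) > 1) {
    stop("person_total_cost expects items for a single participant",
         call. = FALSE)
  }
  bad <- unique(items$source_year[items$source_year != cfg$reference_year])
  stopifnot_msg(length(bad) == 0,
                sprintf("cost items carry unadjusted currency-year(s) %s; run adjust_currency first",
                        paste(bad, collapse = ", ")))
  sum(items$amount) + outpatient_flat
}

#' Program cost ledger
#'
#' Itemized intervention delivery costs (staff compensation, voice
#' messages, printing, system maintenance, development fee, ...) with the
#' participant count over which the grand total is amortized.
#'
#' @param components Data.frame with columns `component`, `unit_cost`,
#'   `quantity`, `total`.
#' @param n_participants Number of intervention participants (> 0 for
#'   per-participant amortization).
#' @return An object of class `program_ledger`.
#' @export
program_ledger <- function(components, n_participants) {
  stopifnot_msg(all(c("component", "unit_cost", "quantity", "total") %in%
                      names(components)),
                "ledger needs columns component, unit_cost, quantity, total")
  stopifnot_msg(all(components$total >= 0), "component totals must be >= 0")
  structure(list(components = components,
                 n_participants = as.integer(n_participants)),
            class = "program_ledger")
}

#' @rdname program_ledger
#' @param path CSV path with the ledger columns plus `n_participants`
#'   supplied separately.
#' @export
read_program_ledger <- function(path, n_participants) {
  stopifnot_msg(file.exists(path), sprintf("file not found: %s", path))
  program_ledger(utils::read.csv(path, stringsAsFactors = FALSE),
                 n_participants)
}

#' Program grand total and per-participant amortization
#'
#' @param ledger A [program_ledger()].
#' @return List with `grand_total` (sum of component totals) and
#'   `per_participant` (grand total / participant count).
#' @export
program_per_participant <- function(ledger) {
  stopifnot_msg(inherits(ledger, "program_ledger"), "not a program_ledger")
  stopifnot_msg(ledger$n_participants > 0,
                "n_participants must be > 0 to amortize program costs")
  gt <- sum(ledger$components$total)
  list(grand_total = gt, per_participant = gt / ledger$n_participants)
}

#' Post-trial inpatient cost from self-reported episode counts
#'
#' Post-trial hospitalization costs are not observed directly; they are
#' estimated as episode counts times the within-trial mean cost per episode
#' for the matching cause category.
#'
#' @param visit_counts Named numeric vector (or data.frame with `cause` and
#'   `count`) of episode counts per cause.
#' @param mean_cost_per_cause Named numeric vector of within-trial mean
#'   costs per episode, named by cause.
#' @return Estimated inpatient cost (USD).
#' @export
estimate_posttrial_inpatient <- function(visit_counts, mean_cost_per_cause) {
  if (is.data.frame(visit_counts)) {
    counts <- stats::setNames(visit_counts$count, visit_counts$cause)
  } else {
    counts <- visit_counts
  }
  if (length(counts) == 0) return(0)
  unknown <- setdiff(names(counts), names(mean_cost_per_cause))
  stopifnot_msg(length(unknown) == 0,
                sprintf("no within-trial mean cost for cause(s): %s",
                        paste(unknown, collapse = ", ")))
  stopifnot_msg(all(counts >= 0), "episode counts must be >= 0")
  sum(counts * mean_cost_per_cause[names(counts)])
}

#' Within-trial mean inpatient cost per episode, by cause
#'
#' @param cost_items Cost-item data.frame; each inpatient row is one
#'   episode.
#' @return Named numeric vector of mean per-episode costs keyed by the
#'   inpatient categories present.
#' @export
inpatient_cause_means <- function(cost_items) {
  inp <- cost_items[grepl("^inpatient_", cost_items$category) &
                      cost_items$period == "within", , drop = FALSE]
  if (nrow(inp) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  tapply(inp$amount, inp$category, mean)
}
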