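#' Trial data container
#'
#' A `trial_table` holds one cluster-randomized trial in long format:
#'
#' * `outcomes`: one row per participant-wave with columns `pid`, `village`,
#'   `township`, `arm` (`"intervention"`/`"control"`), `age`, `sex`
#'   (`"female"`/`"male"`), `wave` (integer index), `time_years` (years since
#'   baseline), `sbp` (mmHg), `utility` (EQ-5D index), `death_time` (years
#'   since baseline, `NA` if alive within the horizon).
#' * `cost_items` (optional): itemized costs keyed by `pid` with columns
#'   `pid`, `category`, `amount`, `source_year`, `currency`, `quantity`,
#'   `unit_price`, `adherence`, `period` (`"within"`/`"post"`).
#' * `posttrial_visits` (optional): self-reported post-trial inpatient
#'   episode counts: `pid`, `cause`, `count`.
#'
#' @param outcomes Outcome data.frame as described above.
#' @param cost_items Optional cost-item data.frame.
#' @param posttrial_visits Optional post-trial visit-count data.frame.
#' @return A validated object of class `trial_table`.
#' @export
trial_table <- function(outcomes, cost_items = NULL, posttrial_visits = NULL) {
  tt <- structure(
    list(outcomes = outcomes, cost_items = cost_items,
         posttrial_visits = posttrial_visits),
    class = "trial_table"
  )
  validate_trial_table(tt)
}

outcome_columns <- function() {
  c("pid", "village", "township", "arm", "age", "sex", "wave",
    "time_years", "sbp", "utility", "death_time")
}

cost_item_columns <- function() {
  c("pid", "category", "amount", "source_year", "currency",
    "quantity", "unit_price", "adherence", "period")
}

#' Cost categories recognized by the costing module
#' @return Character vector of the closed category set.
#' @export
cost_categories <- function() {
  c("inpatient_stroke", "inpatient_cvd_nonstroke", "inpatient_other",
    "outpatient", "med_antiplatelet", "med_statin", "med_antihypertensive",
    "program_component")
}

#' @rdname trial_table
#' @param tt A `trial_table` to validate.
#' @export
validate_trial_table <- function(tt) {
  stopifnot_msg(inherits(tt, "trial_table"), "not a trial_table")
  oc <- tt$outcomes
  missing_cols <- setdiff(outcome_columns(), names(oc))
  stopifnot_msg(length(missing_cols) == 0,
                sprintf("outcome table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  stopifnot_msg(all(oc$arm %in% c("intervention", "control")),
                "arm must be 'intervention' or 'control'")
  # one pid -> one (village, arm); one village -> one township and one arm
  per_pid <- unique(oc[, c("pid", "village", "township", "arm")])
  stopifnot_msg(!anyDuplicated(per_pid$pid),
                "participant mapped to more than one village/arm")
  vmap <- unique(per_pid[, c("village", "township")])
  stopifnot_msg(!anyDuplicated(vmap$village),
                "village mapped to more than one township")
  amap <- unique(per_pid[, c("village", "arm")])
  stopifnot_msg(!anyDuplicated(amap$village),
                "village mapped to more than one arm")
  stopifnot_msg(all(oc$time_years >= 0), "wave times must be nonnegative")
  ord <- order(oc$pid, oc$time_years)
  tsplit <- split(oc$time_years[ord], oc$pid[ord])
  stopifnot_msg(all(vapply(tsplit, function(t) all(diff(t) > 0), logical(1))),
                "wave times must be strictly increasing per participant")
  # no observed outcomes after death
  dead <- !is.na(oc$death_time)
  after <- dead & oc$time_years > oc$death_time &
    (!is.na(oc$sbp) | !is.na(oc$utility))
  stopifnot_msg(!any(after), "observed outcomes after death time")
  if (!is.null(tt$cost_items)) {
    ci <- tt$cost_items
    missing_cols <- setdiff(cost_item_columns(), names(ci))
    stopifnot_msg(length(missing_cols) == 0,
                  sprintf("cost-item table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")))
    stopifnot_msg(all(ci$category %in% cost_categories()),
                  "unknown cost category")
    stopifnot_msg(all(ci$amount >= 0), "cost amounts must be >= 0")
    adh <- ci$adherence[!is.na(ci$adherence)]
    stopifnot_msg(all(adh >= 0 & adh <= 1), "adherence must lie in [0, 1]")
    stopifnot_msg(all(ci$pid %in% oc$pid),
                  "cost item for unknown participant id")
  }
  invisible(tt)
}

#' Number of participants in a trial table
#' @param tt A `trial_table`.
#' @return Integer count of distinct participants.
#' @export
n_participants <- function(tt) length(unique(tt$outcomes$pid))

#' Read / write trial data
#'
#' CSV interchange: comma-separated, UTF-8, `.` decimal. `read_trial`
#' validates all container invariants and fails with the offending column
#' or record named.
#'
#' @param path Outcome CSV path.
#' @param cost_path Optional cost-item CSV path.
#' @param visits_path Optional post-trial visit-count CSV path.
#' @return `read_trial`: a validated `trial_table`.
#' @export
read_trial <- function(path, cost_path = NULL, visits_path = NULL) {
  stopifnot_msg(file.exists(path), sprintf("file not found: %s", path))
  oc <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(outcome_columns(), names(oc))
  stopifnot_msg(length(missing_cols) == 0,
                sprintf("outcome table is missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  ci <- NULL
  if (!is.null(cost_path)) {
    stopifnot_msg(file.exists(cost_path),
                  sprintf("file not found: %s", cost_path))
    ci <- utils::read.csv(cost_path, stringsAsFactors = FALSE)
  }
  pv <- NULL
  if (!is.null(visits_path)) {
    stopifnot_msg(file.exists(visits_path),
                  sprintf("file not found: %s", visits_path))
    pv <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  }
  tt <- trial_table(oc, ci, pv)
  cea_log("read_trial", sprintf(
    "%d outcome rows, %d participants, %d cost items",
    nrow(oc), n_participants(tt),
    if (is.null(ci)) 0L else nrow(ci)))
  tt
}

#' @rdname read_trial
#' @param tt A `trial_table` to write.
#' @export
write_trial <- function(tt, path, cost_path = NULL, visits_path = NULL) {
  validate_trial_table(tt)
  utils::write.csv(tt$outcomes, path, row.names = FALSE)
  if (!is.null(cost_path) && !is.null(tt$cost_items)) {
    utils::write.csv(tt$cost_items, cost_path, row.names = FALSE)
  }
  if (!is.null(visits_path) && !is.null(tt$posttrial_visits)) {
    utils::write.csv(tt$posttrial_visits, visits_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write analysis results to disk
#'
#' Cost-effectiveness results (`ce_result`) are serialized to JSON;
#' tabular results (budget-impact tables, effect tables, DSA tables) to
#' CSV. Re-reading a `ce_result` reproduces the in-memory object to full
#' double precision.
#'
#' @param result A `ce_result` or a data.frame.
#' @param path Output path (`.json` for `ce_result`, `.csv` for tables).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (inherits(result, "ce_result")) {
    stopifnot_msg(!is.null(result$draws) && nrow(result$draws) > 0,
                  "refusing to serialize a ce_result with no bootstrap draws")
    out <- list(
      point = result$point,
      icer = result$icer,
      draws = result$draws,
      ceac = result$ceac,
      summary = result$summary,
      seed = result$seed,
      B = result$B,
      effect_outcome = result$effect_outcome
    )
    jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns", null = "null")
  } else if (is.data.frame(result)) {
    utils::write.csv(result, path, row.names = FALSE)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_ce_result <- function(path) {
  stopifnot_msg(file.exists(path), sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(point = raw$point, icer = raw$icer,
         draws = as.data.frame(raw$draws), ceac = as.data.frame(raw$ceac),
         summary = raw$summary, seed = raw$seed, B = raw$B,
         effect_outcome = raw$effect_outcome),
    class = "ce_result"
  )
}
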