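#' @noRd
.trial_columns <- c("participant_id", "vision", "body_posture",
                    "hand_posture", "soa_ms", "response", "latency_ms",
                    "block_index", "trial_index")

#' Validate a trial-level table
#'
#' Checks a long-format trial table against the trial-record contract:
#' known factor levels, SOAs drawn from the design's SOA set, a latency
#' present exactly when the response is not a timeout, and unique
#' (block, trial) indices within participant. Errors name the offending
#' row and field.
#'
#' @param trials Data frame of trial records.
#' @param soa_set_ms Admissible signed SOAs (ms).
#' @return The validated table, invisibly.
#' @export
validate_trials <- function(trials, soa_set_ms = toj_soa_set()) {
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .bad_row <- function(ok, field, why) {
    if (!all(ok)) {
      stop("invalid trial table: row ", which(!ok)[1], ", field '", field,
           "': ", why, call. = FALSE)
    }
  }
  .bad_row(trials$vision %in% .vision_levels, "vision",
           "must be one of intact, blindfold")
  .bad_row(trials$body_posture %in% .body_levels, "body_posture",
           "must be one of upright, side")
  .bad_row(trials$hand_posture %in% .hand_levels, "hand_posture",
           "must be one of uncrossed, crossed")
  .bad_row(trials$response %in% .response_levels, "response",
           "must be one of left_first, right_first, timeout")
  .bad_row(trials$soa_ms %in% soa_set_ms, "soa_ms",
           paste("must be one of", paste(soa_set_ms, collapse = ", ")))
  timeout <- trials$response == "timeout"
  .bad_row(!timeout | is.na(trials$latency_ms), "latency_ms",
           "must be empty on timeout trials")
  .bad_row(timeout | (!is.na(trials$latency_ms) & trials$latency_ms >= 0),
           "latency_ms", "must be a non-negative number on responded trials")
  .bad_row(trials$block_index >= 0 & trials$trial_index >= 0,
           "block_index/trial_index", "must be non-negative")
  dup <- duplicated(trials[c("participant_id", "block_index", "trial_index")])
  .bad_row(!dup, "block_index/trial_index",
           "duplicated (block, trial) pair within participant")
  invisible(trials)
}

#' Read a trial-level CSV file
#'
#' Reads the long-format trial schema (one row per stimulus
#' presentation) and validates every row. The latency field is empty on
#' timeout trials.
#'
#' @param path Path to a CSV file with header
#'   `participant_id,vision,body_posture,hand_posture,soa_ms,response,latency_ms,block_index,trial_index`.
#' @param soa_set_ms Admissible signed SOAs (ms).
#' @return A validated data frame of trial records, in file order.
#' @seealso [write_trials()], [aggregate_counts()]
#' @export
read_trials <- function(path, soa_set_ms = toj_soa_set()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  trials <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(
                       participant_id = "character", vision = "character",
                       body_posture = "character", hand_posture = "character",
                       soa_ms = "integer", response = "character",
                       latency_ms = "numeric", block_index = "integer",
                       trial_index = "integer"))
  if (!identical(names(trials), .trial_columns)) {
    stop("header of ", path, " does not match the trial schema", call. = FALSE)
  }
  validate_trials(trials, soa_set_ms = soa_set_ms)
  trials
}

#' Write a trial-level CSV file
#'
#' Writes trials in the fixed column order with deterministic
#' formatting; [read_trials()] inverts it exactly. Timeout trials have
#' an empty latency field.
#'
#' @param trials Validated data frame of trial records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials, soa_set_ms = unique(trials$soa_ms))
  write.csv(trials[.trial_columns], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' Aggregate filtered trials into per-cell response counts
#'
#' Tallies right-first and left-first responses per
#' (participant, vision, body posture, hand posture, SOA) cell. The
#' input must already have passed [filter_trials()]: timeout rows are an
#' error here, because exclusion policy belongs to the preprocessing
#' step, not the aggregator.
#'
#' @param trials Filtered trial table.
#' @return A data frame with one row per observed cell and columns
#'   `participant_id`, `vision`, `body_posture`, `hand_posture`,
#'   `soa_ms`, `n_right_first`, `n_left_first`. Cells with no trials are
#'   not emitted.
#' @examples
#' sim <- simulate_experiment(truth_preset("full_vision", n_participants = 2),
#'                            seed = 1)
#' counts <- aggregate_counts(sim$trials)
#' sum(counts$n_right_first + counts$n_left_first) == nrow(sim$trials)
#' @export
aggregate_counts <- function(trials) {
  validate_trials(trials, soa_set_ms = unique(trials$soa_ms))
  if (any(trials$response == "timeout")) {
    stop("trial table contains timeout rows; run filter_trials() first",
         call. = FALSE)
  }
  key <- trials[c("participant_id", "vision", "body_posture",
                  "hand_posture", "soa_ms")]
  counts <- aggregate(
    cbind(n_right_first = trials$response == "right_first",
          n_left_first = trials$response == "left_first"),
    by = key, FUN = sum)
  counts <- counts[order(counts$participant_id, counts$vision,
                         counts$body_posture, counts$hand_posture,
                         counts$soa_ms), ]
  rownames(counts) <- NULL
  counts$n_right_first <- as.integer(counts$n_right_first)
  counts$n_left_first <- as.integer(counts$n_left_first)
  counts
}
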