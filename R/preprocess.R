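#' Apply the trial-exclusion rules
#'
#' Removes timed-out trials (response code `timeout`; the apparatus
#' times a trial out 3.5 s after the second vibration, but the response
#' code, not the latency, is authoritative) and premature responses —
#' responses made strictly less than `premature_cutoff_ms` after the
#' second vibration. A latency exactly at the cutoff is retained. All
#' other rows pass through unchanged, in order; removed trials take no
#' part in any downstream statistic.
#'
#' @param trials Validated trial table.
#' @param premature_cutoff_ms Premature-response cutoff in ms
#'   (default 100); must be non-negative.
#' @return A list of class `toj_filter_result`:
#'   \describe{
#'     \item{trials}{the retained rows;}
#'     \item{removed}{the removed rows;}
#'     \item{report}{counts of timeouts and premature responses removed,
#'       the number of distinct participants affected, and a
#'       per-participant breakdown.}
#'   }
#' @examples
#' sim <- simulate_experiment(truth_preset("full_vision", 2,
#'                            timeout_rate = 0.02), seed = 3)
#' f <- filter_trials(sim$trials)
#' f$report$n_timeouts_removed
#' @export
filter_trials <- function(trials, premature_cutoff_ms = 100) {
  if (!is.numeric(premature_cutoff_ms) || premature_cutoff_ms < 0) {
    stop("premature_cutoff_ms must be non-negative", call. = FALSE)
  }
  validate_trials(trials, soa_set_ms = unique(trials$soa_ms))

  is_timeout <- trials$response == "timeout"
  is_premature <- !is_timeout & trials$latency_ms < premature_cutoff_ms
  drop <- is_timeout | is_premature

  affected <- unique(trials$participant_id[drop])
  breakdown <- if (any(drop)) {
    aggregate(cbind(n_timeouts = is_timeout[drop],
                    n_premature = is_premature[drop]),
              by = list(participant_id = trials$participant_id[drop]),
              FUN = sum)
  } else {
    data.frame(participant_id = character(), n_timeouts = integer(),
               n_premature = integer())
  }

  retained <- trials[!drop, , drop = FALSE]
  removed <- trials[drop, , drop = FALSE]
  attr(retained, "injected") <- NULL

  structure(list(
    trials = retained,
    removed = removed,
    report = list(
      n_timeouts_removed = sum(is_timeout),
      n_premature_removed = sum(is_premature),
      participants_affected = length(affected),
      per_participant = breakdown)
  ), class = "toj_filter_result")
}

#' @export
print.toj_filter_result <- function(x, ...) {
  r <- x$report
  cat("Trial filter: removed", r$n_timeouts_removed, "timeout and",
      r$n_premature_removed, "premature trial(s) across",
      r$participants_affected, "participant(s);",
      nrow(x$trials), "trials retained.\n")
  invisible(x)
}
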