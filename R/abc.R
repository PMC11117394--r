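#' Rejection-ABC acceptance rule
#'
#' A Monte Carlo iterate is accepted when its predicted creatinine-
#' standardized urinary 3PBA falls within `c` orders of magnitude of the
#' measured value: accept iff `|log10(measured) - log10(predicted)| < c`
#' (strict, so a distance of exactly `c` is rejected). `c = 1` is the
#' "order of magnitude" threshold and `c = 0.5` the "half order of
#' magnitude" threshold.
#'
#' @param measured Measured creatinine-standardized concentration (ug/ug),
#'   positive; vectorized.
#' @param predicted Model prediction (ug/ug), positive after flooring.
#' @param c Log10 distance threshold, > 0.
#' @return Logical vector of acceptances.
#' @export
abc_accept <- function(measured, predicted, c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0) {
    stop("abc_accept: 'c' must be a single positive number")
  }
  if (any(measured <= 0)) {
    stop("abc_accept: 'measured' must be positive")
  }
  if (any(predicted <= 0)) {
    stop("abc_accept: 'predicted' must be positive (apply the floor first)")
  }
  abs(log10(measured) - log10(predicted)) < c
}

#' Filter participant-iterates by the ABC rule
#'
#' Discards the Monte Carlo exposure iterates whose predictions are too
#' discrepant from the corresponding biomarker measurement. Participants
#' that lose every iterate are reported separately; filtered summaries
#' exclude them.
#'
#' @param records Data frame with at least `participant_id`, `measured`,
#'   `predicted`.
#' @param c Log10 threshold (see [abc_accept()]).
#' @return List with `accepted` (the retained subset), `counts` (data
#'   frame: `participant_id`, `n_total`, `n_accepted`), and
#'   `dropped_participants` (ids with zero accepted iterates).
#' @export
filter_iterates <- function(records, c) {
  validate_columns(records, c("participant_id", "measured", "predicted"),
                   "records")
  ok <- abc_accept(records$measured, records$predicted, c)
  total <- table(records$participant_id)
  acc <- table(factor(records$participant_id[ok], levels = names(total)))
  counts <- data.frame(participant_id = names(total),
                       n_total = as.integer(total),
                       n_accepted = as.integer(acc),
                       stringsAsFactors = FALSE)
  list(accepted = records[ok, , drop = FALSE],
       counts = counts,
       dropped_participants = counts$participant_id[counts$n_accepted == 0L])
}

#' Acceptance fractions at the standard thresholds
#'
#' Fraction of participant-iterates whose predictions fall within each
#' log10 threshold of their measurement, overall and (optionally) within
#' groups of a stratifying column.
#'
#' @param records Data frame with `measured` and `predicted`.
#' @param thresholds Numeric vector of log10 thresholds (default 1 and
#'   0.5).
#' @param by Optional name of a column in `records` to stratify by.
#' @return Data frame with `group` ("overall" or the stratum label),
#'   `threshold`, `n`, `n_accepted`, `fraction`.
#' @export
acceptance_summary <- function(records, thresholds = c(1.0, 0.5), by = NULL) {
  validate_columns(records, c("measured", "predicted"), "records")
  if (nrow(records) == 0L) stop("acceptance_summary: 'records' is empty")
  groups <- list(overall = seq_len(nrow(records)))
  if (!is.null(by)) {
    validate_columns(records, by, "records")
    groups <- c(groups, split(seq_len(nrow(records)), records[[by]]))
  }
  out <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    for (th in thresholds) {
      n_acc <- sum(abc_accept(records$measured[idx], records$predicted[idx], th))
      out[[length(out) + 1L]] <- data.frame(
        group = g, threshold = th, n = length(idx), n_accepted = n_acc,
        fraction = n_acc / length(idx), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
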