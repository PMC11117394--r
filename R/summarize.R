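#' Average a quantity across each participant's retained iterates
#'
#' Survey summaries operate on one value per participant, obtained by
#' arithmetic averaging over that participant's (accepted) Monte Carlo
#' iterates. Participants with no records are simply absent from the
#' result; callers can compare against the full id list to log exclusions.
#'
#' @param records Data frame with `participant_id` and the value column.
#' @param value_col Name of the column to average.
#' @return Data frame with `participant_id` and `mean_value`.
#' @export
per_participant_mean <- function(records, value_col) {
  validate_columns(records, c("participant_id", value_col), "records")
  agg <- tapply(records[[value_col]], records$participant_id, mean)
  data.frame(participant_id = names(agg), mean_value = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Construct pooled-cycle analysis weights
#'
#' When several survey cycles are pooled, each exam weight is divided by
#' the number of cycles so the pooled sample still represents one
#' population. Strata and PSUs pass through unchanged.
#'
#' @param design Data frame with `survey_weight` (and typically `stratum`,
#'   `psu`, `cycle`).
#' @param n_cycles Number of pooled cycles (default 2).
#' @return `design` with an added `analysis_weight` column.
#' @export
construct_weights <- function(design, n_cycles = 2L) {
  validate_columns(design, "survey_weight", "design")
  if (any(design$survey_weight <= 0)) {
    stop("construct_weights: 'survey_weight' must be positive")
  }
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1) {
    stop("construct_weights: 'n_cycles' must be >= 1")
  }
  design$analysis_weight <- design$survey_weight / n_cycles
  design
}

#' Weighted percentiles (left-continuous inverse CDF)
#'
#' Quantiles of the weighted empirical distribution, defined as
#' `Q(p) = min{x : F(x) >= p}` where `F` is the weighted ECDF. The result
#' is always one of the input values, and with equal weights it reduces to
#' `stats::quantile(..., type = 1)`. The definition is pinned for exact
#' reproducibility and is validated against brute-force expansion of
#' integer weights.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length as `values`.
#' @param probs Probabilities in (0, 1) (default 50/90/95/99th).
#' @return Named numeric vector of percentiles.
#' @export
weighted_percentiles <- function(values, weights = NULL,
                                 probs = c(0.5, 0.9, 0.95, 0.99)) {
  if (length(values) == 0L) stop("weighted_percentiles: 'values' is empty")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) {
    stop("weighted_percentiles: 'values' and 'weights' lengths differ")
  }
  if (any(weights <= 0) || anyNA(weights) || anyNA(values)) {
    stop("weighted_percentiles: weights must be positive and inputs non-missing")
  }
  if (any(probs <= 0) || any(probs >= 1)) {
    stop("weighted_percentiles: 'probs' must lie in (0, 1)")
  }
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / sum(weights)
  out <- vapply(probs, function(p) {
    v[which(cw >= p - 1e-12)[1L]]
  }, numeric(1L))
  names(out) <- paste0("p", format(100 * probs, trim = TRUE))
  out
}

#' Fraction of predictions within a log10 distance of measurements
#'
#' Single-threshold coverage diagnostic: the share of records whose
#' predicted value lies within `c` orders of magnitude of the measured
#' value (delegates to the ABC acceptance rule).
#'
#' @param records Data frame with `measured` and `predicted`.
#' @param c Log10 threshold.
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(records, c) {
  validate_columns(records, c("measured", "predicted"), "records")
  mean(abc_accept(records$measured, records$predicted, c))
}

#' Correlation between predicted and measured biomarker values
#'
#' Pearson correlation of log10 predicted vs log10 measured (the scale on
#' which predictions are thresholded and plotted), computed unweighted as
#' a model-fit indicator. Predictions are floored before the log
#' transform. The raw-scale correlation is attached as attribute
#' `"raw_r"` since the choice of scale is a reporting option.
#'
#' @param records Data frame with `measured` and `predicted` (>= 3 rows).
#' @param floor Floor applied to `predicted` before log10.
#' @return Pearson r on the log10 scale, or `NA` (with a warning) when
#'   either side has zero variance.
#' @export
log_correlation <- function(records, floor = 1e-12) {
  validate_columns(records, c("measured", "predicted"), "records")
  if (nrow(records) < 3L) {
    stop("log_correlation: need at least 3 records")
  }
  lp <- log10(pmax(records$predicted, floor))
  lm_ <- log10(records$measured)
  if (stats::sd(lp) == 0 || stats::sd(lm_) == 0) {
    warning("log_correlation: zero variance; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(lp, lm_)
  }
  raw <- if (stats::sd(records$predicted) == 0 ||
             stats::sd(records$measured) == 0) NA_real_ else {
    stats::cor(records$predicted, records$measured)
  }
  structure(r, raw_r = raw)
}

#' Survey-weighted percentile tables before and after ABC filtering
#'
#' For each requested quantity (day-1 exposure, predicted urinary 3PBA,
#' measured urinary 3PBA) and each filter (unfiltered plus one per ABC
#' threshold), iterates are averaged within participant, weighted with the
#' pooled-cycle analysis weights, and summarized as weighted percentiles.
#' Participants losing every iterate under a threshold are excluded from
#' that filter's rows (their count is `n_total - n`).
#'
#' @param records Prediction records: `participant_id`, `iterate`,
#'   `predicted`, `measured`, `exposure_day1`.
#' @param population Population/design data frame (for weights).
#' @param thresholds ABC thresholds defining the filtered variants.
#' @param n_cycles Pooled survey cycles for [construct_weights()].
#' @param probs Percentile levels.
#' @return Long data frame: `quantity`, `filter`, `percentile`, `value`,
#'   `n` (participants contributing).
#' @export
summary_tables <- function(records, population, thresholds = c(1.0, 0.5),
                           n_cycles = 2L, probs = c(0.5, 0.9, 0.95, 0.99)) {
  validate_columns(records, c("participant_id", "iterate", "predicted",
                              "measured", "exposure_day1"), "records")
  design <- construct_weights(population, n_cycles)
  wt <- stats::setNames(design$analysis_weight, design$participant_id)

  variants <- c(list(unfiltered = records),
                stats::setNames(
                  lapply(thresholds,
                         function(th) filter_iterates(records, th)$accepted),
                  vapply(thresholds,
                         function(th) paste0("c=", format(th, trim = TRUE)),
                         character(1L))))
  quantities <- c(exposure_mgkgday = "exposure_day1",
                  predicted_ugug = "predicted",
                  measured_ugug = "measured")

  out <- list()
  for (fl in names(variants)) {
    recs <- variants[[fl]]
    if (nrow(recs) == 0L) next
    for (qn in names(quantities)) {
      pm <- per_participant_mean(recs, quantities[[qn]])
      w <- wt[pm$participant_id]
      pct <- weighted_percentiles(pm$mean_value, w, probs)
      out[[length(out) + 1L]] <- data.frame(
        quantity = qn, filter = fl, percentile = 100 * probs,
        value = as.numeric(pct), n = nrow(pm), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Accept/reject scatter of predicted vs measured values
#'
#' Log-log scatter of predictions against measurements with points
#' coloured by ABC acceptance at the given threshold (accepted black,
#' rejected red), the identity line, and dashed lines at +/- c.
#'
#' @param records Data frame with `measured` and `predicted`.
#' @param c ABC threshold used for colouring.
#' @param floor Floor applied to predictions before log10.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_accept_reject <- function(records, c = 1.0, floor = 1e-12) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_accept_reject requires the 'ggplot2' package")
  }
  validate_columns(records, c("measured", "predicted"), "records")
  df <- data.frame(
    lm_ = log10(records$measured),
    lp = log10(pmax(records$predicted, floor)),
    accepted = abc_accept(records$measured, pmax(records$predicted, floor), c)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lm_, y = .data$lp,
                                   colour = .data$accepted)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-c, c), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red"),
                                 name = paste0("|log10 diff| < ", c)) +
    ggplot2::labs(x = "log10 measured urinary 3PBA (ug/ug creatinine)",
                  y = "log10 predicted urinary 3PBA (ug/ug creatinine)")
}
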