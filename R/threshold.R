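#' Threshold-based dropout-phase detection
#'
#' Scans per-question dropout proportions against user-specified start and
#' end thresholds: the first question whose dropout proportion strictly
#' exceeds the start threshold is the beginning of the dropout phase, and
#' the last question strictly exceeding the end threshold is its end.
#' "Exceeds" is strict, so a proportion exactly at the threshold does not
#' trigger. The thresholds express what amount of per-question dropout the
#' analyst considers practically meaningful; the smaller they are, the more
#' sensitive the scan.
#'
#' Questions with nobody left at risk have an undefined conditional
#' proportion and terminate the scanned range; if no question is scannable
#' the detection is degenerate.
#'
#' @param x A [dropout_data] or [dropout_summary] object.
#' @param start_threshold,end_threshold Proportions in \[0, 1\] (default
#'   0.03 each; the two may differ).
#' @param mode Proportion definition when `x` is raw data: `"conditional"`
#'   (discrete hazard, default) or `"marginal"` (out of the original
#'   sample). Ignored when `x` is already a summary.
#' @return A `"phase_detection"` object; `$flags` holds the per-question
#'   exceedance indicators (list with `start` and `end` logical vectors).
#' @examples
#' d <- dropout_data(c(rep(3, 12), rep(4, 10), rep(NA, 178)),
#'                   n_questions = 17)
#' detect_threshold(d, 0.03, 0.03)
#' @export
detect_threshold <- function(x, start_threshold = 0.03, end_threshold = 0.03,
                             mode = c("conditional", "marginal")) {
  if (inherits(x, "dropout_data")) {
    s <- dropout_summary(x, mode = match.arg(mode))
  } else if (inherits(x, "dropout_summary")) {
    s <- x
  } else stop("`x` must be dropout_data or a dropout_summary", call. = FALSE)
  if (any(c(start_threshold, end_threshold) < 0) ||
      any(c(start_threshold, end_threshold) > 1))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  K <- nrow(s)
  params <- list(start_threshold = start_threshold,
                 end_threshold = end_threshold, mode = attr(s, "mode"))
  scannable <- which(!is.na(s$proportion))
  # undefined proportions can only be a tail (at-risk counts are
  # nonincreasing), so the scannable range is a prefix
  if (!length(scannable))
    return(new_phase_detection("threshold", K, NA_integer_, NA_integer_,
                               earliest = 1L, fit_status = "degenerate",
                               params = params))
  rng <- seq_len(max(scannable))
  p <- s$proportion[rng]
  over_start <- p > start_threshold
  over_end <- p > end_threshold
  start <- if (any(over_start)) min(which(over_start)) else NA_integer_
  end <- if (any(over_end)) max(which(over_end)) else NA_integer_
  # with unequal thresholds the two scans can disagree on whether a phase
  # exists (or cross); report no phase in that case, keeping start <= end
  if (is.na(start) || is.na(end) || end < start) {
    start <- NA_integer_; end <- NA_integer_
  }
  new_phase_detection("threshold", K, start, end, earliest = 1L,
                      flags = list(start = over_start, end = over_end),
                      params = params)
}
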