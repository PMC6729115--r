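# Shared phase-detection container and boundary/phase-count conventions.

#' Phase-count rule
#'
#' Converts detected dropout-phase boundaries into an implied number of
#' attrition phases:
#'
#' * no boundaries at all — no meaningful/significant attrition anywhere —
#'   one (stable) phase;
#' * boundaries spanning the whole scannable range (start at the earliest
#'   possible position *and* end at the latest) — the dropout phase covers
#'   the whole survey, again a single phase;
#' * exactly one of the two boundaries interior — two phases;
#' * both interior — three phases.
#'
#' The earliest possible position is question 1 for the threshold scan and
#' question 2 for the contrast-based detectors (the first adjacent pair is
#' (1, 2) and boundaries are reported as the later index of a pair); the
#' latest is question K for all methods.
#'
#' @param start,end Detected boundaries (question index) or `NA` for none.
#' @param K Number of questions.
#' @param earliest Earliest position a start boundary can take (1 or 2).
#' @return Integer in 1..3.
#' @examples
#' count_phases(NA, NA, 20)        # 1
#' count_phases(1, 20, 20)         # 1 (dropout throughout)
#' count_phases(10, 14, 20)        # 3
#' @export
count_phases <- function(start, end, K, earliest = 1L) {
  if (is.na(start) && is.na(end)) return(1L)
  if (is.na(start) || is.na(end))
    stop("boundaries must be both present or both absent", call. = FALSE)
  1L + (start > earliest) + (end < K)
}

new_phase_detection <- function(method, K, start, end, earliest,
                                fit_status = "ok", flags = NULL,
                                contrasts = NULL, params = list()) {
  start <- as.integer(start); end <- as.integer(end)
  n_phases <- if (fit_status == "ok") count_phases(start, end, K, earliest)
              else NA_integer_
  structure(list(method = method, K = K,
                 start_question = start, end_question = end,
                 n_phases = n_phases, earliest = earliest,
                 fit_status = fit_status, flags = flags,
                 contrasts = contrasts, params = params),
            class = "phase_detection")
}

#' @export
print.phase_detection <- function(x, ...) {
  cat("Dropout-phase detection (method: ", x$method, ")\n", sep = "")
  if (x$fit_status != "ok") {
    cat("  fit status:", x$fit_status, "- no boundaries reported\n")
    return(invisible(x))
  }
  if (is.na(x$start_question)) {
    cat("  no meaningful/significant attrition detected;",
        "single stable phase\n")
  } else {
    cat("  dropout phase: questions ", x$start_question, " to ",
        x$end_question, " (of ", x$K, ")\n", sep = "")
  }
  cat("  implied number of phases:", x$n_phases, "\n")
  invisible(x)
}

# boundary convention for contrast-based detectors: the later question index
# of the first / last significant adjacent pair
contrast_boundaries <- function(ct) {
  sig <- ct$later[ct$significant]
  if (!length(sig)) c(NA_integer_, NA_integer_)
  else c(min(sig), max(sig))
}
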