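# Simulation-study orchestration: metrics, histograms, and the full grid.

usable <- function(detections) {
  vapply(detections, function(d) d$fit_status == "ok", logical(1L))
}

#' Type I error of a detector under a constant pattern
#'
#' The fraction of usable replicates in which at least two attrition phases
#' were detected although the simulated dropout hazard was constant (phases
#' detected when none exist). Replicates with failed or degenerate fits are
#' excluded from the denominator by default; `failed_as_null = TRUE`
#' instead counts them as non-detections.
#'
#' @param detections List of `"phase_detection"` objects from
#'   constant-pattern replicates.
#' @param failed_as_null Count unusable replicates as "one phase detected"?
#' @return Proportion in \[0, 1\].
#' @export
type_i_error <- function(detections, failed_as_null = FALSE) {
  ok <- usable(detections)
  ph <- vapply(detections[ok], `[[`, integer(1L), "n_phases")
  den <- if (failed_as_null) length(detections) else sum(ok)
  if (den == 0L) stop("no usable replicates", call. = FALSE)
  sum(ph >= 2L) / den
}

#' Sensitivity of a detector under a phased pattern
#'
#' The fraction of usable replicates in which the detected number of phases
#' equals the true number simulated (2 or 3).
#'
#' @inheritParams type_i_error
#' @param true_n_phases True number of phases in the simulated pattern.
#' @return Proportion in \[0, 1\].
#' @export
sensitivity <- function(detections, true_n_phases, failed_as_null = FALSE) {
  stopifnot(true_n_phases %in% 2:3)
  ok <- usable(detections)
  ph <- vapply(detections[ok], `[[`, integer(1L), "n_phases")
  den <- if (failed_as_null) length(detections) else sum(ok)
  if (den == 0L) stop("no usable replicates", call. = FALSE)
  sum(ph == true_n_phases) / den
}

#' Boundary-choice histograms
#'
#' Tabulates how often each question was chosen as the start and as the end
#' of the dropout phase across replicates, with a `none` bin for replicates
#' detecting no phase. Unusable (failed/degenerate) replicates are excluded;
#' each histogram sums to the number of usable replicates.
#'
#' @param detections List of `"phase_detection"` objects.
#' @param K Number of questions; taken from the first detection if omitted.
#' @return List with components `start` and `end`, each a named integer
#'   vector over `1..K` and `"none"`.
#' @export
boundary_histogram <- function(detections, K = NULL) {
  if (is.null(K))
    K <- if (length(detections)) detections[[1L]]$K else
      stop("`K` required for an empty detection list", call. = FALSE)
  ok <- usable(detections)
  tab <- function(field) {
    v <- vapply(detections[ok], `[[`, integer(1L), field)
    counts <- tabulate(v[!is.na(v)], nbins = K)
    stats::setNames(c(counts, sum(is.na(v))), c(seq_len(K), "none"))
  }
  list(start = tab("start_question"), end = tab("end_question"))
}

detector_for <- function(method, alpha, start_threshold, end_threshold,
                         mode, ...) {
  switch(method,
    threshold = function(d) detect_threshold(d, start_threshold,
                                             end_threshold, mode),
    glmm = function(d) detect_glmm(d, alpha = alpha, ...),
    dtsa = function(d) detect_dtsa(d, alpha = alpha),
    stop("unknown method: ", method, call. = FALSE))
}

#' Run the attrition-detection simulation study
#'
#' For every pattern x method cell: simulates a batch of monotone dropout
#' datasets ([simulate_batch()]), applies the detector to each replicate,
#' and computes type I error (patterns with one true phase) or sensitivity
#' (patterns with two or three), together with boundary-choice histograms
#' and fit-failure counts. Each cell draws from its own deterministic
#' seed sequence derived from `master_seed` and the cell's position, so the
#' whole study is reproducible and cells are independent.
#'
#' @param patterns List of [attrition_pattern] objects (default: the full
#'   [study_patterns()] grid).
#' @param methods Character vector among `"threshold"`, `"glmm"`, `"dtsa"`.
#' @param n_replicates Replicates per cell: a single number, or a named
#'   vector like `c(threshold = 10000, glmm = 500, dtsa = 1000)` to give
#'   the costlier model-based detectors smaller batches.
#' @param master_seed Integer master seed (required; the study refuses to
#'   run unseeded).
#' @param n_participants Participants per simulated dataset (default 200).
#' @param alpha Significance level for the contrast-based detectors.
#' @param start_threshold,end_threshold,mode Threshold-detector settings.
#' @param failed_as_null Passed to [type_i_error()] / [sensitivity()].
#' @param verbose Print one line per finished cell?
#' @param ... Additional arguments passed to [detect_glmm()] (e.g. `nAGQ`).
#' @return An object of class `"attrition_study"`: list with `table` (one
#'   row per cell: shape, severity, location, method, metric, value,
#'   n_effective, n_failed, n_replicates) and `histograms` (named list of
#'   [boundary_histogram()] results), plus the configuration echo.
#' @examples
#' pats <- list(attrition_pattern("constant", "severe"))
#' st <- run_study(pats, methods = "threshold", n_replicates = 50,
#'                 master_seed = 1)
#' st$table
#' @export
run_study <- function(patterns = study_patterns(),
                      methods = c("threshold", "glmm", "dtsa"),
                      n_replicates = 1000, master_seed,
                      n_participants = 200, alpha = 0.05,
                      start_threshold = 0.03, end_threshold = 0.03,
                      mode = "conditional", failed_as_null = FALSE,
                      verbose = FALSE, ...) {
  if (missing(master_seed) || is.null(master_seed))
    stop("`master_seed` is required: the study does not run unseeded",
         call. = FALSE)
  if (inherits(patterns, "attrition_pattern")) patterns <- list(patterns)
  methods <- match.arg(methods, several.ok = TRUE)
  reps_for <- function(method) {
    if (length(n_replicates) == 1L && is.null(names(n_replicates)))
      return(as.integer(n_replicates))
    if (!method %in% names(n_replicates))
      stop("n_replicates has names but none for method ", method,
           call. = FALSE)
    as.integer(n_replicates[[method]])
  }
  rows <- list(); hists <- list()
  cell <- 0L
  for (pi in seq_along(patterns)) {
    pat <- patterns[[pi]]
    for (method in methods) {
      cell <- cell + 1L
      reps <- reps_for(method)
      det_fun <- detector_for(method, alpha, start_threshold,
                              end_threshold, mode, ...)
      cell_seed <- (master_seed + 7919L * cell) %% .Machine$integer.max
      detections <- simulate_batch(pat, reps, master_seed = cell_seed,
                                   n_participants = n_participants,
                                   FUN = det_fun)
      ok <- usable(detections)
      metric <- if (pat$true_n_phases == 1L) "type_i_error" else "sensitivity"
      value <- if (metric == "type_i_error")
        type_i_error(detections, failed_as_null)
      else sensitivity(detections, pat$true_n_phases, failed_as_null)
      key <- paste(pat$name, method, sep = "/")
      rows[[key]] <- data.frame(
        shape = pat$shape, severity = pat$severity, location = pat$location,
        method = method, metric = metric, value = value,
        n_effective = sum(ok), n_failed = sum(!ok),
        n_replicates = reps, stringsAsFactors = FALSE)
      hists[[key]] <- boundary_histogram(detections, K = length(pat$hazards))
      if (verbose)
        message(sprintf("%-40s %-9s %s = %.3f (failed %d/%d)", pat$name,
                        method, metric, value, sum(!ok), reps))
    }
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 histograms = hists,
                 config = list(master_seed = master_seed,
                               n_participants = n_participants,
                               alpha = alpha,
                               start_threshold = start_threshold,
                               end_threshold = end_threshold,
                               mode = mode, failed_as_null = failed_as_null,
                               rates = patterns[[1L]]$rates)),
            class = "attrition_study")
}

#' @export
print.attrition_study <- function(x, ...) {
  cat("Attrition-detection simulation study (seed ", x$config$master_seed,
      ", n = ", x$config$n_participants, " per dataset)\n", sep = "")
  print.data.frame(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot boundary-choice histograms for one study cell
#'
#' Paired bar charts of how often each question was chosen as the start and
#' end of the dropout phase in one pattern x method cell of an
#' [run_study()] result.
#'
#' @param x An `"attrition_study"` object.
#' @param cell Name of the cell (`"<pattern name>/<method>"`; see
#'   `names(x$histograms)`). Defaults to the first cell.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the histogram list for the cell.
#' @export
plot.attrition_study <- function(x, cell = names(x$histograms)[1L], ...) {
  h <- x$histograms[[cell]]
  if (is.null(h)) stop("no such cell: ", cell, call. = FALSE)
  total <- max(sum(h$start), 1L)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(100 * h$start / total, main = paste0(cell, ": start"),
                    xlab = "question", ylab = "% of simulations", ...)
  graphics::barplot(100 * h$end / total, main = paste0(cell, ": end"),
                    xlab = "question", ylab = "% of simulations", ...)
  invisible(h)
}

#' Write study outputs as CSV
#'
#' Writes the metric table (`table1.csv`) and one histogram CSV per cell
#' (`hist_<cell>.csv`) into a directory.
#'
#' @param x An `"attrition_study"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_study <- function(x, dir) {
  stopifnot(inherits(x, "attrition_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$table, file.path(dir, "table1.csv"), row.names = FALSE)
  for (key in names(x$histograms)) {
    h <- x$histograms[[key]]
    safe <- gsub("/", "_", key)
    utils::write.csv(data.frame(bin = names(h$start), start = h$start,
                                end = h$end),
                     file.path(dir, paste0("hist_", safe, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
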