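#' Survey design
#'
#' A minimal description of a fixed, ordered battery of survey questions.
#' Questions are indexed 1..K. At least two questions are required, since
#' every detector in this package works on comparisons between adjacent
#' questions.
#'
#' @param n_questions Number of ordered questions (integer, >= 2).
#' @return An object of class `"survey_design"`.
#' @examples
#' survey_design(20)
#' @export
survey_design <- function(n_questions) {
  n_questions <- as.integer(n_questions)
  if (length(n_questions) != 1L || is.na(n_questions) || n_questions < 2L)
    stop("`n_questions` must be a single integer >= 2", call. = FALSE)
  structure(list(n_questions = n_questions), class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Survey design:", x$n_questions, "ordered questions\n")
  invisible(x)
}

#' Monotone dropout records
#'
#' Represents the completion process of a survey with monotone dropout:
#' `exit_question = q` means the participant answered questions `1..q-1` and
#' then stopped (so `q = 1` means they started but answered nothing), while
#' `NA` marks a completer who answered all K questions. Re-entry after
#' dropping out is not representable, by construction.
#'
#' @param exit_question Integer vector; for each participant, the question at
#'   which they dropped out (1..K), or `NA` for completers.
#' @param n_questions Number of questions K, or a [survey_design].
#' @param participant_id Optional vector of unique participant identifiers;
#'   defaults to `"p1".."pN"`.
#' @return An object of class `"dropout_data"`: a list with elements
#'   `design`, `participant_id`, and `exit_question`.
#' @seealso [dropout_from_wide()], [to_cumulative()], [to_person_period()],
#'   [dropout_summary()]
#' @examples
#' d <- dropout_data(c(3, NA, 1, NA), n_questions = 5)
#' d
#' dropout_summary(d)
#' @export
dropout_data <- function(exit_question, n_questions, participant_id = NULL) {
  design <- if (inherits(n_questions, "survey_design")) n_questions
            else survey_design(n_questions)
  K <- design$n_questions
  exit_question <- as.integer(exit_question)
  n <- length(exit_question)
  if (is.null(participant_id)) participant_id <- paste0("p", seq_len(n))
  participant_id <- as.character(participant_id)
  if (length(participant_id) != n)
    stop("`participant_id` and `exit_question` lengths differ", call. = FALSE)
  if (anyDuplicated(participant_id))
    stop("participant ids must be unique", call. = FALSE)
  bad <- !is.na(exit_question) & (exit_question < 1L | exit_question > K)
  if (any(bad))
    stop("exit_question values must lie in 1..", K, " or be NA (completed)",
         call. = FALSE)
  structure(list(design = design,
                 participant_id = participant_id,
                 exit_question = exit_question),
            class = "dropout_data")
}

# internal fast path: inputs already validated (simulator hot loop)
new_dropout_data <- function(exit_question, design) {
  structure(list(design = design,
                 participant_id = paste0("p", seq_along(exit_question)),
                 exit_question = exit_question),
            class = "dropout_data")
}

#' @export
print.dropout_data <- function(x, ...) {
  n <- length(x$exit_question)
  nc <- sum(is.na(x$exit_question))
  cat("Dropout data: ", n, " participants, ", x$design$n_questions,
      " questions\n", sep = "")
  cat("  completed: ", nc, " (", round(100 * nc / max(n, 1), 1), "%), ",
      "dropped out: ", n - nc, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dropout_data <- function(x, ...) {
  data.frame(participant_id = x$participant_id,
             exit_question = x$exit_question,
             stringsAsFactors = FALSE)
}

#' @export
length.dropout_data <- function(x) length(x$exit_question)

#' Build dropout records from a wide response matrix
#'
#' Converts a wide answers table (one row per participant, one column per
#' question, any non-missing value meaning "answered") into monotone
#' [dropout_data]. The exit question is the first unanswered question; a row
#' with an answered question after its first gap violates monotone dropout
#' and is either rejected (`nonmonotone = "error"`) or coerced to a dropout
#' at the first gap (`nonmonotone = "coerce"`, with a warning reporting the
#' number of coerced rows).
#'
#' @param x A data frame or matrix. If it has a `participant_id` column (or
#'   `id_col` names one), that column supplies identifiers and the remaining
#'   columns are the K answer columns in question order.
#' @param nonmonotone Policy for rows that answer a question after a gap.
#' @param missing_values Values treated as "unanswered" in addition to `NA`
#'   (default: the empty string).
#' @param id_col Name of the identifier column, if present.
#' @return A [dropout_data] object; the number of coerced rows is attached
#'   as attribute `"n_coerced"`.
#' @examples
#' wide <- data.frame(participant_id = c("a", "b"),
#'                    Q1 = c("x", "x"), Q2 = c("y", NA), Q3 = c("z", NA))
#' dropout_from_wide(wide)
#' @export
dropout_from_wide <- function(x, nonmonotone = c("error", "coerce"),
                              missing_values = "", id_col = "participant_id") {
  nonmonotone <- match.arg(nonmonotone)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (id_col %in% names(x)) {
    ids <- as.character(x[[id_col]])
    ans <- x[setdiff(names(x), id_col)]
  } else {
    ids <- rownames(x)
    ans <- x
  }
  K <- ncol(ans)
  if (K < 2L)
    stop("need at least 2 answer columns, got ", K, call. = FALSE)
  answered <- !vapply(ans, function(col) {
    is.na(col) | (as.character(col) %in% missing_values)
  }, logical(nrow(ans)))
  if (nrow(ans) == 1L) answered <- matrix(answered, nrow = 1L)
  first_gap <- apply(answered, 1L, function(r) match(FALSE, r))
  answered_after_gap <- vapply(seq_len(nrow(answered)), function(i) {
    g <- first_gap[i]
    !is.na(g) && g < K && any(answered[i, (g + 1L):K])
  }, logical(1L))
  if (any(answered_after_gap)) {
    if (nonmonotone == "error")
      stop(sum(answered_after_gap), " row(s) answer a question after a gap; ",
           "monotone dropout violated (use nonmonotone = \"coerce\" to force ",
           "dropout at the first gap)", call. = FALSE)
    warning(sum(answered_after_gap),
            " nonmonotone row(s) coerced to dropout at the first gap",
            call. = FALSE)
  }
  out <- dropout_data(first_gap, n_questions = K, participant_id = ids)
  attr(out, "n_coerced") <- sum(answered_after_gap)
  out
}

#' Cumulative dropout indicators (long format)
#'
#' Expands dropout records to exactly K rows per participant with a binary
#' `dropped_by` indicator: 1 from the exit question onward, 0 before it, all
#' 0 for completers. This is the outcome format for the cumulative-dropout
#' mixed model ([fit_glmm()]); rows after dropout are retained.
#'
#' @param x A [dropout_data] object.
#' @return A data frame with columns `participant_id`, `question`,
#'   `dropped_by`; `dropped_by` is nondecreasing in `question` within each
#'   participant.
#' @export
to_cumulative <- function(x) {
  stopifnot(inherits(x, "dropout_data"))
  K <- x$design$n_questions
  n <- length(x$exit_question)
  q <- rep(seq_len(K), times = n)
  ex <- rep(x$exit_question, each = K)
  data.frame(participant_id = rep(x$participant_id, each = K),
             question = q,
             dropped_by = as.integer(!is.na(ex) & q >= ex),
             stringsAsFactors = FALSE)
}

#' Person-period (discrete-time survival) format
#'
#' Expands dropout records to one row per participant per question *reached*:
#' a participant exiting at question q contributes rows for questions `1..q`
#' with `event = 1` only in the last row; a completer contributes K
#' event-free rows (censored after the last question).
#'
#' @param x A [dropout_data] object.
#' @return A data frame with columns `participant_id`, `question`, `event`.
#' @export
to_person_period <- function(x) {
  stopifnot(inherits(x, "dropout_data"))
  K <- x$design$n_questions
  last <- ifelse(is.na(x$exit_question), K, x$exit_question)
  idx <- rep(seq_along(last), times = last)
  q <- sequence(last)
  data.frame(participant_id = x$participant_id[idx],
             question = q,
             event = as.integer(q == last[idx] & !is.na(x$exit_question[idx])),
             stringsAsFactors = FALSE)
}

#' Recover dropout records from a person-period table
#'
#' Inverse of [to_person_period()]: each participant's exit question is the
#' question of their single `event = 1` row, or `NA` (completed) if they have
#' none.
#'
#' @param x A data frame with columns `participant_id`, `question`, `event`.
#' @param n_questions Number of questions K; defaults to the maximum question
#'   present.
#' @return A [dropout_data] object.
#' @export
from_person_period <- function(x, n_questions = max(x$question)) {
  stopifnot(all(c("participant_id", "question", "event") %in% names(x)))
  ids <- unique(x$participant_id)
  ex <- vapply(ids, function(id) {
    rows <- x[x$participant_id == id, ]
    hit <- rows$question[rows$event == 1]
    if (length(hit) > 1L)
      stop("participant ", id, " has more than one event row", call. = FALSE)
    if (length(hit)) as.integer(hit) else NA_integer_
  }, integer(1L))
  dropout_data(ex, n_questions = n_questions, participant_id = ids)
}

#' Per-question dropout summary
#'
#' Tabulates, for each question q, the number of participants still at risk
#' (those whose exit question is >= q, completers included), the number who
#' dropped out exactly at q, and the dropout proportion. Two proportion
#' definitions are supported: `"conditional"` (the empirical discrete hazard,
#' dropouts at q divided by participants at risk at q — the default) and
#' `"marginal"` (dropouts at q divided by the original sample size).
#'
#' @param x A [dropout_data] object.
#' @param mode Proportion definition, `"conditional"` or `"marginal"`.
#' @return A data frame of class `"dropout_summary"` with columns `question`,
#'   `n_at_risk`, `n_dropped`, `proportion`. A conditional proportion at a
#'   question with nobody at risk is `NA` (undefined), not 0. Attributes:
#'   `mode`, `n_total`, `n_completed`.
#' @examples
#' d <- dropout_data(c(1, 1, 2, 2, rep(NA, 6)), n_questions = 3)
#' dropout_summary(d)                     # hazards 2/10, 2/8, 0/6
#' dropout_summary(d, mode = "marginal")  # 2/10, 2/10, 0/10
#' @export
dropout_summary <- function(x, mode = c("conditional", "marginal")) {
  stopifnot(inherits(x, "dropout_data"))
  mode <- match.arg(mode)
  K <- x$design$n_questions
  N <- length(x$exit_question)
  n_dropped <- tabulate(x$exit_question, nbins = K)
  n_at_risk <- N - cumsum(c(0L, n_dropped[-K]))
  proportion <- if (mode == "conditional") {
    ifelse(n_at_risk > 0L, n_dropped / n_at_risk, NA_real_)
  } else {
    n_dropped / N
  }
  out <- data.frame(question = seq_len(K),
                    n_at_risk = n_at_risk,
                    n_dropped = n_dropped,
                    proportion = proportion)
  attr(out, "mode") <- mode
  attr(out, "n_total") <- N
  attr(out, "n_completed") <- N - sum(n_dropped)
  class(out) <- c("dropout_summary", "data.frame")
  out
}

#' @export
summary.dropout_data <- function(object,
                                 mode = c("conditional", "marginal"), ...) {
  dropout_summary(object, mode = match.arg(mode))
}

#' @export
print.dropout_summary <- function(x, ...) {
  cat("Per-question dropout (", attr(x, "mode"), " proportions), N = ",
      attr(x, "n_total"), ", completed = ", attr(x, "n_completed"),
      "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# ---- plain-text interchange -------------------------------------------------

#' Read and write dropout-record CSV files
#'
#' Dropout-record CSV: header `participant_id,exit_question`, with
#' `exit_question` blank or the literal `completed` for completers.
#'
#' @param path File path.
#' @param n_questions Number of questions K (required on read; the records
#'   alone do not determine it).
#' @param x A [dropout_data] object (write).
#' @return `read_dropout_records()` returns a [dropout_data];
#'   `write_dropout_records()` returns `path` invisibly.
#' @export
read_dropout_records <- function(path, n_questions) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(exit_question = "character"))
  ex <- trimws(df$exit_question)
  ex[ex %in% c("", "completed", "NA")] <- NA
  dropout_data(as.integer(ex), n_questions = n_questions,
               participant_id = df$participant_id)
}

#' @rdname read_dropout_records
#' @export
write_dropout_records <- function(x, path) {
  stopifnot(inherits(x, "dropout_data"))
  ex <- ifelse(is.na(x$exit_question), "completed", x$exit_question)
  utils::write.csv(data.frame(participant_id = x$participant_id,
                              exit_question = ex),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide survey-response CSV
#'
#' Wide CSV: header `participant_id,Q1,...,QK`; an empty cell (or any value
#' listed in `missing_values`) means the question was not answered.
#'
#' @inheritParams dropout_from_wide
#' @param path File path.
#' @return A [dropout_data] object.
#' @export
read_wide_survey <- function(path, nonmonotone = c("error", "coerce"),
                             missing_values = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  dropout_from_wide(df, nonmonotone = match.arg(nonmonotone),
                    missing_values = missing_values)
}

#' Read a person-period CSV
#'
#' Person-period CSV: header `participant_id,question,event`.
#'
#' @param path File path.
#' @param n_questions Number of questions K; defaults to the maximum question
#'   present in the file.
#' @return A [dropout_data] object.
#' @export
read_person_period <- function(path, n_questions = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(n_questions)) n_questions <- max(df$question)
  from_person_period(df, n_questions = n_questions)
}
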