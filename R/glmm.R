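#' Cumulative-dropout generalized linear mixed model
#'
#' Fits a logistic mixed model to the cumulative dropout indicator: for
#' participant i and question q the outcome is whether i has dropped out of
#' the survey *by* question q, modelled as
#' `logit P(dropped_by[iq] = 1 | b_i) = beta_q + b_i` with
#' `b_i ~ N(0, sigma^2)` a participant random intercept absorbing the
#' within-participant dependence of the K indicators. The question effects
#' use a cell-means parameterization (one coefficient per question, no
#' global intercept), so successive-difference contrasts on the
#' coefficients compare adjacent questions directly.
#'
#' Because cumulative dropout is monotone within a participant, the random
#' intercept can separate completers from early dropouts and the variance
#' component is typically estimated very large; the marginal likelihood is
#' nearly flat in that direction. Estimation therefore defaults to lme4's
#' penalized iteratively reweighted least squares step on the Laplace
#' objective (`nAGQ = 0`), which is fast and deterministic on such
#' quasi-separated data; full Laplace (`nAGQ = 1`) or adaptive quadrature
#' can be requested and is attempted with a small retry ladder
#' (restarting from perturbed parameters) before the fit is declared
#' failed.
#'
#' @param x A [dropout_data] object, or a long data frame with columns
#'   `participant_id`, `question`, `dropped_by` (one row per participant
#'   per question).
#' @param nAGQ Integration setting passed to [lme4::glmer()]; 0 (default)
#'   for the PIRLS fit, 1 for Laplace, >1 for adaptive Gauss-Hermite.
#' @param retries Number of restarts with perturbed starting values before
#'   declaring a non-PIRLS fit failed.
#' @param random_intercept If `FALSE`, the random-intercept variance is
#'   fixed at zero, which reduces the model to independent per-cell
#'   logistic regression; its cell-means MLE is the empirical logit of each
#'   question's cumulative dropout proportion.
#' @return An object of class `"attrition_glmm"`: list with `coefficients`
#'   (K question effects on the logit scale, in question order), `vcov`,
#'   `re_sd` (random-intercept SD), `converged`, `status` (`"ok"`,
#'   `"degenerate"` or `"failed"`), `n_participants`, `K`, `nAGQ`,
#'   `messages`.
#' @seealso [detect_glmm()]
#' @export
fit_glmm <- function(x, nAGQ = 0, retries = 2, random_intercept = TRUE) {
  if (inherits(x, "dropout_data")) x <- to_cumulative(x)
  stopifnot(all(c("participant_id", "question", "dropped_by") %in% names(x)))
  K <- max(x$question)
  n <- length(unique(x$participant_id))
  y <- x$dropped_by
  base <- list(coefficients = rep(NA_real_, K), vcov = NULL, re_sd = NA_real_,
               converged = FALSE, status = "failed", n_participants = n,
               K = K, nAGQ = nAGQ, messages = character(0))
  if (all(y == 0L) || all(y == 1L)) {
    base$status <- "degenerate"
    base$messages <- "outcome constant (no dropout, or everyone dropped out)"
    return(structure(base, class = "attrition_glmm"))
  }
  dat <- data.frame(y = y,
                    question = factor(x$question, levels = seq_len(K)),
                    id = factor(x$participant_id))
  if (!random_intercept) {
    m0 <- stats::glm(y ~ 0 + question, data = dat,
                     family = stats::binomial())
    b <- stats::coef(m0)
    V <- as.matrix(stats::vcov(m0))
    ord <- order(as.integer(sub("^question", "", names(b))))
    base$coefficients <- unname(b[ord])
    base$vcov <- unname(V[ord, ord, drop = FALSE])
    base$re_sd <- 0
    base$converged <- m0$converged
    base$status <- if (m0$converged) "ok" else "failed"
    return(structure(base, class = "attrition_glmm"))
  }
  msgs <- character(0)
  fit_once <- function(start = NULL) {
    withCallingHandlers(
      lme4::glmer(y ~ 0 + question + (1 | id), data = dat,
                  family = stats::binomial(), nAGQ = nAGQ, start = start),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  m <- tryCatch(fit_once(), error = function(e) {
    msgs <<- c(msgs, conditionMessage(e)); NULL
  })
  if (nAGQ > 0) {
    attempt <- 0
    while (attempt < retries &&
           (is.null(m) || length(m@optinfo$conv$lme4$messages) > 0)) {
      attempt <- attempt + 1
      start <- if (is.null(m)) NULL else
        list(theta = lme4::getME(m, "theta") * stats::runif(1, 0.5, 1.5))
      m2 <- tryCatch(fit_once(start), error = function(e) {
        msgs <<- c(msgs, conditionMessage(e)); NULL
      })
      if (!is.null(m2)) m <- m2
    }
  }
  base$messages <- unique(msgs)
  if (is.null(m)) return(structure(base, class = "attrition_glmm"))
  b <- lme4::fixef(m)
  V <- as.matrix(stats::vcov(m))
  ord <- order(as.integer(sub("^question", "", names(b))))
  b <- b[ord]; V <- V[ord, ord, drop = FALSE]
  opt_ok <- is.null(m@optinfo$conv$opt) || m@optinfo$conv$opt == 0
  lme4_ok <- length(m@optinfo$conv$lme4$messages %||% character(0)) == 0
  vcov_ok <- all(is.finite(V)) && all(diag(V) > 0)
  base$coefficients <- unname(b)
  base$vcov <- unname(V)
  base$re_sd <- sqrt(unname(lme4::VarCorr(m)$id[1L, 1L]))
  base$converged <- opt_ok && lme4_ok && vcov_ok
  base$status <- if (vcov_ok && opt_ok) "ok" else "failed"
  structure(base, class = "attrition_glmm")
}

#' @export
coef.attrition_glmm <- function(object, ...) {
  stats::setNames(object$coefficients, paste0("q", seq_len(object$K)))
}

#' @export
vcov.attrition_glmm <- function(object, ...) object$vcov

#' @export
print.attrition_glmm <- function(x, ...) {
  cat("Cumulative-dropout logistic mixed model (cell-means, K = ", x$K,
      ", n = ", x$n_participants, ")\n", sep = "")
  cat("  status: ", x$status,
      if (!x$converged && x$status == "ok") " (convergence not verified)",
      "; random-intercept SD: ",
      if (is.na(x$re_sd)) "NA" else format(x$re_sd, digits = 4),
      "\n", sep = "")
  if (x$status == "ok") {
    p <- stats::plogis(x$coefficients)
    cat("  fitted P(dropped out by question q), subject-specific scale:\n")
    print(round(stats::setNames(p, paste0("q", seq_len(x$K))), 4))
  }
  invisible(x)
}

#' Dropout-phase detection via the cumulative-dropout GLMM
#'
#' Fits [fit_glmm()] and tests the K-1 successive-difference contrasts on
#' the question effects with two-sided Wald tests, Benjamini-Hochberg
#' adjusted at `alpha`. The start of the dropout phase is the later
#' question of the first significant adjacent pair, the end that of the
#' last significant pair; no significant pair means a single stable phase,
#' and a significant span covering questions 2..K is read as dropout
#' throughout (one phase). Fit failures and degenerate outcomes yield a
#' detection with the corresponding `fit_status` and no boundaries.
#'
#' @param x A [dropout_data] object or cumulative-dropout long data frame.
#' @param alpha Significance level on BH-adjusted p-values (default 0.05).
#' @param ... Passed to [fit_glmm()].
#' @return A `"phase_detection"` object with the `"contrast_result"` table
#'   in `$contrasts` and the fitted model in `$fit`.
#' @export
detect_glmm <- function(x, alpha = 0.05, ...) {
  f <- fit_glmm(x, ...)
  K <- f$K
  if (f$status != "ok") {
    out <- new_phase_detection("glmm", K, NA_integer_, NA_integer_,
                               earliest = 2L, fit_status = f$status,
                               params = list(alpha = alpha))
    out$fit <- f
    return(out)
  }
  ct <- contrast_test(f$coefficients, f$vcov, alpha = alpha)
  bounds <- contrast_boundaries(ct)
  out <- new_phase_detection("glmm", K, bounds[1L], bounds[2L],
                             earliest = 2L, contrasts = ct,
                             params = list(alpha = alpha))
  out$fit <- f
  out
}
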