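#' Discrete-time survival model of dropout
#'
#' Treats dropout as a time-to-event outcome on the discrete question grid
#' and fits the person-period logistic model with a step-function baseline
#' hazard: one dummy per question, no global intercept, so coefficient q is
#' the logit of the discrete hazard `h_q = P(drop out at q | reached q)`.
#' Completers are censored after question K. The model is saturated in
#' question, so the maximum-likelihood estimate has closed form:
#' `coef_q = logit(d_q / n_q)` with `d_q` dropouts among `n_q` at risk, and
#' the covariance is diagonal with `var_q = 1 / (n_q h_q (1 - h_q))`.
#' A question where nobody (or everybody) at risk drops out has its hazard
#' on the boundary and is flagged non-estimable. A complementary log-log
#' link is available; its coefficients and delta-method variances are
#' computed from the same empirical hazards.
#'
#' @param x A [dropout_data] object, or a person-period data frame with
#'   columns `participant_id`, `question`, `event`.
#' @param link `"logit"` (default) or `"cloglog"`.
#' @return An object of class `"attrition_dtsa"`: list with `coefficients`
#'   (length K, `NA` where non-estimable), `vcov` (diagonal), `estimable`,
#'   `hazard` (empirical `d_q / n_q`), `n_at_risk`, `n_dropped`, `K`,
#'   `link`, `status` (`"ok"` or `"degenerate"` when no question is
#'   estimable).
#' @seealso [detect_dtsa()]
#' @examples
#' d <- dropout_data(c(1, 1, 2, 2, rep(NA, 6)), n_questions = 3)
#' coef(fit_dtsa(d))  # logit(0.2), logit(0.25), NA
#' @export
fit_dtsa <- function(x, link = c("logit", "cloglog")) {
  link <- match.arg(link)
  if (inherits(x, "dropout_data")) {
    s <- dropout_summary(x, mode = "conditional")
    n_q <- s$n_at_risk; d_q <- s$n_dropped; K <- nrow(s)
  } else {
    stopifnot(all(c("participant_id", "question", "event") %in% names(x)))
    if (!nrow(x)) stop("empty person-period table", call. = FALSE)
    K <- max(x$question)
    n_q <- tabulate(x$question, nbins = K)
    d_q <- tabulate(x$question[x$event == 1], nbins = K)
  }
  h <- ifelse(n_q > 0L, d_q / n_q, NA_real_)
  estimable <- !is.na(h) & h > 0 & h < 1
  trans <- switch(link,
    logit = list(g = stats::qlogis,
                 dg = function(p) 1 / (p * (1 - p))),
    cloglog = list(g = function(p) log(-log(1 - p)),
                   dg = function(p) 1 / ((p - 1) * log(1 - p))))
  co <- ifelse(estimable, trans$g(h), NA_real_)
  v <- ifelse(estimable, trans$dg(h)^2 * h * (1 - h) / n_q, NA_real_)
  structure(list(coefficients = co,
                 vcov = diag(v, nrow = K),
                 estimable = estimable,
                 hazard = h, n_at_risk = n_q, n_dropped = d_q,
                 K = K, link = link,
                 status = if (any(estimable)) "ok" else "degenerate"),
            class = "attrition_dtsa")
}

#' @export
coef.attrition_dtsa <- function(object, ...) {
  stats::setNames(object$coefficients, paste0("q", seq_len(object$K)))
}

#' @export
vcov.attrition_dtsa <- function(object, ...) object$vcov

#' @export
print.attrition_dtsa <- function(x, ...) {
  cat("Discrete-time survival model of dropout (", x$link,
      " link, step baseline hazard, K = ", x$K, ")\n", sep = "")
  cat("  estimable questions: ", sum(x$estimable), "/", x$K, "\n", sep = "")
  print(data.frame(question = seq_len(x$K), n_at_risk = x$n_at_risk,
                   n_dropped = x$n_dropped, hazard = round(x$hazard, 4),
                   coef = round(x$coefficients, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Dropout-phase detection via discrete-time survival analysis
#'
#' Fits [fit_dtsa()] and tests the K-1 adjacent hazard contrasts
#' (question q+1 vs q on the link scale) with two-sided Wald tests,
#' Benjamini-Hochberg adjusted at `alpha`. Boundary and phase-count
#' conventions match [detect_glmm()]: the dropout phase runs from the later
#' question of the first significant pair to that of the last. Pairs that
#' touch a non-estimable hazard (no dropouts, or everyone at risk dropping
#' out) are excluded from the testing family and can never be significant;
#' if no pair is estimable the detection is degenerate.
#'
#' @param x A [dropout_data] object or person-period data frame.
#' @param alpha Significance level on BH-adjusted p-values (default 0.05).
#' @param link Passed to [fit_dtsa()].
#' @return A `"phase_detection"` object with `$contrasts` and `$fit`.
#' @export
detect_dtsa <- function(x, alpha = 0.05, link = "logit") {
  f <- fit_dtsa(x, link = link)
  K <- f$K
  pair_ok <- f$estimable[-K] & f$estimable[-1L]
  if (f$status != "ok" || !any(pair_ok)) {
    out <- new_phase_detection("dtsa", K, NA_integer_, NA_integer_,
                               earliest = 2L, fit_status = "degenerate",
                               params = list(alpha = alpha, link = link))
    out$fit <- f
    return(out)
  }
  ct <- contrast_test(f$coefficients, f$vcov, alpha = alpha,
                      estimable = f$estimable)
  bounds <- contrast_boundaries(ct)
  out <- new_phase_detection("dtsa", K, bounds[1L], bounds[2L],
                             earliest = 2L, contrasts = ct,
                             params = list(alpha = alpha, link = link))
  out$fit <- f
  out
}
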