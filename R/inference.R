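#' Successive-difference contrast matrix
#'
#' The K-1 linear contrasts comparing each coefficient with its predecessor:
#' row j is `e_{j+1} - e_j`, so `C %*% beta` gives the adjacent differences
#' (question 2 vs 1, 3 vs 2, ...).
#'
#' @param K Number of coefficients (questions); must be >= 2.
#' @return A `(K-1) x K` matrix; each row sums to zero and contains exactly
#'   one `-1` and one `+1` in adjacent positions. Row names are
#'   `"2-1", "3-2", ...`.
#' @examples
#' successive_difference_contrasts(3)
#' @export
successive_difference_contrasts <- function(K) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 2L)
    stop("`K` must be a single integer >= 2", call. = FALSE)
  C <- diff(diag(K))
  rownames(C) <- paste0(seq_len(K - 1L) + 1L, "-", seq_len(K - 1L))
  C
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values of the Benjamini-Hochberg false-discovery-rate step-up
#' procedure: on the sorted scale, `adj_(i) = min_{j >= i} min(1,
#' p_(j) * m / j)`, mapped back to the input order. `NA` entries (e.g.
#' non-estimable comparisons) are left `NA` and excluded from the family
#' size m.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (NA allowed).
#' @return Vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.005, 0.5))            # 0.01, 0.5
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m > 0L) {
    o <- order(p[ok])
    scaled <- p[ok][o] * m / seq_len(m)
    adj <- pmin(1, rev(cummin(rev(scaled))))
    out[ok][o] <- adj
  }
  out
}

#' Wald tests of linear contrasts
#'
#' Two-sided Wald tests of `C %*% beta = 0` given a coefficient vector and
#' its covariance matrix: `z_j = c_j' beta / sqrt(c_j' Sigma c_j)`,
#' `p_j = 2 (1 - Phi(|z_j|))` (or a t reference with `df` degrees of
#' freedom). A contrast whose variance is zero or non-finite — or that
#' touches a coefficient flagged non-estimable — is flagged non-estimable:
#' its p-values are `NA` and it can never be significant.
#'
#' @param coefficients Coefficient vector (length K).
#' @param covariance K x K covariance matrix of the coefficients.
#' @param contrasts Contrast matrix, one contrast per row; default
#'   [successive_difference_contrasts()] for K.
#' @param alpha Significance level applied to the BH-adjusted p-values.
#' @param estimable Optional logical vector (length K) flagging which
#'   coefficients are estimable.
#' @param df Degrees of freedom for a t reference; `Inf` (default) gives the
#'   normal (z) reference.
#' @return A data frame of class `"contrast_result"` with one row per
#'   contrast: `pair` (label), `later` (the later question index of the
#'   pair, for adjacent contrasts), `estimate`, `se`, `z`, `p_raw`, `p_adj`
#'   (BH over estimable contrasts), `significant`, `estimable`.
#' @examples
#' ct <- contrast_test(c(0, 1.96), diag(2) / 2)
#' round(ct$p_raw, 3)  # 0.05
#' @export
contrast_test <- function(coefficients, covariance, contrasts = NULL,
                          alpha = 0.05, estimable = NULL, df = Inf) {
  K <- length(coefficients)
  if (is.null(contrasts)) contrasts <- successive_difference_contrasts(K)
  contrasts <- as.matrix(contrasts)
  covariance <- as.matrix(covariance)
  if (ncol(contrasts) != K || any(dim(covariance) != K))
    stop("dimension mismatch between coefficients, covariance and contrasts",
         call. = FALSE)
  if (is.null(estimable)) estimable <- rep(TRUE, K)
  b <- ifelse(estimable, coefficients, 0)
  V <- covariance
  V[!estimable, ] <- 0; V[, !estimable] <- 0
  est <- drop(contrasts %*% b)
  v <- rowSums((contrasts %*% V) * contrasts)
  ok <- apply(contrasts != 0, 1L, function(r) all(estimable[r])) &
    is.finite(v) & v > 0
  se <- ifelse(ok, sqrt(v), NA_real_)
  z <- ifelse(ok, est / se, NA_real_)
  p_raw <- if (is.finite(df)) 2 * stats::pt(-abs(z), df = df)
           else 2 * stats::pnorm(-abs(z))
  p_adj <- bh_adjust(p_raw)
  later <- apply(contrasts, 1L, function(r) {
    pos <- which(r != 0)
    if (length(pos)) max(pos) else NA_integer_
  })
  out <- data.frame(pair = rownames(contrasts) %||%
                      paste0("c", seq_len(nrow(contrasts))),
                    later = as.integer(later),
                    estimate = ifelse(ok, est, NA_real_),
                    se = se, z = z, p_raw = p_raw, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha,
                    estimable = ok,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("contrast_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contrast_result <- function(x, ...) {
  cat("Adjacent-comparison Wald tests (BH-adjusted, alpha = ",
      attr(x, "alpha"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a contrast table to CSV
#'
#' @param x A `"contrast_result"` data frame.
#' @param path File path.
#' @export
write_contrasts <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
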