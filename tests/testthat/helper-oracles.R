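# Independent brute-force oracles and small fixture generators, used to
# cross-check the package implementations.

# step-up FDR adjustment straight from the definition, loops and all
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) min(1, p[o[j]] * m / j), numeric(1))
    adj[o[i]] <- min(vals)
  }
  adj
}

# per-question counts by explicit loops over participants
brute_summary <- function(d, mode = "conditional") {
  K <- d$design$n_questions
  N <- length(d$exit_question)
  out <- data.frame(question = seq_len(K), n_at_risk = NA_integer_,
                    n_dropped = NA_integer_, proportion = NA_real_)
  for (q in seq_len(K)) {
    at_risk <- 0L; dropped <- 0L
    for (ex in d$exit_question) {
      if (is.na(ex) || ex >= q) at_risk <- at_risk + 1L
      if (!is.na(ex) && ex == q) dropped <- dropped + 1L
    }
    out$n_at_risk[q] <- at_risk
    out$n_dropped[q] <- dropped
    out$proportion[q] <- if (mode == "marginal") dropped / N
      else if (at_risk > 0) dropped / at_risk else NA_real_
  }
  out
}

# threshold scan by explicit loops
brute_threshold_scan <- function(proportions, start_thr, end_thr) {
  start <- NA_integer_; end <- NA_integer_
  for (q in seq_along(proportions)) {
    p <- proportions[q]
    if (is.na(p)) break
    if (is.na(start) && p > start_thr) start <- q
    if (p > end_thr) end <- q
  }
  if (is.na(start) || is.na(end) || end < start) c(NA_integer_, NA_integer_)
  else c(start, end)
}

# random monotone dropout dataset with moderate hazards
rand_dropout <- function(n = 30, K = 5, p_drop = 0.2) {
  ex <- integer(n)
  for (i in seq_len(n)) {
    q <- which(stats::runif(K) < p_drop)
    ex[i] <- if (length(q)) min(q) else NA_integer_
  }
  dropout_data(ex, n_questions = K)
}

# phase_detection stub for metric tests
stub_detection <- function(start, end, K = 20, earliest = 1L,
                           fit_status = "ok") {
  attriphase:::new_phase_detection("stub", K, start, end, earliest,
                                   fit_status = fit_status)
}
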