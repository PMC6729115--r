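fake_summary <- function(proportions, n_at_risk = rep(100L,
                                                      length(proportions))) {
  out <- data.frame(question = seq_along(proportions),
                    n_at_risk = n_at_risk,
                    n_dropped = NA_integer_,
                    proportion = proportions)
  attr(out, "mode") <- "conditional"
  attr(out, "n_total") <- n_at_risk[1]
  attr(out, "n_completed") <- NA_integer_
  class(out) <- c("dropout_summary", "data.frame")
  out
}

test_that("the scan finds the first start-exceedance and last end-exceedance", {
  p17 <- c(0.01, 0.02, 0.05, 0.06, 0.04, 0.02, 0.01, 0.02, 0.035,
           rep(0.01, 8))
  det <- detect_threshold(fake_summary(p17), 0.03, 0.03)
  expect_equal(det$start_question, 3L)
  expect_equal(det$end_question, 9L)
  expect_equal(det$n_phases, 3L)
})

test_that("no exceedance means a single stable phase", {
  det <- detect_threshold(fake_summary(rep(0.01, 20)), 0.03, 0.03)
  expect_true(is.na(det$start_question) && is.na(det$end_question))
  expect_equal(det$n_phases, 1L)
})

test_that("exceedance everywhere reads as dropout throughout (one phase)", {
  det <- detect_threshold(fake_summary(rep(0.10, 20)), 0.03, 0.03)
  expect_equal(det$start_question, 1L)
  expect_equal(det$end_question, 20L)
  expect_equal(det$n_phases, 1L)
})

test_that("exceedance is strict: a proportion at the threshold does not trigger", {
  det <- detect_threshold(fake_summary(c(0.03, 0.03, 0.030001)), 0.03, 0.03)
  expect_equal(det$start_question, 3L)
  expect_equal(det$end_question, 3L)
})

test_that("the scan equals a brute-force loop on random summaries", {
  set.seed(41)
  for (i in 1:200) {
    K <- sample(2:25, 1)
    p <- round(runif(K, 0, 0.15), 3)
    thr_s <- round(runif(1, 0, 0.1), 3)
    thr_e <- round(runif(1, 0, 0.1), 3)
    det <- detect_threshold(fake_summary(p), thr_s, thr_e)
    expect_equal(c(det$start_question, det$end_question),
                 brute_threshold_scan(p, thr_s, thr_e))
  }
})

test_that("raising a threshold never widens the detected phase", {
  set.seed(42)
  for (i in 1:100) {
    K <- sample(3:20, 1)
    p <- runif(K, 0, 0.12)
    t1 <- runif(1, 0, 0.05); t2 <- t1 + runif(1, 0, 0.05)
    lo <- detect_threshold(fake_summary(p), t1, t1)
    hi <- detect_threshold(fake_summary(p), t2, t2)
    if (!is.na(hi$start_question) && !is.na(lo$start_question)) {
      expect_gte(hi$start_question, lo$start_question)
      expect_lte(hi$end_question, lo$end_question)
    }
  }
})

test_that("detection is invariant to participant relabeling and order", {
  set.seed(43)
  d <- rand_dropout(n = 60, K = 8)
  perm <- sample(60)
  d2 <- dropout_data(d$exit_question[perm], n_questions = 8,
                     participant_id = paste0("z", seq_len(60)))
  a <- detect_threshold(d, 0.05, 0.05)
  b <- detect_threshold(d2, 0.05, 0.05)
  expect_equal(a$start_question, b$start_question)
  expect_equal(a$end_question, b$end_question)
})

test_that("undefined proportions terminate the scan; no scannable range is degenerate", {
  # everyone gone after question 1: questions 2..3 have nobody at risk
  d <- dropout_data(c(1, 1, 1), n_questions = 3)
  det <- detect_threshold(d, 0.03, 0.03)
  expect_equal(det$fit_status, "ok")
  expect_equal(det$start_question, 1L)
  expect_equal(det$end_question, 1L)

  deg <- detect_threshold(fake_summary(rep(NA_real_, 3), rep(0L, 3)),
                          0.03, 0.03)
  expect_equal(deg$fit_status, "degenerate")
  expect_true(is.na(deg$start_question))
})

test_that("marginal and conditional modes scan different proportions", {
  d <- dropout_data(c(rep(10, 30), rep(NA, 70)), n_questions = 12)
  cond <- detect_threshold(d, 0.2, 0.2, mode = "conditional")  # 30/100 > .2
  marg <- detect_threshold(d, 0.2, 0.2, mode = "marginal")     # 0.3 > .2 too
  expect_equal(cond$start_question, 10L)
  expect_equal(marg$start_question, 10L)
  # tighter threshold separates them: conditional 30/100 = .3, marginal .3;
  # use uneven sample: 30 drop of 200 => marginal .15, conditional .15 at q10
  d2 <- dropout_data(c(rep(1, 50), rep(10, 30), rep(NA, 120)),
                     n_questions = 12)
  s_cond <- dropout_summary(d2, "conditional")
  s_marg <- dropout_summary(d2, "marginal")
  expect_equal(s_cond$proportion[10], 30 / 150)
  expect_equal(s_marg$proportion[10], 30 / 200)
  expect_equal(detect_threshold(d2, 0.18, 0.18)$start_question, 1L)
  expect_equal(detect_threshold(d2, 0.18, 0.18)$end_question, 10L)
  expect_equal(detect_threshold(d2, 0.18, 0.18,
                                mode = "marginal")$end_question, 1L)
})
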