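test_that("wide response matrices convert by the first-gap rule", {
  wide <- data.frame(participant_id = c("a", "b"),
                     Q1 = c("A", "A"), Q2 = c("B", "B"), Q3 = c("C", "C"),
                     Q4 = c(NA, "D"), Q5 = c(NA, "E"),
                     stringsAsFactors = FALSE)
  d <- dropout_from_wide(wide)
  expect_equal(d$exit_question, c(4L, NA_integer_))
  expect_equal(attr(d, "n_coerced"), 0L)
})

test_that("nonmonotone rows error by default and coerce on request", {
  wide <- data.frame(participant_id = "a",
                     Q1 = "A", Q2 = NA, Q3 = "C", stringsAsFactors = FALSE)
  expect_error(dropout_from_wide(wide), "monotone")
  expect_warning(d <- dropout_from_wide(wide, nonmonotone = "coerce"),
                 "coerced")
  expect_equal(d$exit_question, 2L)
  expect_equal(attr(d, "n_coerced"), 1L)
})

test_that("dropout_data validates its invariants", {
  expect_error(dropout_data(c(1, 2), 5, participant_id = c("a", "a")),
               "unique")
  expect_error(dropout_data(6, 5), "1..5")
  expect_error(survey_design(1), ">= 2")
  expect_silent(dropout_data(c(1, 5, NA), 5))
})

test_that("cumulative and person-period expansions match their definitions", {
  d <- dropout_data(c(2, NA, 1), n_questions = 3)
  cum <- to_cumulative(d)
  expect_equal(nrow(cum), 9L)
  expect_equal(cum$dropped_by[cum$participant_id == "p1"], c(0L, 1L, 1L))
  expect_equal(cum$dropped_by[cum$participant_id == "p2"], c(0L, 0L, 0L))
  expect_equal(cum$dropped_by[cum$participant_id == "p3"], c(1L, 1L, 1L))

  pp <- to_person_period(d)
  expect_equal(pp[pp$participant_id == "p1", "question"], 1:2)
  expect_equal(pp[pp$participant_id == "p1", "event"], c(0L, 1L))
  expect_equal(pp[pp$participant_id == "p2", "event"], c(0L, 0L, 0L))
  expect_equal(nrow(pp[pp$participant_id == "p3", ]), 1L)
  expect_equal(pp[pp$participant_id == "p3", "event"], 1L)
})

test_that("exit questions are recoverable from both long formats", {
  set.seed(11)
  for (i in 1:10) {
    d <- rand_dropout(n = 25, K = 6)
    cum <- to_cumulative(d)
    rec_cum <- vapply(split(cum, cum$participant_id), function(rows) {
      rows <- rows[order(rows$question), ]
      hit <- which(rows$dropped_by == 1L)
      if (length(hit)) min(rows$question[hit]) else NA_integer_
    }, integer(1L))
    expect_equal(unname(rec_cum[d$participant_id]), d$exit_question)
    rec_pp <- from_person_period(to_person_period(d), n_questions = 6)
    expect_equal(rec_pp$exit_question[match(d$participant_id,
                                            rec_pp$participant_id)],
                 d$exit_question)
  }
})

test_that("summary counts follow the at-risk recursion and hand counts", {
  d <- dropout_data(c(1, 1, 2, 2, rep(NA, 6)), n_questions = 3)
  s <- dropout_summary(d)
  expect_equal(s$n_at_risk, c(10L, 8L, 6L))
  expect_equal(s$proportion, c(0.2, 0.25, 0))
  m <- dropout_summary(d, mode = "marginal")
  expect_equal(m$proportion, c(0.2, 0.2, 0))
  none <- dropout_summary(dropout_data(rep(NA, 4), 3))
  expect_equal(none$proportion, c(0, 0, 0))
})

test_that("conditional proportion with nobody at risk is undefined, not 0", {
  d <- dropout_data(c(1, 1, 1), n_questions = 3)
  s <- dropout_summary(d)
  expect_equal(s$n_at_risk, c(3L, 0L, 0L))
  expect_true(all(is.na(s$proportion[2:3])))
})

test_that("counts conserve the sample and match brute-force tallies", {
  set.seed(21)
  for (i in 1:15) {
    d <- rand_dropout(n = sample(5:40, 1), K = sample(2:8, 1))
    s <- dropout_summary(d)
    expect_equal(sum(s$n_dropped) + attr(s, "n_completed"), length(d))
    expect_equal(s$n_at_risk[1], length(d))
    expect_equal(s[, 2:4], brute_summary(d)[, 2:4], ignore_attr = TRUE)
    sm <- dropout_summary(d, "marginal")
    expect_equal(sm$proportion, brute_summary(d, "marginal")$proportion)
  }
})

test_that("CSV interchange round-trips all three formats", {
  d <- dropout_data(c(2, NA, 1, 3), n_questions = 3,
                    participant_id = c("w", "x", "y", "z"))
  rec <- withr::local_tempfile(fileext = ".csv")
  write_dropout_records(d, rec)
  d2 <- read_dropout_records(rec, n_questions = 3)
  expect_equal(d2$exit_question, d$exit_question)
  expect_equal(d2$participant_id, d$participant_id)

  wide <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(participant_id = c("a", "b"),
                       Q1 = c("yes", "no"), Q2 = c("", "no")),
            wide, row.names = FALSE)
  d3 <- read_wide_survey(wide)
  expect_equal(d3$exit_question, c(2L, NA_integer_))

  ppf <- withr::local_tempfile(fileext = ".csv")
  write.csv(to_person_period(d), ppf, row.names = FALSE)
  d4 <- read_person_period(ppf, n_questions = 3)
  expect_equal(d4$exit_question[match(d$participant_id, d4$participant_id)],
               d$exit_question)
})
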