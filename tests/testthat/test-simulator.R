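test_that("pattern presets build the canonical hazard vectors", {
  con <- attrition_pattern("constant", "mild")
  expect_equal(con$hazards, rep(0.01, 20))
  expect_equal(con$true_n_phases, 1L)
  expect_length(con$true_transitions, 0L)

  sev <- attrition_pattern("constant", "severe")
  expect_equal(sev$hazards, rep(0.05, 20))

  tp <- attrition_pattern("two_phase", "severe", "middle")
  expect_equal(tp$hazards, c(rep(0.01, 9), rep(0.05, 11)))
  expect_equal(tp$true_transitions, 10L)
  expect_equal(tp$true_n_phases, 2L)

  rev <- attrition_pattern("two_phase_reverse", "mild", "start")
  expect_equal(rev$hazards, c(rep(0.03, 4), rep(0.01, 16)))
  expect_equal(rev$true_transitions, 5L)

  th <- attrition_pattern("three_phase", "severe", "middle")
  expect_equal(th$hazards, c(rep(0.01, 7), rep(0.05, 6), rep(0.01, 7)))
  expect_equal(th$true_transitions, c(8L, 14L))
  expect_equal(th$true_n_phases, 3L)

  ends <- attrition_pattern("three_phase", "mild", "ends")
  expect_equal(ends$true_transitions, c(4L, 17L))
})

test_that("incompatible shape/location pairs and bad rates are rejected", {
  expect_error(attrition_pattern("constant", "mild", "middle"),
               "incompatible")
  expect_error(attrition_pattern("two_phase", "mild", "ends"),
               "incompatible")
  expect_error(attrition_pattern("three_phase", "mild", "start"),
               "incompatible")
  expect_error(attrition_pattern("constant", "mild",
                                 rates = c(stable = 1.2)), "\\[0, 1\\]")
})

test_that("rate overrides propagate and equal rates collapse phases", {
  p <- attrition_pattern("two_phase", "severe", "middle",
                         rates = c(stable = 0.02, severe = 0.2))
  expect_equal(unique(p$hazards), c(0.02, 0.2))
  # dropout rate equal to stable rate: nominal 2-phase collapses to 1
  flat <- attrition_pattern("two_phase", "severe", "middle",
                            rates = c(stable = 0.05, severe = 0.05))
  expect_equal(flat$true_n_phases, 1L)
})

test_that("degenerate hazards produce the forced exit patterns", {
  all_stay <- attrition_pattern("constant", "mild", rates = c(stable = 0))
  d <- simulate(all_stay, seed = 1, n_participants = 50)[[1]]
  expect_true(all(is.na(d$exit_question)))

  all_go <- attrition_pattern("constant", "severe", rates = c(severe = 1))
  d2 <- simulate(all_go, seed = 1, n_participants = 50)[[1]]
  expect_true(all(d2$exit_question == 1L))
})

test_that("completion fraction matches the closed-form survival product", {
  pat <- attrition_pattern("constant", "severe")  # 0.05 throughout
  d <- simulate(pat, seed = 42, n_participants = 10000)[[1]]
  p_hat <- mean(is.na(d$exit_question))
  p_true <- 0.95^20
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("exit distribution follows its closed form (goodness of fit)", {
  pat <- attrition_pattern("three_phase", "severe", "middle")
  counts <- Reduce(`+`, simulate_batch(pat, 50, master_seed = 8,
                                       n_participants = 200,
                                       FUN = function(d) {
    tabulate(ifelse(is.na(d$exit_question), 21L, d$exit_question),
             nbins = 21L)
  }))
  gof <- suppressWarnings(chisq.test(counts, p = exit_distribution(pat)))
  expect_gt(gof$p.value, 0.001)
})

test_that("batches are seed-reproducible and replicates differ", {
  pat <- attrition_pattern("two_phase", "mild", "end")
  a <- simulate_batch(pat, 5, master_seed = 77, n_participants = 30)
  b <- simulate_batch(pat, 5, master_seed = 77, n_participants = 30)
  expect_identical(lapply(a, `[[`, "exit_question"),
                   lapply(b, `[[`, "exit_question"))
  big <- simulate_batch(attrition_pattern("constant", "severe"), 100,
                        master_seed = 3, n_participants = 200,
                        FUN = function(d) d$exit_question)
  expect_equal(anyDuplicated(big), 0L)
})

test_that("batch streams do not disturb the caller's RNG state", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_batch(attrition_pattern("constant", "mild"), 3,
                           master_seed = 5, n_participants = 10))
  expect_equal(runif(1), before)
})

test_that("pooled empirical hazards recover a preset's hazard vector", {
  # heavier all-preset sweep lives in the acceptance suite
  pat <- attrition_pattern("two_phase_reverse", "severe", "middle")
  K <- 20; n <- 200; reps <- 1500
  agg <- Reduce(`+`, simulate_batch(pat, reps, master_seed = 12,
                                    n_participants = n,
                                    FUN = function(d) {
    s <- dropout_summary(d)
    c(s$n_dropped, s$n_at_risk)
  }))
  d_q <- agg[1:K]; n_q <- agg[K + 1:K]
  h_hat <- d_q / n_q
  se <- sqrt(pat$hazards * (1 - pat$hazards) / n_q)
  expect_true(all(abs(h_hat - pat$hazards) < 4 * se))
})
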