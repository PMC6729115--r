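#' Canonical attrition rates
#'
#' Per-question conditional dropout probabilities used by the pattern
#' presets: `stable` is the stable-use (low-attrition) hazard, `mild` and
#' `severe` are the two dropout-phase hazards. Constant patterns use the
#' stable rate ("mild constant") or the severe rate ("severe constant")
#' throughout.
#'
#' @return Named numeric vector `c(stable, mild, severe)`.
#' @export
default_rates <- function() c(stable = 0.01, mild = 0.03, severe = 0.05)

canonical_transitions <- function(shape, location, K) {
  at <- function(f) as.integer(round(f * K))
  switch(shape,
    constant = integer(0),
    two_phase = ,
    two_phase_reverse = switch(location,
      start  = at(0.25),
      middle = at(0.50),
      end    = at(0.75)),
    three_phase = switch(location,
      middle    = c(at(0.40), at(0.70)),
      one_start = c(at(0.20), at(0.50)),
      one_end   = c(at(0.55), at(0.85)),
      ends      = c(at(0.20), at(0.85))))
}

#' Phase-structured attrition pattern
#'
#' Builds the per-question dropout hazard vector for one of the simulated
#' attrition shapes:
#'
#' * `constant` — a single regime for the whole survey: the stable hazard
#'   (`severity = "mild"`) or the severe dropout hazard (`severity =
#'   "severe"`).
#' * `two_phase` — stable use followed by a dropout phase from the
#'   transition question onward.
#' * `two_phase_reverse` — a dropout phase first, transitioning into stable
#'   use.
#' * `three_phase` — stable use, a dropout phase in between, stable use
#'   again (the classic curiosity-plateau / attrition / stable-use shape).
#'
#' A transition question `t` is the first question of the *new* regime. For
#' K = 20 the presets put two-phase transitions at question 5 (`start`), 10
#' (`middle`), or 15 (`end`), and three-phase transitions at (8, 14)
#' (`middle`), (4, 10) (`one_start`), (11, 17) (`one_end`), or (4, 17)
#' (`ends`); other K use the same fractional positions.
#'
#' @param shape Pattern shape (see above).
#' @param severity `"mild"` or `"severe"` dropout-phase hazard.
#' @param location Transition location; `"none"` for `constant`,
#'   `"start"`/`"middle"`/`"end"` for the two-phase shapes,
#'   `"middle"`/`"one_start"`/`"one_end"`/`"ends"` for `three_phase`.
#' @param n_questions Number of questions K (default 20).
#' @param rates Named vector overriding [default_rates()].
#' @return An object of class `"attrition_pattern"`: list with `name`,
#'   `hazards` (length K), `true_n_phases`, `true_transitions`, `shape`,
#'   `severity`, `location`, `rates`.
#' @examples
#' attrition_pattern("three_phase", "severe", "middle")
#' @export
attrition_pattern <- function(shape = c("constant", "two_phase",
                                        "two_phase_reverse", "three_phase"),
                              severity = c("mild", "severe"),
                              location = NULL,
                              n_questions = 20,
                              rates = default_rates()) {
  shape <- match.arg(shape)
  severity <- match.arg(severity)
  K <- survey_design(n_questions)$n_questions
  rates <- as.list(modifyList(as.list(default_rates()), as.list(rates)))
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop("hazard rates must lie in [0, 1]", call. = FALSE)
  allowed <- switch(shape,
    constant = "none",
    two_phase = ,
    two_phase_reverse = c("start", "middle", "end"),
    three_phase = c("middle", "one_start", "one_end", "ends"))
  if (is.null(location)) location <- allowed[1L]
  if (!location %in% allowed)
    stop("location \"", location, "\" is incompatible with shape \"", shape,
         "\" (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  stable <- rates$stable
  drop_rate <- rates[[severity]]
  tr <- canonical_transitions(shape, location, K)
  h <- switch(shape,
    constant = rep(if (severity == "severe") drop_rate else stable, K),
    two_phase = ifelse(seq_len(K) >= tr, drop_rate, stable),
    two_phase_reverse = ifelse(seq_len(K) >= tr, stable, drop_rate),
    three_phase = ifelse(seq_len(K) >= tr[1L] & seq_len(K) < tr[2L],
                         drop_rate, stable))
  n_phases <- switch(shape, constant = 1L, two_phase = 2L,
                     two_phase_reverse = 2L, three_phase = 3L)
  # collapse to actual regime changes (a zero-contrast override can merge
  # nominal phases)
  changes <- which(h[-1L] != h[-K]) + 1L
  structure(list(name = paste(shape, severity, location, sep = "/"),
                 hazards = h,
                 true_n_phases = length(changes) + 1L,
                 true_transitions = changes,
                 shape = shape, severity = severity, location = location,
                 rates = unlist(rates)),
            class = "attrition_pattern")
}

#' @export
print.attrition_pattern <- function(x, ...) {
  cat("Attrition pattern ", x$name, " (K = ", length(x$hazards), ")\n",
      sep = "")
  cat("  phases: ", x$true_n_phases,
      if (length(x$true_transitions))
        paste0(", transitions at question(s) ",
               paste(x$true_transitions, collapse = ", ")) else "",
      "\n  hazards: ", paste(format(unique(x$hazards)), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}

#' The full simulation-study pattern grid
#'
#' The 22 pattern cells of the evaluation grid: constant (mild, severe) for
#' type I error; two-phase and reversed two-phase at each severity and
#' transition location, and three-phase at each severity and location, for
#' sensitivity.
#'
#' @inheritParams attrition_pattern
#' @return List of [attrition_pattern] objects.
#' @export
study_patterns <- function(n_questions = 20, rates = default_rates()) {
  out <- list()
  for (sev in c("mild", "severe"))
    out <- c(out, list(attrition_pattern("constant", sev, "none",
                                         n_questions, rates)))
  for (shape in c("two_phase", "two_phase_reverse"))
    for (sev in c("mild", "severe"))
      for (loc in c("middle", "start", "end"))
        out <- c(out, list(attrition_pattern(shape, sev, loc,
                                             n_questions, rates)))
  for (sev in c("mild", "severe"))
    for (loc in c("middle", "one_start", "one_end", "ends"))
      out <- c(out, list(attrition_pattern("three_phase", sev, loc,
                                           n_questions, rates)))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Exit-question distribution of a pattern
#'
#' Closed-form distribution of the exit question under independent
#' per-question hazards: `P(exit = q) = h_q * prod_{j<q} (1 - h_j)`, with
#' the remaining mass `prod_j (1 - h_j)` on completion.
#'
#' @param pattern An [attrition_pattern] or a bare hazard vector.
#' @return Numeric vector of length K + 1; the last element is the
#'   completion probability.
#' @export
exit_distribution <- function(pattern) {
  h <- if (inherits(pattern, "attrition_pattern")) pattern$hazards
       else as.numeric(pattern)
  surv <- cumprod(1 - h)
  c(h * c(1, surv[-length(h)]), surv[length(h)])
}

r_exit <- function(pattern, n) {
  K <- length(pattern$hazards)
  p <- exit_distribution(pattern)
  ex <- sample.int(K + 1L, n, replace = TRUE, prob = p)
  ex[ex == K + 1L] <- NA_integer_
  ex
}

#' Simulate monotone dropout datasets from a pattern
#'
#' Each participant walks the survey independently; at question q a
#' participant still in the survey drops out with probability `hazards[q]`,
#' and survivors of all K questions are completers (no re-entry). Sampling
#' draws each exit question directly from the closed-form exit distribution
#' ([exit_distribution()]), which has the same law as the sequential walk.
#'
#' @param object An [attrition_pattern].
#' @param nsim Number of datasets to generate.
#' @param seed Optional integer seed (sets R's RNG before sampling).
#' @param n_participants Participants per dataset (default 200).
#' @param ... Unused.
#' @return A list of `nsim` [dropout_data] objects (always a list, even for
#'   `nsim = 1`).
#' @examples
#' pat <- attrition_pattern("constant", "severe")
#' sim <- simulate(pat, nsim = 2, seed = 1, n_participants = 50)
#' sim[[1]]
#' @export
simulate.attrition_pattern <- function(object, nsim = 1, seed = NULL,
                                       n_participants = 200, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- survey_design(length(object$hazards))
  replicate(nsim,
            new_dropout_data(r_exit(object, n_participants), design),
            simplify = FALSE)
}

# .Random.seed state for L'Ecuyer-CMRG substream `index` (1-based) derived
# from `master_seed`; substreams are the standard nextRNGStream jump-ahead
# sequence, so replicate r always sees the same stream regardless of
# execution order.
rng_substream <- function(master_seed, index) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(master_seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(index)) s <- parallel::nextRNGStream(s)
  s
}

with_rng_state <- function(state, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", state, envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  expr
}

#' Seeded replicate engine
#'
#' Generates `n_replicates` independent datasets from `pattern`, each on its
#' own L'Ecuyer-CMRG substream derived deterministically from
#' (`master_seed`, replicate index), and applies `FUN` to each dataset as it
#' is produced (so large batches never need to be held in memory at once).
#' The batch is bitwise reproducible and replicate r's stream does not
#' depend on the order in which replicates are evaluated.
#'
#' @param pattern An [attrition_pattern].
#' @param n_replicates Number of datasets.
#' @param master_seed Integer master seed governing the whole batch.
#' @param n_participants Participants per dataset.
#' @param FUN Function applied to each [dropout_data] (default: identity,
#'   i.e. return the datasets themselves).
#' @param ... Passed on to `FUN`.
#' @return List of length `n_replicates` with the values of `FUN`.
#' @examples
#' pat <- attrition_pattern("constant", "mild")
#' a <- simulate_batch(pat, 3, master_seed = 7, n_participants = 20)
#' b <- simulate_batch(pat, 3, master_seed = 7, n_participants = 20)
#' identical(lapply(a, `[[`, "exit_question"),
#'           lapply(b, `[[`, "exit_question"))
#' @export
simulate_batch <- function(pattern, n_replicates, master_seed,
                           n_participants = 200, FUN = identity, ...) {
  stopifnot(inherits(pattern, "attrition_pattern"),
            n_replicates >= 1, n_participants >= 1)
  design <- survey_design(length(pattern$hazards))
  state <- rng_substream(master_seed, 1L)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    out[[r]] <- with_rng_state(state, {
      d <- new_dropout_data(r_exit(pattern, n_participants), design)
      FUN(d, ...)
    })
    state <- parallel::nextRNGStream(state)
  }
  out
}
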