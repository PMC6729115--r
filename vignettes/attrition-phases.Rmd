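---
title: "Detecting phases of dropout attrition: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phases of dropout attrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(attriphase)
```

## The problem

Web-based questionnaires lose participants mid-survey: someone starts, answers
a few items, and silently stops. This *dropout attrition* (distinct from
nonresponse, where a solicited person never starts) is widely thought to occur
in phases — an initial stretch where curiosity keeps participation high, a
phase of elevated exits, and a stable tail of committed respondents who mostly
finish. Locating the elevated-dropout phase matters twice over: it points at
the survey content that drives people away, and it tells the analyst which
items carry missingness that is plausibly related to content (so MAR/MNAR
handling is needed downstream).

`attriphase` represents the completion process on a fixed grid of K ordered
questions. Each participant is reduced to a single *exit question*: `q` means
questions `1..q-1` were answered and the participant stopped at `q`; a
completer has no exit (coded `NA`). Dropout is monotone by construction — no
re-entry, no skipped items. Surveys that allow question skipping violate this
representation and are out of scope.

## Three detectors

All three methods scan for the start and end of a dropout phase and convert
the boundaries into an implied phase count (see *Conventions* below).

### User-specified thresholds

`detect_threshold()` compares each question's dropout proportion with a start
and an end threshold chosen by the analyst as the practically meaningful
amount of per-question dropout (defaults: 3% each; the two may differ). The
first question strictly exceeding the start threshold begins the dropout
phase; the last question strictly exceeding the end threshold ends it.
"Strictly" is deliberate: a proportion exactly at the threshold is not beyond
it, and with n = 200 participants the discreteness of counts makes the
difference visible.

Two proportion definitions are supported. The *conditional* proportion
(default) is the empirical discrete hazard — dropouts at q over participants
still at risk at q. The *marginal* proportion divides by the original sample
size instead. The conditional definition is the package default because it is
the quantity the survival model estimates, and because marginal proportions
shrink mechanically toward the end of a survey (by question 20 a constant
5%-per-question process leaves a marginal rate under 2%), which would make
late-survey dropout phases undetectable by construction.

### Cumulative-dropout GLMM

`detect_glmm()` fits a logistic mixed model to the cumulative indicator
"participant i has dropped out *by* question q": K rows per participant (rows
after the exit stay 1), a cell-means fixed effect per question (no global
intercept), and a participant random intercept for the within-person
dependence of the K indicators. Adjacent questions are then compared with
successive-difference contrasts on the question effects.

Note what this model tests: differences in *cumulative* dropout between
adjacent questions. Under a constant per-question hazard those differences
are genuinely nonzero (cumulative dropout keeps rising), so with a high
constant hazard the GLMM flags many adjacent pairs — elevated "type I error"
under a constant severe pattern is a property of the outcome definition, not
a bug.

**Estimation.** Monotone cumulative outcomes are nearly separable by the
random intercept: a large enough subject effect reproduces each participant's
0→1 step exactly, so the marginal likelihood is almost flat in the variance
component and the variance estimate runs very large. Full Laplace optimization
on such data is slow (~1 min per fit at 200 × 20) and routinely trips
convergence diagnostics. The package therefore defaults to `lme4::glmer` with
`nAGQ = 0` — the penalized iteratively reweighted least squares step on the
Laplace objective — which is deterministic, roughly two orders of magnitude
faster, and yields the same contrast decisions in practice. `nAGQ` is exposed
for users who want full Laplace or adaptive quadrature; those paths get a
small retry ladder (two restarts from perturbed parameters) before a fit is
declared failed. Failed and degenerate fits (no dropout at all, or everyone
gone) are excluded from study metrics and counted, with an optional
`failed_as_null` mode that counts them as non-detections instead.
`fit_glmm(random_intercept = FALSE)` fixes the variance component at zero,
which reduces the model to independent per-cell logistic regression whose
cell-means MLE is the empirical logit of each question's cumulative
proportion — the oracle the test suite checks against.

### Discrete-time survival analysis

`detect_dtsa()` treats dropout as a time-to-event outcome on the question
grid: person-period rows for every question reached, a step-function baseline
hazard with one dummy per question, logit link, no intercept, completers
censored after question K. Because questions occur in discrete order and a
participant can only exit once, the person-period likelihood needs no random
effect. The model is saturated in question, so the MLE is closed-form:
coefficient q is `logit(d_q / n_q)` with variance `1/(n_q h_q (1 - h_q))`. A
question with zero dropouts (or where everyone at risk exits) sits on the
parameter boundary and is flagged non-estimable; adjacent contrasts touching
it are excluded from the testing family rather than aborting the analysis. A
complementary log-log link is available (`link = "cloglog"`), computed from
the same empirical hazards by the delta method.

Adjacent hazards under a constant pattern are genuinely equal, so — unlike
the GLMM — a correctly specified DTSA has no systematic signal under constant
attrition and its constant-pattern detection rate sits near the nominal
level of the BH-adjusted tests. Published applications of this approach
report far higher constant-pattern detection rates (including significance
between the first two questions at hazards as small as 0.001); the saturated
closed form here reproduces the model, not that anomaly, and the evaluation
reports whatever the Wald/BH machinery yields.

## Shared inference conventions

* **Contrasts.** `successive_difference_contrasts(K)` builds the K−1 adjacent
  comparisons; tests are two-sided Wald tests on the model's link scale
  (z reference by default, t via `df`).
* **Multiplicity.** Raw p-values are Benjamini–Hochberg adjusted
  (`bh_adjust()`, implemented directly from the step-up definition) and
  judged at α = 0.05. Non-estimable comparisons are excluded from the family
  size and can never be significant.
* **Boundaries.** For contrast-based methods the dropout phase starts at the
  *later* question of the first significant pair and ends at the later
  question of the last significant pair.
* **Phase count.** No boundaries → 1 phase. Boundaries spanning the whole
  reportable range — question 1 (threshold) or 2 (contrast methods) through
  K — → 1 phase (dropout throughout the survey). One interior boundary → 2
  phases; both interior → 3. The asymmetry in "earliest possible position"
  exists because the first adjacent pair is (1, 2) and its later index is 2.
* If start and end scans disagree on whether a phase exists (possible only
  with unequal thresholds), no phase is reported.

## The simulator and what it does (not) emulate

`attrition_pattern()` builds per-question hazard vectors for constant,
two-phase (stable→dropout), reversed two-phase (dropout→stable), and
three-phase (stable/dropout/stable) shapes. Participants walk the survey
independently; survivors of all K questions complete. Exit questions are
drawn in one step from the closed-form exit distribution
`P(exit = q) = h_q ∏_{j<q}(1 − h_j)`, which is the same law as the sequential
Bernoulli walk. Replicates run on L'Ecuyer-CMRG substreams
(`parallel::nextRNGStream`), one per replicate, so batches are reproducible
and replicate r's data do not depend on evaluation order.

**Calibration.** The canonical hazards are 0.01 per question in stable-use
phases, 0.03 in a mild dropout phase, 0.05 in a severe one; "mild constant"
is the stable rate throughout and "severe constant" the severe rate. These
values were chosen once, by back-calculation from the published summary
behaviour of the threshold detector at n = 200 (a 0.01 constant hazard gives
a modest chance that some question of 20 exceeds 3%; a 0.05 constant hazard
straddles both the 3% and 5% thresholds), and are not adjusted thereafter;
every study result echoes the rates used. Transition questions for K = 20:
two-phase at 5/10/15 (start/middle/end); three-phase at (8, 14) middle,
(4, 10) one-start, (11, 17) one-end, (4, 17) ends. Other K use the same
fractional positions.

The simulator emulates phase-structured monotone dropout and nothing else:
no covariate-dependent exits, no content-driven (MAR/MNAR) mechanisms, no
question skipping, no nonresponse or longitudinal attrition. Passing
simulation tests therefore says the detectors work when dropout truly is a
phase-structured hazard process — not that real surveys satisfy that model.

## The evaluation engine

`run_study()` crosses patterns with methods; for each cell it simulates a
batch, applies the detector per replicate, and reports *type I error*
(share of replicates detecting ≥ 2 phases when the simulated pattern has
one) or *sensitivity* (share detecting exactly the true phase count when it
is 2 or 3), with boundary-choice histograms (`boundary_histogram()`,
`plot()`) and fit-failure counts. Per-method replicate counts may differ,
which keeps the expensive GLMM cells tractable: the packaged analyses use
10,000 replicates for threshold cells (they run in seconds) and 500–1,000
for the model-based detectors (~0.5 s per GLMM fit). Each cell derives its
own seed deterministically from the master seed and the cell index, so
results are reproducible cell by cell; a study without a master seed refuses
to run.

```{r study, eval = FALSE}
st <- run_study(study_patterns(), n_replicates = c(threshold = 10000,
                                                   glmm = 500, dtsa = 1000),
                master_seed = 20190823)
st$table
plot(st, "constant/severe/none/threshold")
```

## Known limitations

* The threshold scan inherits the discreteness of count data: with n = 200,
  "exceeds 3%" means "7 or more dropouts" at full sample but "5 or more"
  once attrition has thinned the risk set, so exceedance probabilities drift
  across the survey even under a constant hazard.
* The GLMM's cumulative outcome makes its adjacent contrasts sensitive to
  any nonzero hazard, not to hazard *changes*; interpret its detections
  accordingly.
* DTSA loses information at boundary hazards (no dropouts at a question →
  that pair untestable); under very low hazards many pairs are excluded.
* All methods report at most one contiguous dropout phase; two separated
  dropout bursts are summarized by their outer boundaries.
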