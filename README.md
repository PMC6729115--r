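# attriphase

Identifying phases of dropout attrition in item-by-item survey completion
data.

Web-based surveys lose participants mid-questionnaire, and the losses tend to
come in phases: an early stretch where most respondents keep going, a phase
of elevated exits, and a stable tail of committed respondents. For a survey
of K ordered questions, each participant reduces to an *exit question* q
(they answered `1..q-1` and stopped; completers have none), and the
completion process is summarized by the per-question discrete hazard
h\_q = P(drop out at q | reached q). `attriphase` locates the
elevated-dropout phase with three methods and quantifies how well each one
works:

* **User-specified thresholds** — `detect_threshold()`: the dropout phase
  runs from the first question whose dropout proportion strictly exceeds a
  start threshold to the last question strictly exceeding an end threshold
  (defaults 3%/3%, conditional proportions).
* **Cumulative-dropout GLMM** — `detect_glmm()`: a logistic mixed model
  logit P(dropped by q | b\_i) = β\_q + b\_i with a participant random
  intercept, cell-means question effects, and successive-difference Wald
  contrasts (β\_{q+1} − β\_q), Benjamini–Hochberg adjusted at the 5% level.
* **Discrete-time survival analysis** — `detect_dtsa()`: person-period
  logistic model with a step-function baseline hazard (one dummy per
  question, logit h\_q = γ\_q, completers censored after K); the saturated
  MLE is the empirical logit hazard, and adjacent hazards are compared with
  the same contrast/BH machinery.

A phase-structured simulator (`attrition_pattern()`, `simulate_batch()`)
generates monotone dropout under constant, two-phase, and three-phase hazard
patterns, and `run_study()` measures each detector's type I error (detecting
≥ 2 phases when the hazard is constant) and sensitivity (detecting exactly
the true number of phases when it is 2 or 3), with boundary-choice
histograms.

## Worked example

Simulate a 200-participant, 20-question survey with a severe mid-survey
dropout phase (stable hazard 0.01 on questions 1–7 and 14–20, severe hazard
0.05 on questions 8–13), then ask each detector where the dropout phase is:

```r
library(attriphase)

pat <- attrition_pattern("three_phase", "severe", "middle")
dat <- simulate(pat, seed = 42, n_participants = 200)[[1]]
dat
#> Dropout data: 200 participants, 20 questions
#>   completed: 118 (59%), dropped out: 82

detect_threshold(dat, 0.03, 0.03)
#> Dropout-phase detection (method: threshold)
#>   dropout phase: questions 6 to 12 (of 20)
#>   implied number of phases: 3

detect_glmm(dat)
#> Dropout-phase detection (method: glmm)
#>   dropout phase: questions 6 to 12 (of 20)
#>   implied number of phases: 3

detect_dtsa(dat)
#> Dropout-phase detection (method: dtsa)
#>   no meaningful/significant attrition detected; single stable phase
#>   implied number of phases: 1
```

Both the threshold scan and the GLMM bracket the simulated dropout phase
(questions 8–13; boundary questions 6/12 vs 8/13 reflect sampling noise in
one replicate), while DTSA — whose adjacent-hazard contrasts pay a
multiplicity price over 19 comparisons — finds no significant change. Three
detected phases means stable use, a dropout phase, then stable use again.

How often each method gets it right, over many replicates:

```r
st <- run_study(list(attrition_pattern("constant", "severe"),
                     attrition_pattern("three_phase", "severe", "middle")),
                methods = c("threshold", "dtsa"),
                n_replicates = 1000, master_seed = 7)
st$table
#>        shape severity location    method       metric value n_effective
#>     constant   severe     none threshold type_i_error 0.357        1000
#>     constant   severe     none      dtsa type_i_error 0.000        1000
#>  three_phase   severe   middle threshold  sensitivity 0.973        1000
#>  three_phase   severe   middle      dtsa  sensitivity 0.006        1000
```

Under a constant severe hazard the 3% threshold often sees spurious phases
(type I error 0.36), but it detects a true severe three-phase pattern almost
always (sensitivity 0.97). The correctly specified survival model is the
mirror image: nothing to find under a constant hazard (adjacent hazards are
genuinely equal), and little power to resolve all three phases.
`plot(st, "three_phase/severe/middle/threshold")` shows which questions were
chosen as phase boundaries.

A thin command-line front end over the same functions is installed at
`inst/cli/attriphase.R` (`simulate`, `detect`, `study` subcommands; JSON/YAML
configs; a manifest in every output directory).

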