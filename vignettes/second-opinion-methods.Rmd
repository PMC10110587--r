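---
title: "Methods: a second-opinion model for polygraph examiner conclusions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a second-opinion model for polygraph examiner conclusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A classical polygraph screening ends with a per-topic examiner conclusion:
*Deception Indicated* (DI) or *No Deception Indicated* (NDI). Examiners err —
through fatigue, bias, or genuinely hard calls — and full human quality
assurance (a second examiner re-reading every polygram) costs roughly half
of the original screening time, so in practice it rarely happens.

polyverify implements a machine-learning second opinion. A model is trained
to reproduce examiner conclusions from the raw physiological recordings;
conclusions where the examiner said NDI but the model assigns a high DI
probability are ranked and queued for human QA. The premise is that examiner
errors are rare enough that the model learns the true signal rather than the
errors, so strong disagreement is evidence of a possible error. Notably, a
*perfect* mimic of examiners would be useless here — the value of the model
lies exactly in its residual disagreement.

Because real screening archives are proprietary, the package ships a
synthetic-cohort simulator with known deception ground truth and a
controllable examiner-error rate. Every claim the test suite makes is
measured on that simulator.

## Data model

A **screening** is one recording: 10 physiological channels sampled at a
common rate (31 Hz by default; thoracic/abdominal respiration, phasic and
tonic EDA, photoplethysmogram, absolute blood volume, heart rate, cuff
pressure, tremor, and an auxiliary channel), a table of question events, and
the examiner's per-topic conclusions. A screening comprises several
**tests**; within a test every question is asked one or more times
(**repetitions**), and each repetition carries three timestamps: question
start, question end, and the moment of the answer. *Relevant* questions
probe a screening **topic** (drug abuse, corruption, confidential
information leak, debt, unreported income, criminal history, IRD violation);
*comparison* questions serve as physiological reference and carry no topic.

Recordings are serialized in a self-contained NCCA-ASCII-style text dialect
(see `?write_screening`): a key=value header, a conclusions block, a
pipe-delimited event table, and one block per channel. The dialect is
deliberately plain text so that fixtures are diffable and round trips are
reproducible to 1e-9.

## Feature construction

For each (screening, test, topic) we build exactly **600 named features**:

* **Window.** For every repetition of a relevant question, samples are taken
  from the half-open window `[t_question_start, t_answer + 5 s)`. The
  timestamps bound the stimulus; the 5 s extension (configurable via
  `post_answer_s`) captures the tail of the electrodermal and cardiovascular
  response, which peaks seconds after the answer.
* **Base statistics (5).** min, max, mean, standard deviation (population
  form, so singleton windows give 0), amplitude = max − min.
* **Repetition aggregation (4).** Per question: min, max, mean, and
  `diff` = first repetition − mean of the subsequent repetitions. `diff`
  captures habituation — a genuine orienting response attenuates with
  repetition. With a single repetition `diff` is defined as 0.
* **Question aggregation (3).** Per topic within a test: min, max, mean.

10 channels × 5 × 4 × 3 = 600, named
`CHANNEL_basestat_repagg_qagg` (e.g. `ABS_BLOOD_VOLUME_min_min_mean`). The
dimensionality is invariant to the number of questions and repetitions.

Two design points were genuinely open and are resolved as follows. First,
the standard deviation appears only as a *base* statistic, not as an
aggregator: the 4 × 3 aggregator grid is what yields exactly 600 features,
and observed feature names end in the `{min,max,mean,diff}` /
`{min,max,mean}` pattern. Second, comparison questions do not enter the
canonical 600 features; they exist in the data model (and the simulator
emits them) so that a comparison-centred variant can be layered on without
changing the schema.

## The stacking ensemble

Scoring is two-level, to avoid fitting one 600-feature model directly to a
handful of screening-level labels per topic:

1. **First level** — gradient-boosted trees on the 600 features, producing a
   DI probability per (test, topic) row.
2. **Meta-features** — per (screening, topic), the per-test probabilities
   are reduced to `pred_proba_min`, `pred_proba_max`, `pred_proba_mean`, and
   `pred_proba_diff` = max − mean. The max/diff pair matters because a
   subject may not lie in every test on a topic: one confident test should
   be able to dominate.
3. **Second level** — gradient-boosted trees on the four meta-features plus
   whitelisted covariates (by default subject age and sex; job fields,
   examiner ID, weather and a geomagnetic-storm index can be whitelisted),
   producing the screening-topic DI probability. Categorical covariates are
   one-hot encoded with an explicit unseen-category bucket, since the
   learner used here has no native categorical support.

Both levels use balanced class weighting (positives up-weighted by the
negative/positive ratio): DI prevalence is ~6%, and without rebalancing the
scores degenerate.

Three model variants exist:

* **Basic** (`train_two_level()`): topic-blind — the topic code is absent
  from the features unless `topic_as_feature` is set, so the model can score
  topics it has never seen. Topics can also be excluded from training
  (`exclude_topics`) while still being scored.
* **One-topic** (`train_one_topic()`): identical architecture, but both
  levels train on rows of a single topic; inference still covers all
  topics. Useful when one topic holds most of the DI labels.
* **Universal** (`train_universal()`): the arithmetic mean of the
  confidences of (i) the basic gradient-boosting model with covariates,
  (ii) a one-topic gradient-boosting model with covariates, and (iii) a
  basic model built on a random forest (depth-5 trees, balanced class
  weights). The random-forest member deliberately uses the physiological
  meta-features only — the two boosting members already carry the
  covariates, and an architecturally different third member is there to
  cancel single-model quirks rather than to re-learn the same covariate
  effects. Which topic the one-topic member uses is explicit configuration
  (`one_topic`, default `drug_abuse`).

## Leak-free evaluation

All reported scores are **out-of-fold (OOF)**: folds are assigned at
screening level (stratified group K-fold, K = 5 by default), each fold's
models are trained on the other folds and applied to it, so no model ever
scores a row whose screening it saw in training — including the second
level, which consumes only OOF first-level scores. Stratification targets
the screening-level any-topic DI label and is implemented greedily
(positives and negatives shuffled under the seed, dealt round-robin); exact
stratified grouping is NP-hard and the greedy dealer keeps fold sizes and
positive shares balanced to within one group, which suffices at these
cohort sizes. Fitted bundles record the screening IDs behind every fold
(`train_screenings`) so leakage is auditable, and `predict()` on a training
screening returns its stored OOF score rather than refitting scores.

For unseen screenings, `predict()` averages the K per-fold model pairs.

## Metrics and the operating point

`per_topic_report()` reports ROC AUC, Recall, Precision, F1, Accuracy, TNR
and FPR per topic (plus all topics pooled), as mean (sd) over folds, with DI
counts. The decision threshold is chosen **per fold and per topic** on that
fold's OOF scores as the smallest threshold with realized FPR ≤ 5%
(`operating_point()`, `max_fpr` configurable); the pooled all-topics row
uses the fold's pooled threshold. Per-topic thresholds are the only choice
under which every topic row respects the FPR cap — a pooled threshold lets
false positives concentrate on one topic — and a second-opinion tool must
cap the false-alarm load it puts on examiners per topic, so sensitivity at
a fixed FPR, not accuracy, is the operating quantity. AUC uses the rank-statistic
form with ties counted ½. Zero-denominator conventions (no predicted
positives, no negatives in a cell) return 0/1 with a logged message rather
than erroring, so metric sweeps never crash; single-class topic-fold cells
are excluded from the mean (sd) and logged.

## Flagging and measured error recovery

`flag_candidates()` applies the second-opinion rule: only NDI conclusions
are eligible — a DI conclusion is never flagged — and within each topic the
top-k (or top fraction, or above-threshold) eligible conclusions by model
score are queued, ties broken by screening ID for determinism. Flagging
always consumes OOF scores.

On synthetic cohorts, `recovery_report()` compares the flags with the
injected ground truth: precision@k among flagged conclusions, the base
error rate among eligible NDI conclusions, and their ratio — the
**enrichment** — which is the factor by which model-guided QA beats QA-ing
NDI conclusions at random. Error injection defaults to symmetric flips but
offers an NDI-only mode (only truly deceptive topics mislabelled NDI),
which is the error class a tool restricted to NDI conclusions can recover.

## The synthetic cohort

Each channel is baseline drift + a channel-specific periodic component
(respiration ~0.3 Hz, pulse ~1.1 Hz, slow tonic components) + AR(1) noise
(coefficient 0.9, marginal sd 0.3) + a stimulus-locked response at every
question onset: a gamma-shaped rise–decay kernel starting 0.5 s after
question start, peaking near 2 s, truncated at 8 s, with per-channel sign
and gain (EDA up, blood volume down, ...). On relevant questions of topics
where the subject is truly deceptive, the kernel amplitude is multiplied by
(1 + δ); per-subject and per-event lognormal gains add realistic
variability. Deception is a (subject, topic) property constant across
tests; an optional per-test dropout emulates subjects who do not lie in
every test. Signal units are arbitrary — no published amplitude
distributions exist to calibrate against.

Default cohort conditions: 7 topics, 3 tests per screening, 2 questions per
topic per test, 2 repetitions per question, 2 comparison questions per
test, per-topic deception prevalence 0.06 (matching the <7% DI share of
field archives), examiner error rate 0 (errors are injected explicitly),
31 Hz. Covariates are deliberately signal-free: age uniform on 22–60, sex
balanced, weather Gaussian around one city's norms, examiners drawn from a
pool of eight — so a model cannot cheat by reading deception off the
covariates, and tests of covariate balance guard that property.

What the simulator does **not** emulate: real polygraph waveform
morphology, artifacts and counter-measures, examiner-specific labelling
styles, between-city weather confounding, or correlated topics. Passing
tests therefore demonstrate that the pipeline recovers a stimulus-locked,
label-linked signal and concentrates injected label errors — not that the
models reach any particular accuracy on real field data.

## Numerical and reproducibility choices

* Windows are half-open `[start, end)` with sample *i* (1-based) at time
  `(i − 1)/rate`; a 10 s window at 31 Hz has exactly 310 samples.
* Window statistics and the aggregation tree are computed in C++ (the only
  hot loop); the test suite pins them to an independent nested-loop R
  implementation within 1e-9.
* The text writer prints numbers with 12 significant digits; write→read
  round trips are identity within 1e-9.
* Every source of randomness (simulation, fold dealing, both learners)
  derives from explicit integer seeds; identical config + seed reproduces
  cohorts byte-for-byte and OOF scores exactly. Learners run
  single-threaded for determinism.
* Learner hyperparameters are pinned in `train_config()`: first level
  nrounds 50 / depth 4 / η 0.3 / column subsample 0.25; second level
  nrounds 120 / depth 3 / η 0.1; random forest 120 trees / depth 5. The
  shallow-tree, subsampled settings are sized for 600 strongly correlated
  features and a few thousand rows — the regime the pipeline targets.
* Test problem sizes are chosen to exercise each claim at the smallest
  scale where it is statistically meaningful: n = 300 cohorts for the
  effect-size sweep, n = 500 for error recovery (≈10 injected errors per
  seed at ε = 0.05), ten seeds for the enrichment average.

## Known limitations

* The simulator's separability at large δ is higher than anything
  achievable on field data; AUC values on synthetic cohorts characterize
  the pipeline, not the domain.
* Probabilities are not calibrated; only rankings (AUC, top-k flagging) and
  the fixed-FPR operating point are meaningful.
* Operating points are recomputed per fold, so the deployed threshold for
  new screenings is a separate (pilot-time) choice; the per-fold, per-topic
  thresholds characterize achievable sensitivity, they are not a shipped
  constant.
* `recovery_report()` assumes injected (known) errors; on real data the
  analogue is the double-QA of flagged conclusions, which this package does
  not manage.
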