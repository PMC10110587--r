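# polyverify

A second-opinion tool for classical polygraph screenings.

Polygraph screenings end with a per-topic examiner conclusion: *Deception
Indicated* (DI) or *No Deception Indicated* (NDI). Examiner errors happen —
fatigue, bias, genuinely hard calls — but systematic human QA is too
expensive to apply to every screening. polyverify trains a model to
reproduce examiner conclusions from the raw multi-channel physiological
recordings and then ranks the NDI conclusions the model most strongly
contradicts, so a small, targeted set of screenings can be handed to a
second examiner. Internal-security and screening-QA teams are the intended
users; a synthetic-cohort simulator with known ground truth makes the whole
pipeline testable without access to a proprietary archive.

## What it computes

For each (screening, test, topic), **600 named features** are extracted
from the 10 physiological channels (31 Hz): for every repetition of a
relevant question, the window `[t_question_start, t_answer + 5 s)` yields
five base statistics (min, max, mean, population sd, amplitude); these are
aggregated over repetitions with {min, max, mean, diff} — where
`diff` = first repetition − mean of the rest, a habituation measure — and
over the topic's questions with {min, max, mean}:
10 × 5 × 4 × 3 = 600, named `CHANNEL_stat_repagg_qagg`
(e.g. `ABS_BLOOD_VOLUME_min_min_mean`).

Scoring uses a **two-level stacking ensemble** under leak-free stratified
group 5-fold validation (folds assigned per screening): a first-level
gradient-boosted model scores each test from the 600 features; its
out-of-fold per-test probabilities are reduced to
`pred_proba_{min,max,mean,diff}` per (screening, topic) and, with
whitelisted covariates (age, sex, optionally job/examiner/weather fields),
fed to a second-level model that outputs the screening-topic DI
probability. Three variants exist — a topic-blind *basic* model, a
*one-topic* model trained on a single topic but able to score all of them,
and a *universal* ensemble averaging basic + one-topic boosting models and
a random-forest basic model. Thresholds are chosen per fold and per topic
at a fixed false-positive rate (default FPR ≤ 0.05), and flagging selects the
top-scored NDI conclusions per topic (top-k, top-fraction, or threshold
rule). On synthetic cohorts, `recovery_report()` measures the
**enrichment**: precision of the flags for injected examiner errors divided
by the base error rate among eligible NDI conclusions.

## Worked example

```r
library(polyverify)

cfg <- sim_config(n_screenings = 120,
                  topics = c("drug_abuse", "corruption", "debt"),
                  prevalence = 0.15, delta = 1.5,
                  examiner_error_rate = 0.05, error_mode = "ndi_only",
                  seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <poly_cohort> 120 screenings, 3 topics, delta=1.5, prevalence=0.15, error rate=0.05 (ndi_only)
#>   truly deceptive (screening, topic) pairs: 54 / 360

features <- build_feature_table(cohort)   # 1080 rows x (4 id cols + 600)
meta <- merge(screening_info(cohort), cohort$alt, by = "screening_id")
model <- train_universal(features, meta, cfg = train_config(seed = 42))

per_topic_report(model$oof)
#> Per-topic metrics (mean over 5 folds, operating point FPR <= 0.05)
#>     metric corruption   debt drug_abuse all_topics
#>    ROC_AUC     0.9913 0.9950     1.0000     0.9934
#>     Recall     1.0000 1.0000     1.0000     1.0000
#>  Precision     0.6933 0.8300     0.8100     0.7791
#>         F1     0.8044 0.9048     0.8825     0.8758
#>   Accuracy     0.9667 0.9667     0.9750     0.9583
#>        TNR     0.9635 0.9605     0.9718     0.9511
#>        FPR     0.0365 0.0395     0.0282     0.0489
#> Number of DI: corruption=14 debt=21 drug_abuse=18 all_topics=53

flags <- flag_candidates(model$oof,
                         cohort$truth[, c("screening_id", "topic",
                                          "examiner_label")],
                         top_frac = 0.05)
recovery_report(flags, cohort$truth)
#> <recovery_report> flagged 17, injected errors among them 1
#>   precision@k = 0.0588, base error rate = 0.0033, enrichment = 18.06x
```

Reading the output: the simulator made 54 (screening, topic) pairs truly
deceptive but the examiner labels carry only 53 DI conclusions — one true
DI was mislabelled NDI (the injected "examiner error"). The out-of-fold
scores separate DI from NDI labels at AUC ≈ 0.99, and at the 5%-FPR
operating point the model recalls every DI label. Flagging the top 5% of
NDI conclusions per topic (17 conclusions) catches the injected error:
precision@k 0.059 against a 0.003 base rate — an 18× enrichment over
QA-ing NDI conclusions at random.

The same pipeline runs from one YAML config (`run_pipeline("cfg.yaml",
"out/")`), or from the shell via the thin CLI wrapper
`inst/cli/polyverify.R` with subcommands
`simulate | featurize | train | evaluate | flag | run`.

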