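mk_scores <- function() {
  data.frame(screening_id = c("A", "B", "C", "D", "E", "F"),
             topic = "drug_abuse",
             score = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.99),
             stringsAsFactors = FALSE)
}
mk_conclusions <- function() {
  data.frame(screening_id = c("A", "B", "C", "D", "E", "F"),
             topic = "drug_abuse",
             examiner_label = c("NDI", "NDI", "NDI", "NDI", "NDI", "DI"),
             stringsAsFactors = FALSE)
}

test_that("flagging selects top-scored NDI conclusions and never DI ones", {
  fl <- flag_candidates(mk_scores(), mk_conclusions(), per_topic_k = 2)
  expect_identical(fl$candidates$screening_id, c("A", "B"))
  expect_true(all(fl$candidates$examiner_label == "NDI"))

  # the DI-concluded screening F has the top raw score but is ineligible
  fl5 <- flag_candidates(mk_scores(), mk_conclusions(), per_topic_k = 5)
  expect_false("F" %in% fl5$candidates$screening_id)

  # threshold rule
  ft <- flag_candidates(mk_scores(), mk_conclusions(), threshold = 0.75)
  expect_identical(ft$candidates$screening_id, c("A", "B"))

  # candidates sorted by score descending within topic
  expect_true(all(diff(fl5$candidates$score) <= 0))
})

test_that("flagging rules are validated and ties break deterministically", {
  expect_error(flag_candidates(mk_scores(), mk_conclusions(),
                               per_topic_k = -1), ">= 0")
  expect_error(flag_candidates(mk_scores(), mk_conclusions(),
                               threshold = 1.5), "\\[0, 1\\]")
  expect_error(flag_candidates(mk_scores(), mk_conclusions()), "exactly one")
  expect_error(flag_candidates(mk_scores(), mk_conclusions(),
                               per_topic_k = 2, threshold = 0.5),
               "exactly one")

  sc <- mk_scores()
  sc$score <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.9)
  fl <- flag_candidates(sc, mk_conclusions(), per_topic_k = 2)
  expect_identical(fl$candidates$screening_id, c("A", "B"))  # id ascending
})

test_that("recovery reports precision and enrichment against ground truth", {
  truth <- data.frame(screening_id = c("A", "B", "C", "D", "E", "F"),
                      topic = "drug_abuse",
                      true_deceptive = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                      examiner_label = c("NDI", "NDI", "NDI", "NDI", "NDI", "DI"),
                      injected_error = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  fl <- flag_candidates(mk_scores(), mk_conclusions(), per_topic_k = 2)
  rr <- recovery_report(fl, truth)
  expect_equal(rr$precision_at_k, 1)           # A and B are both errors
  expect_equal(rr$base_rate, 2 / 5)            # among 5 eligible NDI
  expect_equal(rr$enrichment, 2.5)

  # no errors anywhere -> zero precision and enrichment
  truth0 <- truth
  truth0$injected_error <- FALSE
  rr0 <- recovery_report(fl, truth0)
  expect_equal(rr0$precision_at_k, 0)
  expect_equal(rr0$enrichment, 0)

  # flagged conclusion missing from the truth table
  expect_error(recovery_report(fl, truth[-1, ]), "missing")
})

test_that("random flagging has enrichment near 1 (chance baseline)", {
  set.seed(501)
  n <- 1000
  enrich <- replicate(50, {
    truth <- data.frame(screening_id = sprintf("S%04d", 1:n),
                        topic = "drug_abuse", true_deceptive = FALSE,
                        examiner_label = "NDI",
                        injected_error = runif(n) < 0.05,
                        stringsAsFactors = FALSE)
    scores <- data.frame(screening_id = truth$screening_id,
                         topic = "drug_abuse", score = runif(n),
                         stringsAsFactors = FALSE)
    fl <- flag_candidates(scores,
                          truth[, c("screening_id", "topic",
                                    "examiner_label")],
                          top_frac = 0.05)
    recovery_report(fl, truth)$enrichment
  })
  expect_lt(abs(mean(enrich) - 1), 0.5)
})

test_that("the pipeline runs end to end, deterministically, from one config", {
  cfg <- list(
    seed = 7,
    simulation = list(n_screenings = 24, topics = c("drug_abuse",
                                                    "corruption"),
                      tests_per_screening = 2,
                      questions_per_topic_per_test = 2,
                      repetitions_per_question = 2,
                      prevalence = 0.3, delta = 2,
                      examiner_error_rate = 0.1, error_mode = "ndi_only",
                      n_comparison_questions = 1),
    model = list(variant = "basic"),
    flagging = list(top_frac = 0.2))
  d1 <- withr::local_tempdir()
  res <- run_pipeline(cfg, d1)

  for (f in c("config_resolved.yaml", "truth.csv", "alt.csv",
              "oof_scores.csv", "metrics.csv", "metrics.json", "flags.csv",
              "flags.json", "recovery.json", "log.txt"))
    expect_true(file.exists(file.path(d1, f)), info = f)

  # no DI-concluded row is ever flagged
  expect_true(all(res$flags$candidates$examiner_label == "NDI"))
  truth_di <- res$cohort$truth[res$cohort$truth$examiner_label == "DI", ]
  flagged_keys <- paste(res$flags$candidates$screening_id,
                        res$flags$candidates$topic)
  expect_length(intersect(flagged_keys,
                          paste(truth_di$screening_id, truth_di$topic)), 0)

  # rerun reproduces the numeric artifacts byte for byte
  d2 <- withr::local_tempdir()
  run_pipeline(cfg, d2)
  for (f in c("metrics.csv", "oof_scores.csv", "flags.csv"))
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     info = f)

  # seeds are mandatory
  expect_error(run_pipeline(list(simulation = list(n_screenings = 4)),
                            withr::local_tempdir()), "seed")
})

test_that("the command-line wrapper drives the simulate stage", {
  cli <- system.file("cli", "polyverify.R", package = "polyverify")
  expect_true(nzchar(cli))
  d <- withr::local_tempdir()
  cfg_file <- file.path(d, "cfg.yaml")
  yaml::write_yaml(list(simulation = list(
    n_screenings = 2, topics = list("drug_abuse"), tests_per_screening = 1,
    questions_per_topic_per_test = 1, repetitions_per_question = 2,
    n_comparison_questions = 1)), cfg_file)
  out <- file.path(d, "cohort")
  res <- system2("Rscript", c(cli, "simulate", "--seed", "5", "--config",
                              shQuote(cfg_file), "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status"), NULL)
  expect_true(file.exists(file.path(out, "recordings", "S0001.poly")))
  expect_true(file.exists(file.path(out, "truth.csv")))
})
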