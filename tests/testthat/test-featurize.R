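test_that("extract_window honours the half-open window arithmetic", {
  ch <- list(name = "EDA", sampling_rate_hz = 31, samples = rnorm(31 * 30))
  ev <- list(t_question_start = 10, t_answer = 15)
  seg <- extract_window(ch, ev, post_answer_s = 5)
  expect_length(seg, 310)  # 31 Hz x 10 s
  expect_identical(seg, ch$samples[311:620])

  # window reaching past the recording end
  ev_end <- list(t_question_start = 25, t_answer = 30)
  expect_error(extract_window(ch, ev_end, post_answer_s = 5), "past recording")
  # empty window
  expect_error(extract_window(ch, list(t_question_start = 10, t_answer = 10),
                              post_answer_s = 0), "empty")
})

test_that("base statistics match their closed forms", {
  expect_equal(base_stats(c(1, 1, 1)),
               c(min = 1, max = 1, mean = 1, std = 0, amplitude = 0))
  expect_equal(base_stats(c(0, 2, 4)),
               c(min = 0, max = 4, mean = 2, std = sqrt(8 / 3),
                 amplitude = 4))
  expect_equal(base_stats(-3),
               c(min = -3, max = -3, mean = -3, std = 0, amplitude = 0))
  expect_error(base_stats(numeric(0)), "empty")
})

test_that("repetition aggregation implements the habituation diff", {
  expect_equal(aggregate_repetitions(c(1, 3, 5)),
               c(min = 1, max = 5, mean = 3, diff = 1 - 4))
  expect_equal(aggregate_repetitions(0.7),
               c(min = 0.7, max = 0.7, mean = 0.7, diff = 0))
  expect_equal(aggregate_repetitions(c(2, 2, 2, 2)),
               c(min = 2, max = 2, mean = 2, diff = 0))
  expect_error(aggregate_repetitions(numeric(0)), "no repetition")
})

test_that("meta-features follow the stated formulas", {
  expect_equal(meta_features(c(0.2, 0.6, 0.4)),
               c(pred_proba_min = 0.2, pred_proba_max = 0.6,
                 pred_proba_mean = 0.4, pred_proba_diff = 0.2))
  expect_equal(meta_features(0.7),
               c(pred_proba_min = 0.7, pred_proba_max = 0.7,
                 pred_proba_mean = 0.7, pred_proba_diff = 0))
  expect_equal(meta_features(c(0, 1)),
               c(pred_proba_min = 0, pred_proba_max = 1,
                 pred_proba_mean = 0.5, pred_proba_diff = 0.5))
  expect_error(meta_features(numeric(0)), "no test scores")
  expect_error(meta_features(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("feature rows have exactly 600 uniquely named finite features", {
  s <- tiny_screening(201)
  row <- build_feature_row(s, 0, "drug_abuse")
  feats <- row[, !(names(row) %in% c("screening_id", "test_index", "topic",
                                     "label"))]
  expect_identical(ncol(feats), 600L)
  expect_false(anyDuplicated(names(feats)) > 0)
  expect_true(all(is.finite(as.numeric(feats[1, ]))))
  expect_true(all(grepl(
    "^[A-Z_]+_(min|max|mean|std|amplitude)_(min|max|mean|diff)_(min|max|mean)$",
    names(feats))))
  expect_identical(names(feats), feature_names())
})

test_that("a single-question, single-repetition topic degenerates correctly", {
  cfg <- tiny_config(202, topics = "drug_abuse", tests_per_screening = 1,
                     questions_per_topic_per_test = 1,
                     repetitions_per_question = 1)
  s <- simulate_screening(cfg, seed = 202)$screening
  f <- build_feature_row(s, 0, "drug_abuse")
  v <- setNames(as.numeric(f[, feature_names()]), feature_names())
  expect_true(all(is.finite(v)))
  expect_true(all(v[grepl("_diff_", names(v))] == 0))
  # with one question and one repetition, min = max = mean at both levels
  for (cn in c("EDA", "CARDIO")) for (st in c("mean", "std")) {
    vals <- v[grep(paste0("^", cn, "_", st, "_(min|max|mean)_"), names(v))]
    nondiff <- vals[!grepl("_diff_", names(vals))]
    expect_equal(unname(nondiff), rep(nondiff[[1]], length(nondiff)))
  }
})

test_that("features agree with the independent nested-loop oracle", {
  for (seed in c(203, 204, 205)) {
    s <- tiny_screening(seed)
    for (tp in c("drug_abuse", "corruption")) {
      got <- build_feature_row(s, 1, tp)
      want <- oracle_features(s, 1, tp)
      expect_equal(setNames(as.numeric(got[, names(want)]), names(want)),
                   want, tolerance = 1e-9)
    }
  }
})

test_that("features are equivariant under positive rescaling of one channel", {
  s <- tiny_screening(206)
  f0 <- build_feature_row(s, 0, "drug_abuse")
  s2 <- s
  s2$channels$EDA$samples <- 3 * s2$channels$EDA$samples
  f1 <- build_feature_row(s2, 0, "drug_abuse")
  eda <- grep("^EDA_", feature_names(), value = TRUE)
  other <- setdiff(feature_names(), eda)
  expect_equal(as.numeric(f1[, eda]), 3 * as.numeric(f0[, eda]),
               tolerance = 1e-12)
  expect_identical(as.numeric(f1[, other]), as.numeric(f0[, other]))
})

test_that("the feature table enumerates (screening, test, topic) combinations", {
  co <- simulate_cohort(tiny_config(207, n_screenings = 4))
  ft <- build_feature_table(co)
  expect_identical(nrow(ft), 4L * 2L * 2L)  # screenings x tests x topics
  expect_identical(ncol(ft), 604L)
  expect_false(any(duplicated(ft[, c("screening_id", "test_index", "topic")])))
  # deterministic ordering
  expect_identical(ft$screening_id, sort(ft$screening_id))

  # a (test, topic) with no relevant questions yields no row
  s <- co$screenings[[1]]
  ev <- s$events
  drop <- ev$qtype == "relevant" & ev$topic == "corruption" & ev$test_index == 1
  s$events <- ev[!drop, ]
  ft2 <- build_feature_table(c(list(s), co$screenings[-1]))
  expect_identical(nrow(ft2), nrow(ft) - 1L)
  missing_row <- ft2[ft2$screening_id == s$screening_id &
                       ft2$test_index == 1 & ft2$topic == "corruption", ]
  expect_identical(nrow(missing_row), 0L)

  # empty cohort -> empty table with the full schema
  empty <- build_feature_table(list())
  expect_identical(nrow(empty), 0L)
  expect_identical(ncol(empty), 604L)
})
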