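# one moderately sized strong-signal cohort shared by several blocks
shared_env <- new.env()
stacking_fixture <- function() {
  if (is.null(shared_env$model)) {
    cfg <- tiny_config(301, n_screenings = 60, prevalence = 0.25, delta = 2)
    co <- simulate_cohort(cfg)
    rows <- build_feature_table(co)
    shared_env$cohort <- co
    shared_env$rows <- rows
    shared_env$model <- fit_basic(co, seed = 301, rows = rows)
  }
  shared_env
}

test_that("group folds keep screenings intact and stratify the DI share", {
  rows <- data.frame(
    screening_id = rep(sprintf("S%03d", 1:10), each = 4),
    label = rep(c("DI", rep("NDI", 4)), 8),
    stringsAsFactors = FALSE)
  f <- make_group_folds(rows, k = 5, seed = 1)
  expect_setequal(names(f), unique(rows$screening_id))
  expect_identical(as.integer(sort(table(f))), rep(2L, 5))

  # no screening split across folds is structural: one fold per screening id
  expect_identical(length(f), 10L)

  # k exceeding the number of screenings
  expect_error(make_group_folds(rows[1:20, ], k = 6), "exceeds")

  # stratification: 100 screenings at 20% positive -> each fold 10%-30%
  big <- data.frame(screening_id = sprintf("S%03d", 1:100),
                    label = rep(c("DI", "NDI", "NDI", "NDI", "NDI"), 20),
                    stringsAsFactors = FALSE)
  fb <- make_group_folds(big, k = 5, seed = 2)
  pos <- big$label == "DI"
  for (k in 1:5) {
    share <- mean(pos[fb[big$screening_id] == k])
    expect_gte(share, 0.10); expect_lte(share, 0.30)
  }
  # deterministic under the seed
  expect_identical(fb, make_group_folds(big, k = 5, seed = 2))
})

test_that("training is deterministic under a fixed config and seed", {
  fx <- stacking_fixture()
  m2 <- fit_basic(fx$cohort, seed = 301, rows = fx$rows)
  expect_identical(fx$model$oof$score, m2$oof$score)
  expect_identical(fx$model$oof_test$score, m2$oof_test$score)
})

test_that("out-of-fold scoring never sees the scored screening", {
  fx <- stacking_fixture()
  m <- fx$model
  # instrumented audit: fold f's training screenings are disjoint from fold f
  for (f in seq_along(m$first_level)) {
    members <- names(m$folds)[m$folds == f]
    expect_length(intersect(m$train_screenings[[f]], members), 0)
  }
  # every input row scored exactly once, in [0, 1]
  expect_false(anyNA(m$oof_test$score))
  expect_identical(nrow(m$oof_test), nrow(fx$rows))
  expect_true(all(m$oof$score >= 0 & m$oof$score <= 1))

  # scoring a training screening returns its stored OOF score exactly
  s <- fx$cohort$screenings[[3]]
  p <- predict(m, s)
  stored <- m$oof[m$oof$screening_id == s$screening_id, ]
  expect_identical(unname(p[stored$topic]), stored$score)
})

test_that("an unseen screening gets one probability per topic", {
  fx <- stacking_fixture()
  cfg <- tiny_config(999, n_screenings = 1)
  new_s <- simulate_screening(cfg, seed = 999,
                              screening_id = "UNSEEN01")$screening
  p <- predict(fx$model, new_s)
  expect_setequal(names(p), c("drug_abuse", "corruption"))
  expect_true(all(p >= 0 & p <= 1))

  # screening with no relevant questions cannot be scored
  bad <- new_s
  bad$events <- bad$events[bad$events$qtype != "relevant", ]
  expect_error(predict(fx$model, bad), "no relevant questions")
})

test_that("strong signal is recovered and labels, not noise, drive the score", {
  fx <- stacking_fixture()
  expect_gte(roc_auc(fx$model$oof$score, fx$model$oof$label), 0.9)
})

test_that("single-class training splits fail loudly with the fold named", {
  fx <- stacking_fixture()
  rows <- fx$rows
  # concentrate every DI screening in fold 1: training folds 2..5 keep both
  # classes, but fold 1's complement loses all positives
  di_screenings <- unique(rows$screening_id[rows$label == "DI"])
  folds <- make_group_folds(rows, k = 5, seed = 301)
  folds[di_screenings] <- 1L
  # fold 1's training complement now holds no DI screening at all
  expect_error(
    train_two_level(rows, folds = folds, cfg = train_config(seed = 1)),
    "fold 1 has a single class")
})

test_that("unknown alternative-data fields are rejected", {
  fx <- stacking_fixture()
  meta <- screening_info(fx$cohort)
  expect_error(
    train_two_level(fx$rows, meta,
                    cfg = train_config(seed = 1,
                                       alt_fields = c("subject_age",
                                                      "shoe_size"))),
    "shoe_size")
})

test_that("a one-topic model trains on its topic but scores all topics", {
  fx <- stacking_fixture()
  m <- train_one_topic(fx$rows, "drug_abuse",
                       meta = screening_info(fx$cohort),
                       cfg = train_config(seed = 302))
  # inference covers every (screening, topic) pair
  expect_identical(nrow(m$oof), nrow(unique(fx$rows[, c("screening_id",
                                                        "topic")])))
  # cross-topic transfer: trained on drug_abuse, still separates corruption
  corr <- m$oof[m$oof$topic == "corruption", ]
  expect_gte(roc_auc(corr$score, corr$label), 0.8)

  expect_error(train_one_topic(fx$rows, "debt", cfg = train_config(seed = 1)),
               "absent")
})

test_that("universal scoring averages its members' confidences", {
  expect_equal(score_universal(0.9, 0.6, 0.3), 0.6)
  expect_equal(score_universal(0.4, 0.4, 0.4), 0.4)
  expect_equal(score_universal(0, 0, 1), 1 / 3)
  expect_equal(score_universal(c(0.9, 0), c(0.6, 0), c(0.3, 1)),
               c(0.6, 1 / 3))
  expect_error(score_universal(0.5, 1.2, 0.1), "\\[0, 1\\]")
})

test_that("class rebalancing keeps scores informative at 5% prevalence", {
  cfg <- tiny_config(303, n_screenings = 80, prevalence = 0.05, delta = 2)
  co <- simulate_cohort(cfg)
  m <- fit_basic(co, seed = 303)
  expect_gt(var(m$oof_test$score), 0)
  expect_gt(max(m$oof_test$score[m$oof_test$label == 1]), 0.5)
})

test_that("the second level adds value when deception dilutes across tests", {
  cfg <- tiny_config(304, n_screenings = 80, prevalence = 0.3, delta = 2,
                     tests_per_screening = 3, test_dropout = 0.5)
  co <- simulate_cohort(cfg)
  m <- fit_basic(co, seed = 304)
  auc_first <- roc_auc(m$oof_test$score, m$oof_test$label)
  auc_second <- roc_auc(m$oof$score, m$oof$label)
  expect_gte(auc_second, auc_first - 0.02)
})
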