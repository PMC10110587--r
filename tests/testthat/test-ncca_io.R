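test_that("write -> read round trip is the identity on the domain model", {
  s <- tiny_screening(101)
  p <- withr::local_tempfile(fileext = ".poly")
  write_screening(s, p)
  s2 <- read_screening(p)

  for (f in c("screening_id", "date", "city", "subject_age", "subject_sex",
              "subject_type", "current_position", "current_department",
              "accepted_position", "accepted_department", "examiner_id"))
    expect_identical(s2[[f]], s[[f]], info = f)
  expect_identical(s2$conclusions, s$conclusions)
  expect_identical(names(s2$channels), names(s$channels))
  for (cn in names(s$channels)) {
    expect_equal(s2$channels[[cn]]$samples, s$channels[[cn]]$samples,
                 tolerance = 1e-9)
    expect_equal(s2$channels[[cn]]$sampling_rate_hz,
                 s$channels[[cn]]$sampling_rate_hz)
  }
  expect_identical(s2$events$question_id, s$events$question_id)
  expect_identical(s2$events$qtype, s$events$qtype)
  expect_identical(s2$events$topic, s$events$topic)
  expect_identical(s2$events$test_index, s$events$test_index)
  expect_identical(s2$events$repetition_index, s$events$repetition_index)
  for (tc in c("t_question_start", "t_question_end", "t_answer"))
    expect_equal(s2$events[[tc]], s$events[[tc]], tolerance = 1e-9)
})

test_that("writing the same screening twice is byte-identical", {
  s <- tiny_screening(102)
  p1 <- withr::local_tempfile(fileext = ".poly")
  p2 <- withr::local_tempfile(fileext = ".poly")
  write_screening(s, p1)
  write_screening(s, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("writer refuses screenings violating invariants", {
  s <- tiny_screening(103)
  p <- withr::local_tempfile(fileext = ".poly")

  s9 <- s
  s9$channels <- s9$channels[1:9]
  expect_error(write_screening(s9, p), "channel_count")

  snan <- s
  snan$channels$EDA$samples[5] <- NaN
  expect_error(write_screening(snan, p), "finite_samples")

  sorphan <- s
  sorphan$conclusions <- c(sorphan$conclusions, debt = "NDI")
  expect_error(write_screening(sorphan, p), "topic_has_events")
})

test_that("validate_screening reports each broken invariant and nothing else", {
  s <- tiny_screening(104)
  expect_identical(nrow(validate_screening(s)), 0L)

  snan <- s
  snan$channels$TREMOR$samples[1] <- NA_real_
  v <- validate_screening(snan)
  expect_identical(v$rule, "finite_samples")

  sbad <- s
  sbad$events$t_answer[3] <- sbad$events$t_question_start[3] - 1
  v <- validate_screening(sbad)
  expect_true("timestamp_order" %in% v$rule)

  sdur <- s
  sdur$channels$EDA$samples <- sdur$channels$EDA$samples[1:10]
  v <- validate_screening(sdur)
  expect_true("common_duration" %in% v$rule)
})

test_that("every simulated screening validates cleanly across seeds", {
  for (seed in 1:100) {
    s <- tiny_screening(seed, n_screenings = 1)
    expect_identical(nrow(validate_screening(s)), 0L)
  }
})

test_that("reader rejects systematically corrupted files", {
  s <- tiny_screening(105)
  p <- withr::local_tempfile(fileext = ".poly")
  write_screening(s, p)
  lines <- readLines(p)
  corrupt <- function(mutate) {
    p2 <- withr::local_tempfile(fileext = ".poly",
                                .local_envir = parent.frame())
    writeLines(mutate(lines), p2)
    p2
  }

  # missing signature
  expect_error(read_screening(corrupt(function(l) l[-1])), "signature")
  # missing header field
  expect_error(read_screening(corrupt(function(l)
    l[!startsWith(l, "subject_age=")])), "missing field")
  # event with t_answer before t_question_start
  i <- grep("^R_", lines)[1]
  expect_error(read_screening(corrupt(function(l) {
    f <- strsplit(l[i], "|", fixed = TRUE)[[1]]
    f[8] <- "0.5"
    l[i] <- paste(f, collapse = "|")
    l
  })), "timestamp_order|within_recording")
  # wrong event field count
  expect_error(read_screening(corrupt(function(l) {
    l[i] <- sub("\\|no$", "", sub("\\|yes$", "", l[i]))
    l
  })), "field count")
  # sample count mismatch
  j <- grep("^n_samples=", lines)[1]
  expect_error(read_screening(corrupt(function(l) {
    l[j] <- "n_samples=1"
    l
  })), "expected 1 samples")
  # non-numeric sample
  expect_error(read_screening(corrupt(function(l) {
    l[j + 1] <- paste(l[j + 1], "oops")
    l
  })), "non-numeric sample|expected")
  # invalid question type
  expect_error(read_screening(corrupt(function(l) {
    l[i] <- sub("relevant", "irrelevant", l[i], fixed = TRUE)
    l
  })), "qtype")
  # missing terminator
  expect_error(read_screening(corrupt(function(l) l[l != "[END]"])), "END")
  # unknown conclusion label
  k <- grep("^(drug_abuse|corruption)=", lines)[1]
  expect_error(read_screening(corrupt(function(l) {
    l[k] <- sub("=.*$", "=MAYBE", l[k])
    l
  })), "conclusion")
})

test_that("a minimal screening (1 test, 1 topic) survives the round trip", {
  cfg <- tiny_config(106, topics = "drug_abuse", tests_per_screening = 1,
                     questions_per_topic_per_test = 1, prevalence = 1)
  s <- simulate_screening(cfg, seed = 106, screening_id = "MIN01")$screening
  p <- withr::local_tempfile(fileext = ".poly")
  write_screening(s, p)
  s2 <- read_screening(p)
  expect_identical(s2$conclusions, c(drug_abuse = "DI"))
  expect_identical(nrow(s2$events), nrow(s$events))
})
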