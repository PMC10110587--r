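# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no stored data files.

# small, fast cohort configuration used throughout the unit tests
tiny_config <- function(seed, n_screenings = 10, topics = c("drug_abuse",
                                                            "corruption"),
                        tests_per_screening = 2,
                        questions_per_topic_per_test = 2,
                        repetitions_per_question = 2,
                        prevalence = 0.25, delta = 2, ...) {
  sim_config(n_screenings = n_screenings, topics = topics,
             tests_per_screening = tests_per_screening,
             questions_per_topic_per_test = questions_per_topic_per_test,
             repetitions_per_question = repetitions_per_question,
             prevalence = prevalence, delta = delta,
             n_comparison_questions = 1, seed = seed, ...)
}

tiny_screening <- function(seed, ...) {
  simulate_screening(tiny_config(seed, ...), seed = seed,
                     screening_id = sprintf("T%04d", seed))$screening
}

# --- independent brute-force feature oracle -------------------------------
# Plain nested loops, no shared code with the package beyond the documented
# conventions: window [t_question_start, t_answer + post) indexed by
# floor/ceiling at the sampling rate; population sd; rep diff = first minus
# mean of the rest (0 for singletons); q-level aggregation min/max/mean.
oracle_features <- function(screening, test_index, topic, post_answer_s = 5) {
  stats_of <- function(seg) {
    m <- sum(seg) / length(seg)
    c(min = min(seg), max = max(seg), mean = m,
      std = sqrt(sum((seg - m)^2) / length(seg)),
      amplitude = max(seg) - min(seg))
  }
  ev <- screening$events
  keep <- which(ev$qtype == "relevant" & !is.na(ev$topic) &
                  ev$topic == topic & ev$test_index == test_index)
  out <- c()
  for (cn in polygraph_channels()) {
    ch <- screening$channels[[cn]]
    rate <- ch$sampling_rate_hz
    for (st in c("min", "max", "mean", "std", "amplitude")) {
      # per-question repetition aggregates
      qids <- unique(ev$question_id[keep])
      per_q <- list()
      for (q in qids) {
        rows <- keep[ev$question_id[keep] == q]
        rows <- rows[order(ev$repetition_index[rows])]
        vals <- c()
        for (r in rows) {
          a <- floor(ev$t_question_start[r] * rate) + 1
          b <- ceiling((ev$t_answer[r] + post_answer_s) * rate)
          vals <- c(vals, stats_of(ch$samples[a:b])[[st]])
        }
        d <- if (length(vals) == 1) 0 else vals[1] - mean(vals[-1])
        per_q[[q]] <- c(min = min(vals), max = max(vals),
                        mean = mean(vals), diff = d)
      }
      for (ra in c("min", "max", "mean", "diff")) {
        v <- sapply(per_q, function(x) x[[ra]])
        for (qa in c("min", "max", "mean")) {
          val <- switch(qa, min = min(v), max = max(v), mean = mean(v))
          out[paste(cn, st, ra, qa, sep = "_")] <- val
        }
      }
    }
  }
  out
}

# --- brute-force AUC oracle: pair counting with ties worth 1/2 ------------
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (if (p > n) 1 else if (p == n) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# cohort -> fitted basic model OOF table, with covariates joined
fit_basic <- function(cohort, seed, cfg = NULL, rows = NULL) {
  if (is.null(rows)) rows <- build_feature_table(cohort)
  meta <- merge(screening_info(cohort), cohort$alt, by = "screening_id")
  if (is.null(cfg)) cfg <- train_config(seed = seed)
  train_two_level(rows, meta, cfg = cfg)
}
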