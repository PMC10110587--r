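BASE_STATS <- c("min", "max", "mean", "std", "amplitude")
REP_AGGS <- c("min", "max", "mean", "diff")
Q_AGGS <- c("min", "max", "mean")

#' Canonical 600 feature names
#'
#' Feature names follow the grammar `CHANNEL_basestat_repagg_qagg`, e.g.
#' `ABS_BLOOD_VOLUME_min_min_mean`: the base statistic of the window
#' (min/max/mean/std/amplitude), aggregated over a question's repetitions
#' (min/max/mean/diff), then over the topic's questions (min/max/mean).
#' 10 channels x 5 x 4 x 3 = 600.
#'
#' @param channels Channel names (default [polygraph_channels()]).
#' @return Character vector of length `10 * 60` in canonical order.
#' @export
feature_names <- function(channels = polygraph_channels()) {
  out <- character(length(channels) * length(BASE_STATS) *
                     length(REP_AGGS) * length(Q_AGGS))
  i <- 0L
  for (ch in channels) for (s in BASE_STATS) for (r in REP_AGGS)
    for (q in Q_AGGS) {
      i <- i + 1L
      out[i] <- paste(ch, s, r, q, sep = "_")
    }
  out
}

#' Extract the analysis window of one question event from a channel
#'
#' The window is half-open `[t_question_start, t_answer + post_answer_s)`,
#' in seconds from recording start; a sample at time `(i-1)/rate` belongs to
#' the window when it falls inside the interval. Physiological responses
#' outlast the answer, so the window extends `post_answer_s` seconds past
#' the answer timestamp (default 5 s).
#'
#' @param channel A channel list (`name`, `sampling_rate_hz`, `samples`).
#' @param event One-row event data frame (or list) with `t_question_start`
#'   and `t_answer`.
#' @param post_answer_s Seconds appended after the answer timestamp.
#' @return Numeric vector of samples; errors if the window is empty or
#'   extends past the recording end.
#' @export
extract_window <- function(channel, event, post_answer_s = 5) {
  rate <- channel$sampling_rate_hz
  t0 <- event$t_question_start
  t1 <- event$t_answer + post_answer_s
  if (t1 <= t0) stop("empty analysis window", call. = FALSE)
  i0 <- floor(t0 * rate) + 1L          # first sample with (i-1)/rate >= t0
  i1 <- ceiling(t1 * rate)             # last sample with (i-1)/rate < t1
  if (i0 < 1L) stop("window starts before the recording", call. = FALSE)
  if (i1 > length(channel$samples))
    stop(sprintf("window [%.3f, %.3f) extends past recording end (%.3f s)",
                 t0, t1, length(channel$samples) / rate), call. = FALSE)
  channel$samples[i0:i1]
}

#' Base statistics of a signal window
#'
#' The five window statistics from which all features are built: minimum,
#' maximum, mean, standard deviation, and amplitude (max - min). The
#' standard deviation is the population form (divide by n), so a singleton
#' window yields 0 rather than NA.
#'
#' @param segment Non-empty numeric vector.
#' @return Named numeric vector `c(min, max, mean, std, amplitude)`.
#' @export
base_stats <- function(segment) {
  if (length(segment) == 0) stop("empty segment", call. = FALSE)
  mn <- min(segment); mx <- max(segment); m <- mean(segment)
  c(min = mn, max = mx, mean = m,
    std = sqrt(mean((segment - m)^2)),
    amplitude = mx - mn)
}

#' Aggregate a per-repetition statistic over a question's repetitions
#'
#' Given one statistic's values across the ordered repetitions of a
#' question, returns min, max, mean, and `diff` — the value at the first
#' repetition minus the mean over the subsequent repetitions, capturing
#' habituation of the response. With a single repetition `diff` is 0.
#'
#' @param values Numeric vector in repetition order, length >= 1.
#' @return Named numeric vector `c(min, max, mean, diff)`.
#' @export
aggregate_repetitions <- function(values) {
  if (length(values) == 0) stop("no repetition values", call. = FALSE)
  d <- if (length(values) == 1) 0 else values[1] - mean(values[-1])
  c(min = min(values), max = max(values), mean = mean(values), diff = d)
}

#' Second-level meta-features from first-level test scores
#'
#' Aggregates the first-level model's per-test DI probabilities for one
#' (screening, topic) into the four meta-features fed to the second-level
#' model: `pred_proba_min`, `pred_proba_max`, `pred_proba_mean`, and
#' `pred_proba_diff` = max - mean.
#'
#' @param test_scores Probabilities in `[0, 1]`, one per test, length >= 1.
#' @return Named numeric vector of the four meta-features.
#' @export
meta_features <- function(test_scores) {
  if (length(test_scores) == 0) stop("no test scores", call. = FALSE)
  if (any(!is.finite(test_scores)) || any(test_scores < 0 | test_scores > 1))
    stop("test scores must lie in [0, 1]", call. = FALSE)
  mx <- max(test_scores); mn <- min(test_scores); m <- mean(test_scores)
  c(pred_proba_min = mn, pred_proba_max = mx, pred_proba_mean = m,
    pred_proba_diff = mx - m)
}

# window sample-index bounds for a set of events; errors mirror
# extract_window's contract
.window_bounds <- function(t_start, t_answer, rate, n_samples,
                           post_answer_s) {
  t1 <- t_answer + post_answer_s
  if (any(t1 <= t_start)) stop("empty analysis window", call. = FALSE)
  i0 <- floor(t_start * rate) + 1L
  i1 <- ceiling(t1 * rate)
  if (any(i0 < 1L)) stop("window starts before the recording", call. = FALSE)
  if (any(i1 > n_samples))
    stop("window extends past recording end", call. = FALSE)
  list(i0 = i0, i1 = i1)
}

# base stats for every event window of one channel: matrix [event, 5]
.stats_matrix <- function(samples, i0, i1) {
  .window_stats_cpp(samples, as.integer(i0), as.integer(i1))
}

# aggregate one (test, topic, channel) block: S holds the per-repetition
# base stats of that block's events; returns the 60 feature values in
# canonical (stat, rep_agg, q_agg) order
.agg_block <- function(S, question_id, repetition_index) {
  qcode <- match(question_id, unique(question_id)) - 1L
  .agg_block_cpp(S, as.integer(qcode), as.integer(repetition_index))
}

# all feature rows of one screening at once: per-event window stats are
# computed once per channel and shared across the (test, topic) blocks
.screening_feature_matrix <- function(screening, post_answer_s, channels) {
  ev <- screening$events
  rel <- which(ev$qtype == "relevant" & !is.na(ev$topic))
  if (length(rel) == 0)
    return(list(combos = data.frame(test_index = integer(0),
                                    topic = character(0)),
                M = matrix(numeric(0), 0, length(feature_names(channels)))))
  rate <- screening$channels[[1]]$sampling_rate_hz
  n <- length(screening$channels[[1]]$samples)
  b <- .window_bounds(ev$t_question_start[rel], ev$t_answer[rel], rate, n,
                      post_answer_s)
  stats_by_channel <- lapply(channels, function(cn) {
    chan <- screening$channels[[cn]]
    if (is.null(chan)) stop("screening lacks channel ", cn, call. = FALSE)
    .stats_matrix(chan$samples, b$i0, b$i1)
  })

  combos <- unique(data.frame(test_index = ev$test_index[rel],
                              topic = ev$topic[rel],
                              stringsAsFactors = FALSE))
  combos <- combos[order(combos$test_index, combos$topic), , drop = FALSE]
  nblock <- length(BASE_STATS) * length(REP_AGGS) * length(Q_AGGS)
  M <- matrix(NA_real_, nrow(combos), length(channels) * nblock)
  for (k in seq_len(nrow(combos))) {
    sel <- which(ev$test_index[rel] == combos$test_index[k] &
                   ev$topic[rel] == combos$topic[k])
    qid <- ev$question_id[rel][sel]
    rep_i <- ev$repetition_index[rel][sel]
    for (ci in seq_along(channels)) {
      M[k, (ci - 1L) * nblock + seq_len(nblock)] <-
        .agg_block(stats_by_channel[[ci]][sel, , drop = FALSE], qid, rep_i)
    }
  }
  colnames(M) <- feature_names(channels)
  if (any(!is.finite(M)))
    stop("non-finite feature value for screening ", screening$screening_id,
         call. = FALSE)
  list(combos = combos, M = M)
}

# named numeric(600) for one (test, topic)
.features_for <- function(screening, test_index, topic,
                          post_answer_s, channels) {
  ev <- screening$events
  sel <- which(ev$qtype == "relevant" & !is.na(ev$topic) & ev$topic == topic &
                 ev$test_index == test_index)
  if (length(sel) == 0)
    stop(sprintf("screening %s: no relevant question for topic '%s' in test %d",
                 screening$screening_id, topic, test_index), call. = FALSE)
  rate <- screening$channels[[1]]$sampling_rate_hz
  n <- length(screening$channels[[1]]$samples)
  b <- .window_bounds(ev$t_question_start[sel], ev$t_answer[sel], rate, n,
                      post_answer_s)
  nblock <- length(BASE_STATS) * length(REP_AGGS) * length(Q_AGGS)
  out <- numeric(length(channels) * nblock)
  for (ci in seq_along(channels)) {
    chan <- screening$channels[[channels[ci]]]
    if (is.null(chan)) stop("screening lacks channel ", channels[ci],
                            call. = FALSE)
    S <- .stats_matrix(chan$samples, b$i0, b$i1)
    out[(ci - 1L) * nblock + seq_len(nblock)] <-
      .agg_block(S, ev$question_id[sel], ev$repetition_index[sel])
  }
  names(out) <- feature_names(channels)
  if (any(!is.finite(out)))
    stop("non-finite feature value for screening ", screening$screening_id,
         call. = FALSE)
  out
}

#' Build the 600-feature row for one (screening, test, topic)
#'
#' Implements the hierarchical aggregation: for each channel and each of the
#' five window base statistics, repetition values are aggregated per
#' question with {min, max, mean, diff}, and the per-question values are
#' aggregated over the topic's questions with {min, max, mean}, giving
#' exactly `10 x 5 x 4 x 3 = 600` named features. The row's label is the
#' examiner conclusion for the topic.
#'
#' @param screening A screening object.
#' @param test_index 0-based test index.
#' @param topic Topic code; must have at least one relevant question in the
#'   test.
#' @param post_answer_s Window extension, see [extract_window()].
#' @param channels Channel names in canonical order.
#' @return One-row data frame: `screening_id`, `test_index`, `topic`,
#'   `label` ("DI"/"NDI" or NA if no conclusion), then the 600 features.
#' @export
build_feature_row <- function(screening, test_index, topic,
                              post_answer_s = 5,
                              channels = polygraph_channels()) {
  f <- .features_for(screening, test_index, topic, post_answer_s, channels)
  lab <- screening$conclusions[topic]
  row <- data.frame(screening_id = screening$screening_id,
                    test_index = as.integer(test_index), topic = topic,
                    label = if (is.null(lab) || is.na(lab)) NA_character_
                            else unname(lab),
                    stringsAsFactors = FALSE)
  cbind(row, as.data.frame(as.list(f), check.names = FALSE))
}

#' Build the feature table for a cohort
#'
#' One 600-feature row per (screening, test, topic) combination that has at
#' least one relevant question; combinations failing the preconditions are
#' skipped with a warning. Rows are ordered by screening_id, test_index,
#' topic.
#'
#' @param cohort A `poly_cohort` or a list of screening objects.
#' @param post_answer_s Window extension, see [extract_window()].
#' @param channels Channel names.
#' @return Data frame with id columns `screening_id`, `test_index`, `topic`,
#'   `label`, followed by the 600 feature columns.
#' @export
build_feature_table <- function(cohort, post_answer_s = 5,
                                channels = polygraph_channels()) {
  screenings <- if (inherits(cohort, "poly_cohort")) cohort$screenings
                else cohort
  fn <- feature_names(channels)
  parts <- list()
  for (s in screenings) {
    res <- tryCatch(
      .screening_feature_matrix(s, post_answer_s, channels),
      error = function(e) {
        warning(sprintf("skipping screening %s: %s", s$screening_id,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(res) || nrow(res$combos) == 0) next
    lab <- s$conclusions[res$combos$topic]
    ids <- data.frame(screening_id = s$screening_id,
                      test_index = as.integer(res$combos$test_index),
                      topic = res$combos$topic,
                      label = ifelse(is.na(lab), NA_character_, unname(lab)),
                      stringsAsFactors = FALSE)
    parts[[length(parts) + 1L]] <- cbind(ids, as.data.frame(res$M,
                                                            check.names = FALSE))
  }
  if (length(parts) == 0) {
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(fn)), fn),
                           check.names = FALSE)
    return(cbind(data.frame(screening_id = character(0),
                            test_index = integer(0), topic = character(0),
                            label = character(0), stringsAsFactors = FALSE),
                 empty))
  }
  tab <- as.data.frame(data.table::rbindlist(parts), check.names = FALSE)
  tab <- tab[order(tab$screening_id, tab$test_index, tab$topic), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}
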