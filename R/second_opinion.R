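#' Flag examiner NDI conclusions that the model contradicts
#'
#' The second-opinion rule: only conclusions where the examiner found No
#' Deception Indicated are eligible (a DI conclusion is never flagged), and
#' within each topic the highest-scoring eligible conclusions are queued
#' for human QA. Selection is per-topic top-k (`per_topic_k`, recycled over
#' topics), per-topic top fraction (`top_frac` of the eligible NDI
#' conclusions), or a global score threshold; exactly one rule must be
#' given. Ties break deterministically: score descending, then
#' screening_id ascending.
#'
#' @param scores Data frame with `screening_id`, `topic`, `score`.
#' @param conclusions Data frame with `screening_id`, `topic`,
#'   `examiner_label` ("DI"/"NDI"); every scored conclusion must be covered.
#' @param per_topic_k Integer k per topic (single value or named by topic).
#' @param top_frac Fraction of eligible NDI conclusions to flag per topic
#'   (k = ceiling(frac * eligible)).
#' @param threshold Score threshold in `[0, 1]`.
#' @return An object of class `"flag_report"`: list with `candidates`
#'   (screening_id, topic, score, examiner_label, rank ordered by topic
#'   then score descending), `rule`, and `eligible_per_topic`.
#' @export
flag_candidates <- function(scores, conclusions, per_topic_k = NULL,
                            top_frac = NULL, threshold = NULL) {
  given <- !vapply(list(per_topic_k, top_frac, threshold), is.null, logical(1))
  if (sum(given) != 1)
    stop("give exactly one of per_topic_k, top_frac, threshold", call. = FALSE)
  if (!is.null(per_topic_k) && any(per_topic_k < 0))
    stop("per_topic_k must be >= 0", call. = FALSE)
  if (!is.null(top_frac) && (top_frac < 0 || top_frac > 1))
    stop("top_frac must lie in [0, 1]", call. = FALSE)
  if (!is.null(threshold) && (threshold < 0 || threshold > 1))
    stop("threshold must lie in [0, 1]", call. = FALSE)

  d <- merge(scores[, c("screening_id", "topic", "score")],
             conclusions[, c("screening_id", "topic", "examiner_label")],
             by = c("screening_id", "topic"))
  if (nrow(d) < nrow(scores))
    stop("conclusions do not cover every scored (screening, topic)",
         call. = FALSE)
  eligible <- d[d$examiner_label == "NDI", , drop = FALSE]
  eligible <- eligible[order(eligible$topic, -eligible$score,
                             eligible$screening_id), , drop = FALSE]
  n_elig <- table(eligible$topic)

  pick <- logical(nrow(eligible))
  if (!is.null(threshold)) {
    pick <- eligible$score >= threshold
    rule <- sprintf("threshold=%g", threshold)
  } else {
    for (tp in names(n_elig)) {
      idx <- which(eligible$topic == tp)
      k <- if (!is.null(top_frac)) ceiling(top_frac * length(idx))
           else if (length(per_topic_k) > 1) per_topic_k[[tp]]
           else per_topic_k
      pick[head(idx, min(k, length(idx)))] <- TRUE
    }
    rule <- if (!is.null(top_frac)) sprintf("top_frac=%g", top_frac)
            else paste0("per_topic_k=", paste(per_topic_k, collapse = ","))
  }
  cand <- eligible[pick, , drop = FALSE]
  cand$rank <- stats::ave(-cand$score, cand$topic,
                          FUN = function(v) rank(v, ties.method = "first"))
  rownames(cand) <- NULL
  structure(list(candidates = cand, rule = rule,
                 eligible_per_topic = n_elig),
            class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat(sprintf("<flag_report> %d candidates (%s) from %d eligible NDI conclusions\n",
              nrow(x$candidates), x$rule, sum(x$eligible_per_topic)))
  print(head(x$candidates, 10), row.names = FALSE)
  invisible(x)
}

#' Measure how well flagging recovers injected examiner errors
#'
#' Against the simulator's ground truth: precision@k is the share of
#' flagged conclusions that are injected examiner errors, the base rate is
#' the error share among all eligible NDI conclusions, and enrichment is
#' their ratio — the factor by which model-guided QA beats QA-ing NDI
#' conclusions at random. Enrichment is 0 when no errors exist.
#'
#' @param flags A `"flag_report"`.
#' @param truth Truth table from [simulate_cohort()] (needs
#'   `screening_id`, `topic`, `examiner_label`, `injected_error`); must
#'   cover every flagged conclusion.
#' @return An object of class `"recovery_report"`: list with `k`,
#'   `flagged`, `errors_flagged`, `precision_at_k`, `base_rate`,
#'   `enrichment`, and a `per_topic` data frame.
#' @export
recovery_report <- function(flags, truth) {
  cand <- flags$candidates
  d <- merge(cand, truth[, c("screening_id", "topic", "injected_error")],
             by = c("screening_id", "topic"), all.x = TRUE)
  if (anyNA(d$injected_error))
    stop("truth records missing for some flagged conclusions", call. = FALSE)

  elig_truth <- truth[truth$examiner_label == "NDI", , drop = FALSE]
  base_rate <- if (nrow(elig_truth) == 0) 0 else mean(elig_truth$injected_error)
  k <- nrow(d)
  prec <- if (k == 0) 0 else mean(d$injected_error)
  enrich <- if (base_rate == 0) 0 else prec / base_rate

  pt <- do.call(rbind, lapply(split(d, d$topic), function(g) {
    et <- elig_truth[elig_truth$topic == g$topic[1], ]
    br <- if (nrow(et) == 0) 0 else mean(et$injected_error)
    data.frame(topic = g$topic[1], flagged = nrow(g),
               errors_flagged = sum(g$injected_error),
               precision_at_k = mean(g$injected_error), base_rate = br,
               enrichment = if (br == 0) 0 else mean(g$injected_error) / br,
               stringsAsFactors = FALSE)
  }))
  rownames(pt) <- NULL
  structure(list(k = k, flagged = k, errors_flagged = sum(d$injected_error),
                 precision_at_k = prec, base_rate = base_rate,
                 enrichment = enrich, per_topic = pt),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> flagged %d, injected errors among them %d\n",
              x$flagged, x$errors_flagged))
  cat(sprintf("  precision@k = %.4f, base error rate = %.4f, enrichment = %.2fx\n",
              x$precision_at_k, x$base_rate, x$enrichment))
  invisible(x)
}
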