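ID_COLS <- c("screening_id", "test_index", "topic", "label")

.lab01 <- function(label) {
  if (is.numeric(label)) as.integer(label > 0) else as.integer(label == "DI")
}

#' Training configuration for the stacking models
#'
#' Both stacking levels use gradient-boosted trees with balanced class
#' weighting (the positive class is up-weighted by the negative/positive
#' ratio); the random-forest variant uses depth-5 trees with balanced class
#' weights. Categorical second-level fields (sex, job fields, examiner,
#' weather condition, ...) are one-hot encoded with an explicit
#' unseen-category bucket. All hyperparameters are pinned here so a fitted
#' bundle records exactly what produced it.
#'
#' @param k_folds Number of stratified group folds (>= 2, default 5).
#' @param seed Integer seed controlling fold assignment and learners.
#' @param alt_fields Whitelist of subject/alternative-data columns fed to
#'   the second level (default age and sex).
#' @param one_topic Topic the one-topic ensemble member is trained on.
#' @param topic_as_feature If TRUE the topic code joins the second-level
#'   features (off by default: the basic model is topic-blind).
#' @param exclude_topics Topics removed from training (still scored).
#' @param max_fpr Operating-point false-positive-rate cap.
#' @param first_level,second_level Gradient-boosting hyperparameters
#'   (nrounds, max_depth, eta, subsample, colsample_bytree).
#' @param rf Random-forest hyperparameters (num_trees, max_depth).
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(k_folds = 5L, seed = 1L,
                         alt_fields = c("subject_age", "subject_sex"),
                         one_topic = "drug_abuse",
                         topic_as_feature = FALSE,
                         exclude_topics = character(0),
                         max_fpr = 0.05,
                         first_level = list(nrounds = 50, max_depth = 4,
                                            eta = 0.3, subsample = 0.8,
                                            colsample_bytree = 0.25),
                         second_level = list(nrounds = 120, max_depth = 3,
                                             eta = 0.1, subsample = 0.9,
                                             colsample_bytree = 1.0),
                         rf = list(num_trees = 120, max_depth = 5)) {
  stopifnot(k_folds >= 2)
  structure(list(k_folds = as.integer(k_folds), seed = as.integer(seed),
                 alt_fields = alt_fields, one_topic = one_topic,
                 topic_as_feature = isTRUE(topic_as_feature),
                 exclude_topics = exclude_topics, max_fpr = max_fpr,
                 first_level = first_level, second_level = second_level,
                 rf = rf),
            class = "train_config")
}

#' Stratified group K-fold assignment at screening level
#'
#' Every row of a screening maps to one fold (the group key is the
#' screening, the minimal leak-free choice), and folds are stratified on
#' the screening-level label (any topic concluded DI): positive and
#' negative screenings are shuffled separately under the seed and dealt
#' round-robin, so fold sizes and positive shares are balanced to within
#' one group.
#'
#' @param rows Feature table (needs `screening_id` and `label` columns), or
#'   any data frame with those columns.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector: screening_id -> fold in `1..k`.
#' @export
make_group_folds <- function(rows, k = 5L, seed = 1L) {
  y <- .lab01(rows$label)
  grp <- tapply(y, rows$screening_id, function(v) as.integer(any(v == 1)))
  ids <- names(grp)
  if (k > length(ids))
    stop(sprintf("k = %d exceeds the %d available screenings", k, length(ids)),
         call. = FALSE)
  set.seed(seed %% .Machine$integer.max)
  pos <- sample(ids[grp == 1])
  neg <- sample(ids[grp == 0])
  ordered <- c(pos, neg)
  folds <- setNames(rep(seq_len(k), length.out = length(ordered)), ordered)
  folds[ids]
}

# --- learners -------------------------------------------------------------

.fit_gbt <- function(X, y, hp, seed) {
  spw <- sum(y == 0) / max(sum(y == 1), 1)
  params <- list(objective = "binary:logistic", tree_method = "hist",
                 nthread = 1, seed = seed %% .Machine$integer.max,
                 eta = hp$eta, max_depth = hp$max_depth,
                 subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 scale_pos_weight = spw)
  m <- xgboost::xgb.train(params = params,
                          data = xgboost::xgb.DMatrix(X, label = y),
                          nrounds = hp$nrounds, verbose = 0)
  list(kind = "gbt", model = m)
}

.fit_rf <- function(X, y, hp, seed) {
  yf <- factor(y, levels = c(0, 1))
  n <- length(y)
  cw <- c("0" = n / (2 * max(sum(y == 0), 1)),
          "1" = n / (2 * max(sum(y == 1), 1)))
  m <- ranger::ranger(x = as.data.frame(X), y = yf, probability = TRUE,
                      num.trees = hp$num_trees, max.depth = hp$max_depth,
                      class.weights = cw, seed = seed %% .Machine$integer.max,
                      num.threads = 1)
  list(kind = "rf", model = m)
}

.predict_learner <- function(fit, X) {
  if (fit$kind == "gbt") {
    as.numeric(predict(fit$model, X))
  } else {
    p <- predict(fit$model, data = as.data.frame(X),
                 num.threads = 1)$predictions
    as.numeric(p[, "1"])
  }
}

# --- one-hot design matrices with an unseen-category bucket ---------------

.design_spec <- function(df) {
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  cat <- setdiff(names(df), num)
  levels <- lapply(df[cat], function(v) sort(unique(as.character(v))))
  names(levels) <- cat
  list(num = num, levels = levels)
}

.design_apply <- function(df, spec) {
  blocks <- list()
  for (f in spec$num) {
    v <- as.numeric(df[[f]])
    v[!is.finite(v)] <- 0
    blocks[[f]] <- matrix(v, ncol = 1, dimnames = list(NULL, f))
  }
  for (f in names(spec$levels)) {
    lev <- spec$levels[[f]]
    v <- as.character(df[[f]])
    v[!(v %in% lev)] <- "__unseen__"
    all_lev <- c(lev, "__unseen__")
    M <- matrix(0, nrow(df), length(all_lev),
                dimnames = list(NULL, paste0(f, "=", all_lev)))
    M[cbind(seq_len(nrow(df)), match(v, all_lev))] <- 1
    blocks[[f]] <- M
  }
  do.call(cbind, blocks[c(spec$num, names(spec$levels))])
}

# --- meta-row assembly ----------------------------------------------------

# aggregate first-level test scores into (screening, topic) meta rows and
# join the whitelisted subject/alt covariates
.assemble_meta <- function(test_scores, meta, cfg) {
  ts <- test_scores[order(test_scores$screening_id, test_scores$topic,
                          test_scores$test_index), , drop = FALSE]
  key <- paste(ts$screening_id, ts$topic, sep = "\r")
  groups <- split(seq_len(nrow(ts)), factor(key, levels = unique(key)))
  agg <- do.call(rbind, lapply(groups, function(idx) {
    mf <- meta_features(ts$score[idx])
    data.frame(screening_id = ts$screening_id[idx[1]],
               topic = ts$topic[idx[1]],
               pred_proba_min = mf[["pred_proba_min"]],
               pred_proba_max = mf[["pred_proba_max"]],
               pred_proba_mean = mf[["pred_proba_mean"]],
               pred_proba_diff = mf[["pred_proba_diff"]],
               label = ts$label[idx[1]], fold = ts$fold[idx[1]],
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  fields <- intersect(cfg$alt_fields, names(meta))
  missing <- setdiff(cfg$alt_fields, names(meta))
  if (length(missing) > 0)
    stop("unknown alternative-data field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(fields) > 0) {
    agg <- merge(agg, meta[, c("screening_id", fields), drop = FALSE],
                 by = "screening_id", sort = FALSE)
  }
  agg[order(agg$screening_id, agg$topic), , drop = FALSE]
}

.meta_feature_frame <- function(meta_rows, cfg) {
  cols <- c("pred_proba_min", "pred_proba_max", "pred_proba_mean",
            "pred_proba_diff", intersect(cfg$alt_fields, names(meta_rows)))
  df <- meta_rows[, cols, drop = FALSE]
  if (cfg$topic_as_feature) df$topic <- meta_rows$topic
  df
}

# --- two-level training ---------------------------------------------------

#' Train the two-level stacking ensemble with out-of-fold scoring
#'
#' The first-level model trains on the 600 physiological features of the
#' per-(test, topic) rows and scores the DI probability of each test; its
#' out-of-fold scores are aggregated per (screening, topic) into the four
#' `pred_proba_*` meta-features, concatenated with the whitelisted
#' subject/alternative-data covariates, and fed to the second-level model,
#' which outputs the DI probability for the screening topic. Both levels
#' are fitted once per fold on the rows outside that fold and applied to
#' the rows inside it, so every row receives exactly one score from models
#' that never saw its screening (leak-free by the group folds). The basic
#' model is topic-blind: the topic code never enters the features unless
#' `cfg$topic_as_feature` is set.
#'
#' @param rows Feature table from [build_feature_table()].
#' @param meta Per-screening covariate table ([screening_info()] optionally
#'   merged with the alternative-data table); may be NULL when
#'   `cfg$alt_fields` is empty.
#' @param folds Fold assignment from [make_group_folds()]; computed from
#'   `cfg` when NULL.
#' @param cfg A [train_config()].
#' @param learner `"gbt"` (gradient-boosted trees) or `"rf"` (random
#'   forest, depth-5, balanced class weights) at both levels.
#' @param train_filter_topic Restrict *training* rows to one topic
#'   (inference still covers every topic) — used by [train_one_topic()].
#' @return An object of class `"poly_model"` carrying the per-fold fitted
#'   models, the fold assignment, the screening IDs each fold's models were
#'   trained on (`train_screenings`, for leak audits), and OOF score tables
#'   `oof_test` (test level) and `oof` (screening-topic level).
#' @export
train_two_level <- function(rows, meta = NULL, folds = NULL,
                            cfg = train_config(),
                            learner = c("gbt", "rf"),
                            train_filter_topic = NULL) {
  learner <- match.arg(learner)
  stopifnot(nrow(rows) > 0)
  if (is.null(folds)) folds <- make_group_folds(rows, cfg$k_folds, cfg$seed)
  if (!all(rows$screening_id %in% names(folds)))
    stop("fold assignment does not cover every screening", call. = FALSE)
  if (is.null(meta))
    meta <- data.frame(screening_id = unique(rows$screening_id),
                       stringsAsFactors = FALSE)
  if (!is.null(train_filter_topic) &&
      !train_filter_topic %in% rows$topic)
    stop("topic '", train_filter_topic, "' absent from the feature table",
         call. = FALSE)

  feat_cols <- setdiff(names(rows), ID_COLS)
  X <- as.matrix(rows[, feat_cols, drop = FALSE])
  y <- .lab01(rows$label)
  row_fold <- unname(folds[rows$screening_id])
  k <- max(folds)

  trainable <- rep(TRUE, nrow(rows))
  if (length(cfg$exclude_topics) > 0)
    trainable <- trainable & !(rows$topic %in% cfg$exclude_topics)
  if (!is.null(train_filter_topic))
    trainable <- trainable & rows$topic == train_filter_topic

  fit_fun <- if (learner == "gbt") {
    function(Xm, yv, seed) .fit_gbt(Xm, yv, cfg$first_level, seed)
  } else {
    function(Xm, yv, seed) .fit_rf(Xm, yv, cfg$rf, seed)
  }

  first_level <- vector("list", k)
  train_screenings <- vector("list", k)   # instrumentation for leak audits
  oof_score <- rep(NA_real_, nrow(rows))
  for (f in seq_len(k)) {
    tr <- which(row_fold != f & trainable)
    te <- which(row_fold == f)
    if (length(unique(y[tr])) < 2)
      stop(sprintf("first-level training split for fold %d has a single class", f),
           call. = FALSE)
    train_screenings[[f]] <- unique(rows$screening_id[tr])
    first_level[[f]] <- fit_fun(X[tr, , drop = FALSE], y[tr], cfg$seed + f)
    oof_score[te] <- .predict_learner(first_level[[f]], X[te, , drop = FALSE])
  }
  oof_test <- data.frame(screening_id = rows$screening_id,
                         test_index = rows$test_index, topic = rows$topic,
                         label = y, fold = row_fold, score = oof_score,
                         stringsAsFactors = FALSE)

  meta_rows <- .assemble_meta(oof_test, meta, cfg)
  mtrainable <- rep(TRUE, nrow(meta_rows))
  if (length(cfg$exclude_topics) > 0)
    mtrainable <- mtrainable & !(meta_rows$topic %in% cfg$exclude_topics)
  if (!is.null(train_filter_topic))
    mtrainable <- mtrainable & meta_rows$topic == train_filter_topic

  second_level <- vector("list", k)
  design_specs <- vector("list", k)
  meta_oof <- rep(NA_real_, nrow(meta_rows))
  feat_frame <- .meta_feature_frame(meta_rows, cfg)
  fit2 <- if (learner == "gbt") {
    function(Xm, yv, seed) .fit_gbt(Xm, yv, cfg$second_level, seed)
  } else {
    function(Xm, yv, seed) .fit_rf(Xm, yv, cfg$rf, seed)
  }
  for (f in seq_len(k)) {
    tr <- which(meta_rows$fold != f & mtrainable)
    te <- which(meta_rows$fold == f)
    if (length(unique(meta_rows$label[tr])) < 2)
      stop(sprintf("second-level training split for fold %d has a single class", f),
           call. = FALSE)
    design_specs[[f]] <- .design_spec(feat_frame[tr, , drop = FALSE])
    X2tr <- .design_apply(feat_frame[tr, , drop = FALSE], design_specs[[f]])
    X2te <- .design_apply(feat_frame[te, , drop = FALSE], design_specs[[f]])
    second_level[[f]] <- fit2(X2tr, meta_rows$label[tr], cfg$seed + 100L + f)
    meta_oof[te] <- .predict_learner(second_level[[f]], X2te)
  }
  oof <- data.frame(screening_id = meta_rows$screening_id,
                    topic = meta_rows$topic, fold = meta_rows$fold,
                    label = meta_rows$label, score = meta_oof,
                    stringsAsFactors = FALSE)

  structure(list(learner = learner, cfg = cfg, folds = folds,
                 feature_cols = feat_cols,
                 first_level = first_level, second_level = second_level,
                 design_specs = design_specs,
                 train_filter_topic = train_filter_topic,
                 train_screenings = train_screenings,
                 oof_test = oof_test, oof = oof),
            class = "poly_model")
}

#' @export
print.poly_model <- function(x, ...) {
  cat(sprintf("<poly_model %s%s>  %d folds, %d test rows, %d screening-topic rows\n",
              x$learner,
              if (is.null(x$train_filter_topic)) ""
              else paste0(", one-topic=", x$train_filter_topic),
              length(x$first_level), nrow(x$oof_test), nrow(x$oof)))
  invisible(x)
}

#' Train the one-topic model
#'
#' Identical architecture to [train_two_level()], but both stacking levels
#' are fitted on rows of a single topic only; inference (including the OOF
#' tables) still covers every topic, so a model trained on one topic can
#' score the others.
#'
#' @inheritParams train_two_level
#' @param topic Topic to train on; must be present with both classes.
#' @return A `"poly_model"`.
#' @export
train_one_topic <- function(rows, topic, meta = NULL, folds = NULL,
                            cfg = train_config()) {
  train_two_level(rows, meta = meta, folds = folds, cfg = cfg,
                  learner = "gbt", train_filter_topic = topic)
}

#' Average the confidences of the three universal-ensemble members
#'
#' @param s_basic_alt,s_onetopic_alt,s_rf_basic Probabilities in `[0, 1]`
#'   (vectors of equal length are averaged elementwise).
#' @return The arithmetic mean of the three scores.
#' @export
score_universal <- function(s_basic_alt, s_onetopic_alt, s_rf_basic) {
  s <- cbind(s_basic_alt, s_onetopic_alt, s_rf_basic)
  if (any(!is.finite(s)) || any(s < 0 | s > 1))
    stop("member scores must lie in [0, 1]", call. = FALSE)
  unname(rowMeans(s))
}

#' Train the universal ensemble
#'
#' Averages the confidence of three models sharing one fold assignment: the
#' basic two-level gradient-boosting model with alternative data, a
#' one-topic gradient-boosting model with alternative data (trained on
#' `cfg$one_topic`), and a basic random-forest model on the physiological
#' meta-features alone.
#'
#' @inheritParams train_two_level
#' @return An object of class `"poly_universal"`: the three member bundles
#'   plus a combined OOF score table.
#' @export
train_universal <- function(rows, meta = NULL, folds = NULL,
                            cfg = train_config()) {
  if (is.null(folds)) folds <- make_group_folds(rows, cfg$k_folds, cfg$seed)
  basic_alt <- train_two_level(rows, meta, folds, cfg, learner = "gbt")
  one_topic_alt <- train_one_topic(rows, cfg$one_topic, meta, folds, cfg)
  cfg_rf <- cfg
  cfg_rf$alt_fields <- character(0)
  basic_rf <- train_two_level(rows, meta, folds, cfg_rf, learner = "rf")

  key <- c("screening_id", "topic", "fold", "label")
  oof <- basic_alt$oof[, key]
  oof$score <- score_universal(basic_alt$oof$score,
                               one_topic_alt$oof$score,
                               basic_rf$oof$score)
  structure(list(members = list(basic_alt = basic_alt,
                                one_topic_alt = one_topic_alt,
                                basic_rf = basic_rf),
                 cfg = cfg, folds = folds, oof = oof),
            class = "poly_universal")
}

#' @export
print.poly_universal <- function(x, ...) {
  cat(sprintf("<poly_universal>  3 members, %d folds, %d screening-topic rows\n",
              max(x$folds), nrow(x$oof)))
  invisible(x)
}

# score one unseen screening with the K fold models of a poly_model,
# averaging the per-fold outputs
.predict_new <- function(object, screening, alt, post_answer_s, channels) {
  rows <- build_feature_table(list(screening), post_answer_s = post_answer_s,
                              channels = channels)
  if (nrow(rows) == 0)
    stop("screening has no relevant questions to score", call. = FALSE)
  X <- as.matrix(rows[, object$feature_cols, drop = FALSE])
  info <- screening_info(list(screening))
  if (!is.null(alt))
    info <- merge(info, alt, by = intersect(names(info), names(alt)),
                  all.x = TRUE, sort = FALSE)
  cfg <- object$cfg
  k <- length(object$first_level)
  per_fold <- matrix(NA_real_, nrow = 0, ncol = k)
  topics <- NULL
  for (f in seq_len(k)) {
    s1 <- .predict_learner(object$first_level[[f]], X)
    ts <- data.frame(screening_id = rows$screening_id,
                     test_index = rows$test_index, topic = rows$topic,
                     label = 0L, fold = f, score = pmin(pmax(s1, 0), 1),
                     stringsAsFactors = FALSE)
    mr <- .assemble_meta(ts, info, cfg)
    if (is.null(topics)) {
      topics <- mr$topic
      per_fold <- matrix(NA_real_, nrow = length(topics), ncol = k)
    }
    X2 <- .design_apply(.meta_feature_frame(mr, cfg), object$design_specs[[f]])
    per_fold[, f] <- .predict_learner(object$second_level[[f]], X2)
  }
  setNames(rowMeans(per_fold), topics)
}

#' Score a screening with a fitted model
#'
#' For a screening that was part of training, the stored out-of-fold score
#' is returned (the leak guard: a training screening is only ever scored by
#' the models that did not see it). For an unseen screening, the K per-fold
#' model pairs are applied and their scores averaged.
#'
#' @param object A `"poly_model"` from [train_two_level()] /
#'   [train_one_topic()].
#' @param screening A screening object.
#' @param alt Optional one-row alternative-data frame for the screening.
#' @param post_answer_s Analysis-window extension used at feature time.
#' @param channels Channel names.
#' @param ... Unused.
#' @return Named numeric vector: topic -> DI probability.
#' @export
predict.poly_model <- function(object, screening, alt = NULL,
                               post_answer_s = 5,
                               channels = polygraph_channels(), ...) {
  sid <- screening$screening_id
  if (sid %in% names(object$folds)) {
    sub <- object$oof[object$oof$screening_id == sid, ]
    return(setNames(sub$score, sub$topic))
  }
  .predict_new(object, screening, alt, post_answer_s, channels)
}

#' @rdname predict.poly_model
#' @export
predict.poly_universal <- function(object, screening, alt = NULL,
                                   post_answer_s = 5,
                                   channels = polygraph_channels(), ...) {
  sid <- screening$screening_id
  if (sid %in% names(object$folds)) {
    sub <- object$oof[object$oof$screening_id == sid, ]
    return(setNames(sub$score, sub$topic))
  }
  ms <- lapply(object$members, predict, screening = screening, alt = alt,
               post_answer_s = post_answer_s, channels = channels)
  topics <- names(ms[[1]])
  setNames(score_universal(ms$basic_alt[topics],
                           ms$one_topic_alt[topics],
                           ms$basic_rf[topics]), topics)
}
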