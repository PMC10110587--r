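.pipeline_defaults <- function() {
  list(
    simulation = list(n_screenings = 300L, topics = screening_topics(),
                      tests_per_screening = 3L,
                      questions_per_topic_per_test = 2L,
                      repetitions_per_question = 2L,
                      prevalence = 0.06, delta = 1.5,
                      examiner_error_rate = 0.05, error_mode = "ndi_only",
                      ar_coef = 0.9, noise_sd = 0.3, sampling_rate_hz = 31,
                      n_comparison_questions = 2L, test_dropout = 0),
    featurization = list(post_answer_s = 5),
    model = list(variant = "universal", k_folds = 5L,
                 alt_fields = c("subject_age", "subject_sex"),
                 one_topic = "drug_abuse", topic_as_feature = FALSE,
                 exclude_topics = character(0)),
    evaluation = list(max_fpr = 0.05),
    flagging = list(top_frac = 0.05),
    output = list(write_recordings = FALSE, write_features = FALSE))
}

.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load and resolve a pipeline configuration
#'
#' Reads a YAML configuration with sections `simulation`, `featurization`,
#' `model`, `evaluation`, `flagging`, `output`, fills unset fields with the
#' defaults, and enforces that a top-level `seed` is present (every source
#' of randomness in the pipeline derives from it).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The resolved configuration list.
#' @export
load_pipeline_config <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(user$seed)) stop("config must set a seed", call. = FALSE)
  out <- .merge_config(.pipeline_defaults(), user)
  out$seed <- as.integer(user$seed)
  out
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full second-opinion pipeline
#'
#' Executes simulate -> featurize -> train -> evaluate -> flag from one
#' configuration and writes every artifact to `out_dir`: the resolved
#' config (with its MD5 hash logged), the cohort truth and alternative-data
#' tables (and optionally the recordings and feature table), the OOF score
#' table, the metric report (CSV + JSON), the flag report, and the
#' error-recovery report. Rerunning with an identical config reproduces
#' all numeric artifacts byte for byte. Any stage failure aborts with a
#' stage-named diagnostic.
#'
#' @param config Path to a YAML config or a named list (see
#'   [load_pipeline_config()]); the seed is mandatory.
#' @param out_dir Artifact directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts: `cohort`,
#'   `features`, `model`, `metrics`, `flags`, `recovery`, `config`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_con <- file(file.path(out_dir, "log.txt"), open = "wt")
  on.exit(close(log_con))
  .log_line(log_con, "polyverify pipeline, config hash ", cfg_hash,
            ", seed ", cfg$seed)

  stage <- function(name, expr) {
    .log_line(log_con, "stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage("simulate", {
    sim <- cfg$simulation
    sc <- sim_config(n_screenings = sim$n_screenings, topics = sim$topics,
                     tests_per_screening = sim$tests_per_screening,
                     questions_per_topic_per_test = sim$questions_per_topic_per_test,
                     repetitions_per_question = sim$repetitions_per_question,
                     prevalence = sim$prevalence, delta = sim$delta,
                     examiner_error_rate = sim$examiner_error_rate,
                     error_mode = sim$error_mode, ar_coef = sim$ar_coef,
                     noise_sd = sim$noise_sd,
                     sampling_rate_hz = sim$sampling_rate_hz,
                     n_comparison_questions = sim$n_comparison_questions,
                     test_dropout = sim$test_dropout, seed = cfg$seed)
    co <- simulate_cohort(sc)
    data.table::fwrite(co$truth, file.path(out_dir, "truth.csv"))
    data.table::fwrite(co$alt, file.path(out_dir, "alt.csv"))
    if (isTRUE(cfg$output$write_recordings)) write_cohort(co, out_dir)
    co
  })

  features <- stage("featurize", {
    ft <- build_feature_table(cohort,
                              post_answer_s = cfg$featurization$post_answer_s)
    if (isTRUE(cfg$output$write_features))
      data.table::fwrite(ft, file.path(out_dir, "features.csv"))
    ft
  })

  model <- stage("train", {
    tc <- train_config(k_folds = cfg$model$k_folds, seed = cfg$seed,
                       alt_fields = cfg$model$alt_fields,
                       one_topic = cfg$model$one_topic,
                       topic_as_feature = cfg$model$topic_as_feature,
                       exclude_topics = cfg$model$exclude_topics,
                       max_fpr = cfg$evaluation$max_fpr)
    meta <- merge(screening_info(cohort), cohort$alt, by = "screening_id")
    m <- switch(cfg$model$variant,
                universal = train_universal(features, meta, cfg = tc),
                basic = train_two_level(features, meta, cfg = tc),
                one_topic = train_one_topic(features, cfg$model$one_topic,
                                            meta, cfg = tc),
                stop("unknown model variant: ", cfg$model$variant))
    data.table::fwrite(m$oof, file.path(out_dir, "oof_scores.csv"))
    m
  })

  metrics <- stage("evaluate", {
    rep <- per_topic_report(model$oof, max_fpr = cfg$evaluation$max_fpr)
    write_metrics_report(rep, file.path(out_dir, "metrics.csv"),
                         file.path(out_dir, "metrics.json"))
    rep
  })

  flags <- stage("flag", {
    conclusions <- data.frame(screening_id = cohort$truth$screening_id,
                              topic = cohort$truth$topic,
                              examiner_label = cohort$truth$examiner_label,
                              stringsAsFactors = FALSE)
    fl <- do.call(flag_candidates,
                  c(list(scores = model$oof, conclusions = conclusions),
                    cfg$flagging))
    data.table::fwrite(fl$candidates, file.path(out_dir, "flags.csv"))
    jsonlite::write_json(list(rule = fl$rule, candidates = fl$candidates,
                              config_hash = cfg_hash),
                         file.path(out_dir, "flags.json"),
                         auto_unbox = TRUE, digits = NA)
    fl
  })

  recovery <- stage("recovery", {
    rr <- recovery_report(flags, cohort$truth)
    jsonlite::write_json(rr[c("k", "flagged", "errors_flagged",
                              "precision_at_k", "base_rate", "enrichment",
                              "per_topic")],
                         file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    rr
  })

  .log_line(log_con, sprintf(
    "done: %d screenings, %d feature rows, %d flagged, enrichment %.2f",
    length(cohort$screenings), nrow(features), nrow(flags$candidates),
    recovery$enrichment))
  invisible(list(cohort = cohort, features = features, model = model,
                 metrics = metrics, flags = flags, recovery = recovery,
                 config = cfg, config_hash = cfg_hash))
}
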