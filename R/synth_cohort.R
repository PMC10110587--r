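# Per-channel response polarity and gain for the stimulus-locked kernel.
# Signs reflect the usual direction of an orienting response: electrodermal
# activity rises, peripheral blood volume and respiration amplitude drop.
CHANNEL_GAIN <- c(
  THORACIC_RESP = -0.6, ABDOMINAL_RESP = -0.5, EDA = 1.0, TONIC_EDA = 0.6,
  PLE = -0.8, ABS_BLOOD_VOLUME = -0.9, HEART_RATE = 0.7, CARDIO = 0.8,
  TREMOR = 0.4, OPTIONAL = 0.5)

# slow periodic component per channel: c(amplitude, frequency Hz)
CHANNEL_PERIODIC <- list(
  THORACIC_RESP = c(0.5, 0.30), ABDOMINAL_RESP = c(0.5, 0.27),
  EDA = c(0.10, 0.05), TONIC_EDA = c(0.15, 0.02), PLE = c(0.30, 1.10),
  ABS_BLOOD_VOLUME = c(0.20, 0.10), HEART_RATE = c(0.20, 0.05),
  CARDIO = c(0.30, 1.15), TREMOR = c(0.10, 0.50), OPTIONAL = c(0.10, 0.08))

#' Simulation configuration for synthetic screening cohorts
#'
#' Defines the cohort-level generative conditions: hierarchy sizes
#' (screenings, tests, questions per topic per test, repetitions per
#' question), per-topic deception prevalence, the deception effect size, the
#' examiner error rate, and the channel noise model. Defaults emulate a
#' routine employee-screening archive: seven topics, three tests per
#' screening, a 6% per-topic DI prevalence, and a 31 Hz sampling rate.
#'
#' Each simulated channel is baseline drift + a channel-specific periodic
#' component + AR(1) noise + a gamma-shaped stimulus-locked response kernel
#' (onset 0.5 s after question start, 8 s duration) at every question onset.
#' The kernel amplitude is multiplied by `(1 + delta)` on relevant questions
#' of topics where the subject is truly deceptive, so `delta` is a
#' dimensionless effect size: `delta = 0` means deceptive and truthful
#' topics are physiologically indistinguishable. Signal units are arbitrary.
#'
#' @param n_screenings Number of screenings in the cohort.
#' @param topics Topic codes (subset of [screening_topics()]).
#' @param tests_per_screening,questions_per_topic_per_test,repetitions_per_question
#'   Hierarchy sizes (all >= 1).
#' @param prevalence Per-topic probability that a subject is truly deceptive.
#' @param delta Deception effect size (>= 0), multiplier on the
#'   stimulus-locked response amplitude for deceptive (subject, topic) pairs.
#' @param examiner_error_rate Probability that an examiner conclusion
#'   contradicts the ground truth (see [inject_examiner_errors()]).
#' @param error_mode `"symmetric"` (any label can flip) or `"ndi_only"`
#'   (only true-DI conclusions are mislabelled NDI — the error class the
#'   second-opinion tool targets).
#' @param ar_coef AR(1) coefficient of the channel noise.
#' @param noise_sd Marginal standard deviation of the channel noise.
#' @param sampling_rate_hz Channel sampling rate (default 31).
#' @param n_comparison_questions Comparison (control) questions per test.
#' @param test_dropout Probability that a deceptive (subject, topic) pair
#'   does not express the effect in a given test (a subject may not lie in
#'   every test on a topic); at least one test always expresses. Default 0.
#' @param seed Integer seed; mandatory, every random draw derives from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_screenings = 100L,
                       topics = screening_topics(),
                       tests_per_screening = 3L,
                       questions_per_topic_per_test = 2L,
                       repetitions_per_question = 2L,
                       prevalence = 0.06,
                       delta = 1,
                       examiner_error_rate = 0,
                       error_mode = c("symmetric", "ndi_only"),
                       ar_coef = 0.9,
                       noise_sd = 0.3,
                       sampling_rate_hz = 31,
                       n_comparison_questions = 2L,
                       test_dropout = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  error_mode <- match.arg(error_mode)
  cfg <- list(n_screenings = as.integer(n_screenings),
              topics = as.character(unlist(topics)),
              tests_per_screening = as.integer(tests_per_screening),
              questions_per_topic_per_test = as.integer(questions_per_topic_per_test),
              repetitions_per_question = as.integer(repetitions_per_question),
              prevalence = prevalence, delta = delta,
              examiner_error_rate = examiner_error_rate,
              error_mode = error_mode,
              ar_coef = ar_coef, noise_sd = noise_sd,
              sampling_rate_hz = sampling_rate_hz,
              n_comparison_questions = as.integer(n_comparison_questions),
              test_dropout = test_dropout,
              seed = as.integer(seed))
  stopifnot(cfg$prevalence >= 0, cfg$prevalence <= 1,
            cfg$examiner_error_rate >= 0, cfg$examiner_error_rate <= 1,
            cfg$delta >= 0, cfg$n_screenings >= 1,
            cfg$tests_per_screening >= 1,
            cfg$questions_per_topic_per_test >= 1,
            cfg$repetitions_per_question >= 1,
            cfg$sampling_rate_hz > 0, cfg$test_dropout >= 0,
            cfg$test_dropout < 1,
            length(cfg$topics) >= 1,
            all(cfg$topics %in% screening_topics()))
  class(cfg) <- "sim_config"
  cfg
}

# gamma-shaped rise-decay response kernel: onset delay 0.5 s, peak ~2 s
# after question start, truncated at 8 s, peak amplitude 1
.response_kernel <- function(rate) {
  u <- seq(0, 8 - 1 / rate, by = 1 / rate) - 0.5
  k <- ifelse(u <= 0, 0, (u / 1.5)^2 * exp(2 * (1 - u / 1.5)))
  k
}

# question/answer schedule for one test; cursor advances ~10.3 s per event
.schedule_test <- function(cfg, test_index, t0) {
  roster <- character(0)
  topic_of <- character(0)
  for (tp in cfg$topics) for (q in seq_len(cfg$questions_per_topic_per_test)) {
    roster <- c(roster, sprintf("R_%s_%d", tp, q))
    topic_of <- c(topic_of, tp)
  }
  if (cfg$n_comparison_questions > 0) {
    roster <- c(roster, sprintf("C%d", seq_len(cfg$n_comparison_questions)))
    topic_of <- c(topic_of, rep(NA_character_, cfg$n_comparison_questions))
  }
  ord <- sample.int(length(roster))
  roster <- roster[ord]; topic_of <- topic_of[ord]

  nq <- length(roster)
  nrep <- cfg$repetitions_per_question
  n_ev <- nq * nrep
  q_dur <- runif(n_ev, 1.8, 2.6)
  ans_delay <- runif(n_ev, 1.0, 2.0)
  gaps <- 10 + runif(n_ev, 0, 0.5)
  starts <- t0 + c(0, cumsum(gaps[-n_ev]))
  events <- data.frame(
    question_id = rep(roster, times = nrep),
    qtype = rep(ifelse(is.na(topic_of), "comparison", "relevant"),
                times = nrep),
    topic = rep(topic_of, times = nrep),
    test_index = test_index,
    repetition_index = rep(seq_len(nrep) - 1L, each = nq),
    t_question_start = starts,
    t_question_end = starts + q_dur,
    t_answer = starts + q_dur + ans_delay,
    answer = sample(c("no", "yes"), n_ev, replace = TRUE,
                    prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
  list(events = events, t_end = starts[n_ev] + gaps[n_ev])
}

#' Simulate one screening with known deception ground truth
#'
#' Generates a full screening recording: a question schedule over
#' `tests_per_screening` tests (each question repeated, with three ordered
#' timestamps per repetition), ten physiological channels with
#' stimulus-locked responses at every question onset, and truth-implied
#' examiner conclusions (DI exactly on truly deceptive topics — error
#' injection is a separate, explicit step, see [inject_examiner_errors()]).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this screening (defaults to `config$seed`).
#' @param screening_id Identifier.
#' @param truth Optional named logical vector (topic -> truly deceptive);
#'   drawn Bernoulli(`prevalence`) per topic when omitted.
#' @return List with elements `screening` (a [new_screening()] object) and
#'   `truth` (data frame: screening_id, topic, true_deceptive,
#'   examiner_label, injected_error).
#' @export
simulate_screening <- function(config, seed = config$seed,
                               screening_id = "S0001", truth = NULL) {
  set.seed(seed %% .Machine$integer.max)
  rate <- config$sampling_rate_hz

  if (is.null(truth)) {
    truth <- setNames(runif(length(config$topics)) < config$prevalence,
                      config$topics)
  } else {
    stopifnot(all(config$topics %in% names(truth)))
    truth <- truth[config$topics]
  }

  # which tests express the effect for each deceptive topic
  expresses <- matrix(TRUE, nrow = length(config$topics),
                      ncol = config$tests_per_screening,
                      dimnames = list(config$topics, NULL))
  if (config$test_dropout > 0) {
    for (tp in config$topics) {
      keep <- runif(config$tests_per_screening) >= config$test_dropout
      if (!any(keep)) keep[sample.int(config$tests_per_screening, 1)] <- TRUE
      expresses[tp, ] <- keep
    }
  }

  # subject metadata
  age <- sample(22:60, 1)
  sex <- sample(c("M", "F"), 1)
  stype <- sample(c("candidate", "employee"), 1, prob = c(0.3, 0.7))
  positions <- c("teller", "manager", "senior_manager", "analyst",
                 "security_officer", "it_specialist")
  departments <- c("retail", "corporate", "it", "security", "operations")
  cur_pos <- sample(positions, 1); cur_dep <- sample(departments, 1)
  acc_pos <- if (stype == "candidate") sample(positions, 1) else cur_pos
  acc_dep <- if (stype == "candidate") sample(departments, 1) else cur_dep
  examiner <- sprintf("E%02d", sample.int(8, 1))
  date <- as.character(as.Date("2021-01-01") + sample.int(364, 1))

  # schedule
  ev_list <- vector("list", config$tests_per_screening)
  cursor <- 15
  for (ti in seq_len(config$tests_per_screening) - 1L) {
    sch <- .schedule_test(config, ti, cursor)
    ev_list[[ti + 1L]] <- sch$events
    cursor <- sch$t_end + 20
  }
  events <- do.call(rbind, ev_list)
  duration <- max(events$t_answer) + 12
  n <- ceiling(duration * rate)

  # event amplitudes: deceptive relevant questions are amplified by (1+delta)
  subject_gain <- exp(rnorm(1, 0, 0.2))
  jitter <- exp(rnorm(nrow(events), 0, 0.25))
  amplified <- events$qtype == "relevant" & !is.na(events$topic) &
    truth[events$topic] &
    expresses[cbind(match(events$topic, config$topics),
                    events$test_index + 1L)]
  amplified[is.na(amplified)] <- FALSE
  amp <- subject_gain * jitter * (1 + config$delta * as.numeric(amplified))
  onset_idx <- floor(events$t_question_start * rate) + 1L

  kernel <- .response_kernel(rate)
  kl <- length(kernel)
  tgrid <- (seq_len(n) - 1L) / rate

  channels <- vector("list", length(polygraph_channels()))
  names(channels) <- polygraph_channels()
  for (cn in polygraph_channels()) {
    per <- CHANNEL_PERIODIC[[cn]]
    base <- rnorm(1, 0, 0.5) +
      0.3 * sin(2 * pi * runif(1, 0.005, 0.02) * tgrid + runif(1, 0, 2 * pi))
    periodic <- per[1] * sin(2 * pi * per[2] * tgrid + runif(1, 0, 2 * pi))
    innov <- rnorm(n, 0, config$noise_sd * sqrt(1 - config$ar_coef^2))
    noise <- as.numeric(stats::filter(innov, config$ar_coef,
                                      method = "recursive"))
    x <- base + periodic + noise
    g <- CHANNEL_GAIN[[cn]]
    for (e in seq_len(nrow(events))) {
      idx <- onset_idx[e]:min(onset_idx[e] + kl - 1L, n)
      x[idx] <- x[idx] + g * amp[e] * kernel[seq_along(idx)]
    }
    channels[[cn]] <- list(name = cn, sampling_rate_hz = rate, samples = x)
  }

  conclusions <- setNames(ifelse(truth, "DI", "NDI"), config$topics)
  s <- new_screening(screening_id, channels, events, conclusions,
                     date = date, subject_age = age, subject_sex = sex,
                     subject_type = stype,
                     current_position = cur_pos, current_department = cur_dep,
                     accepted_position = acc_pos, accepted_department = acc_dep,
                     examiner_id = examiner)
  tr <- data.frame(screening_id = s$screening_id, topic = config$topics,
                   true_deceptive = unname(truth),
                   examiner_label = unname(conclusions),
                   injected_error = FALSE, stringsAsFactors = FALSE)
  list(screening = s, truth = tr)
}

#' Inject examiner labelling errors into truth records
#'
#' Flips examiner conclusions away from the truth-implied label with
#' probability `epsilon`, independently per (screening, topic) conclusion.
#' In `"symmetric"` mode any conclusion may flip; in `"ndi_only"` mode only
#' truly deceptive topics are mislabelled (DI -> NDI), the error class a
#' second-opinion tool on NDI conclusions can recover. Ground-truth fields
#' are untouched and `injected_error` is set exactly where the label
#' disagrees with the truth.
#'
#' @param truth Truth-record data frame as returned by [simulate_cohort()].
#' @param epsilon Error probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param mode `"symmetric"` or `"ndi_only"`.
#' @return The truth data frame with `examiner_label` and `injected_error`
#'   updated.
#' @export
inject_examiner_errors <- function(truth, epsilon, seed,
                                   mode = c("symmetric", "ndi_only")) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  mode <- match.arg(mode)
  set.seed(seed %% .Machine$integer.max)
  implied <- ifelse(truth$true_deceptive, "DI", "NDI")
  u <- runif(nrow(truth))
  flip <- u < epsilon
  if (mode == "ndi_only") flip <- flip & truth$true_deceptive
  truth$examiner_label <- ifelse(flip, ifelse(implied == "DI", "NDI", "DI"),
                                 implied)
  truth$injected_error <- truth$examiner_label != implied
  truth
}

#' Simulate a screening cohort with covariates and examiner labels
#'
#' Generates `n_screenings` independent screenings (see
#' [simulate_screening()]), injects examiner errors at the configured rate,
#' writes the resulting examiner labels back into each screening's
#' conclusions, and draws per-screening alternative data: examiner ID, a
#' geomagnetic storm index, and weather fields (Temperature, Pressure,
#' Humidity, Wind, Wind speed, Dew Point, Condition, Time) for a single
#' city. Subject age is uniform on 22–60 and sex is balanced, so the
#' covariates carry no artificial signal about deception.
#'
#' Fully reproducible: the cohort is a deterministic function of
#' `(config, config$seed)`.
#'
#' @param config A [sim_config()].
#' @return An object of class `"poly_cohort"`: list with `screenings` (list
#'   of screening objects), `truth` (data frame, one row per (screening,
#'   topic)), `alt` (alternative-data data frame keyed by screening_id), and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_screenings + 2L)
  ids <- sprintf("S%04d", seq_len(config$n_screenings))

  screenings <- vector("list", config$n_screenings)
  truth_list <- vector("list", config$n_screenings)
  for (i in seq_len(config$n_screenings)) {
    r <- simulate_screening(config, seed = seeds[i], screening_id = ids[i])
    screenings[[i]] <- r$screening
    truth_list[[i]] <- r$truth
  }
  names(screenings) <- ids
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  if (config$examiner_error_rate > 0)
    truth <- inject_examiner_errors(truth, config$examiner_error_rate,
                                    seed = seeds[config$n_screenings + 1L],
                                    mode = config$error_mode)
  for (i in seq_len(config$n_screenings)) {
    lab <- truth[truth$screening_id == ids[i], ]
    screenings[[i]]$conclusions <- setNames(lab$examiner_label, lab$topic)
  }

  # alternative data: one city, weather Gaussian around city norms
  set.seed(seeds[config$n_screenings + 2L] %% .Machine$integer.max)
  nsc <- config$n_screenings
  temp <- rnorm(nsc, 10, 8)
  alt <- data.frame(
    screening_id = ids,
    examiner_id = vapply(screenings, function(s) s$examiner_id, character(1)),
    geomagnetic_storm = sample(0:9, nsc, replace = TRUE,
                               prob = c(8, 10, 9, 6, 4, 2, 1, 0.5, 0.3, 0.2)),
    Temperature = round(temp, 1),
    Pressure = round(rnorm(nsc, 747, 6), 1),
    Humidity = round(pmin(pmax(rnorm(nsc, 70, 12), 20), 100), 0),
    Wind = sample(c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
                  nsc, replace = TRUE),
    `Wind speed` = round(pmax(rnorm(nsc, 4, 2), 0), 1),
    `Dew Point` = round(temp - runif(nsc, 1, 6), 1),
    Condition = sample(c("clear", "cloudy", "rain", "snow", "fog"),
                       nsc, replace = TRUE, prob = c(3, 4, 2, 1, 0.5)),
    Time = sprintf("%02d:00", sample(9:17, nsc, replace = TRUE)),
    check.names = FALSE, stringsAsFactors = FALSE)

  structure(list(screenings = screenings, truth = truth, alt = alt,
                 config = config),
            class = "poly_cohort")
}

#' @export
print.poly_cohort <- function(x, ...) {
  cat(sprintf("<poly_cohort> %d screenings, %d topics, delta=%g, prevalence=%g, error rate=%g (%s)\n",
              length(x$screenings), length(x$config$topics), x$config$delta,
              x$config$prevalence, x$config$examiner_error_rate,
              x$config$error_mode))
  cat(sprintf("  truly deceptive (screening, topic) pairs: %d / %d\n",
              sum(x$truth$true_deceptive), nrow(x$truth)))
  invisible(x)
}

#' Per-screening subject and examiner metadata table
#'
#' @param screenings List of screening objects (or a `poly_cohort`).
#' @return Data frame keyed by `screening_id` with subject age, sex, type,
#'   the four job fields, examiner_id, date, and city.
#' @export
screening_info <- function(screenings) {
  if (inherits(screenings, "poly_cohort")) screenings <- screenings$screenings
  do.call(rbind, lapply(screenings, function(s) data.frame(
    screening_id = s$screening_id, subject_age = s$subject_age,
    subject_sex = s$subject_sex, subject_type = s$subject_type,
    current_position = s$current_position,
    current_department = s$current_department,
    accepted_position = s$accepted_position,
    accepted_department = s$accepted_department,
    examiner_id = s$examiner_id, date = s$date, city = s$city,
    stringsAsFactors = FALSE)))
}

#' Write a cohort to a directory
#'
#' Writes `recordings/<id>.poly` in the NCCA-ASCII-style dialect plus
#' `truth.csv` and `alt.csv`.
#'
#' @param cohort A `poly_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  rec <- file.path(dir, "recordings")
  dir.create(rec, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$screenings)
    write_screening(s, file.path(rec, paste0(s$screening_id, ".poly")))
  data.table::fwrite(cohort$truth, file.path(dir, "truth.csv"))
  data.table::fwrite(cohort$alt, file.path(dir, "alt.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `recordings/`, `truth.csv`, `alt.csv`.
#' @return A `poly_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(file.path(dir, "recordings"),
                           pattern = "\\.poly$", full.names = TRUE))
  screenings <- lapply(files, read_screening)
  names(screenings) <- vapply(screenings, function(s) s$screening_id,
                              character(1))
  truth <- as.data.frame(data.table::fread(file.path(dir, "truth.csv")))
  alt <- as.data.frame(data.table::fread(file.path(dir, "alt.csv")))
  structure(list(screenings = screenings, truth = truth, alt = alt,
                 config = NULL),
            class = "poly_cohort")
}

#' Shuffle event timestamps within a screening
#'
#' Permutes the (start, end, answer) timestamp triples across a screening's
#' events, detaching every analysis window from its stimulus-locked
#' response. Used as a permutation null: a model trained on shuffled
#' cohorts should score at chance.
#'
#' @param screening A screening object.
#' @param seed Integer seed for the permutation.
#' @return The screening with permuted event timestamps.
#' @export
shuffle_event_times <- function(screening, seed) {
  set.seed(seed %% .Machine$integer.max)
  ev <- screening$events
  p <- sample.int(nrow(ev))
  ev[, c("t_question_start", "t_question_end", "t_answer")] <-
    ev[p, c("t_question_start", "t_question_end", "t_answer")]
  screening$events <- ev
  screening
}
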