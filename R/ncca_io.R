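#' Canonical polygraph channel set
#'
#' The ten physiological channels a screening recording must carry, in
#' canonical order: thoracic and abdominal respiration, phasic and tonic
#' electrodermal activity, photoplethysmogram, absolute blood volume, heart
#' rate, cardio (cuff) pressure, tremor, and an auxiliary channel. The set is
#' configuration-driven: functions that consume recordings accept a
#' `channels` argument and only require that a screening's channels match it.
#'
#' @return Character vector of length 10.
#' @export
polygraph_channels <- function() {
  c("THORACIC_RESP", "ABDOMINAL_RESP", "EDA", "TONIC_EDA", "PLE",
    "ABS_BLOOD_VOLUME", "HEART_RATE", "CARDIO", "TREMOR", "OPTIONAL")
}

#' Screening topics
#'
#' The seven screening topics with labelled training data: drug abuse,
#' corruption, confidential information leak, debt, unreported income,
#' criminal history, and internal-regulatory-document (IRD) violation.
#'
#' @return Character vector of topic codes.
#' @export
screening_topics <- function() {
  c("drug_abuse", "corruption", "conf_info_leak", "debt",
    "unrep_income", "criminal_history", "ird_violation")
}

QTYPES <- c("relevant", "comparison", "neutral", "other")
ANSWERS <- c("yes", "no", "none")
CONCLUSION_LEVELS <- c("DI", "NDI")

HEADER_FIELDS <- c("screening_id", "date", "city", "subject_age",
                   "subject_sex", "subject_type", "current_position",
                   "current_department", "accepted_position",
                   "accepted_department", "examiner_id")

EVENT_COLS <- c("question_id", "qtype", "topic", "test_index",
                "repetition_index", "t_question_start", "t_question_end",
                "t_answer", "answer")

#' Construct a screening object
#'
#' A screening is one polygraph recording: subject and examiner metadata,
#' exactly ten physiological signal channels, a table of timestamped
#' question events, and the examiner's per-topic DI/NDI conclusions. Each
#' question repetition carries three timestamps (seconds from recording
#' start, 0-based): the start of the question, the end of the question, and
#' the moment of the answer. Time windows used downstream are half-open
#' `[start, end)`.
#'
#' @param screening_id Identifier string.
#' @param channels Named list; each element is a list with `name`,
#'   `sampling_rate_hz`, and a numeric `samples` vector. All channels must
#'   share one length.
#' @param events Data frame with columns `question_id`, `qtype` (one of
#'   relevant/comparison/neutral/other), `topic` (NA for non-relevant
#'   questions), `test_index`, `repetition_index` (0-based integers),
#'   `t_question_start`, `t_question_end`, `t_answer` (seconds), `answer`
#'   (yes/no/none).
#' @param conclusions Named character vector, topic -> "DI" or "NDI".
#' @param date,city,subject_age,subject_sex,subject_type Screening metadata.
#' @param current_position,current_department Job fields.
#' @param accepted_position,accepted_department Job fields (position applied
#'   for, if a hiring screening).
#' @param examiner_id Examiner identifier.
#' @return An object of class `"screening"`.
#' @seealso [validate_screening()], [read_screening()], [write_screening()]
#' @export
new_screening <- function(screening_id, channels, events, conclusions,
                          date = "2021-01-01", city = "CityA",
                          subject_age = 30L, subject_sex = "M",
                          subject_type = "employee",
                          current_position = "teller",
                          current_department = "retail",
                          accepted_position = "teller",
                          accepted_department = "retail",
                          examiner_id = "E01") {
  s <- list(
    screening_id = as.character(screening_id),
    date = as.character(date), city = as.character(city),
    subject_age = as.integer(subject_age),
    subject_sex = as.character(subject_sex),
    subject_type = as.character(subject_type),
    current_position = as.character(current_position),
    current_department = as.character(current_department),
    accepted_position = as.character(accepted_position),
    accepted_department = as.character(accepted_department),
    examiner_id = as.character(examiner_id),
    channels = channels,
    events = as.data.frame(events, stringsAsFactors = FALSE),
    conclusions = conclusions
  )
  class(s) <- "screening"
  s
}

#' @export
print.screening <- function(x, ...) {
  dur <- screening_duration(x)
  cat(sprintf("<screening %s>  %d channels @ %g Hz, %.1f s, %d events, %d topics\n",
              x$screening_id, length(x$channels),
              x$channels[[1]]$sampling_rate_hz, dur,
              nrow(x$events), length(x$conclusions)))
  invisible(x)
}

#' Recording duration in seconds
#'
#' @param screening A screening object.
#' @return Duration of the (common-length) channels, seconds.
#' @export
screening_duration <- function(screening) {
  ch <- screening$channels[[1]]
  length(ch$samples) / ch$sampling_rate_hz
}

#' Validate a screening against the domain invariants
#'
#' Total function: never errors, returns a data frame of violations (zero
#' rows when the screening is valid). Checked rules: exactly ten channels
#' with unique names and a common length; positive sampling rate; finite,
#' non-empty samples; event timestamps ordered
#' `t_question_start <= t_question_end <= t_answer` and inside the recording;
#' relevant events carry a topic; valid question types and answers;
#' conclusions in {DI, NDI} with every concluded topic present on at least
#' one relevant event.
#'
#' @param screening A screening object.
#' @param n_channels Required channel count (default 10).
#' @return Data frame with columns `field`, `rule`, `message`; zero rows iff
#'   all invariants hold.
#' @export
validate_screening <- function(screening, n_channels = 10L) {
  v <- list()
  bad <- function(field, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(field = field, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }

  ch <- screening$channels
  if (length(ch) != n_channels)
    bad("channels", "channel_count",
        sprintf("expected %d channels, found %d", n_channels, length(ch)))
  nm <- vapply(ch, function(c) c$name %||% NA_character_, character(1))
  if (anyDuplicated(nm))
    bad("channels", "unique_names", "duplicate channel names")
  lens <- integer(0)
  for (c in ch) {
    if (!is.numeric(c$sampling_rate_hz) || c$sampling_rate_hz <= 0)
      bad(paste0("channels.", c$name), "positive_rate",
          "sampling_rate_hz must be > 0")
    if (length(c$samples) == 0)
      bad(paste0("channels.", c$name), "nonempty_samples",
          "channel has no samples")
    else if (!all(is.finite(c$samples)))
      bad(paste0("channels.", c$name), "finite_samples",
          "channel contains non-finite samples")
    lens <- c(lens, length(c$samples))
  }
  if (length(unique(lens)) > 1)
    bad("channels", "common_duration",
        "channels differ in length within one screening")

  dur <- if (length(ch) > 0 && length(ch[[1]]$samples) > 0 &&
             is.numeric(ch[[1]]$sampling_rate_hz) && ch[[1]]$sampling_rate_hz > 0)
    length(ch[[1]]$samples) / ch[[1]]$sampling_rate_hz else NA_real_

  ev <- screening$events
  if (!all(EVENT_COLS %in% names(ev))) {
    bad("events", "columns",
        paste("missing event columns:",
              paste(setdiff(EVENT_COLS, names(ev)), collapse = ", ")))
  } else if (nrow(ev) > 0) {
    if (!all(ev$qtype %in% QTYPES))
      bad("events.qtype", "qtype_domain",
          "qtype outside {relevant, comparison, neutral, other}")
    if (!all(ev$answer %in% ANSWERS))
      bad("events.answer", "answer_domain",
          "answer outside {yes, no, none}")
    ord <- ev$t_question_start <= ev$t_question_end &
           ev$t_question_end <= ev$t_answer
    if (!all(ord))
      bad("events.timestamps", "timestamp_order",
          sprintf("%d event(s) violate t_question_start <= t_question_end <= t_answer",
                  sum(!ord)))
    if (!is.na(dur)) {
      inside <- ev$t_question_start >= 0 & ev$t_answer <= dur
      if (!all(inside))
        bad("events.timestamps", "within_recording",
            sprintf("%d event(s) have timestamps outside [0, %.3f]",
                    sum(!inside), dur))
    }
    rel <- ev$qtype == "relevant"
    if (any(rel & (is.na(ev$topic) | ev$topic == "")))
      bad("events.topic", "relevant_topic",
          "relevant event without a topic")
    if (any(ev$test_index < 0) || any(ev$repetition_index < 0))
      bad("events.indices", "nonnegative_indices",
          "test_index and repetition_index must be >= 0")
  }

  con <- screening$conclusions
  if (length(con) > 0) {
    if (!all(con %in% CONCLUSION_LEVELS))
      bad("conclusions", "conclusion_domain",
          "conclusions must be DI or NDI")
    if (all(EVENT_COLS %in% names(ev))) {
      rel_topics <- unique(ev$topic[ev$qtype == "relevant"])
      orphan <- setdiff(names(con), rel_topics)
      if (length(orphan) > 0)
        bad("conclusions", "topic_has_events",
            paste("conclusion on topic(s) with no relevant event:",
                  paste(orphan, collapse = ", ")))
    }
  }

  if (length(v) == 0)
    data.frame(field = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  else
    do.call(rbind, v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed decimal formatting shared by writer and tests: 12 significant digits
# keeps the write->read round trip within 1e-9 for the value ranges in play
.fmt_num <- function(x) formatC(x, format = "g", digits = 12, width = -1)

#' Write a screening to the NCCA-ASCII-style text dialect
#'
#' Serializes a screening to a self-contained UTF-8 text format with `\n`
#' line endings: a `[HEADER]` block of `key=value` metadata lines, a
#' `[CONCLUSIONS]` block (`topic=DI|NDI`), an `[EVENTS]` table (one
#' pipe-delimited line per question repetition: id, type, topic or `.`,
#' test index, repetition index, the three timestamps in seconds, answer),
#' one `[CHANNEL]` block per signal (name, rate, sample count, then samples
#' eight per line), and a final `[END]` marker. Output is byte-deterministic
#' for identical input: field order is fixed and numbers are printed with 12
#' significant digits, so a write/read round trip reproduces the screening
#' to within 1e-9.
#'
#' @param screening A valid screening object; invariant violations are
#'   refused with a diagnostic listing them.
#' @param path Output file path.
#' @param n_channels Required channel count passed to [validate_screening()].
#' @return `path`, invisibly.
#' @export
write_screening <- function(screening, path, n_channels = 10L) {
  viol <- validate_screening(screening, n_channels = n_channels)
  if (nrow(viol) > 0)
    stop("refusing to write invalid screening: ",
         paste(sprintf("[%s: %s]", viol$rule, viol$message), collapse = " "),
         call. = FALSE)

  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  add("#NCCA-ASCII-DIALECT 1.0")
  add("[HEADER]")
  for (f in HEADER_FIELDS) add(f, "=", as.character(screening[[f]]))
  add("sampling_rate_hz=", .fmt_num(screening$channels[[1]]$sampling_rate_hz))
  add("n_channels=", length(screening$channels))

  add("[CONCLUSIONS]")
  con <- screening$conclusions
  for (t in names(con)) add(t, "=", con[[t]])

  add("[EVENTS]")
  add(paste(EVENT_COLS, collapse = "|"))
  ev <- screening$events
  if (nrow(ev) > 0) {
    topic <- ifelse(is.na(ev$topic) | ev$topic == "", ".", ev$topic)
    lines <- paste(ev$question_id, ev$qtype, topic,
                   ev$test_index, ev$repetition_index,
                   .fmt_num(ev$t_question_start),
                   .fmt_num(ev$t_question_end),
                   .fmt_num(ev$t_answer), ev$answer, sep = "|")
    out <- c(out, lines)
  }

  for (c in screening$channels) {
    out <- c(out, "[CHANNEL]",
             paste0("name=", c$name),
             paste0("sampling_rate_hz=", .fmt_num(c$sampling_rate_hz)),
             paste0("n_samples=", length(c$samples)))
    sm <- .fmt_num(c$samples)
    grp <- ceiling(seq_along(sm) / 8)
    out <- c(out, vapply(split(sm, grp), paste, character(1), collapse = " "))
  }
  out <- c(out, "[END]")

  con_f <- file(path, open = "wb")
  on.exit(close(con_f))
  writeLines(out, con_f, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.parse_error <- function(line_no, what) {
  stop(sprintf("parse error at line %d: %s", line_no, what), call. = FALSE)
}

#' Read a screening from the NCCA-ASCII-style text dialect
#'
#' Parses a file written in the dialect documented in [write_screening()],
#' reporting malformed sections with their line number, and validates the
#' result: any invariant violation (for example, an event whose answer
#' timestamp precedes the question start) raises a validation error.
#'
#' @param path File path.
#' @param n_channels Required channel count.
#' @return A validated screening object; channel order is preserved from the
#'   file and timestamps are in seconds.
#' @export
read_screening <- function(path, n_channels = 10L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  n <- length(lines)
  if (n < 1 || !startsWith(lines[1], "#NCCA-ASCII-DIALECT"))
    .parse_error(1L, "missing #NCCA-ASCII-DIALECT signature")

  i <- 2L
  expect_section <- function(name) {
    if (i > n || lines[i] != paste0("[", name, "]"))
      .parse_error(i, sprintf("expected [%s] section", name))
    i <<- i + 1L
  }
  read_kv <- function() {
    kv <- list()
    while (i <= n && !startsWith(lines[i], "[")) {
      m <- regmatches(lines[i], regexec("^([^=]+)=(.*)$", lines[i]))[[1]]
      if (length(m) != 3) .parse_error(i, "expected key=value line")
      kv[[m[2]]] <- m[3]
      i <<- i + 1L
    }
    kv
  }

  expect_section("HEADER")
  hdr <- read_kv()
  miss <- setdiff(c(HEADER_FIELDS, "sampling_rate_hz", "n_channels"), names(hdr))
  if (length(miss) > 0)
    .parse_error(i - 1L, paste("header missing field(s):",
                               paste(miss, collapse = ", ")))
  rate <- suppressWarnings(as.numeric(hdr$sampling_rate_hz))
  if (is.na(rate)) .parse_error(i - 1L, "non-numeric sampling_rate_hz")

  expect_section("CONCLUSIONS")
  con_kv <- read_kv()
  conclusions <- setNames(unlist(con_kv, use.names = FALSE), names(con_kv))
  if (is.null(conclusions)) conclusions <- setNames(character(0), character(0))

  expect_section("EVENTS")
  if (i > n || lines[i] != paste(EVENT_COLS, collapse = "|"))
    .parse_error(i, "expected event table header")
  i <- i + 1L
  ev_lines <- character(0)
  while (i <= n && !startsWith(lines[i], "[")) {
    ev_lines <- c(ev_lines, lines[i])
    i <- i + 1L
  }
  if (length(ev_lines) > 0) {
    parts <- strsplit(ev_lines, "|", fixed = TRUE)
    bad <- which(lengths(parts) != length(EVENT_COLS))
    if (length(bad) > 0)
      .parse_error(i - length(ev_lines) + bad[1] - 1L,
                   "event line has wrong field count")
    m <- do.call(rbind, parts)
    events <- suppressWarnings(data.frame(
      question_id = m[, 1], qtype = m[, 2],
      topic = ifelse(m[, 3] == ".", NA_character_, m[, 3]),
      test_index = as.integer(m[, 4]),
      repetition_index = as.integer(m[, 5]),
      t_question_start = as.numeric(m[, 6]),
      t_question_end = as.numeric(m[, 7]),
      t_answer = as.numeric(m[, 8]),
      answer = m[, 9], stringsAsFactors = FALSE))
    if (anyNA(events$test_index) || anyNA(events$t_question_start) ||
        anyNA(events$t_question_end) || anyNA(events$t_answer))
      .parse_error(i - 1L, "non-numeric value in event table")
  } else {
    events <- data.frame(question_id = character(0), qtype = character(0),
                         topic = character(0), test_index = integer(0),
                         repetition_index = integer(0),
                         t_question_start = numeric(0),
                         t_question_end = numeric(0), t_answer = numeric(0),
                         answer = character(0), stringsAsFactors = FALSE)
  }

  channels <- list()
  while (i <= n && lines[i] == "[CHANNEL]") {
    i <- i + 1L
    kv <- list()
    for (k in 1:3) {
      m <- regmatches(lines[i], regexec("^([^=]+)=(.*)$", lines[i]))[[1]]
      if (length(m) != 3) .parse_error(i, "expected channel key=value line")
      kv[[m[2]]] <- m[3]
      i <- i + 1L
    }
    if (is.null(kv$name) || is.null(kv$sampling_rate_hz) || is.null(kv$n_samples))
      .parse_error(i - 1L, "channel block missing name/sampling_rate_hz/n_samples")
    ns <- suppressWarnings(as.integer(kv$n_samples))
    if (is.na(ns)) .parse_error(i - 1L, "non-integer n_samples")
    first_sample_line <- i
    j <- i
    while (j <= n && !startsWith(lines[j], "[")) j <- j + 1L
    samples <- if (j > i)
      suppressWarnings(as.numeric(unlist(
        strsplit(lines[i:(j - 1L)], " ", fixed = TRUE), use.names = FALSE)))
    else numeric(0)
    i <- j
    if (anyNA(samples))
      .parse_error(first_sample_line, "non-numeric sample value")
    if (length(samples) != ns)
      .parse_error(first_sample_line,
                   sprintf("channel %s: expected %d samples, found %d",
                           kv$name, ns, length(samples)))
    channels[[kv$name]] <- list(name = kv$name,
                                sampling_rate_hz = as.numeric(kv$sampling_rate_hz),
                                samples = samples)
  }
  if (i > n || lines[i] != "[END]") .parse_error(min(i, n), "missing [END] marker")

  s <- new_screening(
    screening_id = hdr$screening_id, channels = channels, events = events,
    conclusions = conclusions, date = hdr$date, city = hdr$city,
    subject_age = as.integer(hdr$subject_age), subject_sex = hdr$subject_sex,
    subject_type = hdr$subject_type,
    current_position = hdr$current_position,
    current_department = hdr$current_department,
    accepted_position = hdr$accepted_position,
    accepted_department = hdr$accepted_department,
    examiner_id = hdr$examiner_id)

  viol <- validate_screening(s, n_channels = n_channels)
  if (nrow(viol) > 0)
    stop("validation error in ", path, ": ",
         paste(sprintf("[%s: %s]", viol$rule, viol$message), collapse = " "),
         call. = FALSE)
  s
}
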