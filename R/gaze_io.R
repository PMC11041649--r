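# Reading and writing the plain-text gaze-recording dialect, trial tables
# and tidy result reports. The recording container is the data model every
# other module consumes.

#' Construct a raw gaze recording
#'
#' A gaze recording holds continuous binocular samples on a regular
#' millisecond grid plus a table of event markers. Samples may be missing
#' (`NA`), e.g. during blinks; events include `CALIB_POINT`, `CUE_ONSET`,
#' `RESPONSE_ONSET` and `BLINK_START`/`BLINK_END`.
#'
#' @param time Integer sample times in ms, strictly increasing with constant
#'   step `1000 / sampling_rate`.
#' @param left_x,left_y,right_x,right_y Numeric gaze channels, same length
#'   as `time`; `NA` marks missing samples.
#' @param events Data frame with columns `time` (ms), `label` (character)
#'   and `arg` (character or `NA`).
#' @param sampling_rate Samples per second (default 1000).
#' @param units `"raw"` (tracker units) or `"normalized"` (+/-100 stimulus
#'   frame).
#' @return Object of class `gaze_recording`.
#' @export
gaze_recording <- function(time, left_x, left_y, right_x, right_y,
                           events = empty_events(), sampling_rate = 1000,
                           units = "raw") {
  time <- as.integer(time)
  n <- length(time)
  chans <- list(left_x = left_x, left_y = left_y,
                right_x = right_x, right_y = right_y)
  for (nm in names(chans)) {
    abort_if(length(chans[[nm]]) != n,
             "channel '%s' has length %d, expected %d", nm,
             length(chans[[nm]]), n)
  }
  step <- 1000 / sampling_rate
  if (n > 1) {
    d <- diff(time)
    abort_if(any(d != step),
             "sample times must increase with constant step %g ms", step)
  }
  abort_if(!units %in% c("raw", "normalized"),
           "units must be 'raw' or 'normalized'")
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  abort_if(!all(c("time", "label") %in% names(events)),
           "events need 'time' and 'label' columns")
  if (is.null(events$arg)) events$arg <- rep(NA_character_, nrow(events))
  events$time <- as.integer(events$time)
  events$label <- as.character(events$label)
  events$arg <- as.character(events$arg)
  starts <- events$time[events$label == "BLINK_START"]
  ends <- events$time[events$label == "BLINK_END"]
  abort_if(length(starts) != length(ends) ||
             (length(starts) > 0 && any(sort(ends) <= sort(starts))),
           "every BLINK_START needs a matching later BLINK_END")
  structure(list(sampling_rate = sampling_rate, time = time,
                 left_x = as.numeric(left_x), left_y = as.numeric(left_y),
                 right_x = as.numeric(right_x), right_y = as.numeric(right_y),
                 events = events[c("time", "label", "arg")], units = units),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%s units), %d events\n",
              length(x$time), x$sampling_rate, x$units, nrow(x$events)))
  invisible(x)
}

empty_events <- function() {
  data.frame(time = integer(0), label = character(0), arg = character(0),
             stringsAsFactors = FALSE)
}

#' Read a gaze recording from its plain-text dialect
#'
#' The dialect: header lines `#RATE <hz>` and `#UNITS raw|normalized`;
#' sample lines `t lx ly rx ry` (whitespace-separated, `.` for a missing
#' value); event lines `E t LABEL [arg]`. Missing samples are kept as `NA`,
#' never dropped.
#'
#' @param path Path to the recording file.
#' @return A [gaze_recording()].
#' @export
read_recording <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  n_all <- length(lines)
  kind <- rep("sample", n_all)
  kind[startsWith(lines, "#")] <- "header"
  kind[startsWith(lines, "E ")] <- "event"
  kind[!nzchar(trimws(lines))] <- "blank"

  rate <- 1000
  units <- "raw"
  for (i in which(kind == "header")) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] == "#RATE") rate <- as.numeric(tok[2])
    if (tok[1] == "#UNITS") units <- tok[2]
  }

  samp_i <- which(kind == "sample")
  ev_i <- which(kind == "event")

  time <- integer(0)
  chans <- matrix(numeric(0), 0, 4)
  if (length(samp_i)) {
    toks <- strsplit(trimws(lines[samp_i]), "\\s+")
    lens <- lengths(toks)
    if (any(lens != 5)) {
      bad <- samp_i[which(lens != 5)[1]]
      stop(sprintf("parse error at line %d: expected 5 fields, got %d",
                   bad, lens[which(lens != 5)[1]]), call. = FALSE)
    }
    m <- matrix(unlist(toks), ncol = 5, byrow = TRUE)
    time <- suppressWarnings(as.integer(m[, 1]))
    if (anyNA(time)) {
      bad <- samp_i[which(is.na(time))[1]]
      stop(sprintf("parse error at line %d: non-integer time", bad),
           call. = FALSE)
    }
    chans <- suppressWarnings(apply(m[, 2:5, drop = FALSE], 2, as.numeric))
    chans <- matrix(chans, ncol = 4)
    bad_tok <- is.na(chans) & m[, 2:5] != "."
    if (any(bad_tok)) {
      bad <- samp_i[which(rowSums(bad_tok) > 0)[1]]
      stop(sprintf("parse error at line %d: non-numeric sample value", bad),
           call. = FALSE)
    }
    if (length(time) > 1 && any(diff(time) <= 0)) {
      stop("integrity error: sample times not strictly increasing",
           call. = FALSE)
    }
  }

  events <- empty_events()
  if (length(ev_i)) {
    toks <- strsplit(trimws(lines[ev_i]), "\\s+")
    lens <- lengths(toks)
    if (any(lens < 3)) {
      bad <- ev_i[which(lens < 3)[1]]
      stop(sprintf("parse error at line %d: event needs 'E t LABEL [arg]'",
                   bad), call. = FALSE)
    }
    events <- data.frame(
      time = as.integer(vapply(toks, `[`, "", 2)),
      label = vapply(toks, `[`, "", 3),
      arg = vapply(toks, function(t) if (length(t) >= 4) t[4] else
        NA_character_, ""),
      stringsAsFactors = FALSE)
    abort_if(anyNA(events$time), "parse error: non-integer event time")
  }

  gaze_recording(time, chans[, 1], chans[, 2], chans[, 3], chans[, 4],
                 events = events, sampling_rate = rate, units = units)
}

#' Write a gaze recording in canonical form
#'
#' Canonical form: the two header lines, all samples in time order (values
#' printed with four decimals, `.` for missing), then all events sorted
#' stably by time. `write_recording(read_recording(f))` is byte-identical
#' for files produced by this writer.
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recording, path) {
  abort_if(!inherits(recording, "gaze_recording"),
           "'recording' must be a gaze_recording")
  fmt <- function(v) ifelse(is.na(v), ".", sprintf("%.4f", v))
  samp <- paste(recording$time,
                fmt(recording$left_x), fmt(recording$left_y),
                fmt(recording$right_x), fmt(recording$right_y))
  ev <- recording$events
  ev_lines <- character(0)
  if (nrow(ev)) {
    ev <- ev[order(ev$time), , drop = FALSE]
    ev_lines <- ifelse(is.na(ev$arg),
                       paste("E", ev$time, ev$label),
                       paste("E", ev$time, ev$label, ev$arg))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#RATE %g", recording$sampling_rate),
               sprintf("#UNITS %s", recording$units),
               samp, ev_lines), con)
  invisible(path)
}

#' Read / write a trial table
#'
#' Trial tables are plain CSV with one row per trial: `trial_id`,
#' `experiment`, `condition`, `trial_subtype`, `cued_side`, `cue_onset`
#' (absolute ms in the recording), `target_orientation`,
#' `reported_orientation` (degrees in `[0, 180)`), `response_onset_ms`
#' (ms after the go signal) and `block`.
#'
#' @param path CSV path.
#' @return `read_trials`: data frame of trials.
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(tr)
  tr
}

#' @rdname read_trials
#' @param trials Trial data frame.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_trials <- function(tr) {
  need <- c("trial_id", "experiment", "condition", "trial_subtype",
            "cued_side", "cue_onset", "target_orientation",
            "reported_orientation", "response_onset_ms", "block")
  miss <- setdiff(need, names(tr))
  abort_if(length(miss) > 0, "trial table missing columns: %s",
           paste(miss, collapse = ", "))
  abort_if(!all(tr$cued_side %in% c("left", "right")),
           "cued_side must be 'left' or 'right'")
  ok_ori <- function(v) all(is.na(v) | (v >= 0 & v < 180))
  abort_if(!ok_ori(tr$target_orientation) || !ok_ori(tr$reported_orientation),
           "orientations must lie in [0, 180)")
  abort_if(any(tr$response_onset_ms <= 0, na.rm = TRUE),
           "response_onset_ms must be positive")
  invisible(tr)
}

#' Write tidy result tables and a JSON statistics summary
#'
#' Writes each data frame in `tables` as `<name>.csv` under `dir`, and the
#' list `summary` (scalar statistics, cluster results, provenance) as
#' `summary.json`. Time-course tables are expected in tidy long form
#' (participant, condition, time_ms, value).
#'
#' @param tables Named list of data frames.
#' @param summary List serialisable to JSON (may be `NULL`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tables, summary = NULL, dir) {
  abort_if(!is.list(tables) || (length(tables) > 0 && is.null(names(tables))),
           "'tables' must be a named list of data frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    abort_if(!is.data.frame(tables[[nm]]),
             "report table '%s' is not a data frame", nm)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(summary)) {
    p <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
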