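# On-disk artifacts: EEG recordings (CSV + JSON sidecar), session logs
# (JSON lines), model snapshots (full-precision JSON), rankings (CSV).
# Formats are deliberately plain text so fixtures stay diffable.

#' Construct a two-channel EEG recording
#'
#' @param samples numeric matrix, channels x time (2 rows: left, right), in
#'   microvolts (arbitrary scale).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names ordered channel labels, default `c("left", "right")`.
#' @param t0 recording start time in seconds.
#' @param events data frame with columns `time` (s, relative to recording
#'   start) and `label`, or `NULL`.
#' @return object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(samples, fs, channel_names = c("left", "right"),
                          t0 = 0, events = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (nrow(samples) != 2) {
    stop("an eeg_recording must have exactly 2 data channels, got ",
         nrow(samples), call. = FALSE)
  }
  if (length(channel_names) != 2) {
    stop("channel_names must have length 2", call. = FALSE)
  }
  if (is.null(events)) {
    events <- data.frame(time = numeric(0), label = character(0))
  }
  events <- as.data.frame(events)
  stopifnot(all(c("time", "label") %in% names(events)))
  dur <- ncol(samples) / fs
  if (nrow(events) && (any(events$time < 0) || any(events$time > dur))) {
    stop("event times must lie within [0, duration]", call. = FALSE)
  }
  rownames(samples) <- channel_names
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 t0 = t0, events = events[, c("time", "label")]),
            class = "eeg_recording")
}

#' @exportS3Method base::print
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> 2 ch x %d samples @ %g Hz (%.2f s), %d event(s)\n",
              ncol(x$samples), x$fs, ncol(x$samples) / x$fs, nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' Write / read an EEG recording
#'
#' The samples go to a delimited-text file with header `time,left,right`
#' (times in seconds); the sampling rate, start time and event markers go to
#' a JSON sidecar `<name>.meta.json`. `read_eeg_recording(write_eeg_recording(x))`
#' reproduces `x` up to text-precision round-off (17 significant digits, i.e.
#' bit-exact for doubles).
#'
#' @param rec an [eeg_recording()].
#' @param path CSV file path.
#' @param max_nan_run longest run of missing samples tolerated on read.
#' @return `write_eeg_recording` returns `path` invisibly;
#'   `read_eeg_recording` returns an `eeg_recording`.
#' @export
write_eeg_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  t <- (seq_len(ncol(rec$samples)) - 1) / rec$fs
  df <- data.frame(time = t,
                   left = rec$samples[1, ],
                   right = rec$samples[2, ])
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs, t0 = rec$t0,
               channel_names = rec$channel_names,
               events = rec$events)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17), dataframe = "rows")
  invisible(path)
}

#' @rdname write_eeg_recording
#' @export
read_eeg_recording <- function(path, max_nan_run = 10) {
  if (!file.exists(path)) stop("EEG file not found: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing JSON sidecar for EEG recording: ", sp, call. = FALSE)
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs <= 0) {
    stop("sidecar fs must be > 0", call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (!identical(names(df), c("time", "left", "right"))) {
    stop("EEG file must have header time,left,right (2 data channels)",
         call. = FALSE)
  }
  for (ch in c("left", "right")) {
    runs <- rle(is.na(df[[ch]]))
    if (any(runs$values & runs$lengths > max_nan_run)) {
      stop("channel '", ch, "' contains a NaN run longer than ", max_nan_run,
           " samples", call. = FALSE)
    }
  }
  ev <- meta$events
  if (is.null(ev) || (is.data.frame(ev) && nrow(ev) == 0) || length(ev) == 0) {
    ev <- NULL
  } else {
    ev <- as.data.frame(ev)
  }
  eeg_recording(rbind(df$left, df$right), fs = meta$fs,
                channel_names = if (!is.null(meta$channel_names)) {
                  meta$channel_names
                } else c("left", "right"),
                t0 = if (!is.null(meta$t0)) meta$t0 else 0,
                events = ev)
}

#' Construct a session log
#'
#' One record per played song: identity, experimental condition, onset and
#' duration within the session, chill key-press times (seconds, relative to
#' song onset) and VAS ratings (0--100) keyed by item.
#'
#' @param participant_id opaque participant identifier.
#' @param phase `"recording"` (calibration) or `"playlist"`.
#' @param song_records list of records; each a list with fields `song_id`,
#'   `condition`, `onset`, `duration`, `chill_press_times` (numeric vector)
#'   and `vas_ratings` (named list/vector, values in 0--100).
#' @return object of class `"session_log"`.
#' @export
session_log <- function(participant_id, phase, song_records) {
  stopifnot(phase %in% c("recording", "playlist"), is.list(song_records))
  for (i in seq_along(song_records)) {
    r <- song_records[[i]]
    need <- c("song_id", "condition", "onset", "duration",
              "chill_press_times", "vas_ratings")
    missing <- setdiff(need, names(r))
    if (length(missing)) {
      stop("song record ", i, " is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    vas <- unlist(r$vas_ratings)
    if (length(vas) && (any(vas < 0) || any(vas > 100))) {
      stop("VAS ratings must lie in [0, 100] (song record ", i, ")",
           call. = FALSE)
    }
    ct <- r$chill_press_times
    if (length(ct) && (any(ct < 0) || any(ct > r$duration))) {
      stop("chill press times must lie within the song window (song record ",
           i, ")", call. = FALSE)
    }
  }
  structure(list(participant_id = participant_id, phase = phase,
                 song_records = song_records),
            class = "session_log")
}

#' Write / read a session log as JSON lines
#'
#' One JSON object per line per song; `read_session_log(write_session_log(x))`
#' equals `x`.
#'
#' @param log a [session_log()].
#' @param path file path (conventionally `.jsonl`).
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   returns a `session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- list(participant_id = log$participant_id, phase = log$phase)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17)), con)
  for (r in log$song_records) {
    r$chill_press_times <- as.numeric(r$chill_press_times)
    r$vas_ratings <- as.list(r$vas_ratings)
    writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(17),
                                null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("session log not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty session log: ", path, call. = FALSE)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
             error = function(e) {
               stop("malformed session-log line ", i, " in ", path, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  header <- parse_line(1)
  recs <- lapply(seq_along(lines)[-1], function(i) {
    r <- parse_line(i)
    r$chill_press_times <- as.numeric(unlist(r$chill_press_times))
    r$vas_ratings <- as.list(r$vas_ratings)
    r
  })
  session_log(header$participant_id, header$phase, recs)
}

#' Save / load a fitted model snapshot
#'
#' Serializes a fitted [fit_pleasure_regressor()] or [fit_eeg_classifier()]
#' model to plain JSON at full floating-point precision, so a reloaded model
#' reproduces predictions bit-identically.
#'
#' @param model a fitted `pleasure_regressor` or `eeg_classifier`.
#' @param path JSON file path.
#' @return `save_model_snapshot` returns `path` invisibly;
#'   `load_model_snapshot` returns the model.
#' @export
save_model_snapshot <- function(model, path) {
  if (inherits(model, "pleasure_regressor")) {
    kind <- "pleasure_regressor"
  } else if (inherits(model, "eeg_classifier")) {
    kind <- "eeg_classifier"
  } else {
    stop("model must be a pleasure_regressor or eeg_classifier", call. = FALSE)
  }
  if (is.null(model$fitted) || !isTRUE(model$fitted)) {
    stop("cannot snapshot an unfitted model", call. = FALSE)
  }
  payload <- unclass(model)
  if (!is.null(payload$validation)) {
    payload$validation <- list(
      train_acc = payload$validation$train$accuracy,
      train_auc = payload$validation$train$auc,
      test_acc = payload$validation$test$accuracy,
      test_auc = payload$validation$test$auc)
  }
  payload$.class <- kind
  out <- tryCatch(
    jsonlite::write_json(payload, path, auto_unbox = TRUE,
                         digits = I(17), matrix = "rowmajor", null = "null"),
    error = function(e) stop("cannot write model snapshot to '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname save_model_snapshot
#' @export
load_model_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$.class
  obj$.class <- NULL
  for (nm in c("pca_basis", "weights")) {
    if (!is.null(obj[[nm]]) && is.null(dim(obj[[nm]]))) {
      obj[[nm]] <- matrix(obj[[nm]], nrow = 1)
    }
  }
  class(obj) <- kind
  obj
}

#' Write / read a ranked candidate library as CSV
#'
#' Columns `rank,song_id,score`, ranks ascending (rank 1 = best).
#'
#' @param ranked a `ranked_library` from [rank_candidates()] (or any data
#'   frame with `rank`, `song_id`, `score`).
#' @param path CSV file path.
#' @return `write_ranking` returns `path` invisibly; `read_ranking` a data
#'   frame.
#' @export
write_ranking <- function(ranked, path) {
  df <- as.data.frame(ranked)[, c("rank", "song_id", "score")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  utils::read.csv(path, colClasses = c(rank = "integer",
                                       song_id = "character",
                                       score = "numeric"))
}
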