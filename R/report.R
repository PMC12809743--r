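# Descriptive session summaries: chill counts (slots 2-7 only), VAS
# summaries, baseline-corrected decoded pleasure, inclusion criteria.
# Group inferential statistics are intentionally out of scope; the outputs
# are tidy data frames consumable by any stats environment.

#' Count chills in a playlist session, excluding the baseline song
#'
#' Total key presses across slots 2--7 (the first song of every playlist is
#' the baseline and is excluded). Presses outside any song window raise a
#' warning and are dropped.
#'
#' @param log a playlist-phase [session_log()].
#' @param condition optional condition filter (records whose `condition`
#'   matches).
#' @return integer chill count.
#' @export
count_chills <- function(log, condition = NULL) {
  stopifnot(inherits(log, "session_log"))
  recs <- log$song_records
  if (!is.null(condition)) {
    recs <- Filter(function(r) identical(r$condition, condition), recs)
  }
  total <- 0L
  for (i in seq_along(recs)) {
    if (i == 1) next      # baseline slot
    ct <- recs[[i]]$chill_press_times
    bad <- ct < 0 | ct > recs[[i]]$duration
    if (any(bad)) {
      warning(sum(bad), " press(es) outside the song window excluded")
      ct <- ct[!bad]
    }
    total <- total + length(ct)
  }
  total
}

#' Check the participant inclusion criteria
#'
#' Included iff (self-selected chills - other-selected chills >= 3) AND
#' (mean self-selected VAS > mean other-selected VAS).
#'
#' @param log a recording-phase (calibration) [session_log()] whose records
#'   carry conditions `"self"` / `"other"`, chill presses and a `pleasure`
#'   VAS rating per song.
#' @return list with `included` (logical) and `reasons` (character vector of
#'   failed criteria, empty when included).
#' @export
check_inclusion <- function(log) {
  stopifnot(inherits(log, "session_log"))
  recs <- log$song_records
  is_self <- vapply(recs, function(r) identical(r$condition, "self"), logical(1))
  get_vas <- function(r) {
    v <- r$vas_ratings$pleasure
    if (is.null(v)) stop("missing calibration pleasure rating for song ",
                         r$song_id, call. = FALSE)
    as.numeric(v)
  }
  chills <- vapply(recs, function(r) length(r$chill_press_times), integer(1))
  vas <- vapply(recs, get_vas, numeric(1))
  reasons <- character(0)
  if (sum(chills[is_self]) - sum(chills[!is_self]) < 3) {
    reasons <- c(reasons, "chill criterion")
  }
  if (!(mean(vas[is_self]) > mean(vas[!is_self]))) {
    reasons <- c(reasons, "pleasure criterion")
  }
  list(included = length(reasons) == 0, reasons = reasons)
}

#' Baseline-correct per-slot decoded means
#'
#' Subtracts the slot-1 (baseline song) mean from every slot's mean; slot 1
#' maps to exactly 0.
#'
#' @param decoded_means numeric per-slot means; the first element is the
#'   baseline.
#' @return corrected numeric vector.
#' @export
baseline_correct <- function(decoded_means) {
  if (length(decoded_means) < 1 || is.na(decoded_means[1])) {
    stop("baseline (slot 1) decoded mean is missing", call. = FALSE)
  }
  decoded_means - decoded_means[1]
}

#' Summarize a closed-loop session
#'
#' @param result a [run_session()] result.
#' @return object of class `"condition_summary"`: `condition`, `n_chills`
#'   (slots 2--7), `decoded_means`, `baseline_corrected`, `n_retrains`,
#'   `songs`.
#' @export
condition_summary <- function(result) {
  stopifnot(inherits(result, "session_result"))
  structure(list(condition = result$condition,
                 n_chills = count_chills(result$log),
                 decoded_means = result$decoded_means,
                 baseline_corrected = baseline_correct(result$decoded_means),
                 n_retrains = length(result$retrain_events),
                 songs = result$songs),
            class = "condition_summary")
}

#' @exportS3Method base::print
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s: %d chills (slots 2-7), %d retrains\n",
              x$condition, x$n_chills, x$n_retrains))
  cat("  baseline-corrected decoded means:",
      paste(sprintf("%+.3f", x$baseline_corrected), collapse = " "), "\n")
  invisible(x)
}

#' Tidy per-condition report table
#' @param results list of [run_session()] results (one per condition).
#' @return data frame with one row per condition x slot.
#' @export
report_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(condition = r$condition,
               slot = seq_along(r$songs),
               song_id = r$songs,
               decoded_mean = r$decoded_means,
               baseline_corrected = baseline_correct(r$decoded_means),
               chills = vapply(r$log$song_records, function(x)
                 length(x$chill_press_times), integer(1)),
               row.names = NULL)
  }))
}
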