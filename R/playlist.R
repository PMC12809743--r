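# Composite ranking of the candidate library and per-condition song
# selection.
#
# Composite score = z(predicted pleasure across the library) + z(mean
# Pearson correlation with the three self-selected songs). Candidates are
# ranked in descending score order. Playlist conditions: Aug* draw from the
# top of the ranking, Dim* from the bottom; *EEG conditions use a narrow
# 72-rank window re-ranked after every song, *NoEEG a fixed wide 432-rank
# window; every playlist opens with a baseline song from the middle window
# (ranks 3577--3649 at library size 7225). Other library sizes scale the
# windows by the same fractions with floor rounding.

PLAYLIST_CONDITIONS <- c("AugEEG", "AugNoEEG", "DimEEG", "DimNoEEG")

#' Rank the candidate library by composite pleasure score
#'
#' @param model1 a fitted [fit_pleasure_regressor()] model.
#' @param lib_features standardized, clipped candidate features
#'   ([normalize_and_clip_library()]), rownames = song ids.
#' @param self_features matrix of the three self-selected songs' features on
#'   the same dimension mask.
#' @return object of class `"ranked_library"`: a data frame `entries` with
#'   `rank`, `song_id`, `pred_z`, `sim_z`, `score`, ordered by descending
#'   score with ties broken by song id.
#' @export
rank_candidates <- function(model1, lib_features, self_features) {
  stopifnot(inherits(model1, "pleasure_regressor"))
  pred <- predict_pleasure(model1, lib_features)
  sims <- apply(lib_features, 1, function(v) {
    if (pop_sd(v) == 0) return(0)
    mean(as.numeric(stats::cor(v, t(self_features))))
  })
  zs <- function(v) if (pop_sd(v) == 0) rep(0, length(v)) else
    (v - mean(v)) / pop_sd(v)
  pred_z <- zs(pred)
  sim_z <- zs(sims)
  score <- pred_z + sim_z
  ids <- rownames(lib_features)
  ord <- order(-score, ids)
  entries <- data.frame(rank = seq_along(ord), song_id = ids[ord],
                        pred_z = pred_z[ord], sim_z = sim_z[ord],
                        score = score[ord], row.names = NULL)
  structure(list(entries = entries, library_size = nrow(lib_features)),
            class = "ranked_library")
}

#' @exportS3Method base::print
print.ranked_library <- function(x, ...) {
  cat(sprintf("<ranked_library> %d songs; top: %s (score %.3f)\n",
              x$library_size, x$entries$song_id[1], x$entries$score[1]))
  invisible(x)
}

#' @export
as.data.frame.ranked_library <- function(x, ...) x$entries

#' Rank window for a playlist slot
#'
#' Slot 1 is always the baseline window (ranks 3577--3649 at library size
#' 7225, the central band); slots 2--7 use the condition window: top/bottom
#' 72 for the EEG conditions, top/bottom 432 for the NoEEG conditions. For
#' other library sizes the widths scale by the same fractions (72/7225,
#' 432/7225, 73/7225) with floor rounding, the baseline staying central.
#'
#' @param condition one of `"AugEEG"`, `"AugNoEEG"`, `"DimEEG"`, `"DimNoEEG"`.
#' @param slot playlist slot, 1--7.
#' @param library_size number of ranked candidates.
#' @param cfg a [run_config()] (holds the window constants).
#' @return integer `c(lo, hi)` rank window (inclusive).
#' @export
selection_window <- function(condition, slot, library_size,
                             cfg = run_config()) {
  condition <- match.arg(condition, PLAYLIST_CONDITIONS)
  if (!(slot %in% seq_len(cfg$playlist_len))) {
    stop("slot must be in 1..", cfg$playlist_len, call. = FALSE)
  }
  ref <- cfg$library_size
  scale_w <- function(w) {
    if (library_size == ref) w else max(1L, as.integer(floor(w * library_size / ref)))
  }
  if (slot == 1) {
    if (library_size == ref) return(as.integer(cfg$baseline_window))
    w <- scale_w(cfg$baseline_window[2] - cfg$baseline_window[1] + 1L)
    lo <- as.integer(floor((library_size - w) / 2)) + 1L
    return(c(lo, lo + w - 1L))
  }
  w <- scale_w(if (grepl("NoEEG", condition)) cfg$window_wide else cfg$window_top)
  if (w > library_size) {
    stop("library (", library_size, ") smaller than the selection window (",
         w, ")", call. = FALSE)
  }
  if (startsWith(condition, "Aug")) c(1L, w) else
    c(library_size - w + 1L, library_size)
}

#' Randomly select an unplayed song from a rank window
#'
#' @param ranking a `ranked_library`.
#' @param window integer `c(lo, hi)` rank window.
#' @param already_played character vector of song ids to exclude.
#' @param seed RNG seed.
#' @return the chosen song id.
#' @export
select_song <- function(ranking, window, already_played = character(0),
                        seed = 1L) {
  stopifnot(inherits(ranking, "ranked_library"))
  pool <- ranking$entries$song_id[window[1]:window[2]]
  pool <- setdiff(pool, already_played)
  if (!length(pool)) {
    stop("selection window exhausted: all ", diff(window) + 1L,
         " songs already played", call. = FALSE)
  }
  set.seed(seed)
  pool[sample.int(length(pool), 1L)]
}

#' Build a playlist plan for one condition
#'
#' Slot 1 (the baseline) is always drawn immediately. For the NoEEG
#' conditions all six remaining songs are drawn up-front from the fixed
#' ranking; for the EEG conditions slots 2--7 are left `NA` ("deferred") and
#' resolved by [run_session()] after each retrain/re-rank.
#'
#' @param condition playlist condition.
#' @param ranking a `ranked_library`.
#' @param seed RNG seed; each slot draws from an independent per-slot stream
#'   derived from it.
#' @param cfg a [run_config()].
#' @return object of class `"playlist_plan"`: `condition`, `slots` (song ids,
#'   `NA` = deferred), `windows` (per-slot rank windows), `seed`.
#' @export
build_playlist_plan <- function(condition, ranking, seed = 1L,
                                cfg = run_config()) {
  condition <- match.arg(condition, PLAYLIST_CONDITIONS)
  n_slots <- cfg$playlist_len
  windows <- lapply(seq_len(n_slots), function(s) {
    selection_window(condition, s, ranking$library_size, cfg)
  })
  slots <- rep(NA_character_, n_slots)
  slots[1] <- select_song(ranking, windows[[1]], character(0),
                          seed = (seed %% 21000000L) * 101L + 1L)
  deferred <- grepl("EEG$", condition) && !grepl("NoEEG", condition)
  if (!deferred) {
    for (s in 2:n_slots) {
      slots[s] <- select_song(ranking, windows[[s]], slots[!is.na(slots)],
                              seed = (seed %% 21000000L) * 101L + s)
    }
  }
  structure(list(condition = condition, slots = slots, windows = windows,
                 seed = seed, deferred = deferred),
            class = "playlist_plan")
}
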