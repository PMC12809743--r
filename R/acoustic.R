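# Frame-level 128-d audio embeddings -> standardized per-song feature
# vectors for the acoustic pleasure model and the ranking engine.
#
# A 90-s excerpt's frames are averaged into nine 10-s bins (9 x 128). The
# default per-song feature vector concatenates the nine bin means (1152
# dims); "mean" mode collapses to the 128-dim grand mean. Calibration
# features are z-scored across the six calibration songs (population-SD
# convention) and dimensions with non-finite means or SD <= 0.01 are dropped.

#' Average embedding frames into fixed-length time bins
#'
#' Frames are assigned to half-open `bin_len`-second bins by their midpoint;
#' each bin must receive at least one frame.
#'
#' @param frame_matrix frames x dims numeric matrix.
#' @param frame_times optional frame midpoint times (s); defaults to a
#'   uniform grid over `[0, excerpt_len)`.
#' @param bin_len bin length in seconds (default 10).
#' @param excerpt_len excerpt length in seconds (default 90, giving 9 bins).
#' @return bins x dims matrix of per-bin means.
#' @export
frame_average <- function(frame_matrix, frame_times = NULL, bin_len = 10,
                          excerpt_len = 90) {
  frame_matrix <- as.matrix(frame_matrix)
  n <- nrow(frame_matrix)
  if (is.null(frame_times)) {
    frame_times <- (seq_len(n) - 0.5) * excerpt_len / n
  }
  stopifnot(length(frame_times) == n)
  n_bins <- as.integer(floor(excerpt_len / bin_len))
  idx <- pmin(n_bins, floor(frame_times / bin_len) + 1L)
  out <- matrix(NA_real_, n_bins, ncol(frame_matrix))
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    if (!any(sel)) {
      stop("no frames fall in time bin ", b, " [",
           (b - 1) * bin_len, ", ", b * bin_len, ") s", call. = FALSE)
    }
    out[b, ] <- colMeans(frame_matrix[sel, , drop = FALSE])
  }
  out
}

#' Build a per-song acoustic profile
#'
#' @param song_id identifier.
#' @param frame_matrix frames x 128 embedding matrix.
#' @param frame_times optional frame midpoints (s).
#' @param mode `"concat"` (default; flattened 9 x 128 = 1152 dims, bin-major:
#'   bin 1 dims 1..128, then bin 2, ...), `"mean"` (128-dim grand mean of the
#'   bin means).
#' @param bin_len,excerpt_len see [frame_average()].
#' @return object of class `"acoustic_profile"` with `means_10s` (9 x 128)
#'   and `feature_vector`.
#' @export
acoustic_profile <- function(song_id, frame_matrix, frame_times = NULL,
                             mode = c("concat", "mean"),
                             bin_len = 10, excerpt_len = 90) {
  mode <- match.arg(mode)
  m <- frame_average(frame_matrix, frame_times, bin_len, excerpt_len)
  fv <- switch(mode,
               concat = as.numeric(t(m)),
               mean = colMeans(m))
  if (mode == "concat") {
    names(fv) <- paste0("d", rep(seq_len(ncol(m)), nrow(m)),
                        "_b", rep(seq_len(nrow(m)), each = ncol(m)))
  } else {
    names(fv) <- paste0("d", seq_len(ncol(m)))
  }
  structure(list(song_id = song_id, means_10s = m, feature_vector = fv,
                 mode = mode),
            class = "acoustic_profile")
}

#' Profile every song in a library
#' @param library a `song_library` from [generate_song_library()], or a list
#'   of `list(song_id, frames)` entries.
#' @inheritParams acoustic_profile
#' @return list of `acoustic_profile` objects, named by song id.
#' @export
profile_library <- function(library, mode = c("concat", "mean"),
                            bin_len = 10, excerpt_len = 90) {
  mode <- match.arg(mode)
  songs <- if (inherits(library, "song_library")) library$songs else library
  out <- lapply(songs, function(s) {
    acoustic_profile(s$song_id, s$frames, mode = mode, bin_len = bin_len,
                     excerpt_len = excerpt_len)
  })
  names(out) <- vapply(out, `[[`, character(1), "song_id")
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Build the calibration design matrix and z-scored response
#'
#' Feature z-scores are computed per dimension across the calibration songs
#' (population-SD convention, so ratings (86.1, 86.1, 86.1, 57.1, 57.1, 57.1)
#' map to (+1, +1, +1, -1, -1, -1)). Dimensions whose mean is not finite or
#' whose SD is <= 0.01 are dropped; the scaler (means, SDs, retained mask) is
#' stored for candidate songs and retraining points.
#'
#' @param profiles list of 6 [acoustic_profile()]s (3 self + 3 other), or any
#'   number if `strict = FALSE`.
#' @param ratings numeric VAS ratings, one per profile.
#' @param sd_min dimension-retention SD threshold (default 0.01).
#' @param strict require exactly the 6-song calibration design.
#' @return list with `X` (songs x retained dims), `y` (z-scored ratings),
#'   `scaler` (`mean`, `sd`, `mask` over the original dims, `vas_mean`,
#'   `vas_sd`, ratings).
#' @export
build_calibration_matrix <- function(profiles, ratings, sd_min = 0.01,
                                     strict = TRUE) {
  stopifnot(length(profiles) == length(ratings))
  if (strict && length(profiles) != 6) {
    stop("calibration design requires exactly 6 songs (3 self + 3 other); ",
         "pass strict = FALSE to relax", call. = FALSE)
  }
  raw <- do.call(rbind, lapply(profiles, `[[`, "feature_vector"))
  mu <- colMeans(raw)
  sd_ <- apply(raw, 2, pop_sd)
  mask <- is.finite(mu) & sd_ > sd_min
  if (!any(mask)) stop("no feature dimension passed the retention filter",
                       call. = FALSE)
  if (pop_sd(ratings) == 0) {
    stop("all calibration ratings are identical: zero-variance response",
         call. = FALSE)
  }
  X <- sweep(sweep(raw[, mask, drop = FALSE], 2, mu[mask], "-"),
             2, sd_[mask], "/")
  y <- (ratings - mean(ratings)) / pop_sd(ratings)
  scaler <- list(mean = mu, sd = sd_, mask = mask,
                 vas_mean = mean(ratings), vas_sd = pop_sd(ratings),
                 ratings = as.numeric(ratings), sd_min = sd_min)
  list(X = X, y = y, scaler = scaler)
}

#' Apply a calibration scaler to new song profiles
#'
#' @param profiles list of [acoustic_profile()]s.
#' @param scaler a [build_calibration_matrix()] scaler.
#' @return songs x retained-dims matrix of z-scores (no clipping).
#' @export
apply_calibration_scaler <- function(profiles, scaler) {
  raw <- do.call(rbind, lapply(profiles, `[[`, "feature_vector"))
  if (ncol(raw) != length(scaler$mask)) {
    stop("feature dimensionality does not match the calibration scaler",
         call. = FALSE)
  }
  sweep(sweep(raw[, scaler$mask, drop = FALSE], 2,
              scaler$mean[scaler$mask], "-"),
        2, scaler$sd[scaler$mask], "/")
}

#' Normalize and clip candidate-library features
#'
#' Candidate features are z-scored (with the library's own per-dimension
#' statistics by default, or a supplied calibration scaler) and values
#' exceeding `clip_sd` standard deviations are clipped to exactly
#' `+/- clip_sd`.
#'
#' @param profiles list of [acoustic_profile()]s for the candidate songs.
#' @param scaler optional calibration scaler; if `NULL` (default) the
#'   library's own statistics are used, restricted to `mask` if given.
#' @param clip_sd clip threshold in SD units (default 2; `Inf` disables).
#' @param mask optional logical retained-dimension mask (required when
#'   `scaler` is `NULL` and the features must align with a calibration fit).
#' @return songs x dims matrix of clipped z-scores, rownames = song ids.
#' @export
normalize_and_clip_library <- function(profiles, scaler = NULL, clip_sd = 2,
                                       mask = NULL) {
  raw <- do.call(rbind, lapply(profiles, `[[`, "feature_vector"))
  rownames(raw) <- vapply(profiles, `[[`, character(1), "song_id")
  if (!is.null(scaler)) {
    if (ncol(raw) != length(scaler$mask)) {
      stop("feature dimensionality does not match the scaler mask", call. = FALSE)
    }
    z <- sweep(sweep(raw[, scaler$mask, drop = FALSE], 2,
                     scaler$mean[scaler$mask], "-"),
               2, scaler$sd[scaler$mask], "/")
  } else {
    if (!is.null(mask)) {
      if (ncol(raw) != length(mask)) {
        stop("feature dimensionality does not match the mask", call. = FALSE)
      }
      raw <- raw[, mask, drop = FALSE]
    }
    mu <- colMeans(raw)
    sd_ <- apply(raw, 2, pop_sd)
    sd_[sd_ == 0] <- 1
    z <- sweep(sweep(raw, 2, mu, "-"), 2, sd_, "/")
  }
  if (is.finite(clip_sd)) z[] <- pmin(pmax(z, -clip_sd), clip_sd)
  z
}

#' Acoustic similarity of a candidate to the self-selected songs
#'
#' Pearson correlation between the candidate's feature vector and each of the
#' three self-selected songs' feature vectors, plus their mean.
#'
#' @param candidate numeric feature vector.
#' @param self_features matrix with one row per self-selected song (same
#'   dimension mask as `candidate`).
#' @return list with `correlations` and `mean`.
#' @export
similarity_to_self <- function(candidate, self_features) {
  self_features <- as.matrix(self_features)
  if (length(candidate) != ncol(self_features)) {
    stop("candidate and self-selected features use different dimension masks",
         call. = FALSE)
  }
  if (pop_sd(candidate) == 0 || any(apply(self_features, 1, pop_sd) == 0)) {
    stop("zero-variance feature vector: correlation undefined", call. = FALSE)
  }
  r <- as.numeric(stats::cor(candidate, t(self_features)))
  list(correlations = r, mean = mean(r))
}
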