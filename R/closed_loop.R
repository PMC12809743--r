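# Real-time decoding and the closed loop.
#
# Every second the trailing 4-s window of the stream is causally filtered
# (no artifact-component removal in real time), featurized, standardized
# with the stored calibration scaler, projected onto the stored PCA basis
# and decoded to a pleasure probability; window noise metrics are z-scored
# against stored calibration statistics. The song-mean decoded probability
# (noise excluded) is rescaled to VAS units via
#   y' = (VAS_max - VAS_min) * ybar + VAS_min,
# standardized with the calibration VAS mean/SD, appended as a training
# point, the acoustic model is refit (10-fold CV) and the library re-ranked
# before the next song is drawn.

#' Reference statistics for real-time noise flagging
#'
#' Means/SDs of the per-window noise metrics on the calibration recordings,
#' stored so that streaming windows can be z-scored without drifting
#' statistics. For streaming use the metrics must come from calibration data
#' processed the real-time way (causal filter, no artifact-component
#' removal) so that the amplitude scales match; see
#' [realtime_noise_reference()].
#'
#' @param metrics a [compute_noise_metrics()] result from the calibration
#'   session.
#' @return list of per-channel metric means and SDs.
#' @export
noise_reference <- function(metrics) {
  stopifnot(inherits(metrics, "noise_metrics"))
  raw <- metrics$raw
  mets <- dimnames(raw)[[3]]
  list(mean = apply(raw, c(2, 3), mean),
       sd = apply(raw, c(2, 3), stats::sd),
       metrics = mets, shape = metrics$shape, rms_source = metrics$rms_source)
}

#' Noise reference from calibration recordings, processed the real-time way
#'
#' Causally filters each calibration recording (no artifact-component
#' removal, matching the streaming path), epochs it, and summarizes the
#' per-window noise metrics into the stored reference used by
#' [decode_stream()].
#'
#' @param recordings list of raw calibration [eeg_recording()]s.
#' @param cfg a [run_config()].
#' @return a [noise_reference()] list.
#' @export
realtime_noise_reference <- function(recordings, cfg = run_config()) {
  pooled <- list(epochs = list(), times = NULL, fs = cfg$fs)
  for (rec in recordings) {
    filt <- bandpass_filter(rec, cfg$band[1], cfg$band[2], cfg$filter_order,
                            mode = "realtime")
    eps <- epoch_signal(filt, cfg$epoch_len, cfg$overlap)
    pooled$epochs <- c(pooled$epochs, eps$epochs)
  }
  nm <- compute_noise_metrics(pooled, cfg$feature_band, cfg$bin,
                              shape = cfg$shape_stat,
                              rms_source = cfg$rms_source)
  noise_reference(nm)
}

window_noise_z <- function(epoch, fs, ref, feature_band, bin) {
  shape_fn <- if (ref$shape == "skewness") sample_skewness else sample_kurtosis
  centers <- seq(feature_band[1], feature_band[2], by = bin)
  z <- numeric(length(ref$metrics))
  names(z) <- ref$metrics
  for (m in ref$metrics) {
    vals <- vapply(1:2, function(ch) {
      x <- epoch[ch, ]
      v <- switch(m,
                  rms = if (ref$rms_source == "bandpower") {
                    p <- welch_psd(x, fs)
                    sqrt(sum(bin_psd(p$freq, p$psd, centers, bin)))
                  } else sqrt(mean(x^2)),
                  max_gradient = max(abs(diff(x))),
                  shape = shape_fn(x))
      s <- ref$sd[ch, m]
      if (!is.finite(s) || s == 0) 0 else (v - ref$mean[ch, m]) / s
    }, numeric(1))
    z[m] <- mean(vals)
  }
  z
}

#' Decode a pleasure-probability trace from a streaming recording
#'
#' One output per second from t = 4 s (a 90-s song gives 87 values): the
#' trailing 4-s window of the causally filtered stream is featurized,
#' standardized with the model's stored feature scaler, projected to PC
#' scores and decoded. Artifact-component removal is omitted (real-time
#' constraint); windows are flagged against stored calibration noise
#' statistics instead.
#'
#' @param recording an [eeg_recording()] (the stream).
#' @param model2 a fitted [fit_eeg_classifier()] with stored `pca_basis`,
#'   `pc_scaler` and `feature_scaler`.
#' @param noise_ref a [noise_reference()] from the calibration phase.
#' @param cfg a [run_config()].
#' @return object of class `"decoded_trace"`: `times` (s), `raw_probs`,
#'   `flags`, `smoothed`.
#' @export
decode_stream <- function(recording, model2, noise_ref, cfg = run_config()) {
  stopifnot(inherits(model2, "eeg_classifier"))
  if (is.null(model2$pca_basis) || is.null(model2$feature_scaler)) {
    stop("model2 must carry pca_basis and feature_scaler for streaming",
         call. = FALSE)
  }
  dur <- recording_duration(recording)
  if (dur < cfg$epoch_len) {
    return(structure(list(times = numeric(0), raw_probs = numeric(0),
                          flags = logical(0), smoothed = numeric(0)),
                     class = "decoded_trace"))
  }
  filt <- bandpass_filter(recording, cfg$band[1], cfg$band[2],
                          cfg$filter_order, mode = "realtime")
  fs <- recording$fs
  n_win <- as.integer(cfg$epoch_len * fs)
  times <- seq(cfg$epoch_len, floor(dur), by = 1)
  raw <- numeric(length(times))
  flags <- logical(length(times))
  basis <- as.matrix(model2$pca_basis)
  for (i in seq_along(times)) {
    i1 <- as.integer(times[i] * fs)
    ep <- filt$samples[, (i1 - n_win + 1L):i1, drop = FALSE]
    feats <- compute_psd_features(ep, fs, cfg$feature_band, cfg$bin,
                                  epoch_index = i)
    std <- apply_feature_scaler(model2$feature_scaler, feats)
    pcs <- (std - model2$pca_center) %*% basis
    pcs <- (pcs - model2$pc_scaler$mean) / model2$pc_scaler$sd
    raw[i] <- decode_probability(model2, pcs)
    z <- window_noise_z(ep, fs, noise_ref, cfg$feature_band, cfg$bin)
    flags[i] <- any(z > cfg$noise_z)
  }
  structure(list(times = times, raw_probs = raw, flags = flags,
                 smoothed = smooth_decoded(raw, flags, cfg$smooth_k)),
            class = "decoded_trace")
}

#' Moving average of decoded values, skipping noise flags
#'
#' At each second: the mean of the latest `k` non-flagged raw values if at
#' least `k` exist so far, otherwise the mean of all non-flagged values so
#' far; `NA` until the first non-flagged value.
#'
#' @param raw_probs raw decoded values.
#' @param flags logical noise flags aligned with `raw_probs`.
#' @param k smoothing span (default 5).
#' @return numeric vector aligned with `raw_probs`.
#' @export
smooth_decoded <- function(raw_probs, flags = rep(FALSE, length(raw_probs)),
                           k = 5) {
  stopifnot(length(raw_probs) == length(flags))
  out <- rep(NA_real_, length(raw_probs))
  good <- numeric(0)
  for (i in seq_along(raw_probs)) {
    if (!flags[i]) good <- c(good, raw_probs[i])
    if (length(good)) {
      out[i] <- if (length(good) >= k) {
        mean(utils::tail(good, k))
      } else mean(good)
    }
  }
  out
}

#' Song-level decoded pleasure
#' @param trace a [decode_stream()] trace.
#' @return mean of the non-flagged raw decoded values over the song.
#' @export
song_level_pleasure <- function(trace) {
  stopifnot(inherits(trace, "decoded_trace"))
  good <- !trace$flags
  if (!any(good)) {
    stop("all decoded seconds were flagged as noise: no usable signal",
         call. = FALSE)
  }
  mean(trace$raw_probs[good])
}

#' Rescale a decoded probability to VAS units
#'
#' Exact affine map `y' = (vas_max - vas_min) * ybar + vas_min`.
#'
#' @param ybar mean decoded probability in `[0, 1]`.
#' @param vas_min,vas_max the participant's extreme calibration VAS ratings.
#' @return `y'` in VAS units.
#' @export
rescale_to_vas <- function(ybar, vas_min, vas_max) {
  if (vas_max <= vas_min) {
    stop("degenerate calibration: vas_max must exceed vas_min", call. = FALSE)
  }
  stopifnot(ybar >= 0, ybar <= 1)
  (vas_max - vas_min) * ybar + vas_min
}

#' Standardize a VAS-scale value with the calibration ratings
#' @param y_prime VAS-scale value.
#' @param scaler a [build_calibration_matrix()] scaler (uses `vas_mean`,
#'   `vas_sd`).
#' @return standardized value on the calibration z scale.
#' @export
standardize_vas <- function(y_prime, scaler) {
  (y_prime - scaler$vas_mean) / scaler$vas_sd
}

#' Retrain the acoustic model with decoded playlist points
#'
#' Refits on the six calibration rows plus the completed playlist songs of
#' the current playlist (accumulate mode, default) or plus only the latest
#' point (single mode), with 10-fold (capped at the row count) CV.
#'
#' @param calib the [build_calibration_matrix()] result.
#' @param new_X matrix of playlist-song features on the calibration mask
#'   (rows in play order).
#' @param new_y standardized decoded pleasure values, one per row of `new_X`.
#' @param cv_folds CV folds (default 10).
#' @param seed RNG seed.
#' @param mode `"accumulate"` or `"single"`.
#' @return a `pleasure_regressor`.
#' @export
retrain_model1 <- function(calib, new_X, new_y, cv_folds = 10, seed = 1L,
                           mode = c("accumulate", "single")) {
  mode <- match.arg(mode)
  if (is.null(dim(new_X))) new_X <- matrix(new_X, nrow = 1)
  if (ncol(new_X) != ncol(calib$X)) {
    stop("playlist-song features do not match the calibration mask",
         call. = FALSE)
  }
  stopifnot(nrow(new_X) == length(new_y))
  if (mode == "single" && nrow(new_X) > 1) {
    new_X <- new_X[nrow(new_X), , drop = FALSE]
    new_y <- utils::tail(new_y, 1)
  }
  X <- rbind(calib$X, new_X)
  y <- c(calib$y, new_y)
  folds <- min(cv_folds, nrow(X))
  fit_pleasure_regressor(X, y, cv_folds = folds, seed = seed)
}

#' Run one closed-loop (or open-loop) playlist session
#'
#' Simulates a participant listening to one 7-song playlist. For the EEG
#' conditions, after each song the decoded pleasure is summarized, rescaled
#' to VAS, standardized, appended to the training set, the acoustic model is
#' refit and the library re-ranked before the next song is drawn from the
#' narrow window. NoEEG conditions play their pre-drawn plan and never
#' retrain. Songs whose decoded seconds are all flagged are skipped from
#' retraining (logged) and the session continues.
#'
#' @param design a [generate_participant()] design.
#' @param condition playlist condition.
#' @param model1 initial fitted acoustic model.
#' @param model2 fitted EEG classifier (with scaler/PCA for streaming).
#' @param calib the calibration matrix/scaler list.
#' @param ranking initial `ranked_library`.
#' @param lib_features standardized clipped candidate features (for
#'   re-ranking and retraining rows).
#' @param self_features the three self-selected songs' features.
#' @param library,truth the synthetic library and ground truth (EEG states
#'   during playback are simulated from the participant's true pleasure).
#' @param noise_ref a [noise_reference()].
#' @param seed RNG seed.
#' @param cfg a [run_config()].
#' @param artifact_rate artifact bursts per minute in the simulated streams.
#' @return object of class `"session_result"`: per-slot `songs`, `traces`,
#'   `decoded_means`, `baseline_corrected`, `retrain_events`, `skipped`,
#'   `log` (a [session_log()]), `condition`.
#' @export
run_session <- function(design, condition, model1, model2, calib, ranking,
                        lib_features, self_features, library, truth,
                        noise_ref, seed = 1L, cfg = run_config(),
                        artifact_rate = 0) {
  condition <- match.arg(condition, PLAYLIST_CONDITIONS)
  plan <- build_playlist_plan(condition, ranking, seed, cfg)
  eeg_update <- plan$deferred
  n_slots <- cfg$playlist_len
  songs <- plan$slots
  traces <- vector("list", n_slots)
  decoded_means <- rep(NA_real_, n_slots)
  retrain_events <- list()
  skipped <- character(0)
  new_X <- NULL; new_y <- numeric(0)
  model <- model1
  rank_now <- ranking
  records <- vector("list", n_slots)
  own_pleasure <- function(id) {
    library$true_pleasure[match(id, library$song_ids), design$participant]
  }
  base_seed <- (seed %% 1000003L) * 1000L
  for (s in seq_len(n_slots)) {
    if (is.na(songs[s])) {
      songs[s] <- select_song(rank_now, plan$windows[[s]],
                              songs[!is.na(songs)],
                              seed = base_seed + 31L * s)
    }
    id <- songs[s]
    pl <- own_pleasure(id)
    set.seed(base_seed + 31L * s + 1L)
    state <- if (stats::runif(1) < stats::plogis((pl - 57.1) / 8)) "high" else "low"
    stream <- generate_eeg(state, cfg$song_len, truth,
                           artifact_rate = artifact_rate,
                           seed = base_seed + 31L * s + 2L)
    trace <- decode_stream(stream, model2, noise_ref, cfg)
    traces[[s]] <- trace
    ybar <- tryCatch(song_level_pleasure(trace), error = function(e) NA_real_)
    decoded_means[s] <- ybar
    # simulated chill presses for reporting
    set.seed(base_seed + 31L * s + 3L)
    n_chill <- stats::rpois(1, chill_rate(pl))
    records[[s]] <- list(song_id = id, condition = condition,
                         onset = (s - 1) * cfg$song_len,
                         duration = cfg$song_len,
                         chill_press_times = sort(stats::runif(n_chill, 0,
                                                               cfg$song_len)),
                         vas_ratings = list())
    if (eeg_update && s < n_slots) {
      if (is.na(ybar)) {
        skipped <- c(skipped, id)   # model unchanged, event logged
      } else {
        vmin <- min(calib$scaler$ratings); vmax <- max(calib$scaler$ratings)
        y_prime <- rescale_to_vas(ybar, vmin, vmax)
        y_std <- standardize_vas(y_prime, calib$scaler)
        xi <- lib_features[match(id, rownames(lib_features)), , drop = FALSE]
        if (cfg$retrain_mode == "single") {
          new_X <- xi; new_y <- y_std
        } else {
          new_X <- rbind(new_X, xi); new_y <- c(new_y, y_std)
        }
        model <- retrain_model1(calib, new_X, new_y,
                                cv_folds = cfg$cv_model1_retrain,
                                seed = base_seed + 31L * s + 4L,
                                mode = cfg$retrain_mode)
        rank_now <- rank_candidates(model, lib_features, self_features)
        retrain_events[[length(retrain_events) + 1L]] <-
          list(after_slot = s, song_id = id, ybar = ybar,
               y_prime = y_prime, y_std = y_std,
               n_rows = model$fit_rows)
      }
    }
  }
  log <- session_log(paste0("sim_", design$participant), "playlist", records)
  structure(list(condition = condition, songs = songs, traces = traces,
                 decoded_means = decoded_means,
                 baseline_corrected = decoded_means - decoded_means[1],
                 retrain_events = retrain_events, skipped = skipped,
                 log = log, final_model = model, seed = seed),
            class = "session_result")
}
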