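#' Calibrate both models for one (synthetic) participant
#'
#' Convenience wrapper over the full calibration phase: simulate the six-song
#' listening session, preprocess the EEG into labeled spectral epochs, build
#' the acoustic calibration matrix, and fit the acoustic pleasure model
#' (Model 1) and the EEG pleasure-state classifier (Model 2).
#'
#' @param design a [generate_participant()] design.
#' @param library,truth from [generate_song_library()].
#' @param cfg a [run_config()].
#' @param seed RNG seed.
#' @param artifact_rate artifact bursts/minute in the simulated calibration
#'   EEG.
#' @param profiles optional precomputed library profiles
#'   ([profile_library()]); computed on demand otherwise.
#' @return list with `model1`, `model2`, `calib`, `featset`, `noise_ref`,
#'   `bundle` (the simulated recordings + log), `profiles`, `lib_features`,
#'   `self_features`, `ranking`.
#' @export
calibrate_participant <- function(design, library, truth, cfg = run_config(),
                                  seed = 1L, artifact_rate = 0,
                                  profiles = NULL) {
  bundle <- simulate_listening(design, library, truth, seed = seed,
                               song_len = cfg$song_len,
                               artifact_rate = artifact_rate)
  labels <- rep(c(TRUE, FALSE), each = 3)
  featset <- preprocess_session(bundle$recordings, labels, cfg,
                                remove_component = TRUE, seed = seed)
  if (is.null(profiles)) {
    profiles <- profile_library(library, mode = cfg$aggregate_mode,
                                excerpt_len = cfg$song_len)
  }
  cal_ids <- c(design$self_ids, design$other_ids)
  calib <- build_calibration_matrix(profiles[cal_ids],
                                    unname(design$ratings[cal_ids]))
  model1 <- fit_pleasure_regressor(calib$X, calib$y,
                                   cv_folds = cfg$cv_model1_initial,
                                   seed = seed)
  ts <- build_training_set(featset, cfg$max_pcs, seed)
  model2 <- fit_eeg_classifier(ts$scores, ts$labels, cfg$cv_model2,
                               split = 0.9, seed = seed, pca = ts,
                               feature_scaler = featset$scaler)
  noise_ref <- realtime_noise_reference(bundle$recordings, cfg)
  lib_features <- normalize_and_clip_library(profiles, scaler = NULL,
                                             clip_sd = cfg$clip_sd,
                                             mask = calib$scaler$mask)
  self_features <- apply_calibration_scaler(profiles[design$self_ids],
                                            calib$scaler)
  ranking <- rank_candidates(model1, lib_features, self_features)
  list(model1 = model1, model2 = model2, calib = calib, featset = featset,
       noise_ref = noise_ref, bundle = bundle, profiles = profiles,
       lib_features = lib_features, self_features = self_features,
       ranking = ranking)
}
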