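test_that("smoothing follows the fewer-than-five / latest-five rule", {
  expect_equal(smooth_decoded(rep(0.7, 8)), rep(0.7, 8))
  expect_equal(smooth_decoded(c(0.2, 0.4, 0.6))[3], 0.4)
  # 10 s at 0.9 with seconds 6-10 flagged: smoothed(10) uses seconds 1-5
  raw <- rep(0.9, 10)
  flags <- c(rep(FALSE, 5), rep(TRUE, 5))
  sm <- smooth_decoded(raw, flags, k = 5)
  expect_equal(sm[10], 0.9)
  # hand-enumerated mixed case
  raw2 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  fl2 <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  sm2 <- smooth_decoded(raw2, fl2, k = 5)
  expect_equal(sm2[1], 0.1)
  expect_equal(sm2[2], 0.1)                       # flagged second keeps history
  expect_equal(sm2[4], mean(c(0.1, 0.3, 0.4)))    # fewer than five so far
  expect_equal(sm2[7], mean(c(0.3, 0.4, 0.5, 0.6, 0.7)))  # latest five clean
  # all-flagged prefix is undefined
  sm3 <- smooth_decoded(c(0.5, 0.6), c(TRUE, FALSE))
  expect_true(is.na(sm3[1]))
  expect_equal(sm3[2], 0.6)
})

test_that("song-level pleasure averages non-flagged seconds only", {
  tr <- structure(list(times = 1:10, raw_probs = rep(c(0.2, 0.8), 5),
                       flags = rep(FALSE, 10), smoothed = NULL),
                  class = "decoded_trace")
  expect_equal(song_level_pleasure(tr), 0.5)
  tr$flags <- rep(c(TRUE, FALSE), 5)
  expect_equal(song_level_pleasure(tr), 0.8)
  tr$flags <- rep(TRUE, 10)
  expect_error(song_level_pleasure(tr), "flagged")
})

test_that("VAS rescaling is the exact affine map with exact inverse", {
  expect_identical(rescale_to_vas(0, 30, 90), 30)
  expect_identical(rescale_to_vas(1, 30, 90), 90)
  expect_identical(rescale_to_vas(0.5, 30, 90), 60)
  for (ybar in seq(0, 1, by = 0.125)) {
    y <- rescale_to_vas(ybar, 23.5, 91.25)
    expect_equal((y - 23.5) / (91.25 - 23.5), ybar, tolerance = 1e-15)
  }
  expect_error(rescale_to_vas(0.5, 50, 50), "degenerate")
  scaler <- list(vas_mean = 70, vas_sd = 10)
  expect_equal(standardize_vas(80, scaler), 1)
})

test_that("decoding cadence: one value per second from t = 4 s", {
  w <- shared_world()
  st <- generate_eeg("high", 30, w$truth, seed = 77)
  tr <- decode_stream(st, w$cal$model2, w$cal$noise_ref, w$cfg)
  expect_equal(tr$times, 4:30)
  expect_length(tr$raw_probs, 27)
  expect_true(all(tr$raw_probs > 0 & tr$raw_probs < 1))
  expect_length(tr$smoothed, 27)
  # stream shorter than one window: empty trace
  short <- generate_eeg("high", 4, w$truth, seed = 78)
  short$samples <- short$samples[, 1:1200]
  expect_length(decode_stream(short, w$cal$model2, w$cal$noise_ref,
                              w$cfg)$times, 0)
})

test_that("high and low pleasure states decode apart; gamma = 0 is constant", {
  w <- shared_world()
  hi <- decode_stream(generate_eeg("high", 30, w$truth, seed = 80),
                      w$cal$model2, w$cal$noise_ref, w$cfg)
  lo <- decode_stream(generate_eeg("low", 30, w$truth, seed = 81),
                      w$cal$model2, w$cal$noise_ref, w$cfg)
  expect_gt(mean(hi$raw_probs), mean(lo$raw_probs) + 0.2)
  m0 <- w$cal$model2
  m0$gamma <- rep(0, length(m0$gamma))
  tr0 <- decode_stream(generate_eeg("high", 10, w$truth, seed = 82),
                       m0, w$cal$noise_ref, w$cfg)
  expect_equal(tr0$raw_probs, rep(plogis(m0$gamma0), 7))
})

test_that("online decoding tracks the offline pipeline", {
  w <- shared_world()
  # one recording per state; offline epochs [0,4),[2,6),... match the online
  # trailing windows at even seconds
  probs_off <- c(); probs_on <- c()
  for (st in c("high", "low")) {
    rec <- generate_eeg(st, 30, w$truth, seed = if (st == "high") 90 else 91)
    tr <- decode_stream(rec, w$cal$model2, w$cal$noise_ref, w$cfg)
    on_t <- seq(4, 30, by = 2)
    probs_on <- c(probs_on, tr$raw_probs[match(on_t, tr$times)])
    filt <- bandpass_filter(rec, mode = "offline")
    cln <- remove_artifact_component(filt, seed = 1)
    eps <- epoch_signal(cln, 4, 0.5)
    raw <- psd_feature_matrix(eps)
    std <- apply_feature_scaler(w$cal$model2$feature_scaler, raw)
    pcs <- sweep(std, 2, w$cal$model2$pca_center) %*% w$cal$model2$pca_basis
    pcs <- sweep(sweep(pcs, 2, w$cal$model2$pc_scaler$mean), 2,
                 w$cal$model2$pc_scaler$sd, "/")
    probs_off <- c(probs_off, decode_probability(w$cal$model2, pcs))
  }
  expect_gt(cor(probs_on, probs_off), 0.95)
})

test_that("retraining appends rows and honours its contracts", {
  w <- shared_world()
  calib <- w$cal$calib
  xi <- calib$X[2, , drop = FALSE]
  # after the first playlist song the model is fitted on 7 rows
  m7 <- retrain_model1(calib, xi, 0.5, cv_folds = 10, seed = 1)
  expect_equal(m7$fit_rows, 7)
  # duplicate of a calibration row at the same fixed lambda leaves the
  # solution essentially unchanged
  lam <- 0.5
  base <- fit_pleasure_regressor_fixed(calib$X, calib$y, lam)
  dup <- fit_pleasure_regressor_fixed(rbind(calib$X, calib$X[2, ]),
                                      c(calib$y, calib$y[2]), lam)
  expect_equal(predict_pleasure(dup, calib$X), predict_pleasure(base, calib$X),
               tolerance = 0.1)
  # single mode keeps only the newest point
  m_single <- retrain_model1(calib, rbind(xi, xi), c(0.1, 0.9),
                             cv_folds = 10, seed = 1, mode = "single")
  expect_equal(m_single$fit_rows, 7)
  expect_error(retrain_model1(calib, xi[, 1:3, drop = FALSE], 0.5), "mask")
})

test_that("closed-loop sessions retrain per contract and log everything", {
  w <- shared_world()
  res_no <- run_session(w$design, "DimNoEEG", w$cal$model1, w$cal$model2,
                        w$cal$calib, w$cal$ranking, w$cal$lib_features,
                        w$cal$self_features, w$library, w$truth,
                        w$cal$noise_ref, seed = 21, cfg = w$cfg)
  expect_equal(length(res_no$retrain_events), 0)
  expect_length(res_no$songs, 7)
  expect_equal(anyDuplicated(res_no$songs), 0)

  res_eeg <- run_session(w$design, "AugEEG", w$cal$model1, w$cal$model2,
                         w$cal$calib, w$cal$ranking, w$cal$lib_features,
                         w$cal$self_features, w$library, w$truth,
                         w$cal$noise_ref, seed = 22, cfg = w$cfg)
  expect_equal(length(res_eeg$retrain_events) + length(res_eeg$skipped), 6)
  expect_equal(res_eeg$baseline_corrected[1], 0)
  expect_length(res_eeg$log$song_records, 7)

  cs <- condition_summary(res_eeg)
  expect_equal(cs$condition, "AugEEG")
  expect_gte(cs$n_chills, 0)
  tbl <- report_table(list(res_no, res_eeg))
  expect_equal(nrow(tbl), 14)
  expect_equal(tbl$baseline_corrected[tbl$slot == 1], c(0, 0))
})

test_that("report helpers count chills and check inclusion as specified", {
  recs <- lapply(1:7, function(i) {
    list(song_id = paste0("s", i), condition = "AugEEG", onset = (i - 1) * 90,
         duration = 90,
         chill_press_times = if (i == 1) c(1, 2) else if (i == 4) c(5, 6, 7)
                             else numeric(0),
         vas_ratings = list())
  })
  log <- session_log("p", "playlist", recs)
  expect_equal(count_chills(log), 3)    # baseline presses excluded
  recs2 <- lapply(recs, function(r) { r$chill_press_times <- numeric(0); r })
  expect_equal(count_chills(session_log("p", "playlist", recs2)), 0)
  recs3 <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]; r$chill_press_times <- if (i >= 2) 1 else numeric(0); r
  })
  expect_equal(count_chills(session_log("p", "playlist", recs3)), 6)

  cal_rec <- function(id, cond, n_chill, vas) {
    list(song_id = id, condition = cond, onset = 0, duration = 90,
         chill_press_times = seq_len(n_chill) * 2,
         vas_ratings = list(pleasure = vas))
  }
  ok <- session_log("p", "recording", c(
    lapply(1:3, function(i) cal_rec(paste0("a", i), "self", 7, 86)),
    lapply(1:3, function(i) cal_rec(paste0("b", i), "other", 2, 57))))
  expect_true(check_inclusion(ok)$included)
  # self 5 vs other 3 chills: a difference of 2 fails the >= 3 criterion
  few <- session_log("p", "recording", c(
    list(cal_rec("a1", "self", 5, 86)),
    lapply(2:3, function(i) cal_rec(paste0("a", i), "self", 0, 86)),
    lapply(1:3, function(i) cal_rec(paste0("b", i), "other", 1, 57))))
  ci <- check_inclusion(few)
  expect_false(ci$included)
  expect_true("chill criterion" %in% ci$reasons)
  flat <- session_log("p", "recording", c(
    lapply(1:3, function(i) cal_rec(paste0("a", i), "self", 7, 70)),
    lapply(1:3, function(i) cal_rec(paste0("b", i), "other", 2, 70))))
  expect_equal(check_inclusion(flat)$reasons, "pleasure criterion")

  expect_equal(baseline_correct(c(0.5, 0.7, 0.6)), c(0, 0.2, 0.1))
  expect_equal(baseline_correct(rep(0.4, 5)), rep(0, 5))
  expect_error(baseline_correct(c(NA, 0.5)), "baseline")
})
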