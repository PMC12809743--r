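make_rec <- function(duration, fs = 600, seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  eeg_recording(matrix(rnorm(2 * n), nrow = 2), fs = fs)
}

test_that("epoching yields the enumerated window counts", {
  # 90 s, 4 s windows, 50% overlap -> floor((90 - 4)/2) + 1 = 44
  expect_equal(length(epoch_signal(make_rec(90), 4, 0.5)$epochs), 44)
  expect_equal(length(epoch_signal(make_rec(4), 4, 0.5)$epochs), 1)
  expect_equal(length(epoch_signal(make_rec(3.9), 4, 0.5)$epochs), 0)
  eps <- epoch_signal(make_rec(10), 4, 0.5)
  expect_equal(eps$times$start, c(0, 2, 4, 6))
  expect_equal(eps$times$end, c(4, 6, 8, 10))
  expect_error(epoch_signal(make_rec(10), 4, 1), "overlap")
})

test_that("spectral features have the documented geometry", {
  ep <- toy_epoch()
  v <- compute_psd_features(ep, 600)
  expect_length(v, 219)
  expect_equal(length(seq(4, 40, by = 0.5)), 73)
  expect_equal(sum(startsWith(names(v), "left_")), 73)
  expect_equal(names(v)[74], "right_4")
  bad <- ep; bad[1, 5] <- NA
  expect_error(compute_psd_features(bad, 600, epoch_index = 7), "7")
})

test_that("a shared pure tone peaks at its bin and zeroes the difference", {
  fs <- 600
  t <- (0:(4 * fs - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  ep <- rbind(tone, tone)
  v <- compute_psd_features(ep, fs)
  left <- v[1:73]; right <- v[74:146]; diff_ <- v[147:219]
  centers <- seq(4, 40, by = 0.5)
  expect_equal(centers[which.max(left)], 10)
  expect_equal(centers[which.max(right)], 10)
  expect_lt(max(diff_), 1e-20)
})

test_that("PSD binning conserves in-band power against a periodogram oracle", {
  fs <- 600
  set.seed(11)
  # average over many epochs so both estimators approach the flat truth
  n_ep <- 200
  tot_bins <- 0; tot_direct <- 0
  for (i in 1:n_ep) {
    x <- rnorm(4 * fs)
    v <- compute_psd_features(rbind(x, 0), fs)
    tot_bins <- tot_bins + sum(v[1:73])
    # direct periodogram integral over [3.75, 40.25)
    sp <- Mod(fft(x - mean(x))[1:(2 * fs + 1)])^2 / (fs * length(x))
    sp[2:(2 * fs)] <- 2 * sp[2:(2 * fs)]
    f <- (0:(2 * fs)) * fs / length(x)
    sel <- f >= 3.75 & f < 40.25
    tot_direct <- tot_direct + sum(sp[sel]) * (f[2] - f[1])
  }
  expect_equal(tot_bins / n_ep, tot_direct / n_ep, tolerance = 0.01)
})

test_that("noise metrics flag a planted spike via the gradient metric", {
  fs <- 600
  set.seed(3)
  recs <- lapply(1:50, function(i) matrix(rnorm(2 * 4 * fs), nrow = 2))
  recs[[17]][1, 1000:1010] <- recs[[17]][1, 1000:1010] + 50
  eps <- list(epochs = recs, fs = fs,
              times = data.frame(start = seq(0, by = 4, length.out = 50),
                                 end = seq(4, by = 4, length.out = 50)))
  nm <- compute_noise_metrics(eps)
  flags <- flag_noisy_epochs(nm, 2.5)
  expect_true(flags[17])
  attrib <- attr(flags, "attribution")
  expect_true(attrib[17, "max_gradient"])
  # direct z computation confirms the threshold crossing
  z <- nm$z[, "max_gradient"]
  expect_gt(z[17], 2.5)
  expect_lt(mean(flags), 0.2)
  # threshold = Inf -> nothing flagged
  expect_false(any(flag_noisy_epochs(nm, Inf)))
})

test_that("statistically identical epochs yield no flags at z = 2.5 rarely", {
  # clean Gaussian epochs: expected flag fraction is the upper-tail mass of
  # the (channel-averaged) metric z-scores, < 5%
  fs <- 600
  set.seed(4)
  recs <- lapply(1:80, function(i) matrix(rnorm(2 * 4 * fs), nrow = 2))
  eps <- list(epochs = recs, fs = fs, times = NULL)
  flags <- flag_noisy_epochs(compute_noise_metrics(eps), 2.5)
  expect_lt(mean(flags), 0.05)
})

test_that("standardization uses only clean epochs and stores its scaler", {
  set.seed(6)
  raw <- matrix(rexp(40 * 10), 40, 10)
  flags <- rep(FALSE, 40); flags[c(3, 9)] <- TRUE
  fs <- standardize_features(raw, flags)
  clean <- fs$features[!flags, ]
  expect_equal(unname(colMeans(clean)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(clean, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # flagged epochs transformed with the same scaler
  expect_equal(unname(fs$features[3, ]),
               unname((raw[3, ] - fs$scaler$mean) / fs$scaler$sd))
  # reusing the scaler on data equal to the stored means gives zeros
  z <- apply_feature_scaler(fs$scaler, matrix(fs$scaler$mean, nrow = 1))
  expect_equal(unname(as.numeric(z)), rep(0, 10))
  # constant feature: clamped, not an error
  raw2 <- cbind(raw, 5)
  expect_message(fs2 <- standardize_features(raw2, flags), "clamped")
  expect_true(fs2$scaler$clamped[11])
})

test_that("artifact-component removal recovers the planted clean source", {
  set.seed(8)
  n <- 6000
  # independent non-Gaussian sources with very different scales, identity mix
  a <- 10 * rt(n, df = 3)   # RMS ~ 17, heavy-tailed "artifact"
  b <- 1 * tanh(rnorm(n)) * sqrt(2)  # RMS ~ 1
  rec <- eeg_recording(rbind(a + 0.05 * b, b + 0.05 * a), fs = 600)
  out <- remove_artifact_component(rec)
  sep <- attr(out, "separation")
  expect_equal(sort(sep$component_rms, decreasing = TRUE)[1],
               max(sep$component_rms))
  # residual power of the artifact source in the cleaned channels < 1%
  for (ch in 1:2) {
    res <- out$samples[ch, ]
    beta_a <- sum(res * a) / sum(a * a)
    expect_lt(var(beta_a * a) / var(rec$samples[ch, ]), 0.01)
  }
  # the quiet source survives in at least one channel
  cor_b <- max(abs(cor(out$samples[1, ], b)), abs(cor(out$samples[2, ], b)))
  expect_gt(cor_b, 0.9)
})

test_that("degenerate and deterministic separation behaviour", {
  t <- seq(0, 5, by = 1 / 600)
  tone <- sin(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(tone, tone), fs = 600)
  expect_error(remove_artifact_component(rec), "degenerate")
  rec2 <- make_rec(5, seed = 10)
  o1 <- remove_artifact_component(rec2, seed = 3)
  o2 <- remove_artifact_component(rec2, seed = 3)
  expect_identical(o1$samples, o2$samples)
})

test_that("flags on artifact-laden synthetic EEG cover the planted bursts", {
  # With 4-s/50% epochs a one-sided z-score can reach at most
  # sqrt((1 - f)/f) where f is the contaminated-epoch fraction, so the 2.5
  # threshold can only fire when f < ~0.14; 1 burst/min keeps f ~ 0.07.
  gen <- generate_song_library(n_songs = 10, n_frames = 4, sparsity = 0,
                               seed = 2, eeg_effect = 0)
  rec <- generate_eeg("low", 360, gen$truth, artifact_rate = 1, seed = 21)
  arts <- attr(rec, "artifacts")
  expect_gt(nrow(arts), 2)
  filt <- bandpass_filter(rec)
  eps <- epoch_signal(filt, 4, 0.5)
  flags <- flag_noisy_epochs(compute_noise_metrics(eps), 2.5)
  overlaps <- vapply(seq_len(nrow(arts)), function(i) {
    hit <- eps$times$start < arts$end[i] & eps$times$end > arts$start[i]
    any(flags[hit])
  }, logical(1))
  expect_gt(mean(overlaps), 0.8)
})
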