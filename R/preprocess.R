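# Raw two-channel in-ear EEG -> flagged, standardized spectral feature epochs.
#
# Pipeline: 3-40 Hz band-pass (zero-phase offline, causal in real time) ->
# two-component blind separation with removal of the larger-RMS component
# (offline only) -> 4-s sliding windows with 50% overlap -> Welch PSD binned
# at 0.5 Hz from 4 to 40 Hz for left, right and their difference (73 x 3 =
# 219 features) -> noise flags from z-scored RMS / max-gradient / shape
# metrics at a 2.5 threshold -> per-feature standardization over clean epochs.

#' Band-pass filter a recording
#'
#' @param recording an [eeg_recording()].
#' @param low,high band edges in Hz (default 3--40).
#' @param order Butterworth prototype order (default 4).
#' @param mode `"offline"` applies the filter forward-backward (zero phase);
#'   `"realtime"` applies it causally, as in live decoding.
#' @return a filtered `eeg_recording`; the mode is recorded in
#'   `attr(, "filter_mode")`.
#' @export
bandpass_filter <- function(recording, low = 3, high = 40, order = 4,
                            mode = c("offline", "realtime")) {
  stopifnot(inherits(recording, "eeg_recording"))
  mode <- match.arg(mode)
  flt <- butter_bandpass(low, high, recording$fs, order)
  out <- recording
  for (i in 1:2) {
    out$samples[i, ] <- apply_filter(recording$samples[i, ], flt,
                                     zero_phase = (mode == "offline"))
  }
  attr(out, "filter_mode") <- mode
  out
}

sample_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

#' Remove the higher-power blind-source component from a 2-channel recording
#'
#' Unmixes the two channels into two maximally non-Gaussian components
#' (whitening followed by a kurtosis-contrast rotation), measures each
#' component's root-mean-square contribution in sensor space, zeroes the
#' larger one (presumed muscle/movement artifact), and remixes. The result is
#' a 2-channel sensor-space recording.
#'
#' @param recording an [eeg_recording()]; channels must not be collinear.
#' @param seed RNG seed (the separation itself is deterministic; the seed
#'   fixes tie-breaking).
#' @return cleaned `eeg_recording`; the removed component index and mixing
#'   matrix are stored in `attr(, "separation")`.
#' @export
remove_artifact_component <- function(recording, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- xc %*% t(xc) / ncol(xc)
  ev <- eigen(cv, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values)) {
    stop("channels are (nearly) identical; blind separation is degenerate. ",
         "Skip component removal for this recording.", call. = FALSE)
  }
  whitener <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  z <- whitener %*% xc
  # one rotation angle fully parameterizes the 2-d orthogonal unmixing;
  # maximize the summed absolute excess kurtosis of the two sources
  contrast <- function(theta) {
    r <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    s <- r %*% z
    abs(sample_kurtosis(s[1, ])) + abs(sample_kurtosis(s[2, ]))
  }
  grid <- seq(0, pi / 2, length.out = 181L)
  vals <- vapply(grid, contrast, numeric(1))
  best <- grid[which.max(vals)]
  opt <- stats::optimize(contrast, lower = max(0, best - 0.02),
                         upper = min(pi / 2, best + 0.02), maximum = TRUE)
  theta <- opt$maximum
  r <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  unmix <- r %*% whitener
  mix <- solve(unmix)
  s <- unmix %*% xc
  # sensor-space RMS of each component's contribution
  rms_c <- vapply(1:2, function(k) {
    contrib <- mix[, k, drop = FALSE] %*% s[k, , drop = FALSE]
    sqrt(mean(contrib^2))
  }, numeric(1))
  drop_k <- which.max(rms_c)
  s[drop_k, ] <- 0
  out <- recording
  out$samples <- (mix %*% s) + mu
  rownames(out$samples) <- recording$channel_names
  attr(out, "separation") <- list(removed = drop_k, mixing = mix,
                                  component_rms = rms_c, theta = theta)
  out
}

#' Slice a recording into sliding-window epochs
#'
#' Half-open windows `[k * hop, k * hop + epoch_len)` with
#' `hop = epoch_len * (1 - overlap)`; a trailing partial window is dropped.
#' 90 s at 4 s / 50% overlap yields 44 epochs.
#'
#' @param recording an [eeg_recording()].
#' @param epoch_len window length in seconds (default 4).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return list with `epochs` (list of 2 x n matrices), `times` (data frame
#'   of start/end seconds) and `fs`.
#' @export
epoch_signal <- function(recording, epoch_len = 4, overlap = 0.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (overlap < 0 || overlap >= 1) {
    stop("overlap must lie in [0, 1)", call. = FALSE)
  }
  fs <- recording$fs
  n_ep <- as.integer(round(epoch_len * fs))
  hop <- epoch_len * (1 - overlap)
  n_hop <- as.integer(round(hop * fs))
  total <- ncol(recording$samples)
  starts <- seq(1L, by = n_hop, length.out = max(0L, (total - n_ep) %/% n_hop + 1L))
  if (total < n_ep) starts <- integer(0)
  epochs <- lapply(starts, function(s0) {
    recording$samples[, s0:(s0 + n_ep - 1L), drop = FALSE]
  })
  times <- data.frame(start = (starts - 1L) / fs,
                      end = (starts - 1L) / fs + epoch_len)
  list(epochs = epochs, times = times, fs = fs)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Welch power spectral density
#'
#' Averaged modified periodograms (Hann window) over `seg_len`-second
#' segments with 50% overlap; one-sided density in units^2/Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in seconds (default 2).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = 2, overlap = 0.5) {
  nseg <- as.integer(round(seg_len * fs))
  if (length(x) < nseg) stop("signal shorter than one Welch segment", call. = FALSE)
  hop <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- hann_window(nseg)
  u <- sum(w^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- stats::fft(seg)[1:(nf + 1L)]
    acc <- acc + (Mod(sp)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (0:nf) * fs / nseg, psd = psd)
}

# integrate a PSD into bins centred at `centers` with width `bin`
bin_psd <- function(freq, psd, centers, bin) {
  df <- freq[2] - freq[1]
  lo <- centers - bin / 2
  hi <- centers + bin / 2
  vapply(seq_along(centers), function(i) {
    sel <- freq >= lo[i] & freq < hi[i]
    sum(psd[sel]) * df
  }, numeric(1))
}

#' Spectral feature vector of one epoch
#'
#' Welch PSD per derivation (left, right, left - right), integrated into
#' `bin`-Hz bins centred 4.0, 4.5, ..., 40.0 Hz (73 bins). Features are raw
#' (unstandardized) band power, concatenated derivation-major:
#' left bins 1--73, right 74--146, difference 147--219.
#'
#' @param epoch 2 x n numeric matrix (one [epoch_signal()] window).
#' @param fs sampling rate (Hz).
#' @param feature_band numeric length-2, bin-centre range in Hz (default 4--40).
#' @param bin bin width in Hz (default 0.5).
#' @param epoch_index optional index used in error messages.
#' @return numeric vector of length `3 * n_bins` (219 for the defaults), with
#'   names like `left_4`, `diff_40`.
#' @export
compute_psd_features <- function(epoch, fs, feature_band = c(4, 40),
                                 bin = 0.5, epoch_index = NA) {
  if (any(is.na(epoch))) {
    stop("epoch ", epoch_index, " contains NaN samples", call. = FALSE)
  }
  centers <- seq(feature_band[1], feature_band[2], by = bin)
  der <- list(left = epoch[1, ], right = epoch[2, ],
              diff = epoch[1, ] - epoch[2, ])
  out <- unlist(lapply(names(der), function(nm) {
    p <- welch_psd(der[[nm]], fs)
    v <- bin_psd(p$freq, p$psd, centers, bin)
    names(v) <- paste0(nm, "_", as.character(centers))
    v
  }))
  out
}

#' Feature matrix over a list of epochs
#' @param epochs result of [epoch_signal()].
#' @inheritParams compute_psd_features
#' @return matrix, epochs x features.
#' @export
psd_feature_matrix <- function(epochs, feature_band = c(4, 40), bin = 0.5) {
  mats <- lapply(seq_along(epochs$epochs), function(i) {
    compute_psd_features(epochs$epochs[[i]], epochs$fs, feature_band, bin,
                         epoch_index = i)
  })
  do.call(rbind, mats)
}

#' Per-epoch noise metrics
#'
#' For each epoch and channel: RMS (square root of summed band power by
#' default, or time-domain RMS), the maximum absolute first difference of the
#' signal, and a shape statistic (skewness by default, kurtosis optionally).
#' Each metric is z-scored across epochs per channel and averaged over the
#' two channels.
#'
#' @param epochs result of [epoch_signal()].
#' @param feature_band,bin spectral range used for the band-power RMS.
#' @param shape `"skewness"` (default) or `"kurtosis"`.
#' @param rms_source `"bandpower"` (default) or `"time"`.
#' @return object of class `"noise_metrics"`: raw per-channel metrics and the
#'   channel-averaged z-composites (`z` matrix, epochs x metrics).
#' @export
compute_noise_metrics <- function(epochs, feature_band = c(4, 40), bin = 0.5,
                                  shape = c("skewness", "kurtosis"),
                                  rms_source = c("bandpower", "time")) {
  shape <- match.arg(shape)
  rms_source <- match.arg(rms_source)
  n <- length(epochs$epochs)
  if (n < 2) stop("need at least 2 epochs to z-score noise metrics", call. = FALSE)
  centers <- seq(feature_band[1], feature_band[2], by = bin)
  shape_fn <- if (shape == "skewness") sample_skewness else sample_kurtosis
  raw <- array(NA_real_, dim = c(n, 2, 3),
               dimnames = list(NULL, c("left", "right"),
                               c("rms", "max_gradient", "shape")))
  for (i in seq_len(n)) {
    ep <- epochs$epochs[[i]]
    for (ch in 1:2) {
      x <- ep[ch, ]
      if (rms_source == "bandpower") {
        p <- welch_psd(x, epochs$fs)
        raw[i, ch, "rms"] <- sqrt(sum(bin_psd(p$freq, p$psd, centers, bin)))
      } else {
        raw[i, ch, "rms"] <- sqrt(mean(x^2))
      }
      raw[i, ch, "max_gradient"] <- max(abs(diff(x)))
      raw[i, ch, "shape"] <- shape_fn(x)
    }
  }
  zmat <- sapply(dimnames(raw)[[3]], function(m) {
    zz <- sapply(1:2, function(ch) {
      v <- raw[, ch, m]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) return(rep(0, n))  # zero variance -> z = 0
      (v - mean(v)) / s
    })
    rowMeans(zz)
  })
  structure(list(raw = raw, z = zmat, shape = shape, rms_source = rms_source),
            class = "noise_metrics")
}

#' Flag noisy epochs
#'
#' An epoch is flagged when ANY channel-averaged metric z-score exceeds the
#' threshold (one-sided).
#'
#' @param metrics a [compute_noise_metrics()] result.
#' @param z_threshold flag threshold (default 2.5).
#' @return logical vector (`TRUE` = noisy) with attribute `"attribution"`, a
#'   logical epochs x metrics matrix saying which metric(s) fired.
#' @export
flag_noisy_epochs <- function(metrics, z_threshold = 2.5) {
  stopifnot(inherits(metrics, "noise_metrics"))
  hits <- metrics$z > z_threshold
  flags <- apply(hits, 1, any)
  attr(flags, "attribution") <- hits
  flags
}

#' Standardize spectral features over clean epochs
#'
#' Per-feature mean/SD are computed on non-flagged epochs only; all epochs
#' (flagged included) are transformed. The scaler is stored for reuse on
#' streaming data. Zero-SD features are kept with the SD clamped to a stored
#' epsilon.
#'
#' @param raw epochs x features matrix from [psd_feature_matrix()].
#' @param flags logical vector from [flag_noisy_epochs()] (default: none).
#' @param labels optional logical per-epoch class labels
#'   (`TRUE` = high pleasure / self-selected).
#' @param epoch_times optional data frame of epoch start/end seconds.
#' @param eps SD clamp for constant features.
#' @return object of class `"epoch_feature_set"` with fields `features`
#'   (standardized), `flags`, `labels`, `epoch_times`, `scaler`.
#' @export
standardize_features <- function(raw, flags = rep(FALSE, nrow(raw)),
                                 labels = NULL, epoch_times = NULL,
                                 eps = 1e-12) {
  raw <- as.matrix(raw)
  keep <- !flags
  if (sum(keep) < 2) {
    stop("need at least 2 non-flagged epochs to standardize", call. = FALSE)
  }
  mu <- colMeans(raw[keep, , drop = FALSE])
  sd_ <- apply(raw[keep, , drop = FALSE], 2, stats::sd)
  clamped <- !is.finite(sd_) | sd_ < eps
  if (any(clamped)) {
    message(sum(clamped), " feature(s) had ~zero SD; clamped to eps")
    sd_[clamped] <- eps
  }
  feats <- sweep(sweep(raw, 2, mu, "-"), 2, sd_, "/")
  scaler <- list(mean = mu, sd = sd_, clamped = clamped, eps = eps)
  structure(list(features = feats, flags = flags, labels = labels,
                 epoch_times = epoch_times, scaler = scaler),
            class = "epoch_feature_set")
}

#' Apply a stored feature scaler to new data
#' @param scaler the `scaler` element of an [standardize_features()] result.
#' @param newdata matrix or vector of raw features.
#' @return standardized matrix.
#' @export
apply_feature_scaler <- function(scaler, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(sweep(newdata, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Full offline preprocessing pipeline
#'
#' filter -> separate (artifact component removal) -> epoch -> PSD features ->
#' noise flags -> standardize. Labels, when given per song via `events`, are
#' assigned to epochs wholly inside a labeled interval.
#'
#' @param recording an [eeg_recording()].
#' @param cfg a [run_config()].
#' @param label optional single logical label applied to all epochs of this
#'   recording (`TRUE` = high-pleasure class).
#' @param remove_component apply blind-source artifact removal (default TRUE,
#'   the offline setting).
#' @param seed RNG seed for the separation step.
#' @return an `epoch_feature_set`.
#' @export
preprocess_recording <- function(recording, cfg = run_config(), label = NULL,
                                 remove_component = TRUE, seed = cfg$seed) {
  rec <- bandpass_filter(recording, cfg$band[1], cfg$band[2],
                         cfg$filter_order, mode = "offline")
  if (remove_component) rec <- remove_artifact_component(rec, seed)
  eps <- epoch_signal(rec, cfg$epoch_len, cfg$overlap)
  raw <- psd_feature_matrix(eps, cfg$feature_band, cfg$bin)
  nm <- compute_noise_metrics(eps, cfg$feature_band, cfg$bin,
                              shape = cfg$shape_stat,
                              rms_source = cfg$rms_source)
  flags <- flag_noisy_epochs(nm, cfg$noise_z)
  labels <- if (!is.null(label)) rep(as.logical(label), nrow(raw)) else NULL
  standardize_features(raw, flags, labels = labels, epoch_times = eps$times)
}

#' Preprocess a whole session of per-song recordings into one labeled set
#'
#' @details Given several recordings (one per song) this epochs and
#' featurizes each, pools the raw features, flags noise across the pool and
#' standardizes once over all non-flagged epochs, which matches the offline
#' modeling procedure (standardization across all clean epochs of a session).
#'
#' @param recordings list of [eeg_recording()] objects.
#' @param labels logical vector, one label per recording.
#' @param cfg a [run_config()].
#' @param remove_component,seed see [preprocess_recording()].
#' @return an `epoch_feature_set` covering all songs.
#' @export
preprocess_session <- function(recordings, labels, cfg = run_config(),
                               remove_component = TRUE, seed = cfg$seed) {
  stopifnot(length(recordings) == length(labels))
  raw_list <- list(); lab_list <- list(); time_list <- list()
  all_eps <- list()
  for (i in seq_along(recordings)) {
    rec <- bandpass_filter(recordings[[i]], cfg$band[1], cfg$band[2],
                           cfg$filter_order, mode = "offline")
    if (remove_component) rec <- remove_artifact_component(rec, seed + i)
    eps <- epoch_signal(rec, cfg$epoch_len, cfg$overlap)
    all_eps[[i]] <- eps
    raw_list[[i]] <- psd_feature_matrix(eps, cfg$feature_band, cfg$bin)
    lab_list[[i]] <- rep(as.logical(labels[i]), nrow(raw_list[[i]]))
    time_list[[i]] <- eps$times
  }
  raw <- do.call(rbind, raw_list)
  pooled <- list(epochs = do.call(c, lapply(all_eps, `[[`, "epochs")),
                 times = do.call(rbind, time_list), fs = cfg$fs)
  nm <- compute_noise_metrics(pooled, cfg$feature_band, cfg$bin,
                              shape = cfg$shape_stat,
                              rms_source = cfg$rms_source)
  flags <- flag_noisy_epochs(nm, cfg$noise_z)
  fs <- standardize_features(raw, flags, labels = unlist(lab_list),
                             epoch_times = do.call(rbind, time_list))
  fs$noise_metrics <- nm
  fs
}
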