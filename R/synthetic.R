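# Synthetic study generator.
#
# Emulates the statistical structure the pipeline assumes: a candidate-song
# library of frame-level 128-d audio embeddings drawn from a low-rank latent
# factor model; per-participant "true pleasure" that is a clipped affine
# function of a sparse linear functional of the mean embedding; calibration
# sessions (3 self-selected high-pleasure + 3 other-selected low-pleasure
# songs, 90 s each) with VAS ratings and Poisson chill counts whose group
# means default to self 86.1 VAS / 20.7 chills vs other 57.1 / 6.7; and
# two-channel 600 Hz EEG whose band power (theta/alpha/beta/gamma) shifts
# with the pleasure state. Every generator is a pure function of
# (parameters, seed).

BAND_DEFS <- list(theta = c(4, 7), alpha = c(8, 13),
                  beta = c(14, 30), gamma = c(31, 40))

# expected mean of the top-3 standard-normal order statistics of n draws
expected_top3_z <- function(n) {
  k <- 0:2
  mean(stats::qnorm((n - k - 0.375) / (n + 0.25)))
}

#' Generate a synthetic candidate-song library with planted ground truth
#'
#' Frame embeddings follow a low-rank latent factor model plus noise; each
#' participant's true pleasure is a clipped affine transform of the inner
#' product between a song's mean embedding and that participant's sparse
#' coefficient vector. The affine map is calibrated so that the library mean
#' pleasure is `mean_pleasure` (57.1, the observed other-selected VAS mean)
#' and the expected mean of a participant's top-3 songs is `top_pleasure`
#' (86.1, the observed self-selected VAS mean).
#'
#' @param n_songs number of candidate songs (>= 10; the full-scale default in
#'   the field setup is 7225).
#' @param n_frames embedding frames per 90-s excerpt (default 372).
#' @param sparsity number of nonzero coefficients in each participant's
#'   ground-truth vector (< 128). `0` gives the zero-signal library where all
#'   pleasures equal the intercept.
#' @param n_participants number of simulated participants with independent
#'   tastes (>= 2 so "other-selected" songs exist).
#' @param seed RNG seed; the generator is deterministic given it.
#' @param embedding_dim embedding dimensionality (128).
#' @param latent_rank rank of the factor model.
#' @param frame_noise_sd frame-level noise SD around the song's latent
#'   embedding (lower = higher signal-to-noise).
#' @param eeg_effect per-band log-power shift between high/low pleasure EEG
#'   states (scalar, or length 4 for theta/alpha/beta/gamma); 0 gives
#'   exchangeable classes.
#' @param mean_pleasure,top_pleasure calibration targets described above.
#' @return list with `library` (class `song_library`: `songs` list of
#'   `song_id`/`frames`; `true_pleasure` songs x participants matrix) and
#'   `truth` (class `ground_truth`: `w_star` of participant 1, `active_set`,
#'   `pleasure_fn` parameters, `eeg_effect`, `seed`).
#' @export
generate_song_library <- function(n_songs, n_frames = 372, sparsity = 5,
                                  n_participants = 2, seed = 1L,
                                  embedding_dim = 128, latent_rank = 12,
                                  frame_noise_sd = 0.1, eeg_effect = 0.5,
                                  mean_pleasure = 57.1, top_pleasure = 86.1) {
  if (n_songs < 10) stop("n_songs must be >= 10", call. = FALSE)
  if (sparsity >= embedding_dim) {
    stop("sparsity must be < the embedding dimension (", embedding_dim, ")",
         call. = FALSE)
  }
  stopifnot(n_participants >= 2)
  set.seed(seed)
  loadings <- matrix(stats::rnorm(embedding_dim * latent_rank),
                     latent_rank, embedding_dim) / sqrt(latent_rank)
  u <- matrix(stats::rnorm(n_songs * latent_rank), n_songs, latent_rank)
  mean_emb <- u %*% loadings
  songs <- vector("list", n_songs)
  song_ids <- sprintf("song_%05d", seq_len(n_songs))
  for (s in seq_len(n_songs)) {
    fr <- matrix(rep(mean_emb[s, ], each = n_frames), n_frames, embedding_dim)
    fr <- fr + matrix(stats::rnorm(n_frames * embedding_dim, sd = frame_noise_sd),
                      n_frames, embedding_dim)
    songs[[s]] <- list(song_id = song_ids[s], frames = fr)
  }
  # participant-specific sparse coefficient vectors over embedding dims
  w_all <- matrix(0, embedding_dim, n_participants)
  active <- vector("list", n_participants)
  for (k in seq_len(n_participants)) {
    if (sparsity > 0) {
      idx <- sample.int(embedding_dim, sparsity)
      w_all[idx, k] <- sample(c(-1, 1), sparsity, TRUE) *
        stats::runif(sparsity, 0.5, 1.5)
      active[[k]] <- sort(idx)
    } else {
      active[[k]] <- integer(0)
    }
  }
  raw <- mean_emb %*% w_all                    # songs x participants
  top3 <- expected_top3_z(n_songs)
  slope_z <- (top_pleasure - mean_pleasure) / top3
  pleasure <- matrix(mean_pleasure, n_songs, n_participants)
  if (sparsity > 0) {
    rz <- scale(raw)                           # z per participant
    pleasure[] <- mean_pleasure + slope_z * rz
    pleasure[] <- pmin(pmax(pleasure, 0), 100)
  }
  dimnames(pleasure) <- list(song_ids, NULL)
  library <- structure(list(songs = songs, song_ids = song_ids,
                            true_pleasure = pleasure,
                            n_frames = n_frames,
                            embedding_dim = embedding_dim),
                       class = "song_library")
  truth <- structure(list(w_star = w_all[, 1], active_set = active[[1]],
                          w_all = w_all, active_all = active,
                          pleasure_fn = list(mean = mean_pleasure,
                                             slope_z = slope_z,
                                             top = top_pleasure),
                          eeg_effect = rep_len(eeg_effect, 4L),
                          seed = seed),
                     class = "ground_truth")
  list(library = library, truth = truth)
}

# per-song chill rate, log-linear in true pleasure; the two parameters are
# pinned by the reported group means over three 90-s songs:
# 3 * rate(86.1) = 20.7 and 3 * rate(57.1) = 6.7
chill_rate <- function(pleasure, slope = log((20.7 / 3) / (6.7 / 3)) / (86.1 - 57.1),
                       rate_at_other = 6.7 / 3, other_pleasure = 57.1) {
  rate_at_other * exp(slope * (pleasure - other_pleasure))
}

#' Generate one participant's calibration design
#'
#' Self-selected songs are the participant's top-3 by own true pleasure;
#' other-selected songs are drawn from another simulated participant's top
#' picks (which are approximately average songs under this participant's
#' taste). VAS ratings are true pleasure plus Gaussian noise; chill counts
#' are Poisson with a rate that is log-linear in true pleasure, calibrated so
#' group means default to self 20.7 / other 6.7 chills over three songs.
#'
#' @param library,truth from [generate_song_library()].
#' @param participant index of the participant (default 1).
#' @param seed RNG seed.
#' @param vas_noise_sd rating noise SD in VAS units (default 5).
#' @param chill_slope multiplier on the calibrated chill-rate slope; 0 makes
#'   self and other chill distributions identical.
#' @param song_len excerpt length in seconds (press times are drawn within
#'   it).
#' @return list of class `"participant_design"`: `self_ids`, `other_ids`,
#'   `ratings` (named, VAS 0--100), `chill_counts` (named), `chill_times`
#'   (list of press times per song), `pleasure` (true pleasure of the six
#'   songs), `participant`.
#' @export
generate_participant <- function(library, truth, participant = 1, seed = 1L,
                                 vas_noise_sd = 5, chill_slope = 1,
                                 song_len = 90) {
  stopifnot(inherits(library, "song_library"), inherits(truth, "ground_truth"))
  if (length(library$songs) < 6) {
    stop("library must contain at least 6 songs", call. = FALSE)
  }
  set.seed(seed)
  own <- library$true_pleasure[, participant]
  partner <- if (participant == ncol(library$true_pleasure)) 1L else participant + 1L
  self_idx <- order(own, decreasing = TRUE)[1:3]
  partner_top <- order(library$true_pleasure[, partner], decreasing = TRUE)
  partner_pool <- setdiff(partner_top[seq_len(min(72, length(partner_top)))],
                          self_idx)
  other_idx <- sample(partner_pool, 3)
  idx <- c(self_idx, other_idx)
  pl <- own[idx]
  ratings <- pmin(100, pmax(0, pl + stats::rnorm(6, sd = vas_noise_sd)))
  base_slope <- log((20.7 / 3) / (6.7 / 3)) / (86.1 - 57.1)
  rates <- chill_rate(pl, slope = chill_slope * base_slope)
  counts <- stats::rpois(6, rates)
  chill_times <- lapply(counts, function(k) sort(stats::runif(k, 0, song_len)))
  ids <- library$song_ids[idx]
  names(ratings) <- names(counts) <- names(chill_times) <- names(pl) <- ids
  structure(list(self_ids = ids[1:3], other_ids = ids[4:6],
                 self_idx = self_idx, other_idx = other_idx,
                 ratings = ratings, chill_counts = counts,
                 chill_times = chill_times, pleasure = pl,
                 participant = participant),
            class = "participant_design")
}

# band-limited Gaussian noise via order-2 Butterworth filtering of white noise
bandlimited_noise <- function(n, fs, band) {
  flt <- butter_bandpass(band[1], band[2], fs, order = 2)
  iir_filter_causal(stats::rnorm(n + fs), flt)[-(1:fs)]  # drop warm-up second
}

# 1/f-shaped background via spectral shaping of white noise
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  sp <- sp / sqrt(pmax(f, 2))
  Re(stats::fft(sp, inverse = TRUE)) / n
}

#' Generate synthetic two-channel in-ear EEG
#'
#' Each channel is a sum of band-limited noise processes (theta, alpha, beta,
#' gamma) whose log power shifts by `truth$eeg_effect` between the high and
#' low pleasure states, a 1/f background, and optional transient
#' high-amplitude artifact bursts. Channels share part of their band-limited
#' sources, so left and right are correlated and the difference derivation is
#' informative. Sampled at `fs` Hz; deterministic given `seed`.
#'
#' @param state `"high"` (self-selected / pleasurable) or `"low"`.
#' @param duration length in seconds (>= the 4-s epoch length).
#' @param truth a `ground_truth` (uses its `eeg_effect`).
#' @param artifact_rate artifact bursts per minute (default 0).
#' @param fs sampling rate, Hz (default 600).
#' @param seed RNG seed.
#' @return an [eeg_recording()]; planted artifact intervals (start/end s) are
#'   stored in `attr(, "artifacts")`.
#' @export
generate_eeg <- function(state = c("high", "low"), duration, truth,
                         artifact_rate = 0, fs = 600, seed = 1L) {
  state <- match.arg(state)
  if (duration < 4) stop("duration must be at least the 4-s epoch length",
                         call. = FALSE)
  set.seed(seed)
  n <- as.integer(round(duration * fs))
  eff <- rep_len(truth$eeg_effect, 4L)
  centers <- vapply(BAND_DEFS, mean, numeric(1))
  base_amp <- 10 / sqrt(centers)    # 1/f-like band scaling, muV-ish
  gain <- if (state == "high") exp(eff / 2) else rep(1, 4L)
  left <- numeric(n); right <- numeric(n)
  for (b in seq_along(BAND_DEFS)) {
    shared <- bandlimited_noise(n, fs, BAND_DEFS[[b]])
    own_l <- bandlimited_noise(n, fs, BAND_DEFS[[b]])
    own_r <- bandlimited_noise(n, fs, BAND_DEFS[[b]])
    amp <- base_amp[b] * gain[b]
    left <- left + amp * (sqrt(0.5) * shared + sqrt(0.5) * own_l)
    right <- right + amp * (sqrt(0.5) * shared + sqrt(0.5) * own_r)
  }
  left <- left + 3 * pink_noise(n) + stats::rnorm(n, sd = 0.5)
  right <- right + 3 * pink_noise(n) + stats::rnorm(n, sd = 0.5)
  artifacts <- data.frame(start = numeric(0), end = numeric(0))
  if (artifact_rate > 0) {
    k <- stats::rpois(1, artifact_rate * duration / 60)
    if (k > 0) {
      starts <- sort(stats::runif(k, 0, max(0, duration - 0.5)))
      sd_sig <- stats::sd(left)
      for (s0 in starts) {
        i0 <- as.integer(s0 * fs) + 1L
        len <- as.integer(0.3 * fs)
        i1 <- min(n, i0 + len - 1L)
        burst <- hann_window(i1 - i0 + 1L) * stats::rnorm(i1 - i0 + 1L,
                                                          sd = 30 * sd_sig)
        left[i0:i1] <- left[i0:i1] + burst
        right[i0:i1] <- right[i0:i1] + 0.8 * burst
      }
      artifacts <- data.frame(start = starts, end = starts + 0.3)
    }
  }
  rec <- eeg_recording(rbind(left, right), fs = fs)
  attr(rec, "artifacts") <- artifacts
  rec
}

#' Simulate a full listening bundle for one participant
#'
#' Calibration phase: one 90-s recording per calibration song (state `high`
#' for self-selected, `low` for other-selected) plus a session log with chill
#' presses and VAS ratings. Playlist phase (when `playlist_ids` is given):
#' one recording per playlist song with the state drawn Bernoulli with
#' probability increasing in the song's true pleasure.
#'
#' @param design a [generate_participant()] result.
#' @param library,truth from [generate_song_library()].
#' @param seed RNG seed.
#' @param song_len song excerpt length in seconds (default 90).
#' @param artifact_rate artifact bursts per minute passed to [generate_eeg()].
#' @param playlist_ids optional character vector of playlist song ids.
#' @return list with `recordings` (named by song id), `log` (a
#'   [session_log()]), and for playlist simulations `states`.
#' @export
simulate_listening <- function(design, library, truth, seed = 1L,
                               song_len = 90, artifact_rate = 0,
                               playlist_ids = NULL) {
  stopifnot(inherits(design, "participant_design"))
  set.seed(seed)
  if (is.null(playlist_ids)) {
    ids <- c(design$self_ids, design$other_ids)
    states <- rep(c("high", "low"), each = 3)
    conds <- rep(c("self", "other"), each = 3)
  } else {
    ids <- playlist_ids
    own <- library$true_pleasure[match(ids, library$song_ids),
                                 design$participant]
    p_high <- stats::plogis((own - 57.1) / 8)
    states <- ifelse(stats::runif(length(ids)) < p_high, "high", "low")
    conds <- rep("playlist", length(ids))
  }
  recordings <- vector("list", length(ids))
  names(recordings) <- make.unique(ids)
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    recordings[[i]] <- generate_eeg(states[i], song_len, truth,
                                    artifact_rate = artifact_rate,
                                    seed = (seed %% 1000003L) * 1000L + i)
    in_cal <- ids[i] %in% names(design$chill_times)
    presses <- if (is.null(playlist_ids) && in_cal) {
      design$chill_times[[ids[i]]]
    } else numeric(0)
    vas <- if (is.null(playlist_ids) && in_cal) {
      list(pleasure = unname(design$ratings[ids[i]]))
    } else list()
    records[[i]] <- list(song_id = ids[i], condition = conds[i],
                         onset = (i - 1) * song_len, duration = song_len,
                         chill_press_times = presses, vas_ratings = vas)
  }
  log <- session_log(paste0("sim_", design$participant),
                     phase = if (is.null(playlist_ids)) "recording" else "playlist",
                     song_records = records)
  list(recordings = recordings, log = log, states = states)
}
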