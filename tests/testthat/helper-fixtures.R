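# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# A small but complete calibrated world: 80-song library, one participant,
# 30-s songs, strong EEG effect, windows sized for the 80-song library.
shared_world <- function() {
  if (!exists("world", envir = .fixture_env)) {
    gen <- generate_song_library(n_songs = 80, n_frames = 18, sparsity = 5,
                                 n_participants = 3, seed = 42,
                                 eeg_effect = 1.5)
    cfg <- run_config(song_len = 30, library_size = 80, window_top = 8,
                      window_wide = 20, baseline_window = c(37, 44),
                      aggregate_mode = "mean")
    des <- generate_participant(gen$library, gen$truth, participant = 1,
                                seed = 7, song_len = 30)
    cal <- calibrate_participant(des, gen$library, gen$truth, cfg, seed = 7)
    assign("world",
           list(library = gen$library, truth = gen$truth, cfg = cfg,
                design = des, cal = cal),
           envir = .fixture_env)
  }
  get("world", envir = .fixture_env)
}

# hand-rolled population z-score used as an independent check
z_pop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# independent AUC oracle: enumerate all positive-negative pairs
auc_by_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# a tiny valid 4-s two-channel epoch at 600 Hz
toy_epoch <- function(fs = 600, epoch_len = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(2 * fs * epoch_len), nrow = 2)
}
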