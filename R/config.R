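#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' The defaults are the values the system was designed around: 600 Hz in-ear
#' EEG, a 3--40 Hz 4th-order Butterworth band-pass, spectral features from
#' 4--40 Hz in 0.5 Hz bins, 4-s epochs with 50% overlap, a noise z-threshold
#' of 2.5, up to 150 principal components, 5-/10-/20-fold cross-validation
#' for the initial acoustic fit, retraining and the EEG classifier, a
#' 1000-shuffle permutation test, selection windows of 72 (narrow) and 432
#' (wide) ranks with a baseline window at ranks 3577--3649 of a 7225-song
#' library, 90-s songs, 7-song playlists and a 5-point smoothing window.
#'
#' @param ... named overrides of any default listed above, e.g.
#'   `run_config(song_len = 30)`.
#' @return A list of class `"bmi_config"`.
#' @examples
#' cfg <- run_config()
#' cfg$epoch_len
#' @export
run_config <- function(...) {
  cfg <- list(
    fs = 600,
    band = c(3, 40),
    filter_order = 4,
    feature_band = c(4, 40),
    bin = 0.5,
    epoch_len = 4,
    overlap = 0.5,
    noise_z = 2.5,
    shape_stat = "skewness",
    rms_source = "bandpower",
    max_pcs = 150,
    cv_model1_initial = 5,
    cv_model1_retrain = 10,
    cv_model2 = 20,
    perm_n = 1000,
    window_top = 72,
    window_wide = 432,
    baseline_window = c(3577, 3649),
    library_size = 7225,
    song_len = 90,
    playlist_len = 7,
    smooth_k = 5,
    clip_sd = 2,
    embedding_dim = 128,
    frames_per_excerpt = 372,
    aggregate_mode = "concat",
    retrain_mode = "accumulate",
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  class(cfg) <- "bmi_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$fs > 0,
    length(cfg$band) == 2, cfg$band[1] > 0, cfg$band[1] < cfg$band[2],
    cfg$band[2] < cfg$fs / 2,
    length(cfg$feature_band) == 2, cfg$feature_band[1] < cfg$feature_band[2],
    cfg$bin > 0,
    cfg$epoch_len > 0,
    cfg$overlap >= 0, cfg$overlap < 1,
    cfg$noise_z > 0,
    cfg$max_pcs >= 1,
    cfg$perm_n >= 1,
    cfg$window_top >= 1, cfg$window_wide >= cfg$window_top,
    cfg$song_len > 0, cfg$playlist_len >= 1, cfg$smooth_k >= 1
  )
  if (!cfg$shape_stat %in% c("skewness", "kurtosis")) {
    stop("shape_stat must be 'skewness' or 'kurtosis'", call. = FALSE)
  }
  if (!cfg$rms_source %in% c("bandpower", "time")) {
    stop("rms_source must be 'bandpower' or 'time'", call. = FALSE)
  }
  if (!cfg$aggregate_mode %in% c("concat", "mean", "rows")) {
    stop("aggregate_mode must be 'concat', 'mean' or 'rows'", call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, path))` equals `cfg`.
#'
#' @param cfg a [run_config()] object.
#' @param path file path of the YAML document.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `bmi_config` list.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "bmi_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @exportS3Method base::print
print.bmi_config <- function(x, ...) {
  cat("<bmi_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
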