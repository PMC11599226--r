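#' Specification of a synthetic ECG-like periodic waveform
#'
#' Each beat is a train of Gaussian bumps on a flat baseline — a simplified
#' P/QRS/T morphology. Selected beats are transformed (anomalies) and every
#' sample of a transformed beat is labeled abnormal. Values are kept inside
#' the encoder's admissible range.
#'
#' @param beat_period beat duration in seconds (default 0.75, i.e. 80 bpm).
#' @param sample_rate samples per second (default 128).
#' @param n_beats total number of beats.
#' @param baseline baseline potential in mV (default -0.75).
#' @param beat_shape data frame with columns `center` (s, offset within the
#'   beat), `width` (s, Gaussian sd) and `amplitude` (mV). The default three
#'   bumps emulate the P wave, QRS complex and T wave, spanning the full
#'   admissible range `[-2, 0.5]` mV when the main bump is inverted.
#' @param anomalies data frame with columns `beat` (1-based beat index) and
#'   `type` (one of `"invert"`, `"widen"`, `"scale"`, `"drop"`,
#'   `"invert_widen"`). The benchmark default is `"widen"`: the main bump
#'   tripled in width at unchanged amplitude, emulating a premature
#'   ventricular contraction's wide QRS complex.
#' @param noise_sd additive white-noise standard deviation in mV
#'   (default 0.02).
#' @param seed RNG seed used by [generate_waveform()].
#' @return A list of class `waveform_spec`.
#' @export
waveform_spec <- function(beat_period = 0.75, sample_rate = 128,
                          n_beats = 60, baseline = -0.75,
                          beat_shape = default_beat_shape(),
                          anomalies = NULL, noise_sd = 0.02, seed = 1) {
  stopifnot(beat_period > 0, sample_rate > 0, n_beats >= 1, noise_sd >= 0)
  stopifnot(all(c("center", "width", "amplitude") %in% names(beat_shape)))
  if (!is.null(anomalies)) {
    stopifnot(all(c("beat", "type") %in% names(anomalies)))
    if (any(anomalies$beat < 1 | anomalies$beat > n_beats))
      stop("anomaly beat index out of range (1..n_beats)")
    bad <- setdiff(anomalies$type,
                   c("invert", "widen", "scale", "drop", "invert_widen"))
    if (length(bad)) stop("unknown anomaly type: ", paste(bad, collapse = ", "))
  }
  structure(list(beat_period = beat_period, sample_rate = sample_rate,
                 n_beats = n_beats, baseline = baseline,
                 beat_shape = beat_shape, anomalies = anomalies,
                 noise_sd = noise_sd, seed = seed),
            class = "waveform_spec")
}

#' Default three-bump beat morphology
#'
#' P wave (+0.20 mV), QRS main bump (+1.25 mV, narrow) and T wave
#' (+0.35 mV) on the -0.75 mV baseline: normal peaks reach +0.5 mV and the
#' inverted main bump bottoms out at -2.0 mV, exactly the admissible
#' encoder range.
#'
#' @return Data frame with columns `center`, `width`, `amplitude`.
#' @export
default_beat_shape <- function() {
  data.frame(center = c(0.18, 0.36, 0.56),
             width = c(0.025, 0.018, 0.040),
             amplitude = c(0.20, 1.25, 0.35))
}

#' Generate a labeled synthetic periodic waveform
#'
#' Deterministic given `spec$seed`. Normal beats are identical up to the
#' additive noise; transformed beats are labeled sample-wise. The series is
#' clipped to the default encoder range `[-2, 0.5]` mV.
#'
#' @param spec a [waveform_spec()].
#' @return List with `series` (mV samples), `labels` (integer 0/1),
#'   `time` (s) and `spec`.
#' @export
generate_waveform <- function(spec) {
  spb <- as.integer(round(spec$beat_period * spec$sample_rate))
  tt <- (seq_len(spb) - 1) / spec$sample_rate
  bump <- function(shape) {
    v <- rep(0, spb)
    for (r in seq_len(nrow(shape)))
      v <- v + shape$amplitude[r] *
        exp(-0.5 * ((tt - shape$center[r]) / shape$width[r])^2)
    v
  }
  normal <- spec$baseline + bump(spec$beat_shape)
  transform_beat <- function(type) {
    sh <- spec$beat_shape
    main <- which.max(abs(sh$amplitude))
    if (type == "invert") sh$amplitude[main] <- -sh$amplitude[main]
    if (type == "widen") sh$width[main] <- 3 * sh$width[main]
    if (type == "scale") sh$amplitude[main] <- 2 * sh$amplitude[main]
    if (type == "invert_widen") {
      sh$amplitude[main] <- -sh$amplitude[main]
      sh$width[main] <- 3 * sh$width[main]
    }
    if (type == "drop") sh <- sh[-main, , drop = FALSE]
    spec$baseline + bump(sh)
  }
  series <- rep(normal, spec$n_beats)
  labels <- integer(spb * spec$n_beats)
  if (!is.null(spec$anomalies)) {
    for (r in seq_len(nrow(spec$anomalies))) {
      b <- spec$anomalies$beat[r]
      idx <- ((b - 1) * spb + 1):(b * spb)
      series[idx] <- transform_beat(spec$anomalies$type[r])
      labels[idx] <- 1L
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    series <- series + rnorm(length(series), 0, spec$noise_sd)
  }
  series <- pmin(pmax(series, -2), 0.5)
  list(series = series, labels = labels,
       time = (seq_along(series) - 1) / spec$sample_rate, spec = spec)
}

#' Default end-to-end anomaly-detection benchmark
#'
#' 120 beats at 80 bpm: the first 60 are anomaly-free (the training
#' segment), the last 60 contain `n_anomalies` inverted-and-widened beats
#' evenly spread through the test segment.
#'
#' @param n_train_beats,n_test_beats beats in each segment (defaults 60/60).
#' @param n_anomalies number of transformed beats in the test segment
#'   (default 5).
#' @param anomaly_type transform applied (default `"invert_widen"`: the
#'   main bump inverted and tripled in width, an ectopic-beat-like
#'   morphology whose encoded frequency leaves the normal range).
#' @param noise_sd additive noise sd in mV (default 0.02).
#' @param seed generator seed.
#' @return List with `series`, `labels`, `time`, `spec` and `n_train`
#'   (samples in the training segment).
#' @export
default_benchmark <- function(n_train_beats = 60, n_test_beats = 60,
                              n_anomalies = 5,
                              anomaly_type = "invert_widen",
                              noise_sd = 0.02, seed = 1) {
  n_beats <- n_train_beats + n_test_beats
  ab <- n_train_beats +
    round(seq(0.15, 0.9, length.out = n_anomalies) * n_test_beats)
  spec <- waveform_spec(
    n_beats = n_beats, noise_sd = noise_sd, seed = seed,
    anomalies = data.frame(beat = ab, type = anomaly_type))
  wf <- generate_waveform(spec)
  spb <- as.integer(round(spec$beat_period * spec$sample_rate))
  wf$n_train <- n_train_beats * spb
  wf
}

#' Read a 2-3 column time-series CSV
#'
#' Column 1 is a time stamp or index, column 2 the value in mV, and an
#' optional column 3 holds 0/1 anomaly labels. A header line is detected
#' automatically. PhysioNet-style CSV exports fit this shape.
#'
#' @param path file path.
#' @param rescale if `TRUE`, affinely map the values into the encoder range
#'   `[-2, 0.5]` mV; the transform is attached as attribute `"rescale"`.
#' @return List with `time`, `series`, `labels` (`NULL` if absent).
#' @export
load_series_csv <- function(path, rescale = FALSE) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("parse error: empty file: ", path)
  header <- !grepl("^\\s*[-+0-9.]", strsplit(first, ",")[[1]][1])
  df <- tryCatch(read.csv(path, header = header),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (ncol(df) < 2) stop("parse error: expected 2-3 columns in ", path)
  for (j in 1:2) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[j]]))))
    if (length(bad))
      stop("parse error at line ", bad[1] + header, " of ", path,
           ": non-numeric value")
  }
  series <- as.numeric(df[[2]])
  if (rescale) {
    lo <- min(series); hi <- max(series)
    a <- if (hi > lo) 2.5 / (hi - lo) else 0
    b <- -2 - a * lo
    series <- a * series + b
    attr(series, "rescale") <- c(scale = a, offset = b)
    message(sprintf("rescaled input: value' = %.6g * value + %.6g", a, b))
  }
  labels <- if (ncol(df) >= 3) as.integer(df[[3]]) else NULL
  list(time = as.numeric(df[[1]]), series = series, labels = labels)
}

#' Write a time series in the CSV shape read by [load_series_csv()]
#'
#' @param wf list with `time`, `series` and optionally `labels`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(wf, path) {
  df <- data.frame(time = wf$time, value = wf$series)
  if (!is.null(wf$labels)) df$label <- wf$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
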