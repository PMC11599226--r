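#' One-step-ahead detection statistic
#'
#' `D[k+1] = |F_out[k] - F_in[k+1]|`: the absolute difference between the
#' frequency predicted from the network state at sample `k` and the actual
#' encoded input frequency of sample `k+1`. `D[1]` has no prediction and is
#' `NA`.
#'
#' @param F_out per-sample predicted frequencies (length `K` or `K - 1`;
#'   with length `K` the last prediction has no target and is dropped).
#' @param F_in per-sample encoded input frequencies (length `K`).
#' @return Numeric vector of length `K`; first element `NA`.
#' @export
compute_D <- function(F_out, F_in) {
  K <- length(F_in)
  if (length(F_out) == K) F_out <- F_out[-K]
  if (length(F_out) != K - 1)
    stop("alignment error: F_out must have length ", K, " or ", K - 1)
  c(NA_real_, abs(F_out - F_in[-1]))
}

anomaly_events <- function(labels) {
  r <- rle(as.integer(labels) > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  lapply(idx, function(i) starts[i]:ends[i])
}

#' Judgment margin of a detection run
#'
#' `D_thr_no` is the highest peak of `D` over normal-labeled samples — the
#' smallest threshold that misdetects no normal point. `D_thr_ab` is the
#' lowest of the per-event peaks of `D` over anomaly events (maximal runs of
#' abnormal labels) — the smallest threshold that overlooks no anomaly. The
#' judgment margin `delta_thr = D_thr_ab - D_thr_no` is positive iff a
#' threshold exists that detects every anomaly event with zero false
#' positives; for an untrained network it is typically negative.
#'
#' @param D detection statistic from [compute_D()]; `NA` entries ignored.
#' @param labels per-sample labels, 0/`FALSE` = normal, 1/`TRUE` = abnormal.
#' @return List with `D_thr_no`, `D_thr_ab`, `delta_thr` and `event_peaks`.
#' @export
judgment_margin <- function(D, labels) {
  stopifnot(length(D) == length(labels))
  lab <- as.integer(labels) > 0
  normal <- !lab & !is.na(D)
  if (!any(normal)) stop("no normal samples with a defined statistic")
  D_thr_no <- max(D[normal])
  ev <- anomaly_events(lab)
  ev <- Filter(function(i) any(!is.na(D[i])), ev)
  if (length(ev) == 0)
    stop(sprintf(
      "margin undefined: no labeled anomaly events (D_thr_no = %.6g)",
      D_thr_no))
  peaks <- vapply(ev, function(i) max(D[i], na.rm = TRUE), numeric(1))
  D_thr_ab <- min(peaks)
  list(D_thr_no = D_thr_no, D_thr_ab = D_thr_ab,
       delta_thr = D_thr_ab - D_thr_no, event_peaks = peaks)
}

#' True/false positive rates across detection thresholds
#'
#' At each threshold, `FPR` is the fraction of normal-labeled samples with
#' `D > D_thr`. `TPR_event` is the fraction of anomaly events whose peak `D`
#' exceeds `D_thr` (so `TPR_event = 1` exactly when `D_thr < D_thr_ab`);
#' `TPR_point`, the fraction of abnormal-labeled samples above threshold, is
#' also reported for comparison.
#'
#' @inheritParams judgment_margin
#' @param thresholds ascending numeric thresholds; default: all finite
#'   values of `D` plus one below and one above.
#' @return Data frame with columns `D_thr`, `FPR`, `TPR_event`, `TPR_point`.
#' @export
tpr_fpr_curve <- function(D, labels, thresholds = NULL) {
  stopifnot(length(D) == length(labels))
  lab <- as.integer(labels) > 0
  ok <- !is.na(D)
  if (is.null(thresholds)) {
    v <- sort(unique(D[ok]))
    thresholds <- c(min(v) - 1, v, max(v) + 1)
  }
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  dn <- D[!lab & ok]
  dp <- D[lab & ok]
  peaks <- vapply(Filter(function(i) any(ok[i]), anomaly_events(lab)),
                  function(i) max(D[i], na.rm = TRUE), numeric(1))
  data.frame(
    D_thr = thresholds,
    FPR = vapply(thresholds, function(th) mean(dn > th), numeric(1)),
    TPR_event = vapply(thresholds, function(th)
      if (length(peaks)) mean(peaks > th) else NA_real_, numeric(1)),
    TPR_point = vapply(thresholds, function(th)
      if (length(dp)) mean(dp > th) else NA_real_, numeric(1)))
}

#' Full three-phase anomaly-detection pipeline
#'
#' Phase 1 (unsupervised reconstruction): the network is driven by the
#' Poisson-encoded training segment with SDSP and IP active, reshaping the
#' E-to-E weights and firing thresholds. Phase 2 (readout learning): with
#' plasticity frozen, the training segment is presented again, per-bin
#' excitatory firing rates are collected, and a rectified-linear readout is
#' fit to predict the next sample's input frequency. Phase 3 (test): with
#' plasticity still frozen, the labeled test segment is presented, the
#' detection statistic `D`, the judgment margin, and the ROC curve are
#' computed. With `plasticity_on = FALSE` Phase 1 is skipped and the result
#' is the untrained-network baseline.
#'
#' @param series numeric vector of samples in mV.
#' @param labels per-sample 0/1 anomaly labels.
#' @param n_train number of leading samples used for training; these must
#'   all be labeled normal.
#' @param config a [run_config()] bundling all module parameters.
#' @param seed integer seed controlling wiring and every Poisson draw.
#' @param plasticity_on run Phase 1 with learning enabled (default `TRUE`).
#' @return A list of class `srnn_detection`: per-sample `D`, `labels`
#'   (test segment), `F_in`, `F_out`, margin fields `D_thr_no`, `D_thr_ab`,
#'   `delta_thr`, the midpoint and practical thresholds with their achieved
#'   `TPR_event` / `FPR`, the `roc` data frame, the trained `readout` and
#'   `network`, the per-bin excitatory test rates (`rates_test`), and
#'   bookkeeping (`seed`, `n_train`, `T_bin`).
#' @export
run_pipeline <- function(series, labels, n_train, config = run_config(),
                         seed = 1, plasticity_on = TRUE) {
  stopifnot(length(series) == length(labels),
            n_train >= 2, n_train < length(series))
  if (any(as.integer(labels[seq_len(n_train)]) > 0))
    stop("training segment contains labeled anomalies")
  enc <- config$encoding
  enc$dt <- config$network$dt
  set.seed(seed)
  net <- build_network(config$network, config$plasticity, config$neuron,
                       config$synapse)
  train <- series[seq_len(n_train)]
  test <- series[-seq_len(n_train)]
  test_labels <- as.integer(labels[-seq_len(n_train)]) > 0
  F_train <- encode_rate(train, enc)
  F_test <- encode_rate(test, enc)
  T_train <- n_train * enc$T_bin
  T_test <- length(test) * enc$T_bin
  ne <- config$network$N_exc
  n_tot <- ne + config$network$N_inh

  # Phase 1: unsupervised reconstruction (skipped for the frozen baseline,
  # whose weights and thresholds would be returned unchanged anyway)
  if (plasticity_on) {
    r1 <- gen_input_raster(F_train, enc, config$network$N_input)
    net <- run_network(net, r1, T_train, plasticity_on = TRUE)$network
  }
  # Phase 2: frozen run over the training segment; fit the readout
  r2 <- gen_input_raster(F_train, enc, config$network$N_input)
  run2 <- run_network(net, r2, T_train, plasticity_on = FALSE)
  X2 <- bin_rates(run2$spikes, enc$T_bin, T_train, n_tot,
                  neurons = 0:(ne - 1))
  al <- align_readout_data(X2, F_train)
  readout <- fit_readout(al$X, al$y, ridge = config$ridge)
  # Phase 3: frozen run over the test segment; detection statistic
  r3 <- gen_input_raster(F_test, enc, config$network$N_input)
  run3 <- run_network(net, r3, T_test, plasticity_on = FALSE)
  X3 <- bin_rates(run3$spikes, enc$T_bin, T_test, n_tot,
                  neurons = 0:(ne - 1))
  F_out <- predict_Fout(readout, X3)
  D <- compute_D(F_out, F_test)
  margin <- tryCatch(judgment_margin(D, test_labels), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    list(D_thr_no = max(D[!test_labels & !is.na(D)]), D_thr_ab = NA_real_,
         delta_thr = NA_real_, event_peaks = numeric(0))
  })
  roc <- tpr_fpr_curve(D, test_labels)
  at_thr <- function(th) {
    r <- tpr_fpr_curve(D, test_labels, thresholds = th)
    c(TPR_event = r$TPR_event, FPR = r$FPR)
  }
  midpoint <- if (is.na(margin$D_thr_ab)) NA_real_ else
    (margin$D_thr_no + margin$D_thr_ab) / 2
  practical <- margin$D_thr_no * (1 + config$eps_practical)
  out <- list(D = D, labels = test_labels, F_in = F_test, F_out = F_out,
              D_thr_no = margin$D_thr_no, D_thr_ab = margin$D_thr_ab,
              delta_thr = margin$delta_thr,
              event_peaks = margin$event_peaks,
              D_thr_mid = midpoint,
              at_midpoint = if (is.na(midpoint)) NULL else at_thr(midpoint),
              D_thr_practical = practical,
              at_practical = at_thr(practical),
              roc = roc, readout = readout, network = net,
              rates_test = X3,
              seed = seed, n_train = n_train, T_bin = enc$T_bin,
              plasticity_on = plasticity_on)
  class(out) <- "srnn_detection"
  out
}

#' @export
print.srnn_detection <- function(x, ...) {
  cat(sprintf("srnn_detection (%s network, seed %d)\n",
              if (x$plasticity_on) "reconstructed" else "initial", x$seed))
  cat(sprintf("  test samples: %d (%d anomaly events)\n",
              length(x$D), length(x$event_peaks)))
  cat(sprintf("  D_thr_no = %.3f, D_thr_ab = %.3f, delta_thr = %.3f fires/s\n",
              x$D_thr_no, x$D_thr_ab, x$delta_thr))
  if (!is.null(x$at_midpoint))
    cat(sprintf("  at midpoint D_thr = %.3f: TPR(event) = %.3f, FPR = %.3f\n",
                x$D_thr_mid, x$at_midpoint["TPR_event"],
                x$at_midpoint["FPR"]))
  invisible(x)
}

#' Write a detection report (per-sample CSV + scalar summary)
#'
#' @param result an `srnn_detection` from [run_pipeline()].
#' @param path_csv path for the per-sample table (`D`, label, `F_in`,
#'   `F_out`).
#' @param path_summary optional path for a JSON scalar summary.
#' @return `result`, invisibly.
#' @export
write_detection_report <- function(result, path_csv, path_summary = NULL) {
  K <- length(result$D)
  df <- data.frame(index = seq_len(K), D = result$D,
                   label = as.integer(result$labels),
                   F_in = result$F_in,
                   F_out = c(result$F_out, rep(NA_real_,
                                               K - length(result$F_out))))
  write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_summary)) {
    s <- result[c("D_thr_no", "D_thr_ab", "delta_thr", "D_thr_mid",
                  "D_thr_practical", "seed", "n_train", "T_bin",
                  "plasticity_on")]
    jsonlite::write_json(s, path_summary, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(result)
}

#' Judgment-margin parameter sweep
#'
#' Runs the full three-phase pipeline once per grid cell per seed and
#' collects the judgment margin, reproducing the heatmap-style experiments
#' over the learning-rate grids and the input-layer parameters.
#'
#' @param grid data frame whose columns may include `LR_SDSP`, `LR_thr`,
#'   `T_bin`, `N_input`, `F_poisson`; each row is one cell (use
#'   [expand.grid()]).
#' @param series,labels,n_train benchmark data as in [run_pipeline()].
#' @param config base [run_config()]; grid columns override its fields.
#' @param seeds integer vector of seeds; every cell is run with each.
#' @param plasticity_on passed through to [run_pipeline()].
#' @return Data frame, one row per cell per seed, with the grid columns,
#'   `seed`, `delta_thr`, `D_thr_no`, `D_thr_ab`, a `binary` flag marking
#'   the binary-resolution cells (`LR_SDSP = 2`, `LR_thr = 0.3`), and an
#'   `error` column (message for failed cells, `NA` otherwise).
#' @export
sweep_margin <- function(grid, series, labels, n_train,
                         config = run_config(), seeds = 1L,
                         plasticity_on = TRUE) {
  stopifnot(nrow(grid) >= 1)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cell <- grid[g, , drop = FALSE]
    if (!is.null(cell$LR_SDSP)) cfg$plasticity$LR_SDSP <- cell$LR_SDSP
    if (!is.null(cell$LR_thr)) cfg$plasticity$LR_thr <- cell$LR_thr
    if (!is.null(cell$T_bin)) cfg$encoding$T_bin <- cell$T_bin
    if (!is.null(cell$F_poisson)) cfg$encoding$F_poisson <- cell$F_poisson
    if (!is.null(cell$N_input)) cfg$network$N_input <- cell$N_input
    for (s in seeds) {
      res <- tryCatch(
        run_pipeline(series, labels, n_train, cfg, seed = s,
                     plasticity_on = plasticity_on),
        error = function(e) e)
      failed <- inherits(res, "error")
      rows[[length(rows) + 1]] <- cbind(
        cell,
        data.frame(
          seed = s,
          delta_thr = if (failed) NA_real_ else res$delta_thr,
          D_thr_no = if (failed) NA_real_ else res$D_thr_no,
          D_thr_ab = if (failed) NA_real_ else res$D_thr_ab,
          binary = isTRUE(cfg$plasticity$LR_SDSP == 2 &&
                            cfg$plasticity$LR_thr == 0.3),
          error = if (failed) conditionMessage(res) else NA_character_,
          stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("srnn_sweep", class(out))
  out
}
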