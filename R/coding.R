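#' Poisson rate-encoding configuration
#'
#' A raw sample `E` (electrostatic potential in mV) is converted to an input
#' firing frequency `F_in = F_poisson * (4 + 2 E) / 5`, and every input-layer
#' neuron emits an independent Poisson spike train at that frequency while
#' the sample is held for `T_bin` seconds.
#'
#' @param F_poisson conversion coefficient in Hz (default 75). The affine
#'   map gives `F_in = F_poisson` at `E = 0.5` mV and `F_in = 0` at
#'   `E = -2` mV.
#' @param T_bin hold duration per sample in seconds (default 150 ms; the
#'   study also uses 7 ms and 600 ms).
#' @param dt simulation step in seconds; `F_in * dt` must stay below 1.
#' @param E_min,E_max admissible sample range in mV (defaults -2 and 0.5,
#'   the non-negativity interval of the affine map with unit gain at its
#'   upper end). Samples outside are clipped and counted.
#' @return A list of class `encoding_config`.
#' @export
encoding_config <- function(F_poisson = 75, T_bin = 0.15, dt = 1e-4,
                            E_min = -2, E_max = 0.5) {
  stopifnot(F_poisson > 0, T_bin > 0, dt > 0, E_min < E_max)
  structure(list(F_poisson = F_poisson, T_bin = T_bin, dt = dt,
                 E_min = E_min, E_max = E_max),
            class = "encoding_config")
}

#' Encode samples as input firing frequencies
#'
#' Applies `F_in = F_poisson * (4 + 2 E) / 5` after clipping `E` into
#' `[E_min, E_max]`. The map is affine and monotone increasing, and the
#' default range guarantees `F_in >= 0`.
#'
#' @param E numeric vector of samples in mV.
#' @param cfg an [encoding_config()].
#' @return Numeric vector of rates in fires per second. The number of
#'   clipped samples is attached as attribute `"n_clipped"`.
#' @export
encode_rate <- function(E, cfg = encoding_config()) {
  clipped <- sum(E < cfg$E_min | E > cfg$E_max)
  E <- pmin(pmax(E, cfg$E_min), cfg$E_max)
  out <- pmax(cfg$F_poisson * (4 + 2 * E) / 5, 0)
  attr(out, "n_clipped") <- clipped
  out
}

#' Generate a Poisson input spike raster from encoded rates
#'
#' Each of the `n_input` input neurons independently emits a
#' Bernoulli(`F_in * dt`) spike per step while sample `k` is held for
#' `T_bin` seconds; all input neurons share the sample's rate but draw
#' independent trains. Uses R's RNG (`set.seed()` for reproducibility).
#'
#' @param rates numeric vector of per-sample rates `F_in` in fires/s.
#' @param cfg an [encoding_config()] supplying `T_bin` and `dt`.
#' @param n_input number of input neurons.
#' @return Data frame with columns `step` (0-based integration step),
#'   `time` (s, end of the step) and `neuron` (0-based input index),
#'   sorted by step.
#' @export
gen_input_raster <- function(rates, cfg, n_input) {
  stopifnot(all(is.finite(rates)), all(rates >= 0), n_input > 0)
  spb <- as.integer(round(cfg$T_bin / cfg$dt))
  res <- cpp_gen_input_raster(as.numeric(rates), spb, as.integer(n_input),
                              cfg$dt)
  data.frame(step = res$step, time = (res$step + 1) * cfg$dt,
             neuron = res$neuron)
}

#' Fit the linear readout that predicts the next input frequency
#'
#' The readout is an abstract rectified-linear unit over the excitatory
#' per-bin firing rates: trained by (ridge-regularized) least squares so
#' that the rates observed while sample `k` is presented predict the input
#' frequency of sample `k+1`. Rows of `X` must already be aligned with `y`
#' (row `k` of `X` pairs with `y[k] = F_in[k+1]`); [align_readout_data()]
#' does this from raw series.
#'
#' @param X numeric matrix, bins x excitatory neurons, in fires/s.
#' @param y numeric vector of target frequencies, length `nrow(X)`.
#' @param ridge ridge penalty added to the (non-intercept) normal-equation
#'   diagonal, default `1e-6` for numerical conditioning; set 0 for plain
#'   least squares.
#' @return A list of class `srnn_readout` with `weights` (per neuron) and
#'   `intercept`.
#' @export
fit_readout <- function(X, y, ridge = 1e-6) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y have mismatched lengths")
  if (nrow(X) < 2) stop("insufficient data: need at least 2 bins")
  stopifnot(ridge >= 0)
  Xi <- cbind(1, X)
  A <- crossprod(Xi)
  diag(A)[-1] <- diag(A)[-1] + ridge
  coef <- tryCatch(solve(A, crossprod(Xi, y)),
                   error = function(e) qr.coef(qr(Xi), y))
  coef[is.na(coef)] <- 0
  structure(list(intercept = coef[1], weights = as.numeric(coef[-1])),
            class = "srnn_readout")
}

#' Align per-bin rates with next-sample targets
#'
#' @param rates_mat bins x neurons rate matrix (one row per presented
#'   sample).
#' @param F_in per-sample encoded input frequencies, same number of rows.
#' @return List with `X` (rows 1..K-1) and `y` (`F_in[2..K]`).
#' @export
align_readout_data <- function(rates_mat, F_in) {
  K <- nrow(rates_mat)
  stopifnot(K == length(F_in), K >= 2)
  list(X = rates_mat[-K, , drop = FALSE], y = as.numeric(F_in[-1]))
}

#' Predict the output frequency from a rate vector
#'
#' `F_out = max(0, w . x + b)`: rectified because a firing frequency cannot
#' be negative.
#'
#' @param readout an `srnn_readout` from [fit_readout()].
#' @param x rate vector (or bins x neurons matrix) matching the readout
#'   length.
#' @return Predicted frequency (vector if `x` is a matrix).
#' @export
predict_Fout <- function(readout, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(readout$weights))
      stop("rate matrix width does not match readout")
    pmax(as.numeric(x %*% readout$weights) + readout$intercept, 0)
  } else {
    if (length(x) != length(readout$weights))
      stop("rate vector length does not match readout")
    max(sum(readout$weights * x) + readout$intercept, 0)
  }
}
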