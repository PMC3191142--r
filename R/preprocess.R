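#' Discard initial volumes
#'
#' Removes the first `k` time points of every region — the standard guard
#' against initial signal instability (the default drops 5 volumes, turning
#' a 300-volume run into 295 analysed time points).
#'
#' @param ts A [ts_matrix()].
#' @param k Number of leading rows to drop (default 5); must be < T.
#' @return A shorter [ts_matrix()].
#' @export
discard_initial <- function(ts, k = 5) {
  stopifnot(inherits(ts, "ts_matrix"))
  T <- nrow(ts$values)
  if (k < 0) stop("'k' must be non-negative")
  if (k >= T) stop("cannot discard ", k, " of ", T, " time points")
  if (k == 0) return(ts)
  ts_matrix(ts$values[(k + 1):T, , drop = FALSE], ts$node_labels,
            ts$tr_seconds)
}

#' Remove per-region linear trends
#'
#' Subtracts the least-squares line (intercept plus slope) from every
#' column, leaving each region zero-mean and free of linear drift.
#'
#' @param ts A [ts_matrix()] with at least 3 time points.
#' @return Detrended [ts_matrix()].
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "ts_matrix"))
  T <- nrow(ts$values)
  if (T < 3) stop("need at least 3 time points to detrend")
  tt <- seq_len(T)
  res <- stats::lsfit(tt, ts$values)$residuals
  ts_matrix(matrix(res, T, ncol(ts$values)), ts$node_labels, ts$tr_seconds)
}

#' Ideal band-pass filter in the frequency domain
#'
#' Forward FFT per region, zeroing of every frequency bin outside the closed
#' band \[`f_lo`, `f_hi`\], inverse FFT.  The defaults keep the
#' 0.01-0.1 Hz band in which resting-state BOLD fluctuations live; with
#' `f_lo > 0` the DC component is removed, so filtered series are zero-mean.
#' As an ideal filter this is a projection: applying it twice equals
#' applying it once.
#'
#' @param ts A [ts_matrix()]; its `tr_seconds` sets the frequency axis.
#' @param f_lo,f_hi Band edges in Hz; `f_hi` must not exceed the Nyquist
#'   frequency 1/(2 TR).
#' @return Filtered [ts_matrix()].
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.1) {
  stopifnot(inherits(ts, "ts_matrix"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (f_lo < 0 || f_hi <= f_lo)
    stop("need 0 <= f_lo < f_hi")
  if (f_hi > nyq + 1e-12)
    stop(sprintf("f_hi = %g Hz exceeds the Nyquist frequency %g Hz",
                 f_hi, nyq))
  T <- nrow(ts$values)
  k <- seq_len(T) - 1
  freq <- pmin(k, T - k) / (T * ts$tr_seconds)  # two-sided frequency axis
  keep <- freq >= f_lo & freq <= f_hi
  filt <- apply(ts$values, 2, function(col) {
    z <- stats::fft(col)
    z[!keep] <- 0+0i
    Re(stats::fft(z, inverse = TRUE)) / T
  })
  ts_matrix(matrix(filt, T, ncol(ts$values)), ts$node_labels, ts$tr_seconds)
}

#' Regress out the global signal
#'
#' Replaces every region by its residual after least-squares regression on
#' an intercept and the global signal.  When no global signal is supplied it
#' is estimated as the mean over the supplied regions at each time point
#' (no whole-brain mask is available at this stage of the pipeline).
#'
#' @param ts A [ts_matrix()].
#' @param global_signal Optional numeric vector of length T with nonzero
#'   variance; default `NULL` uses the row mean of `ts`.
#' @return A [ts_matrix()] of residuals, each uncorrelated with the global
#'   signal.
#' @export
remove_global_signal <- function(ts, global_signal = NULL) {
  stopifnot(inherits(ts, "ts_matrix"))
  T <- nrow(ts$values)
  if (is.null(global_signal)) global_signal <- rowMeans(ts$values)
  if (length(global_signal) != T)
    stop("global_signal must have one value per time point")
  if (stats::sd(global_signal) == 0)
    stop("global_signal is constant; cannot regress it out")
  res <- stats::lsfit(global_signal, ts$values)$residuals
  ts_matrix(matrix(res, T, ncol(ts$values)), ts$node_labels, ts$tr_seconds)
}

#' Temporal preprocessing pipeline
#'
#' Fixed-order composition: discard initial volumes, remove linear trends,
#' band-pass filter, regress out the global signal.
#'
#' @param ts A [ts_matrix()].
#' @param discard Leading volumes to drop (default 5).
#' @param f_lo,f_hi Band-pass edges in Hz (defaults 0.01 and 0.1).
#' @param gsr Apply global-signal removal (default TRUE).
#' @return Preprocessed [ts_matrix()].
#' @export
preprocess_pipeline <- function(ts, discard = 5, f_lo = 0.01, f_hi = 0.1,
                                gsr = TRUE) {
  out <- discard_initial(ts, discard)
  out <- detrend_linear(out)
  out <- bandpass(out, f_lo, f_hi)
  if (gsr) out <- remove_global_signal(out)
  out
}
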