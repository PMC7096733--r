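# Minimal per-session time-series cleaning: volume discard, Friston-24 motion
# regression with detrending, and ideal band-pass filtering. The fixed order
# is discard -> regress (+trend) -> bandpass; spatial smoothing applies only
# to metric maps (see smooth_map), never to the series.

#' Discard initial volumes
#'
#' Drops the first `k` volumes of a run (signal equilibration / adaptation
#' period).
#'
#' @param bold a [bold4d()].
#' @param k number of volumes to drop (default 10); must be < number of
#'   volumes - 1.
#' @return A [bold4d()] with `t - k` volumes.
#' @export
discard_initial <- function(bold, k = 10) {
  stopifnot(inherits(bold, "bold4d"))
  n_t <- n_timepoints(bold)
  if (k < 0) stop("`k` must be >= 0")
  if (k >= n_t) stop("cannot discard ", k, " of ", n_t, " volumes")
  if (k == 0) return(bold)
  bold4d(bold$data[, , , (k + 1):n_t, drop = FALSE], bold$tr_s,
         bold$voxel_size_mm)
}

#' Friston 24-parameter motion regressor set
#'
#' Expands six realignment parameters R(t) into 24 columns ordered
#' `[R(t), R(t-1), R(t)^2, R(t-1)^2]`, with the lagged block zero-padded at
#' the first row.
#'
#' @param motion data frame or matrix with 6 columns (3 translations in mm,
#'   3 rotations in radians) and one row per retained time point.
#' @return A t x 24 numeric matrix with labeled columns.
#' @export
friston24 <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) stop("motion table must have exactly 6 columns")
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag, m^2, lag^2)
  base <- if (!is.null(colnames(m))) colnames(m) else paste0("R", 1:6)
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lagsq"))
  out
}

#' Regress nuisance signals (and optionally a linear trend) out of a run
#'
#' Per voxel, ordinary-least-squares residuals on
#' `[intercept, linear trend (if flagged), nuisance columns]`. Collinear
#' columns are dropped with a warning; residuals are orthogonal to every
#' retained design column.
#'
#' @param bold a [bold4d()].
#' @param nuis nuisance matrix (t rows; e.g. [friston24()] output) or `NULL`.
#' @param include_trend add a linear trend column (detrending), default TRUE.
#' @return A [bold4d()] of residuals.
#' @export
regress_nuisance <- function(bold, nuis = NULL, include_trend = TRUE) {
  stopifnot(inherits(bold, "bold4d"))
  n_t <- n_timepoints(bold)
  X <- matrix(1, n_t, 1)
  if (include_trend) X <- cbind(X, seq_len(n_t) - (n_t + 1) / 2)
  if (!is.null(nuis) && NCOL(nuis) > 0) {
    nuis <- as.matrix(nuis)
    if (nrow(nuis) != n_t)
      stop("nuisance rows (", nrow(nuis), ") do not match time points (",
           n_t, ")")
    X <- cbind(X, nuis)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop_cols <- qrx$pivot[(qrx$rank + 1):ncol(X)]
    warning("dropping ", length(drop_cols),
            " collinear design column(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(X)
  }
  Y <- bold_matrix(bold)
  res <- qr.resid(qrx, Y)
  matrix_bold(res, bold)
}

# ideal frequency-domain band-pass on a t x V matrix; bins with
# low_hz <= |f| <= high_hz are kept, everything else (including DC) zeroed
fft_bandpass <- function(m, tr_s, low_hz, high_hz) {
  n_t <- nrow(m)
  f <- (seq_len(n_t) - 1) / (n_t * tr_s)
  f <- pmin(f, 1 / tr_s - f)             # fold to [0, Nyquist]
  keep <- f >= low_hz & f <= high_hz
  sp <- stats::mvfft(m)
  sp[!keep, ] <- 0
  Re(stats::mvfft(sp, inverse = TRUE)) / n_t
}

#' Ideal band-pass filter of a run
#'
#' Frequency-domain boxcar filter: Fourier bins inside `[low_hz, high_hz]` are
#' kept unchanged, all others (including the DC component) are zeroed.
#'
#' @param bold a [bold4d()].
#' @param low_hz,high_hz pass band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 tr_s)`.
#' @return Filtered [bold4d()].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(bold, "bold4d"))
  nyquist <- 1 / (2 * bold$tr_s)
  if (high_hz >= nyquist)
    stop("`high_hz` (", high_hz, ") must be below Nyquist (", nyquist, " Hz)")
  if (low_hz < 0 || low_hz >= high_hz)
    stop("need 0 <= low_hz < high_hz")
  Y <- fft_bandpass(bold_matrix(bold), bold$tr_s, low_hz, high_hz)
  matrix_bold(Y, bold)
}

#' Standard resting-state cleaning of one session
#'
#' Fixed order: discard initial volumes, regress the Friston-24 motion set
#' plus a linear trend, band-pass filter.
#'
#' @param bold a [bold4d()].
#' @param motion 6-column motion table aligned to the raw run.
#' @param discard number of initial volumes to drop.
#' @param low_hz,high_hz band-pass edges in Hz.
#' @return Cleaned [bold4d()].
#' @export
preprocess_rest <- function(bold, motion, discard = 10,
                            low_hz = 0.01, high_hz = 0.08) {
  bold <- discard_initial(bold, discard)
  motion <- as.matrix(motion)[(discard + 1):nrow(as.matrix(motion)), ,
                              drop = FALSE]
  bold <- regress_nuisance(bold, friston24(motion), include_trend = TRUE)
  bandpass(bold, low_hz, high_hz)
}
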