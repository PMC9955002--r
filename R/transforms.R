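#' Hann window (1-based convention, nonzero endpoints)
#'
#' Evaluates w(n) = 0.5 * (1 - cos(2 * pi * n / (N + 1))) for n = 1..N.
#' This is the "periodic-like" 1-based dialect in which both endpoints are
#' strictly positive; it differs from the common 0..N-1 convention whose
#' endpoints are exactly zero.
#'
#' @param N Window length in samples, >= 1.
#' @return Numeric vector of length `N`, values in (0, 1], symmetric:
#'   `w[n] == w[N + 1 - n]`.
#' @examples
#' hann_window(3)  # middle value is exactly 1
#' @export
hann_window <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || !is.finite(N) || N < 1 ||
      N != round(N)) {
    stop_seizr("'N' must be a positive integer", "seizr_error_invalid_argument")
  }
  n <- seq_len(N)
  0.5 * (1 - cos(2 * pi * n / (N + 1)))
}

windows_for_length <- function(n, W, H) {
  if (W > n) {
    stop_seizr(sprintf("segment of %d samples is shorter than one %d-sample window",
                       n, W),
               "seizr_error_short_segment")
  }
  starts <- seq.int(1L, n - W + 1L, by = H)
  cbind(start = starts, end = starts + W - 1L)
}

#' Moving-window index ranges over a segment
#'
#' Lays a grid of fixed-length analysis windows over a segment. The hop is
#' `round(W * (1 - overlap_pct / 100))` where `W = window_s * rate`; windows
#' that would overrun the end of the segment are dropped, so the count is
#' `floor((len - W) / H) + 1`.
#'
#' @param segment A [signal_segment()].
#' @param window_s Window length in seconds; `window_s * rate` must be a
#'   positive integer (the study grid uses 0.5 s and 1 s).
#' @param overlap_pct Percent overlap between consecutive windows. The study
#'   grid uses 0, 25 and 50; other values work but trigger a warning.
#' @return Integer matrix with columns `start`, `end` (1-based, inclusive),
#'   one row per window.
#' @export
segment_windows <- function(segment, window_s, overlap_pct = 0) {
  segment <- as_signal_segment(segment)
  W <- window_s * segment$sampling_rate_hz
  if (!is.finite(W) || W <= 0 || abs(W - round(W)) > 1e-8) {
    stop_seizr("'window_s' times the sampling rate must be a positive integer",
               "seizr_error_invalid_argument")
  }
  W <- as.integer(round(W))
  if (!is.numeric(overlap_pct) || length(overlap_pct) != 1 ||
      overlap_pct < 0 || overlap_pct >= 100) {
    stop_seizr("'overlap_pct' must be in [0, 100)",
               "seizr_error_invalid_argument")
  }
  if (!overlap_pct %in% c(0, 25, 50)) {
    warning("overlap_pct outside the standard {0, 25, 50} grid")
  }
  H <- max(1L, as.integer(round(W * (1 - overlap_pct / 100))))
  windows_for_length(length(segment$samples), W, H)
}

#' Short-time Fourier log-power spectrogram
#'
#' Discrete STFT with a per-frame taper and one-sided frequency axis from 0
#' to Nyquist. The DFT length equals the window length (no zero padding), so
#' bin k maps to frequency k * fs / N. Log power is computed as
#' `log(pmax(|X|^2, eps))`; the floor `eps` keeps silent frames finite.
#'
#' @param segment A [signal_segment()] (or numeric vector with
#'   `sampling_rate_hz` supplied via [signal_segment()]).
#' @param window Numeric taper vector, typically [hann_window()]; its length
#'   sets the frame length and must not exceed the segment length.
#' @param hop Hop between frame starts in samples (default: no overlap).
#' @param eps Floor applied to |X|^2 before the log. Default 1e-12.
#' @return An object of class `spectrogram`: complex `coef` (bins x frames),
#'   linear `power`, log-power `logpower`, `freq_hz`, `time_s`,
#'   `sampling_rate_hz` and `eps`.
#' @export
spectrogram <- function(segment, window, hop = length(window), eps = 1e-12) {
  segment <- as_signal_segment(segment)
  x <- segment$samples
  W <- length(window)
  if (W < 1 || W > length(x)) {
    stop_seizr("window length must be in [1, segment length]",
               "seizr_error_invalid_argument")
  }
  if (!is.numeric(hop) || hop < 1) {
    stop_seizr("'hop' must be >= 1", "seizr_error_invalid_argument")
  }
  idx <- windows_for_length(length(x), W, as.integer(round(hop)))
  nbin <- floor(W / 2) + 1L               # one-sided: DC .. Nyquist
  frames <- vapply(seq_len(nrow(idx)), function(i) {
    x[idx[i, "start"]:idx[i, "end"]] * window
  }, numeric(W))
  frames <- matrix(frames, nrow = W)
  cf <- stats::mvfft(frames)[seq_len(nbin), , drop = FALSE]
  pw <- Mod(cf)^2
  fs <- segment$sampling_rate_hz
  structure(
    list(coef = cf,
         power = pw,
         logpower = log(pmax(pw, eps)),
         freq_hz = (seq_len(nbin) - 1) * fs / W,
         time_s = (idx[, "start"] - 1 + (W - 1) / 2) / fs,
         sampling_rate_hz = fs,
         eps = eps),
    class = "spectrogram")
}

# ---------------------------------------------------------------------------
# MODWT

# Daubechies extremal-phase scaling filter with 4 vanishing moments
# (db4, L = 8 taps). Orthonormal DWT normalization: sum(g) = sqrt(2).
DB4_SCALING <- c(
   0.23037781330889650633,
   0.71484657055291567218,
   0.63088076792985892105,
  -0.027983769416859854279,
  -0.18703481171909308589,
   0.030841381835560763985,
   0.032883011666885196556,
  -0.010597401785069031702)

#' Wavelet filter bank
#'
#' Base DWT wavelet/scaling filter pair for the MODWT. Only the Daubechies
#' db4 filter (4 vanishing moments, 8 taps) is provided; it is the standard
#' choice for seizure EEG. The wavelet filter is the quadrature mirror of
#' the scaling filter: `h[l] = (-1)^l * g[L - 1 - l]` (0-based l).
#'
#' @param wavelet Filter name; only `"db4"` is supported.
#' @return An object of class `wavelet_filter_bank` with base filters `g`
#'   (scaling, sums to sqrt(2)) and `h` (wavelet, sums to 0), width `L`, and
#'   the MODWT-rescaled pair `g_modwt = g / sqrt(2)`, `h_modwt = h / sqrt(2)`.
#' @export
wavelet_filter_bank <- function(wavelet = "db4") {
  wavelet <- match.arg(wavelet, "db4")
  g <- DB4_SCALING
  L <- length(g)
  l <- seq_len(L) - 1
  h <- (-1)^l * rev(g)
  structure(
    list(wavelet = wavelet, g = g, h = h, L = L,
         g_modwt = g / sqrt(2), h_modwt = h / sqrt(2)),
    class = "wavelet_filter_bank")
}

modwt_filter_width <- function(L, j) (2^j - 1) * (L - 1) + 1

# One pyramid stage: circular filtering of v with the level-j stride
# 2^(j-1). Returns list(w, v) each the length of the input.
modwt_stage <- function(v, bank, j) {
  n <- length(v)
  stride <- 2^(j - 1)
  w_out <- numeric(n)
  v_out <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_len(bank$L) - 1L) {
    idx <- ((t0 - l * stride) %% n) + 1L
    w_out <- w_out + bank$h_modwt[l + 1L] * v[idx]
    v_out <- v_out + bank$g_modwt[l + 1L] * v[idx]
  }
  list(w = w_out, v = v_out)
}

# Inverse of one pyramid stage (time-reversed circular filtering).
imodwt_stage <- function(w, v, bank, j) {
  n <- length(v)
  stride <- 2^(j - 1)
  out <- numeric(n)
  t0 <- seq_len(n) - 1L
  for (l in seq_len(bank$L) - 1L) {
    idx <- ((t0 + l * stride) %% n) + 1L
    out <- out + bank$h_modwt[l + 1L] * w[idx] + bank$g_modwt[l + 1L] * v[idx]
  }
  out
}

#' Maximal-overlap discrete wavelet transform
#'
#' Undecimated, shift-invariant wavelet transform via the pyramid algorithm
#' with circular (periodic) boundary treatment. Every coefficient series has
#' the input's length, and with the 2^(-j/2) filter normalization the
#' transform conserves energy exactly:
#' sum_j ||W_j||^2 + ||V_J||^2 = ||X||^2.
#'
#' @param segment A [signal_segment()] or numeric vector.
#' @param bank A [wavelet_filter_bank()]; default db4.
#' @param J Number of decomposition levels, >= 1 (the pipeline uses 6, which
#'   at 400 Hz yields the seven bands D1..D6, A6).
#' @return An object of class `modwt_decomposition`: matrix `W` (N x J) of
#'   wavelet coefficients per level, vector `V` of level-J scaling
#'   coefficients, the input `x`, `J`, `bank`, and (after [modwt_mra()])
#'   detail matrix `D` and approximation `A`.
#' @seealso [modwt_mra()], [band_edges()]
#' @export
modwt <- function(segment, bank = wavelet_filter_bank("db4"), J = 6) {
  if (!inherits(bank, "wavelet_filter_bank")) {
    stop_seizr("'bank' must be a wavelet_filter_bank",
               "seizr_error_invalid_argument")
  }
  if (!is.numeric(J) || length(J) != 1 || J < 1 || J != round(J)) {
    stop_seizr("'J' must be a positive integer", "seizr_error_invalid_argument")
  }
  J <- as.integer(J)
  if (inherits(segment, "signal_segment")) {
    x <- segment$samples
  } else if (is.numeric(segment)) {
    x <- as.numeric(segment)
  } else {
    stop_seizr("'segment' must be a signal_segment or numeric vector",
               "seizr_error_invalid_argument")
  }
  n <- length(x)
  if (n < 2) {
    stop_seizr("input must have at least 2 samples",
               "seizr_error_invalid_argument")
  }
  if (n <= modwt_filter_width(bank$L, J)) {
    warning(sprintf(
      "input length %d does not exceed the level-%d filter width %d; circular boundary effects dominate",
      n, J, modwt_filter_width(bank$L, J)))
  }
  W <- matrix(0, nrow = n, ncol = J,
              dimnames = list(NULL, paste0("W", seq_len(J))))
  v <- x
  for (j in seq_len(J)) {
    st <- modwt_stage(v, bank, j)
    W[, j] <- st$w
    v <- st$v
  }
  structure(
    list(W = W, V = v, x = x, J = J, bank = bank, D = NULL, A = NULL),
    class = "modwt_decomposition")
}

#' Multiresolution analysis from a MODWT decomposition
#'
#' Fills in the per-level detail series D_j and the approximation A_J by
#' inverting the transform with all but one series zeroed. The series form
#' an additive decomposition of the input: sum_j D_j + A_J = X (to
#' round-off).
#'
#' @param dec A `modwt_decomposition` from [modwt()].
#' @param bank The filter bank used to produce `dec`; must match.
#' @return `dec` with `D` (N x J matrix, columns `D1..DJ`) and `A` filled.
#' @export
modwt_mra <- function(dec, bank = dec$bank) {
  if (!inherits(dec, "modwt_decomposition")) {
    stop_seizr("'dec' must come from modwt()", "seizr_error_invalid_argument")
  }
  if (!inherits(bank, "wavelet_filter_bank") ||
      !identical(bank$wavelet, dec$bank$wavelet)) {
    stop_seizr("filter bank does not match the one used for the decomposition",
               "seizr_error_invalid_argument")
  }
  n <- length(dec$x)
  J <- dec$J
  D <- matrix(0, nrow = n, ncol = J,
              dimnames = list(NULL, paste0("D", seq_len(J))))
  zero <- numeric(n)
  for (j in seq_len(J)) {
    # keep only W_j, cascade the inverse down to level 0
    d <- imodwt_stage(dec$W[, j], zero, bank, j)
    if (j > 1) {
      for (jj in seq.int(j - 1, 1)) d <- imodwt_stage(zero, d, bank, jj)
    }
    D[, j] <- d
  }
  a <- dec$V
  for (jj in seq.int(J, 1)) a <- imodwt_stage(zero, a, bank, jj)
  dec$D <- D
  dec$A <- a
  dec
}

#' Dyadic frequency bands of the MODWT series
#'
#' Maps each decomposition series to its nominal passband: detail D_j covers
#' `[fs / 2^(j+1), fs / 2^j]` and the approximation A_J covers
#' `[0, fs / 2^(J+1)]`. At 400 Hz with J = 6 this gives D1 = 100-200 Hz down
#' to A6 = 0-3.125 Hz.
#'
#' @param sampling_rate_hz Sampling rate in Hz, > 0.
#' @param J Number of levels, >= 1.
#' @return Data frame with columns `series` (`D1..DJ`, `AJ`), `low_hz`,
#'   `high_hz`.
#' @export
band_edges <- function(sampling_rate_hz, J) {
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop_seizr("'sampling_rate_hz' must be > 0", "seizr_error_invalid_argument")
  }
  if (!is.numeric(J) || length(J) != 1 || J < 1 || J != round(J)) {
    stop_seizr("'J' must be a positive integer", "seizr_error_invalid_argument")
  }
  j <- seq_len(J)
  data.frame(
    series = c(paste0("D", j), paste0("A", J)),
    low_hz = c(sampling_rate_hz / 2^(j + 1), 0),
    high_hz = c(sampling_rate_hz / 2^j, sampling_rate_hz / 2^(J + 1)),
    stringsAsFactors = FALSE)
}

#' @export
print.modwt_decomposition <- function(x, ...) {
  cat(sprintf("<modwt_decomposition> %s, J = %d, N = %d%s\n",
              x$bank$wavelet, x$J, length(x$x),
              if (is.null(x$D)) "" else ", MRA filled"))
  invisible(x)
}

# Coefficient series named the way the bands are reported: W1..WJ map to
# D1..DJ and V_J to A_J.
modwt_series_list <- function(dec) {
  out <- lapply(seq_len(dec$J), function(j) dec$W[, j])
  names(out) <- paste0("D", seq_len(dec$J))
  out[[paste0("A", dec$J)]] <- dec$V
  out
}
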