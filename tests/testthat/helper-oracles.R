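# Brute-force oracles, kept independent of the package's pyramid /
# vectorized code paths.

# Equivalent level-j MODWT filters built by cascading upsampled base
# filters (H_j(z) = H(z^(2^(j-1))) * prod G(z^(2^k))), then applied by
# direct circular convolution. No pyramid recursion.
oracle_upsample <- function(f, m) {
  if (m == 1) return(f)
  out <- numeric((length(f) - 1) * m + 1)
  out[seq(1, length(out), by = m)] <- f
  out
}

oracle_equiv_filters <- function(bank, J) {
  filts <- list()
  casc <- 1
  for (j in seq_len(J)) {
    filts[[paste0("h", j)]] <- convolve(oracle_upsample(bank$h_modwt, 2^(j - 1)),
                                        rev(casc), type = "open")
    filts[[paste0("g", j)]] <- convolve(oracle_upsample(bank$g_modwt, 2^(j - 1)),
                                        rev(casc), type = "open")
    casc <- filts[[paste0("g", j)]]
  }
  filts
}

oracle_circ_filter <- function(x, f) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    idx <- ((t - 1 - (seq_along(f) - 1)) %% n) + 1
    out[t] <- sum(f * x[idx])
  }
  out
}

oracle_modwt <- function(x, bank, J) {
  ef <- oracle_equiv_filters(bank, J)
  W <- sapply(seq_len(J), function(j) oracle_circ_filter(x, ef[[paste0("h", j)]]))
  list(W = W, V = oracle_circ_filter(x, ef[[paste0("g", J)]]))
}

# Plain-formula moment oracle (explicit loops, no vectorized reuse).
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(skew = m3 / m2^1.5, kurt = m4 / m2^2)
}

# One-vs-rest binary metrics straight from the formulas.
oracle_binary_metrics <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) 0 else a / b
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(sn = div(tp, tp + fn), sp = div(tn, tn + fp), pr = div(tp, tp + fp),
    ac = div(tp + tn, tp + tn + fp + fn), f1 = div(2 * tp, 2 * tp + fp + fn),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Fraction of one-sided periodogram power above cutoff (DC excluded).
highband_power_fraction_of <- function(seg, cutoff_hz = 25) {
  n <- length(seg$samples)
  p <- Mod(stats::fft(seg$samples))^2
  f <- (0:(n - 1)) * seg$sampling_rate_hz / n
  keep <- f <= seg$sampling_rate_hz / 2 & f > 0
  sum(p[keep & f > cutoff_hz]) / sum(p[keep])
}

make_sine_segment <- function(freq_hz, fs = 400, dur = 4, amp = 1) {
  t <- (seq_len(fs * dur) - 1) / fs
  signal_segment(amp * sin(2 * pi * freq_hz * t), fs)
}
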