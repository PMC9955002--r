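test_that("hann window follows the 1-based cosine formula and is symmetric", {
  expect_equal(hann_window(3)[2], 1.0)
  expect_equal(round(hann_window(4), 4), c(0.3455, 0.9045, 0.9045, 0.3455))
  for (N in c(1, 2, 7, 200)) {
    w <- hann_window(N)
    expect_equal(w, rev(w))
    expect_true(all(w > 0 & w <= 1))
  }
  expect_error(hann_window(0), class = "seizr_error_invalid_argument")
})

test_that("segment_windows produces the floor((len-W)/H)+1 grid", {
  seg <- signal_segment(seq_len(1600), 400)
  expect_equal(nrow(segment_windows(seg, 0.5, 50)), 15)
  expect_equal(nrow(segment_windows(seg, 0.5, 0)), 8)
  expect_equal(nrow(segment_windows(seg, 1, 25)), 5)  # W=400, H=300
  w <- segment_windows(seg, 0.5, 50)
  expect_true(all(w[, "end"] - w[, "start"] == 199))
  expect_true(all(w[, "end"] <= 1600))
  short <- signal_segment(seq_len(100), 400)
  expect_error(segment_windows(short, 0.5, 0),
               class = "seizr_error_short_segment")
  expect_warning(segment_windows(seg, 0.5, 10), "grid")
})

test_that("spectrogram localizes tones and floors silent frames", {
  # DC
  dc <- signal_segment(rep(1, 800), 400)
  sp <- spectrogram(dc, hann_window(200))
  expect_true(all(apply(sp$power, 2, which.max) == 1))
  # 10 Hz tone: arg-max bin at 10 Hz (bin width 2 Hz), >= 80 % of frame
  # power within +/- 2 bins
  s10 <- make_sine_segment(10)
  sp <- spectrogram(s10, hann_window(200), hop = 100)
  peak <- apply(sp$power, 2, which.max)
  expect_true(all(sp$freq_hz[peak] == 10))
  for (fr in seq_len(ncol(sp$power))) {
    pk <- peak[fr]
    band <- max(1, pk - 2):min(nrow(sp$power), pk + 2)
    expect_gte(sum(sp$power[band, fr]) / sum(sp$power[, fr]), 0.8)
  }
  # silence: everything at the log floor, no NaN/Inf
  z <- spectrogram(signal_segment(rep(0, 400), 400), hann_window(200))
  expect_true(all(is.finite(z$logpower)))
  expect_true(all(z$logpower == log(1e-12)))
  expect_equal(z$freq_hz[1], 0)
  expect_equal(z$freq_hz[length(z$freq_hz)], 200)
})

test_that("db4 filter bank satisfies the quadrature-mirror identities", {
  bank <- wavelet_filter_bank("db4")
  expect_equal(bank$L, 8)
  expect_equal(sum(bank$g), sqrt(2), tolerance = 1e-14)
  expect_equal(sum(bank$h), 0, tolerance = 1e-14)
  expect_equal(sum(bank$g^2), 1, tolerance = 1e-14)
  # orthogonality to even shifts
  expect_lt(abs(sum(bank$g[1:6] * bank$g[3:8])), 1e-14)
})

test_that("modwt matches the direct circular-convolution oracle", {
  bank <- wavelet_filter_bank("db4")
  set.seed(42)
  for (n in c(128, 512)) {
    x <- rnorm(n)
    J <- if (n >= 512) 6 else 3
    dec <- suppressWarnings(modwt(x, bank, J))
    orc <- oracle_modwt(x, bank, J)
    expect_lt(max(abs(dec$W - orc$W)), 1e-10)
    expect_lt(max(abs(dec$V - orc$V)), 1e-10)
  }
})

test_that("modwt conserves energy and annihilates constants", {
  set.seed(7)
  x <- rnorm(1024)
  dec <- modwt(x, J = 6)
  expect_equal(sum(dec$W^2) + sum(dec$V^2), sum(x^2), tolerance = 1e-10)
  # impulse
  xi <- c(1, rep(0, 255))
  di <- suppressWarnings(modwt(xi, J = 6))
  expect_equal(sum(di$W^2) + sum(di$V^2), 1, tolerance = 1e-10)
  # constant: wavelet filters sum to zero
  dc <- suppressWarnings(modwt(rep(3.7, 256), J = 6))
  expect_lt(max(abs(dc$W)), 1e-10)
})

test_that("MRA reconstructs the signal additively", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(64:1024, 1)
    J <- sample(1:6, 1)
    x <- rnorm(n)
    dec <- suppressWarnings(modwt_mra(modwt(x, J = J)))
    expect_lt(max(abs(x - rowSums(dec$D) - dec$A)), 1e-8)
  }
  # constant signal: approximation carries everything
  dc <- suppressWarnings(modwt_mra(modwt(rep(2, 300), J = 4)))
  expect_lt(max(abs(dc$A - 2)), 1e-8)
  expect_lt(max(abs(dc$D)), 1e-8)
})

test_that("a 10 Hz tone concentrates in the D5 (6.25-12.5 Hz) band", {
  dec <- modwt_mra(modwt(make_sine_segment(10)))
  energies <- colSums(dec$D^2)
  expect_equal(unname(which.max(energies)), 5)
})

test_that("band_edges maps levels to dyadic bands", {
  be <- band_edges(400, 6)
  expect_equal(be$series, c("D1", "D2", "D3", "D4", "D5", "D6", "A6"))
  expect_equal(be[be$series == "D1", c("low_hz", "high_hz")],
               data.frame(low_hz = 100, high_hz = 200, row.names = 1L))
  expect_equal(be$high_hz[be$series == "A6"], 3.125)
  expect_equal(be$low_hz[be$series == "A6"], 0)
  be2 <- band_edges(2, 1)
  expect_equal(be2$low_hz[1], 0.5)
  expect_equal(be2$high_hz[1], 1)
})

test_that("modwt validates arguments and warns on short inputs", {
  expect_error(modwt(rnorm(100), J = 0), class = "seizr_error_invalid_argument")
  expect_warning(modwt(rnorm(100), J = 6), "filter width")
  dec <- modwt(rnorm(1024), J = 3)
  expect_error(modwt_mra(dec, bank = list()),
               class = "seizr_error_invalid_argument")
})
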