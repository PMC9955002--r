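test_that("sample_moments implements the population estimators", {
  expect_equal(sample_moments(c(-1, 0, 1))$skewness, 0)
  m <- sample_moments(c(0, 0, 0, 1))
  expect_equal(round(m$skewness, 4), 1.1547)
  expect_equal(m$mean, 0.25)
  expect_equal(m$sd, sqrt(0.1875))
  # excess flag shifts kurtosis by 3
  expect_equal(sample_moments(c(0, 0, 0, 1), excess = TRUE)$kurtosis,
               m$kurtosis - 3)
  expect_error(sample_moments(rep(2, 10)), class = "seizr_error_degenerate")
  expect_error(sample_moments(1), class = "seizr_error_invalid_argument")
})

test_that("large-sample Gaussian kurtosis approaches 3 (non-excess)", {
  set.seed(123)
  expect_equal(sample_moments(rnorm(1e6))$kurtosis, 3, tolerance = 0.02 / 3)
})

test_that("moments agree with a direct-summation oracle and obey Pearson", {
  set.seed(11)
  for (i in 1:200) {
    x <- switch(1 + i %% 4,
                rnorm(sample(5:200, 1)),
                rexp(sample(5:200, 1)),
                runif(sample(5:200, 1)),
                rt(sample(5:200, 1), df = 3))
    m <- sample_moments(x)
    o <- oracle_moments(x)
    expect_equal(m$skewness, unname(o["skew"]), tolerance = 1e-12)
    expect_equal(m$kurtosis, unname(o["kurt"]), tolerance = 1e-12)
    expect_gte(m$kurtosis, m$skewness^2 + 1 - 1e-12)
  }
})

test_that("spectral_shape reproduces hand-computed centroid moments", {
  expect_equal(spectral_shape(c(1, 1), c(0, 1))$skewness, 0)
  s <- spectral_shape(c(3, 1), c(0, 1))
  expect_equal(s$centroid, 0.25)
  expect_equal(round(s$spread, 4), 0.4330)
  expect_equal(round(s$skewness, 4), 1.1547)
  expect_error(spectral_shape(c(0, 5, 0), c(1, 2, 3)),
               class = "seizr_error_degenerate")
  expect_error(spectral_shape(numeric(0), numeric(0)),
               class = "seizr_error_invalid_argument")
})

test_that("temporal features: finite on noise, degenerate on constants", {
  set.seed(5)
  seg <- signal_segment(rnorm(1600), 400)
  tf <- temporal_features(seg, window_config(0.5, 50))
  expect_true(all(is.finite(tf)))
  expect_lt(abs(tf[["skew"]]), 0.5)
  expect_identical(tf, temporal_features(seg, window_config(0.5, 50)))
  expect_error(temporal_features(signal_segment(rep(1, 1600), 400)),
               class = "seizr_error_feature")
})

test_that("spectral features of white noise are near-symmetric; tones do not yield NaN", {
  set.seed(6)
  sk <- replicate(50, spectral_features(
    signal_segment(rnorm(1600), 400), window_config(0.5, 50))[["skew"]])
  expect_lt(abs(median(sk)), 0.3)
  # pure tone: taper leakage keeps the spread positive; must stay finite
  sf <- spectral_features(make_sine_segment(10), window_config(0.5, 50))
  expect_true(all(is.finite(sf)))
})

test_that("wavelet features give (J+1) moment pairs and fail on constants", {
  set.seed(8)
  wf <- wavelet_features(signal_segment(rnorm(1600), 400),
                         window_config(0.5, 50))
  expect_length(wf, 14)
  expect_true(all(is.finite(wf)))
  expect_named(wf, c(paste0("wavelet_skew_", c(paste0("D", 1:6), "A6")),
                     paste0("wavelet_kurt_", c(paste0("D", 1:6), "A6"))))
  wf5 <- wavelet_features(signal_segment(rnorm(1600), 400),
                          window_config(0.5, 50), include_approx = FALSE)
  expect_length(wf5, 12)
  expect_error(wavelet_features(signal_segment(rep(1, 1600), 400)),
               class = "seizr_error_feature")
})

test_that("extract_feature_table assembles the full column contract", {
  segs <- simulate_dataset(dataset_spec(c(TCSZ = 3, CPSZ = 3, EGSZ = 3),
                                        seed = 2))
  ft <- extract_feature_table(segs, window_config(0.5, 50))
  expect_equal(dim(ft), c(9, 2 + 2 + 2 + 14))
  expect_true(!anyNA(ft))
  expect_equal(sort(unique(ft$label)), c("CPSZ", "EGSZ", "TCSZ"))
  # wavelet-only selection
  ftw <- extract_feature_table(segs, window_config(0.5, 50),
                               domains = "wavelet")
  expect_equal(ncol(ftw), 2 + 14)
  # a constant segment is excluded and reported, not emitted
  segs2 <- c(segs[1:8], list(signal_segment(rep(0.5, 1600), 400, "flat",
                                            "TCSZ")))
  ft2 <- extract_feature_table(segs2, window_config(0.5, 50))
  expect_equal(nrow(ft2), 8)
  expect_equal(attr(ft2, "excluded")$channel_id, "flat")
})

test_that("feature extraction is deterministic and permutation-equivariant", {
  segs <- simulate_dataset(dataset_spec(c(TCSZ = 2, CPSZ = 2, EGSZ = 2),
                                        seed = 4))
  a <- extract_feature_table(segs, window_config(1, 0))
  b <- extract_feature_table(segs, window_config(1, 0))
  expect_identical(a, b)
  perm <- c(4, 1, 6, 2, 5, 3)
  p <- extract_feature_table(segs[perm], window_config(1, 0))
  reord <- p[match(a$channel_id, p$channel_id), ]
  rownames(reord) <- NULL
  attr(reord, "window_config") <- attr(a, "window_config")
  attr(reord, "excluded") <- attr(a, "excluded")
  expect_equal(reord, a)
})

test_that("the window/overlap study grid runs end-to-end", {
  segs <- simulate_dataset(dataset_spec(c(TCSZ = 2, CPSZ = 2, EGSZ = 2),
                                        seed = 12))
  for (w in c(0.5, 1)) for (o in c(0, 25, 50)) {
    ft <- extract_feature_table(segs, window_config(w, o))
    expect_equal(nrow(ft), 6)
    expect_equal(ncol(ft), 20)
  }
})

test_that("select_features subsets one domain/moment block", {
  segs <- simulate_dataset(dataset_spec(c(TCSZ = 2, CPSZ = 2, EGSZ = 2),
                                        seed = 3))
  ft <- extract_feature_table(segs, window_config(0.5, 50))
  ws <- select_features(ft, "wavelet", "skew")
  expect_equal(ncol(ws), 9)
  expect_true(all(grepl("^wavelet_skew_", setdiff(names(ws),
                                                  c("channel_id", "label")))))
  ts <- select_features(ft, "temporal", "kurt")
  expect_equal(ncol(ts), 3)
})
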