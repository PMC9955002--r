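#' Population skewness and kurtosis of a sample
#'
#' Third and fourth standardized moments with population (biased)
#' estimators: mu = mean(x), sigma = sqrt(mean((x - mu)^2)),
#' SK = mean((x - mu)^3) / sigma^3, KU = mean((x - mu)^4) / sigma^4.
#' Kurtosis is non-excess (a Gaussian gives 3); subtract 3 via
#' `excess = TRUE` if the zero-centred convention is wanted. No
#' small-sample bias correction is applied.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param excess If `TRUE`, report kurtosis - 3.
#' @return List with `skewness`, `kurtosis`, `mean`, `sd`. Always satisfies
#'   the Pearson bound `kurtosis >= skewness^2 + 1` (non-excess).
#' @examples
#' sample_moments(c(0, 0, 0, 1))$skewness  # 1.1547
#' @export
sample_moments <- function(values, excess = FALSE) {
  if (!is.numeric(values) || length(values) < 2) {
    stop_seizr("'values' must be numeric with length >= 2",
               "seizr_error_invalid_argument")
  }
  if (!all(is.finite(values))) {
    stop_seizr("'values' must be finite", "seizr_error_invalid_argument")
  }
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  if (m2 <= 0) {
    stop_seizr("degenerate sample: zero variance", "seizr_error_degenerate")
  }
  s <- sqrt(m2)
  list(skewness = mean(d^3) / s^3,
       kurtosis = mean(d^4) / m2^2 - if (excess) 3 else 0,
       mean = mu,
       sd = s)
}

moments_or_null <- function(values, excess = FALSE) {
  tryCatch(sample_moments(values, excess = excess),
           seizr_error_degenerate = function(e) NULL)
}

#' Windowing configuration for feature extraction
#'
#' @param window_s Analysis window length in seconds; the study grid uses
#'   0.5 and 1.
#' @param overlap_pct Window overlap percent; the study grid uses 0, 25, 50.
#' @param taper Taper applied in spectral estimation; only `"hann"`.
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_s = 0.5, overlap_pct = 50, taper = "hann") {
  taper <- match.arg(taper, "hann")
  if (!is.numeric(window_s) || window_s <= 0) {
    stop_seizr("'window_s' must be > 0", "seizr_error_invalid_argument")
  }
  structure(list(window_s = window_s, overlap_pct = overlap_pct,
                 taper = taper),
            class = "window_config")
}

# Mean of per-window moments over a series; NULL if every window is
# degenerate. Returns c(skew, kurt) with attributes n_windows, n_dropped.
windowed_moments <- function(x, idx, excess = FALSE) {
  ms <- lapply(seq_len(nrow(idx)), function(i) {
    moments_or_null(x[idx[i, "start"]:idx[i, "end"]], excess = excess)
  })
  keep <- !vapply(ms, is.null, logical(1))
  if (!any(keep)) return(NULL)
  ms <- ms[keep]
  out <- c(skew = mean(vapply(ms, `[[`, numeric(1), "skewness")),
           kurt = mean(vapply(ms, `[[`, numeric(1), "kurtosis")))
  attr(out, "n_windows") <- length(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Temporal skewness and kurtosis of a segment
#'
#' Moments of the raw sample distribution within each moving window,
#' averaged over windows. The samples are deliberately left untapered:
#' multiplying a sample distribution by a taper would distort the very
#' moments being measured, so the Hann taper is reserved for spectral
#' estimation.
#'
#' @param segment A [signal_segment()].
#' @param cfg A [window_config()].
#' @return Named numeric vector `c(skew, kurt)` with window-count
#'   attributes.
#' @export
temporal_features <- function(segment, cfg = window_config()) {
  segment <- as_signal_segment(segment)
  idx <- segment_windows(segment, cfg$window_s, cfg$overlap_pct)
  out <- windowed_moments(segment$samples, idx)
  if (is.null(out)) {
    stop_seizr("all temporal windows degenerate (constant signal?)",
               "seizr_error_feature")
  }
  out
}

#' Spectral shape moments about the centroid
#'
#' Power-weighted moments of frequency: centroid mu1 = sum(f * s) / sum(s),
#' spread mu2 = sqrt(sum((f - mu1)^2 * s) / sum(s)), skewness
#' sum((f - mu1)^3 * s) / (mu2^3 * sum(s)) and the analogous fourth-moment
#' kurtosis. `s` is a linear power spectrum over the band `b1..b2`.
#'
#' @param s Nonnegative spectral values s_k over the band.
#' @param f Frequencies f_k (Hz) of the same length.
#' @return List with `centroid`, `spread`, `skewness`, `kurtosis`.
#' @examples
#' spectral_shape(c(3, 1), c(0, 1))$skewness  # 1.1547
#' @export
spectral_shape <- function(s, f) {
  if (length(s) != length(f) || length(s) < 2) {
    stop_seizr("'s' and 'f' must be equal-length vectors (>= 2 bins)",
               "seizr_error_invalid_argument")
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    stop_seizr("spectral values must be finite and nonnegative",
               "seizr_error_invalid_argument")
  }
  tot <- sum(s)
  if (tot <= 0 || sum(s > 0) < 2) {
    stop_seizr("degenerate spectrum: fewer than 2 bins with power",
               "seizr_error_degenerate")
  }
  mu1 <- sum(f * s) / tot
  mu2 <- sqrt(sum((f - mu1)^2 * s) / tot)
  if (mu2 <= 0) {
    stop_seizr("degenerate spectrum: zero spread", "seizr_error_degenerate")
  }
  list(centroid = mu1,
       spread = mu2,
       skewness = sum((f - mu1)^3 * s) / (mu2^3 * tot),
       kurtosis = sum((f - mu1)^4 * s) / (mu2^4 * tot))
}

#' Spectral skewness and kurtosis of a segment
#'
#' Per analysis window: Hann-tapered one-sided power spectrum (linear
#' power, DFT length = window length), band = all bins in (0, fs/2]
#' excluding DC; [spectral_shape()] moments; then the mean across windows.
#' Windows whose spectrum is degenerate (fewer than two bins with power)
#' are dropped and counted, never emitted as NaN.
#'
#' @inheritParams temporal_features
#' @return Named numeric vector `c(skew, kurt)` with window-count
#'   attributes.
#' @export
spectral_features <- function(segment, cfg = window_config()) {
  segment <- as_signal_segment(segment)
  idx <- segment_windows(segment, cfg$window_s, cfg$overlap_pct)
  W <- idx[1, "end"] - idx[1, "start"] + 1L
  taper <- hann_window(W)
  nbin <- floor(W / 2) + 1L
  fs <- segment$sampling_rate_hz
  f <- (seq_len(nbin) - 1) * fs / W
  band <- 2:nbin                        # exclude DC
  shapes <- lapply(seq_len(nrow(idx)), function(i) {
    xw <- segment$samples[idx[i, "start"]:idx[i, "end"]] * taper
    pw <- Mod(stats::fft(xw)[seq_len(nbin)])^2
    tryCatch(spectral_shape(pw[band], f[band]),
             seizr_error_degenerate = function(e) NULL)
  })
  keep <- !vapply(shapes, is.null, logical(1))
  if (!any(keep)) {
    stop_seizr("all spectral windows degenerate", "seizr_error_feature")
  }
  shapes <- shapes[keep]
  out <- c(skew = mean(vapply(shapes, `[[`, numeric(1), "skewness")),
           kurt = mean(vapply(shapes, `[[`, numeric(1), "kurtosis")))
  attr(out, "n_windows") <- length(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-level wavelet skewness and kurtosis of a segment
#'
#' MODWT at `J` levels on the full segment; each coefficient series
#' (W1..WJ, reported under its band name D1..DJ, plus the scaling series
#' A_J) is then windowed with `cfg` and the per-window moments averaged,
#' giving `J + 1` skewness and `J + 1` kurtosis values per channel.
#'
#' @inheritParams temporal_features
#' @param bank A [wavelet_filter_bank()].
#' @param J Decomposition levels (default 6).
#' @param include_approx Include the scaling series A_J (default `TRUE`).
#' @return Named numeric vector `wavelet_skew_D1..`, `wavelet_kurt_D1..`.
#'   Any fully degenerate level is reported as `NA` and flagged via the
#'   `dropped_levels` attribute; a segment degenerate at every level is an
#'   error.
#' @export
wavelet_features <- function(segment, cfg = window_config(),
                             bank = wavelet_filter_bank("db4"), J = 6,
                             include_approx = TRUE) {
  segment <- as_signal_segment(segment)
  idx <- segment_windows(segment, cfg$window_s, cfg$overlap_pct)
  dec <- modwt(segment, bank = bank, J = J)
  series <- modwt_series_list(dec)
  if (!include_approx) series[[paste0("A", J)]] <- NULL
  per_level <- lapply(series, windowed_moments, idx = idx)
  if (all(vapply(per_level, is.null, logical(1)))) {
    stop_seizr("all wavelet coefficient series degenerate",
               "seizr_error_feature")
  }
  sk <- vapply(per_level, function(m) if (is.null(m)) NA_real_ else m[["skew"]],
               numeric(1))
  ku <- vapply(per_level, function(m) if (is.null(m)) NA_real_ else m[["kurt"]],
               numeric(1))
  out <- c(stats::setNames(sk, paste0("wavelet_skew_", names(series))),
           stats::setNames(ku, paste0("wavelet_kurt_", names(series))))
  attr(out, "dropped_levels") <- names(series)[vapply(per_level, is.null,
                                                      logical(1))]
  out
}

#' Extract a labeled feature table from segments
#'
#' Runs the requested feature domains over every segment and assembles one
#' row per channel. Segments whose extraction fails (e.g. a constant
#' channel) are excluded and reported in the `excluded` attribute rather
#' than emitted as NaN rows.
#'
#' @param segments List of [signal_segment()]s.
#' @param cfg A [window_config()].
#' @param domains Subset of `c("temporal", "spectral", "wavelet")`.
#' @param bank,J Passed to [wavelet_features()].
#' @return Data frame with columns `channel_id`, `label`, then the feature
#'   columns (`temporal_skew`, `temporal_kurt`, `spectral_skew`,
#'   `spectral_kurt`, `wavelet_skew_D1` .. `wavelet_kurt_A6` depending on
#'   `domains`). Attributes: `window_config`, `excluded` (data frame of
#'   channel_id / reason).
#' @export
extract_feature_table <- function(segments, cfg = window_config(),
                                  domains = c("temporal", "spectral",
                                              "wavelet"),
                                  bank = wavelet_filter_bank("db4"), J = 6) {
  domains <- match.arg(domains, c("temporal", "spectral", "wavelet"),
                       several.ok = TRUE)
  if (length(segments) < 1) {
    stop_seizr("'segments' must be non-empty", "seizr_error_invalid_argument")
  }
  rows <- list()
  excluded <- list()
  for (seg in segments) {
    seg <- as_signal_segment(seg)
    feats <- tryCatch({
      parts <- list()
      if ("temporal" %in% domains) {
        tf <- temporal_features(seg, cfg)
        parts$temporal <- stats::setNames(as.numeric(tf),
                                          paste0("temporal_", names(tf)))
      }
      if ("spectral" %in% domains) {
        sf <- spectral_features(seg, cfg)
        parts$spectral <- stats::setNames(as.numeric(sf),
                                          paste0("spectral_", names(sf)))
      }
      if ("wavelet" %in% domains) {
        wf <- wavelet_features(seg, cfg, bank = bank, J = J)
        if (anyNA(wf)) {
          stop_seizr("degenerate wavelet level", "seizr_error_feature")
        }
        parts$wavelet <- wf
      }
      unlist(parts, use.names = TRUE)
    }, seizr_error = function(e) e)
    if (inherits(feats, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(channel_id = seg$channel_id,
                   reason = conditionMessage(feats),
                   stringsAsFactors = FALSE)
      next
    }
    names(feats) <- sub("^(temporal|spectral|wavelet)\\.", "", names(feats))
    row <- data.frame(channel_id = seg$channel_id,
                      label = if (is.null(seg$label)) NA_character_ else
                        seg$label,
                      stringsAsFactors = FALSE)
    row <- cbind(row, as.data.frame(as.list(feats)))
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) {
    stop_seizr("feature extraction failed for every segment",
               "seizr_error_pipeline")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window_config") <- cfg
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(channel_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Select one feature set from a feature table
#'
#' Subsets a feature table to the columns of a single domain/moment
#' combination (the unit compared across window configurations, e.g.
#' "wavelet skewness" = the 7 per-level skewness columns).
#'
#' @param table A feature table from [extract_feature_table()].
#' @param domain One of `"temporal"`, `"spectral"`, `"wavelet"`.
#' @param moment One of `"skew"`, `"kurt"`.
#' @return The table restricted to `channel_id`, `label` and the matching
#'   feature columns.
#' @export
select_features <- function(table, domain = c("wavelet", "temporal",
                                              "spectral"),
                            moment = c("skew", "kurt")) {
  domain <- match.arg(domain)
  moment <- match.arg(moment)
  pat <- paste0("^", domain, "_", moment)
  cols <- grep(pat, names(table), value = TRUE)
  if (length(cols) == 0) {
    stop_seizr(sprintf("no '%s %s' columns in table", domain, moment),
               "seizr_error_invalid_argument")
  }
  out <- table[, c("channel_id", "label", cols), drop = FALSE]
  attr(out, "window_config") <- attr(table, "window_config")
  out
}
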