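#' Quality-control configuration
#'
#' Windows and thresholds for the four per-spectrum QC metrics. Defaults:
#' amide-I signal window 1600-1700 cm^-1; noise window 1800-1900 cm^-1 with
#' fallback 2000-2200 cm^-1; spike and fingerprint windows 900-1800 cm^-1;
#' spike z threshold 6; cosine review threshold 0.99.
#'
#' @param signal_window,noise_window,fallback_noise_window,spike_window,fingerprint_window
#'   Length-2 numeric windows in cm^-1.
#' @param z_threshold Positive spike z-score threshold.
#' @param cosine_flag_threshold Samples with cosine-to-median below this are
#'   flagged for review.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(signal_window = c(1600, 1700),
                      noise_window = c(1800, 1900),
                      fallback_noise_window = c(2000, 2200),
                      spike_window = c(900, 1800),
                      fingerprint_window = c(900, 1800),
                      z_threshold = 6,
                      cosine_flag_threshold = 0.99) {
  stopifnot(z_threshold > 0)
  win <- function(w) { stopifnot(length(w) == 2, w[1] < w[2]); as.numeric(w) }
  structure(list(signal_window = win(signal_window),
                 noise_window = win(noise_window),
                 fallback_noise_window = win(fallback_noise_window),
                 spike_window = win(spike_window),
                 fingerprint_window = win(fingerprint_window),
                 z_threshold = z_threshold,
                 cosine_flag_threshold = cosine_flag_threshold),
            class = "qc_config")
}

window_values <- function(y, grid, w) {
  idx <- which(grid >= w[1] & grid <= w[2])
  list(y = unname(y[idx]), grid = grid[idx], idx = idx)
}

# SD of residuals after linear detrend; NA when fewer than 3 points.
detrended_sd <- function(y, x) {
  if (length(y) < 3) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, x), y)
  stats::sd(fit$residuals)
}

#' Amide-I signal-to-noise ratio
#'
#' Numerator: maximum of the rubber-band-corrected spectrum inside the
#' signal window. Denominator: SD of residuals after linear detrending in
#' the noise window; if that is degenerate (< 1e-12 or too few points) the
#' fallback noise window is used; if still degenerate the value is `Inf`
#' with a `"degenerate_snr"` flag.
#'
#' @param y Numeric spectrum.
#' @param grid Ascending wavenumber vector.
#' @param cfg A [qc_config()].
#' @return List with `value` (ratio) and `flag` (`NA` or flag name).
#' @export
amide_snr <- function(y, grid, cfg = qc_config()) {
  sw <- window_values(y, grid, cfg$signal_window)
  if (length(sw$y) < 2) stop("signal window is empty on this grid")
  corrected <- rubberband_baseline(sw$y, sw$grid)$corrected
  num <- max(corrected)
  nw <- window_values(y, grid, cfg$noise_window)
  den <- detrended_sd(nw$y, nw$grid)
  if (is.na(den) || den < 1e-12) {
    fw <- window_values(y, grid, cfg$fallback_noise_window)
    den <- detrended_sd(fw$y, fw$grid)
    if (is.na(den) || den < 1e-12) {
      return(list(value = Inf, flag = "degenerate_snr"))
    }
  }
  list(value = num / den, flag = NA_character_)
}

#' Robust spike-event count
#'
#' First differences of the in-window spectrum are z-scored against their
#' median using the Gaussian-consistent MAD (scale factor 1.4826);
#' differences with `|z|` above the threshold are flagged, and runs of
#' consecutive flagged difference indices merge into one event (a
#' single-point spike produces two adjacent large differences and counts
#' once). A zero MAD (perfectly smooth signal, e.g. a linear ramp) returns
#' zero events with a `"degenerate_mad"` flag.
#'
#' @inheritParams amide_snr
#' @return List with `value` (event count) and `flag`.
#' @export
spike_event_count <- function(y, grid, cfg = qc_config()) {
  w <- window_values(y, grid, cfg$spike_window)
  if (length(w$y) < 3) stop("spike window needs at least 3 grid points")
  d <- diff(w$y)
  s <- stats::mad(d)           # 1.4826 * median absolute deviation
  if (s == 0) return(list(value = 0L, flag = "degenerate_mad"))
  z <- (d - stats::median(d)) / s
  flagged <- abs(z) > cfg$z_threshold
  events <- sum(flagged & !c(FALSE, flagged[-length(flagged)]))
  list(value = as.integer(events), flag = NA_character_)
}

#' Cosine similarity to the cohort median profile
#'
#' Each spectrum is restricted to the fingerprint window and scaled to unit
#' Euclidean norm; the reference is the pointwise median of the normalized
#' cohort, and each similarity is the cosine between a normalized spectrum
#' and that reference. Values are bounded in `[-1, 1]` and invariant to
#' positive per-spectrum scaling.
#'
#' @param x A [spectrum_set()] with at least two samples.
#' @param cfg A [qc_config()].
#' @return Named numeric vector of similarities, one per sample.
#' @export
cosine_similarity_profile <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "spectrum_set"))
  if (nrow(x$intensities) < 2) {
    stop("cosine similarity needs >= 2 samples (median reference undefined)")
  }
  xs <- restrict_windows(x, windows(cfg$fingerprint_window))
  m <- vector_normalize(xs$intensities, ids = x$sample_ids)
  ref <- apply(m, 2, stats::median)
  rn <- sqrt(sum(ref^2))
  if (rn == 0) stop("zero-norm median reference in fingerprint window")
  sims <- as.numeric(m %*% ref) / rn
  names(sims) <- x$sample_ids
  pmin(pmax(sims, -1), 1)
}

#' Baseline-area fraction
#'
#' Rubber-band baseline estimated inside the fingerprint window; returns
#' `100 * area(baseline) / area(raw)` with areas by trapezoidal
#' integration. A compact index of how much of the raw in-window area is
#' baseline drift rather than informative structure.
#'
#' @inheritParams amide_snr
#' @return Percentage (numeric scalar).
#' @export
baseline_area_fraction <- function(y, grid, cfg = qc_config()) {
  w <- window_values(y, grid, cfg$fingerprint_window)
  if (length(w$y) < 3) stop("fingerprint window needs at least 3 grid points")
  raw_area <- pracma::trapz(w$grid, w$y)
  if (raw_area <= 0) {
    stop("nonpositive raw area in fingerprint window; shift absorbance ",
         "nonnegative before computing the baseline fraction")
  }
  bl <- rubberband_baseline(w$y, w$grid)$baseline
  100 * pracma::trapz(w$grid, bl) / raw_area
}

#' Per-sample QC report
#'
#' Computes all four QC metrics for every sample and attaches review flags:
#' `low_cosine` (similarity below the configured threshold),
#' `degenerate_snr` / `degenerate_mad` (sentinel metric states), and
#' `outlier_<metric>` for samples whose metric robust z-score
#' (median/MAD across the cohort) exceeds 3.5 in absolute value. Flags are
#' advisory: no sample is ever dropped automatically, so downstream
#' analyses stay free of post hoc exclusion bias.
#'
#' @param x A [spectrum_set()] with at least two samples.
#' @param cfg A [qc_config()].
#' @return A data.frame of class `qc_report` with one row per sample:
#'   `sample_id`, `snr`, `spike_count`, `cosine_to_median`,
#'   `baseline_fraction_pct`, `flags` (semicolon-joined, `""` if none).
#' @export
build_qc_report <- function(x, cfg = qc_config()) {
  stopifnot(inherits(x, "spectrum_set"))
  n <- nrow(x$intensities)
  if (n < 2) stop("QC report needs >= 2 samples (median reference undefined)")
  grid <- x$wavenumbers
  snr <- numeric(n); spikes <- integer(n); basefrac <- numeric(n)
  flags <- vector("list", n)
  for (i in seq_len(n)) {
    flags[[i]] <- character(0)
    s <- amide_snr(x$intensities[i, ], grid, cfg)
    snr[i] <- s$value
    if (!is.na(s$flag)) flags[[i]] <- c(flags[[i]], s$flag)
    sp <- spike_event_count(x$intensities[i, ], grid, cfg)
    spikes[i] <- sp$value
    if (!is.na(sp$flag)) flags[[i]] <- c(flags[[i]], sp$flag)
    basefrac[i] <- baseline_area_fraction(x$intensities[i, ], grid, cfg)
  }
  cosine <- cosine_similarity_profile(x, cfg)
  for (i in seq_len(n)) {
    if (cosine[i] < cfg$cosine_flag_threshold) {
      flags[[i]] <- c(flags[[i]], "low_cosine")
    }
  }
  metrics <- list(snr = snr, spike_count = as.numeric(spikes),
                  cosine_to_median = as.numeric(cosine),
                  baseline_fraction_pct = basefrac)
  for (mname in names(metrics)) {
    v <- metrics[[mname]]
    ok <- is.finite(v)
    if (sum(ok) >= 3) {
      s <- stats::mad(v[ok])
      if (s > 0) {
        z <- (v - stats::median(v[ok])) / s
        out <- which(ok & abs(z) > 3.5)
        for (i in out) flags[[i]] <- c(flags[[i]], paste0("outlier_", mname))
      }
    }
  }
  rep <- data.frame(sample_id = x$sample_ids, snr = snr,
                    spike_count = spikes, cosine_to_median = as.numeric(cosine),
                    baseline_fraction_pct = basefrac,
                    flags = vapply(flags, function(f) paste(unique(f), collapse = ";"),
                                   character(1)),
                    stringsAsFactors = FALSE)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d samples, %d flagged\n", nrow(x),
              sum(nzchar(x$flags))))
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' Group summary of QC metrics
#'
#' Median `[IQR]` and mean +/- SD per metric, overall and (when labels are
#' present) per class, in the layout customarily used for cohort QC tables.
#'
#' @param object A `qc_report`.
#' @param labels Optional 0/1 label vector aligned with the report rows.
#' @param ... Unused.
#' @return A data.frame of formatted summaries.
#' @export
summary.qc_report <- function(object, labels = NULL, ...) {
  fmt <- function(v) {
    v <- v[is.finite(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.3g [%.3g-%.3g] | %.3g +/- %.3g", q[2], q[1], q[3],
            mean(v), stats::sd(v))
  }
  metrics <- c("snr", "spike_count", "cosine_to_median", "baseline_fraction_pct")
  out <- data.frame(metric = metrics,
                    overall = vapply(metrics, function(m) fmt(object[[m]]), character(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    for (g in sort(unique(labels))) {
      out[[paste0("class_", g)]] <-
        vapply(metrics, function(m) fmt(object[[m]][labels == g]), character(1))
    }
  }
  rownames(out) <- NULL
  out
}
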