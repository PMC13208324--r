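#' Default serum-like band table
#'
#' Gaussian band parameters emulating a dried-serum mid-IR absorbance
#' profile: dominant amide I/II protein bands, amide III, carbohydrate /
#' glycoprotein fingerprint contributions, CH-stretch lipid bands and the
#' broad N-H/amide A envelope. Class contrast (`class_delta`) is planted in
#' three regions where serum discriminant information is typically reported:
#' the carbohydrate band block (~946-1161 cm^-1), the amide III region
#' (~1300 cm^-1) and the C-H/N-H stretching region (~2865-3163 cm^-1).
#'
#' @param effect_scale Multiplier applied to every `class_delta` (0 gives a
#'   pure-noise null cohort; 1 the default "strong effect" condition).
#' @return A data.frame with columns `center`, `width` (Gaussian sigma,
#'   cm^-1), `amplitude` and `class_delta` (absorbance units added for the
#'   positive class).
#' @export
default_band_table <- function(effect_scale = 1) {
  b <- data.frame(
    center      = c(1655, 1545, 1300, 1050, 1160,  960, 2852, 2925, 2960, 3075, 3290),
    width       = c(  25,   22,   28,   45,   20,   18,   14,   16,   12,   30,   80),
    amplitude   = c(1.00, 0.62, 0.22, 0.30, 0.12, 0.08, 0.25, 0.38, 0.30, 0.15, 0.55),
    class_delta = c(0,    0,    0.045, 0.052, 0,  0.030, 0,   0.045, 0,   0.038, 0)
  )
  b$class_delta <- b$class_delta * effect_scale
  if (any(b$width <= 0) || any(b$amplitude < 0)) stop("invalid band table")
  b
}

#' Ground-truth configuration for a synthetic dried-serum FTIR cohort
#'
#' Collects every parameter of the generative model: the Gaussian band table
#' (composition + planted class effect), the artifact model (multiplicative
#' film-thickness gain, convex quadratic baseline drift, white noise,
#' sparse single-point spikes), the acquisition grid and the design size.
#' The random generator is R's default Mersenne-Twister; `seed` is required
#' so that a cohort is exactly reproducible.
#'
#' @param seed Integer seed (required).
#' @param n_per_class Samples per class (default 12, emulating a balanced
#'   12 vs 12 case-control design).
#' @param bands Band table as from [default_band_table()].
#' @param effect_scale Convenience multiplier forwarded to
#'   [default_band_table()] when `bands` is not supplied.
#' @param grid_from,grid_to,grid_by Wavenumber grid (default 400-4000 cm^-1
#'   at 2 cm^-1 spacing).
#' @param baseline_range 3x2 matrix of `[min, max]` for the baseline
#'   coefficients `(intercept, slope, curvature)` on the normalized
#'   coordinate `t in [-1, 1]`; curvature is kept nonnegative so the drift
#'   is convex.
#' @param gain_range Length-2 positive range of the multiplicative gain.
#' @param noise_sd Standard deviation of additive white noise (absorbance).
#' @param spike_rate Expected number of single-point spikes per spectrum
#'   (Poisson).
#' @param spike_amplitude_range Length-2 range of spike amplitudes.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed,
                            n_per_class = 12,
                            bands = default_band_table(effect_scale),
                            effect_scale = 1,
                            grid_from = 400, grid_to = 4000, grid_by = 2,
                            baseline_range = rbind(intercept = c(0.00, 0.05),
                                                   slope     = c(-0.04, 0.04),
                                                   curvature = c(0.00, 0.08)),
                            gain_range = c(0.95, 1.05),
                            noise_sd = 0.004,
                            spike_rate = 2,
                            spike_amplitude_range = c(0.05, 0.4)) {
  if (missing(seed)) stop("seed is a required field")
  seed <- as.integer(seed)
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  if (any(gain_range <= 0) || gain_range[1] > gain_range[2]) {
    stop("gain_range must be positive and ordered")
  }
  baseline_range <- as.matrix(baseline_range)
  if (nrow(baseline_range) != 3 || any(baseline_range[, 1] > baseline_range[, 2])) {
    stop("invalid baseline_range")
  }
  if (any(baseline_range[3, ] < 0)) {      # third row = quadratic coefficient
    stop("curvature range must be nonnegative (convex drift)")
  }
  if (spike_amplitude_range[1] > spike_amplitude_range[2]) stop("invalid spike_amplitude_range")
  structure(list(seed = seed, n_per_class = as.integer(n_per_class),
                 bands = bands,
                 grid = seq(grid_from, grid_to, by = grid_by),
                 baseline_range = baseline_range, gain_range = gain_range,
                 noise_sd = noise_sd, spike_rate = spike_rate,
                 spike_amplitude_range = spike_amplitude_range),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: seed %d, %d per class, grid [%g, %g] @ %g cm^-1\n",
              x$seed, x$n_per_class, min(x$grid), max(x$grid),
              stats::median(diff(x$grid))))
  cat(sprintf("  %d bands (%d carrying class effect), noise_sd %g, spike_rate %g\n",
              nrow(x$bands), sum(x$bands$class_delta != 0), x$noise_sd, x$spike_rate))
  invisible(x)
}

#' Clean band profile for one class
#'
#' Sum of Gaussian bands; for class 1 each band amplitude is shifted by its
#' `class_delta`. An empty band table yields the zero vector.
#'
#' @param grid Ascending wavenumber vector.
#' @param bands Band table (see [default_band_table()]).
#' @param class_label 0 or 1.
#' @return Numeric vector, nonnegative.
#' @export
band_profile <- function(grid, bands, class_label = 0) {
  stopifnot(class_label %in% c(0, 1))
  y <- numeric(length(grid))
  if (is.null(bands) || nrow(bands) == 0) return(y)
  for (k in seq_len(nrow(bands))) {
    amp <- bands$amplitude[k] + class_label * bands$class_delta[k]
    y <- y + amp * exp(-0.5 * ((grid - bands$center[k]) / bands$width[k])^2)
  }
  pmax(y, 0)
}

# Evaluate the convex baseline for coefficients (a0, a1, a2) on t in [-1, 1].
baseline_poly <- function(grid, coeffs) {
  t <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  coeffs[1] + coeffs[2] * t + coeffs[3] * t^2
}

#' Corrupt a clean spectrum with acquisition artifacts
#'
#' Applies, in order: multiplicative gain, additive convex quadratic
#' baseline, white Gaussian noise, and a Poisson number of single-grid-point
#' additive spikes. All realized parameters are returned so the exact
#' corrupted spectrum can be rebuilt from the record alone
#' (see [rebuild_spectrum()]).
#'
#' @param clean Numeric clean spectrum on `truth$grid`.
#' @param truth A [synthetic_truth()].
#' @param n_spikes Optional forced spike count (overrides the Poisson draw).
#' @return List with `spectrum` (corrupted vector) and `params` (gain,
#'   baseline coefficients, noise seed, spike indices and amplitudes).
#' @export
corrupt_spectrum <- function(clean, truth, n_spikes = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  gain <- stats::runif(1, truth$gain_range[1], truth$gain_range[2])
  coeffs <- stats::runif(3, truth$baseline_range[, 1], truth$baseline_range[, 2])
  noise_seed <- sample.int(.Machine$integer.max, 1L)
  n <- length(clean)
  set.seed(noise_seed)
  noise <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else numeric(n)
  k <- if (is.null(n_spikes)) stats::rpois(1, truth$spike_rate) else as.integer(n_spikes)
  spike_idx <- if (k > 0) sort(sample.int(n, k)) else integer(0)
  spike_amp <- if (k > 0) stats::runif(k, truth$spike_amplitude_range[1],
                                       truth$spike_amplitude_range[2]) else numeric(0)
  out <- gain * clean + baseline_poly(truth$grid, coeffs) + noise
  out[spike_idx] <- out[spike_idx] + spike_amp
  list(spectrum = out,
       params = list(gain = gain, baseline_coeffs = coeffs,
                     noise_seed = noise_seed,
                     spike_idx = spike_idx, spike_amp = spike_amp))
}

#' Rebuild a corrupted spectrum from its sidecar record
#'
#' @param truth A [synthetic_truth()].
#' @param class_label 0 or 1.
#' @param params One `params` record as produced by [corrupt_spectrum()].
#' @return The corrupted spectrum, bit-identical to the original draw.
#' @export
rebuild_spectrum <- function(truth, class_label, params) {
  clean <- band_profile(truth$grid, truth$bands, class_label)
  n <- length(clean)
  set.seed(params$noise_seed)
  noise <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else numeric(n)
  out <- params$gain * clean + baseline_poly(truth$grid, params$baseline_coeffs) + noise
  out[params$spike_idx] <- out[params$spike_idx] + params$spike_amp
  out
}

#' Generate a labeled synthetic dried-serum FTIR cohort
#'
#' Deterministic under `truth$seed`: the same truth object always yields a
#' bit-identical cohort. Labels are balanced (`n_per_class` of each class);
#' the returned sidecar stores every planted parameter and per-sample
#' realized artifact draws.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `set` (a labeled [spectrum_set()]) and `sidecar`
#'   (the truth object plus per-sample artifact records).
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(truth$seed)
  n <- 2L * truth$n_per_class
  labels <- rep(c(0L, 1L), each = truth$n_per_class)
  mat <- matrix(0, nrow = n, ncol = length(truth$grid))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    clean <- band_profile(truth$grid, truth$bands, labels[i])
    cs <- corrupt_spectrum(clean, truth)
    mat[i, ] <- cs$spectrum
    records[[i]] <- cs$params
  }
  ids <- sprintf("SYN%02d", seq_len(n))
  set <- spectrum_set(truth$grid, mat, sample_ids = ids, labels = labels)
  list(set = set,
       sidecar = list(truth = truth, labels = labels, sample_ids = ids,
                      samples = records))
}
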