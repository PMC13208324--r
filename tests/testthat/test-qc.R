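grid_full <- seq(400, 4000, by = 2)

test_that("amide SNR recovers a constructed signal/noise ratio", {
  # flat spectrum with a triangular amide-I peak of height 100 and a noise
  # window whose detrended residual SD is known
  y <- numeric(length(grid_full))
  sig <- grid_full >= 1600 & grid_full <= 1700
  y[sig] <- 100 * pmax(0, 1 - abs(grid_full[sig] - 1650) / 50)
  nw <- which(grid_full >= 1800 & grid_full <= 1900)
  set.seed(4)
  noise <- rnorm(length(nw))
  noise <- noise - mean(noise)
  fit <- lm(noise ~ grid_full[nw])
  y[nw] <- residuals(fit)            # detrended residual sd == sd(residuals)
  expected <- 100 / sd(residuals(fit))
  got <- amide_snr(y, grid_full)
  expect_equal(got$value, expected, tolerance = 1e-9)
  expect_true(is.na(got$flag))
})

test_that("degenerate noise windows fall back, then flag", {
  y <- numeric(length(grid_full))
  sig <- grid_full >= 1600 & grid_full <= 1700        # triangular signal
  y[sig] <- 10 * pmax(0, 1 - abs(grid_full[sig] - 1650) / 50)
  # noise window constant (sd 0); fallback window has known sd
  fw <- which(grid_full >= 2000 & grid_full <= 2200)
  set.seed(7)
  y[fw] <- rnorm(length(fw), sd = 1)
  got <- amide_snr(y, grid_full)
  expect_equal(got$value, 10 / oracle_detrended_sd(y[fw], grid_full[fw]),
               tolerance = 1e-9)
  flat <- numeric(length(grid_full))
  got2 <- amide_snr(flat, grid_full)
  expect_identical(got2$value, Inf)
  expect_identical(got2$flag, "degenerate_snr")
})

test_that("spike events count merged runs of flagged first differences", {
  y <- 0.1 * sin(grid_full / 50)        # smooth signal: bounded |z| everywhere
  expect_equal(spike_event_count(y, grid_full)$value, 0)
  ys <- y
  ys[grid_full == 1200] <- ys[grid_full == 1200] + 1e6   # one-point spike
  got <- spike_event_count(ys, grid_full)
  expect_equal(got$value, 1L)   # two adjacent large differences merge
  # linear ramp: constant first difference, MAD = 0
  ramp <- seq_along(grid_full) * 0.01
  got2 <- spike_event_count(ramp, grid_full)
  expect_equal(got2$value, 0L)
  expect_identical(got2$flag, "degenerate_mad")
})

test_that("cosine similarity handles identity, orthogonality and hand values", {
  g <- c(1000, 1100)
  same <- spectrum_set(g, matrix(rep(c(1, 2), 4), nrow = 4, byrow = TRUE))
  expect_equal(unname(cosine_similarity_profile(same)), rep(1, 4),
               tolerance = 1e-12)
  # u = (1,1,0) against median (1,0,0): 1/sqrt(2)
  g3 <- c(1000, 1100, 1200)
  m <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 0, 0))
  s3 <- spectrum_set(g3, m)
  sims <- cosine_similarity_profile(s3)
  expect_equal(unname(sims[1]), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(
    cosine_similarity_profile(spectrum_set(g3, m[1, , drop = FALSE])),
    ">= 2 samples")
})

test_that("cosine similarity is invariant to positive per-spectrum scaling", {
  coh <- make_cohort(seed = 5, n_per_class = 4)
  base <- cosine_similarity_profile(coh$set)
  scaled <- coh$set
  scaled$intensities[2, ] <- 3 * scaled$intensities[2, ]
  expect_equal(cosine_similarity_profile(scaled), base, tolerance = 1e-12)
})

test_that("baseline fraction hits its closed forms", {
  g <- seq(900, 1800, by = 2)
  line <- 2 + 0.001 * (g - 900)
  expect_equal(baseline_area_fraction(line, g), 100, tolerance = 1e-9)
  peak <- exp(-0.5 * ((g - 1350) / 40)^2)
  expect_lt(baseline_area_fraction(peak, g), 0.5)
  # Gaussian (area a) on constant offset c: 100 * cL / (cL + a)
  cst <- 0.2
  yy <- cst + peak
  L <- max(g) - min(g)
  a <- oracle_trapz(g, peak)
  expect_equal(baseline_area_fraction(yy, g),
               100 * (cst * L) / (cst * L + a), tolerance = 0.2)
  expect_error(baseline_area_fraction(-peak, g), "nonpositive")
})

test_that("all four QC metrics match naive brute-force recomputations", {
  set.seed(12)
  coh <- make_cohort(seed = 12, n_per_class = 4, spike_rate = 3)
  m <- coh$set$intensities
  g <- coh$set$wavenumbers
  cos_oracle <- oracle_cosine_profile(m, g)
  for (i in seq_len(nrow(m))) {
    expect_equal(amide_snr(m[i, ], g)$value, oracle_snr(m[i, ], g),
                 tolerance = 1e-9)
    expect_equal(spike_event_count(m[i, ], g)$value,
                 oracle_spike_count(m[i, ], g))
    expect_equal(baseline_area_fraction(m[i, ], g),
                 unname(oracle_baseline_fraction(m[i, ], g)), tolerance = 1e-9)
  }
  expect_equal(unname(cosine_similarity_profile(coh$set)), cos_oracle,
               tolerance = 1e-9)
})

test_that("QC report flags a noise-replaced sample but never drops it", {
  clean <- make_cohort(seed = 9, n_per_class = 6, noise_sd = 0.001,
                       spike_rate = 0,
                       baseline_range = rbind(c(0, 0.01), c(0, 0.01), c(0, 0.01)))
  rep_clean <- build_qc_report(strip_labels(clean$set))
  expect_identical(unique(rep_clean$flags), "")
  coh <- make_cohort(seed = 9, n_per_class = 6)
  rep0 <- build_qc_report(strip_labels(coh$set))
  expect_equal(nrow(rep0), 12)
  bad <- coh$set
  set.seed(1)
  bad$intensities[3, ] <- abs(rnorm(ncol(bad$intensities), sd = 0.05)) + 0.01
  rep1 <- build_qc_report(strip_labels(bad))
  expect_match(rep1$flags[3], "low_cosine")
  expect_equal(nrow(rep1), 12)                 # report-only, nothing excluded
  one <- coh$set[1]
  expect_error(build_qc_report(one), ">= 2 samples")
})

test_that("QC summary reports overall and per-class rows", {
  coh <- make_cohort(seed = 2, n_per_class = 3)
  rep <- build_qc_report(strip_labels(coh$set))
  s <- summary(rep, labels = as.integer(coh$set$labels))
  expect_equal(nrow(s), 4)
  expect_true(all(c("overall", "class_0", "class_1") %in% colnames(s)))
})
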