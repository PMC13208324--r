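test_that("rubber band corrects a concave peak to zero endpoints", {
  g <- seq(1000, 1200, by = 2)
  y <- 0.3 + exp(-0.5 * ((g - 1100) / 25)^2)
  rb <- rubberband_baseline(y, g)
  expect_equal(rb$corrected[1], 0)
  expect_equal(rb$corrected[length(g)], 0)
  expect_true(all(rb$baseline <= y + 1e-12))
  expect_true(all(rb$corrected >= 0))
  # equal endpoints: baseline is the straight chord
  expect_equal(rb$baseline, rep(y[1], length(g)), tolerance = 1e-9)
})

test_that("a convex spectrum lies on its own lower hull", {
  g <- seq(900, 1100, by = 2)
  y <- (g - 1000)^2 / 1e4
  rb <- rubberband_baseline(y, g)
  expect_equal(rb$baseline, y, tolerance = 1e-10)
  expect_equal(rb$corrected, numeric(length(g)), tolerance = 1e-10)
})

test_that("rubber band equals the brute-force hull oracle on random spectra", {
  for (s in 1:10) {
    set.seed(s)
    g <- sort(runif(200, 400, 4000))
    y <- cumsum(rnorm(200, sd = 0.05)) + 0.3 * sin(g / 100)
    rb <- rubberband_baseline(y, g)
    oracle <- oracle_rubberband(g, y)
    expect_lt(max(abs(rb$baseline - oracle$baseline)), 1e-10)
    expect_lt(max(abs(rb$corrected - pmax(oracle$corrected, 0))), 1e-10)
  }
})

test_that("re-correcting a corrected spectrum leaves endpoints at zero", {
  g <- seq(600, 1900, by = 2)
  set.seed(3)
  y <- abs(cumsum(rnorm(length(g), sd = 0.02))) + 0.1
  once <- rubberband_baseline(y, g)$corrected
  twice <- rubberband_baseline(once, g)$corrected
  expect_equal(twice[1], 0)
  expect_equal(twice[length(g)], 0)
})

test_that("vector normalization scales rows to unit norm and is idempotent", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  m <- matrix(rnorm(50, sd = 3), nrow = 5)
  nm <- vector_normalize(m)
  expect_equal(unname(sqrt(rowSums(nm^2))), rep(1, 5), tolerance = 1e-12)
  expect_equal(vector_normalize(nm), nm, tolerance = 1e-12)
  bad <- rbind(c(1, 1), c(0, 0))
  rownames(bad) <- c("ok", "empty")
  expect_error(vector_normalize(bad), "empty")
})

test_that("savgol is exact for low-degree polynomials including edges", {
  g <- seq(1000, 1200, by = 2)
  quad <- g^2
  d2 <- savgol_derivative(quad, g, order = 2, window_pts = 15, deriv = 2)
  expect_equal(d2, rep(2, length(g)), tolerance = 1e-9)
  lin <- 5 * g + 3
  expect_equal(savgol_derivative(lin, g, deriv = 2),
               rep(0, length(g)), tolerance = 1e-9)
  expect_equal(savgol_derivative(lin, g, deriv = 1),
               rep(5, length(g)), tolerance = 1e-9)
  # deriv = 0 reproduces any degree <= 2 polynomial exactly
  p2 <- 0.5 * g^2 - 7 * g + 2
  expect_lt(max(abs(savgol_derivative(p2, g, deriv = 0) - p2)), 1e-9)
})

test_that("savgol first derivative tracks the analytic derivative of a sine", {
  g <- seq(1000, 1600, by = 2)
  y <- sin(g / 40)
  d1 <- savgol_derivative(y, g, deriv = 1)
  analytic <- cos(g / 40) / 40
  # bound from an independent finite-difference oracle: a quadratic fit over
  # a window attenuates a sinusoid like a wide central difference; the edge
  # values extrapolate the terminal fits, so the worst-case effective span
  # is the full window width
  h <- 2
  span <- 14 * h
  fd <- (sin((g + span) / 40) - sin((g - span) / 40)) / (2 * span)
  bound <- max(abs(fd - analytic)) * 1.2
  expect_lt(max(abs(d1 - analytic)), bound)
  interior <- 8:(length(g) - 7)
  fd7 <- (sin((g + 7 * h) / 40) - sin((g - 7 * h) / 40)) / (14 * h)
  expect_lt(max(abs(d1 - analytic)[interior]),
            max(abs(fd7 - analytic)) * 1.2)
})

test_that("savgol refuses non-uniform grids and short segments", {
  g <- c(seq(600, 640, by = 2), seq(700, 740, by = 2))
  y <- rnorm(length(g))
  expect_error(savgol_derivative(y, g), "non-uniform")
  expect_error(savgol_derivative(y[1:5], g[1:5], window_pts = 15), "window_pts")
  expect_error(savgol_derivative(y, g, window_pts = 4), "odd")
})

test_that("atmospheric mask interpolates across the CO2 and water-vapor regions", {
  g <- seq(1700, 2500, by = 2)
  y <- 0.001 * g            # linear: interpolation fixed point
  expect_equal(atmospheric_mask(y, g), y, tolerance = 1e-12)
  y2 <- y
  y2[g == 2350] <- y2[g == 2350] + 5
  masked <- atmospheric_mask(y2, g)
  expect_equal(masked[g == 2350], 0.001 * 2350, tolerance = 1e-9)
  # grid with no points in the mask regions: identity
  g3 <- seq(600, 900, by = 2)
  y3 <- rnorm(length(g3))
  expect_equal(atmospheric_mask(y3, g3), y3)
})

test_that("pipelines compose steps in declared order and record provenance", {
  coh <- make_cohort(seed = 4, n_per_class = 3)
  idcfg <- preprocess_config(steps = list(), windows = windows(c(400, 4000)))
  expect_equal(apply_preprocess(coh$set, idcfg)$intensities,
               coh$set$intensities)
  cfg <- preprocess_config(
    steps = list(list(name = "savgol", deriv = 2), "vector_normalize"),
    windows = default_windows(), window_stage = "before")
  auto <- apply_preprocess(coh$set, cfg)
  # manual composition of the two ops on the restricted set
  man <- restrict_windows(coh$set, default_windows())
  segs <- grid_segments(man$wavenumbers)
  mm <- man$intensities
  for (sg in segs) {
    mm[, sg] <- savgol_derivative(mm[, sg, drop = FALSE], man$wavenumbers[sg],
                                  deriv = 2)
  }
  mm <- vector_normalize(mm)
  expect_equal(unname(auto$intensities), unname(mm), tolerance = 1e-12)
  expect_match(auto$meta$preprocess, "savgol")
})

test_that("window stage before vs after agree when windows span the grid", {
  coh <- make_cohort(seed = 6, n_per_class = 2)
  full <- windows(c(400, 4000))
  a <- apply_preprocess(coh$set, preprocess_config(
    steps = list("vector_normalize"), windows = full, window_stage = "before"))
  b <- apply_preprocess(coh$set, preprocess_config(
    steps = list("vector_normalize"), windows = full, window_stage = "after"))
  expect_equal(a$intensities, b$intensities, tolerance = 1e-15)
})

test_that("pipelines are deterministic and variants resolve by name", {
  coh <- make_cohort(seed = 8, n_per_class = 2)
  cfg <- preprocess_variant("sg2_norm")
  expect_identical(apply_preprocess(coh$set, cfg)$intensities,
                   apply_preprocess(coh$set, cfg)$intensities)
  expect_error(preprocess_variant("nope"), "unknown variant")
  for (v in preprocess_variant_names()) {
    expect_s3_class(preprocess_variant(v), "preprocess_config")
  }
})
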