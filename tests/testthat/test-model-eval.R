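test_that("equal-frequency discretization follows the averaging quantile convention", {
  d <- equal_frequency_discretize(1:8, n_bins = 4)
  expect_equal(d$cuts, c(2.5, 4.5, 6.5))
  expect_equal(as.integer(table(d$codes)), rep(2L, 4))
  # boundary contract: below all cuts -> first code; above all -> last code
  d2 <- equal_frequency_discretize(c(-100, 100), n_bins = 4, fit = 1:8)
  expect_equal(d2$codes, c(1L, 4L))
  cst <- equal_frequency_discretize(rep(7, 10), n_bins = 4)
  expect_true(cst$constant)
  expect_equal(unique(cst$codes), 1L)
})

test_that("symmetric uncertainty matches closed forms and a brute-force oracle", {
  x <- rep(c(0, 1), each = 8)
  expect_equal(symmetric_uncertainty(x, x), 1)
  xi <- rep(c(0, 0, 1, 1), 4)
  yi <- rep(c(0, 1, 0, 1), 4)               # all four cells equal: independent
  expect_equal(symmetric_uncertainty(xi, yi), 0)
  # joint counts (7,1; 2,6)
  xj <- c(rep(0, 8), rep(1, 8))
  yj <- c(rep(0, 7), 1, 0, 0, rep(1, 6))
  expect_equal(symmetric_uncertainty(xj, yj), oracle_su(xj, yj),
               tolerance = 1e-10)
  expect_error(symmetric_uncertainty(1:3, 1:4), "equal length")
  expect_equal(symmetric_uncertainty(rep(1, 5), rep(2, 5)), 0)  # both constant
})

test_that("FCBF keeps the informative feature and prunes its copy", {
  set.seed(42)
  y <- rep(c(0L, 1L), each = 12)
  f1 <- y + 1L                      # identical to the label
  f2 <- f1                          # redundant copy
  f3 <- sample(1:4, 24, replace = TRUE)
  codes <- cbind(f1, f2, f3)
  sel <- fcbf_select(codes, y, n_bins = 4)
  expect_equal(sel$selected[1], 1L)
  expect_false(2L %in% sel$selected)        # predominated by f1
  single <- fcbf_select(cbind(f1), y, n_bins = 4)
  expect_equal(single$selected, 1L)
  none <- fcbf_select(cbind(rep(1L, 24), rep(2L, 24)), y, n_bins = 4)
  expect_length(none$selected, 0)
})

test_that("FCBF equals the exhaustive predominance oracle on random code sets", {
  for (s in 1:12) {
    set.seed(s)
    n <- 24
    y <- rep(c(0L, 1L), each = n / 2)
    p <- sample(4:8, 1)
    codes <- matrix(sample(1:4, n * p, replace = TRUE), n, p)
    codes[, 1] <- pmin(4L, y * 2L + sample(1:2, n, replace = TRUE)) # informative
    got <- fcbf_select(codes, y, n_bins = 4)$selected
    expect_equal(got, oracle_fcbf(codes, y))
  }
})

test_that("gaussian NB reproduces closed-form posteriors", {
  x <- matrix(c(-1 - 0.1, -1 + 0.1, 1 - 0.1, 1 + 0.1), ncol = 1)
  y <- c(0, 0, 1, 1)
  nb <- gaussian_nb(x, y)
  p <- predict(nb, matrix(0, 1, 1))
  expect_equal(unname(p[1, "1"]), 0.5, tolerance = 1e-9)   # symmetric point
  # test point at a class mean, far (>= 10 SD) from the other class
  x2 <- matrix(c(rnorm(10, 0, 0.5), rnorm(10, 20, 0.5)), ncol = 1)
  y2 <- rep(c(0, 1), each = 10)
  nb2 <- gaussian_nb(x2, y2)
  expect_gt(predict(nb2, matrix(20, 1, 1))[1, "1"], 0.999)
  # rows sum to one on random fixtures
  set.seed(2)
  x3 <- matrix(rnorm(60), 20, 3)
  y3 <- rep(c(0, 1), 10)
  nb3 <- gaussian_nb(x3, y3)
  post <- predict(nb3, matrix(rnorm(30), 10, 3))
  expect_equal(rowSums(post), rep(1, 10), tolerance = 1e-12)
  expect_error(gaussian_nb(x3, rep(0, 20)), "both classes")
})

test_that("gaussian NB agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- matrix(rnorm(80), 20, 4)
  y <- rep(c(0, 1), each = 10)
  x[y == 1, ] <- x[y == 1, ] + 1
  mine <- predict(gaussian_nb(x, y), x)[, "1"]
  ref <- e1071::naiveBayes(data.frame(x), factor(y))
  theirs <- predict(ref, data.frame(x), type = "raw")[, "1"]
  expect_equal(mine, unname(theirs), tolerance = 1e-6)
})

test_that("AUC and confusion metrics match hand values and the pair oracle", {
  m <- classification_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(m$auc, 0.75)
  perfect <- classification_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$accuracy, 1)
  ties <- classification_metrics(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(ties$auc, 0.5)                       # midrank convention
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:40, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)                          # force some ties
    expect_equal(classification_metrics(p, y)$auc, oracle_auc(p, y))
  }
  expect_error(classification_metrics(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC agrees with pROC on a random fixture", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rep(c(0, 1), each = 15)
  p <- runif(30) + 0.3 * y
  expect_equal(classification_metrics(p, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("LOOCV yields one out-of-fold probability per sample", {
  coh <- make_cohort(seed = 13)
  cv <- nb_loocv(coh$set, preprocess = preprocess_variant("sg2_norm"))
  expect_equal(nrow(cv$oof), 24)
  expect_false(anyNA(cv$oof$prob))
  expect_true(all(cv$oof$prob >= 0 & cv$oof$prob <= 1))
  expect_length(cv$selected_wavenumbers, 24)
  # per-fold selections come only from that fold's training data: removing
  # the held-out sample's value cannot be checked directly, but selections
  # must vary across folds on noisy data (identical selections everywhere
  # would suggest a shared fit)
  expect_gt(length(unique(sapply(cv$selected_wavenumbers, paste, collapse = ","))), 1)
})

test_that("metrics are invariant to sample order", {
  coh <- make_cohort(seed = 17, n_per_class = 6)
  cv1 <- nb_loocv(coh$set, preprocess = preprocess_variant("sg2"))
  perm <- sample(seq_len(12))
  shuffled <- coh$set[perm]
  cv2 <- nb_loocv(shuffled, preprocess = preprocess_variant("sg2"))
  expect_equal(cv1$metrics$auc, cv2$metrics$auc, tolerance = 1e-12)
  expect_equal(sort(cv1$oof$prob), sort(cv2$oof$prob), tolerance = 1e-12)
})

test_that("reliability bins and Brier score match hand computations", {
  rb <- reliability_and_brier(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(rb$brier, 0.25)
  rb2 <- reliability_and_brier(c(rep(0, 5), rep(1, 5)), c(rep(0, 5), rep(1, 5)))
  expect_equal(rb2$brier, 0)
  expect_equal(mean((c(0.8, 0.4) - c(1, 0))^2), 0.10)
  rb3 <- reliability_and_brier(c(0.8, 0.4, 0.7, 0.3, 0.6), c(1, 0, 1, 0, 1),
                               n_bins = 2)
  expect_equal(rb3$brier, mean((c(0.8, 0.4, 0.7, 0.3, 0.6) - c(1, 0, 1, 0, 1))^2))
  expect_true(all(rb3$bins$obs_rate >= 0 & rb3$bins$obs_rate <= 1))
  expect_match(rb3$note, "case-control")
})

test_that("band summary merges adjacent selections and ranks by SU", {
  coh <- make_cohort(seed = 19)
  cv <- nb_loocv(coh$set, preprocess = preprocess_variant("sg2_norm"))
  bands <- discriminant_band_summary(cv)
  expect_true(nrow(bands) >= 1)
  expect_true(all(bands$lo <= bands$hi))
  expect_equal(bands$mean_su, sort(bands$mean_su, decreasing = TRUE))
  expect_true(all(bands$max_freq > 0 & bands$max_freq <= 1))
  # hand fixture: selections at 946 and 948 merge into one band
  fake <- cv
  fake$selected_wavenumbers <- rep(list(c(946, 948)), 24)
  fake$selected_su <- rep(list(c(0.5, 0.4)), 24)
  fb <- discriminant_band_summary(fake)
  expect_equal(nrow(fb), 1)
  expect_equal(fb$lo, 946)
  expect_equal(fb$hi, 948)
  expect_equal(fb$max_freq, 1)     # selected in every fold -> frequency 1
})

test_that("permutation test is seed-deterministic and preserves class counts", {
  coh <- make_cohort(seed = 23, n_per_class = 5)
  pre <- preprocess_variant("sg2")
  p1 <- permutation_test(coh$set, preprocess = pre, n_permutations = 3, seed = 11)
  p2 <- permutation_test(coh$set, preprocess = pre, n_permutations = 3, seed = 11)
  expect_identical(p1$table, p2$table)
  expect_error(permutation_test(coh$set, n_permutations = 0), "n_permutations")
})

test_that("variant grid is deterministic with the documented schema", {
  coh <- make_cohort(seed = 29, n_per_class = 5)
  g <- variant_grid(coh$set, variants = c("raw", "raw"), seed = 1)
  expect_equal(g[1, -1], g[2, -1], ignore_attr = TRUE)
  expect_equal(colnames(g),
               c("variant", "auc", "accuracy", "f1", "precision", "recall",
                 "specificity"))
  expect_error(variant_grid(coh$set, variants = "bogus"), "unknown variant")
})
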