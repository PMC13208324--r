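#' Model configuration for the supervised core
#'
#' @param selector Feature selector: `"fcbf"` (default; symmetric-uncertainty
#'   ranking with predominance pruning), `"rank_top_k"` (univariate SU
#'   ranking), or `"none"`.
#' @param k Number of features kept by `rank_top_k`.
#' @param fcbf_delta SU-with-label threshold; features at or below it are
#'   discarded before predominance pruning (default 0).
#' @param n_bins Equal-frequency discretization bins used for SU (default 4).
#' @param threshold Probability threshold for the confusion-matrix metrics.
#' @return An object of class `model_config`.
#' @export
model_config <- function(selector = c("fcbf", "rank_top_k", "none"),
                         k = 10, fcbf_delta = 0, n_bins = 4, threshold = 0.5) {
  selector <- match.arg(selector)
  stopifnot(k >= 1, fcbf_delta >= 0, n_bins >= 2)
  structure(list(selector = selector, k = as.integer(k),
                 fcbf_delta = fcbf_delta, n_bins = as.integer(n_bins),
                 threshold = threshold),
            class = "model_config")
}

#' Equal-frequency discretization
#'
#' Cut points are the `1/n_bins .. (n_bins-1)/n_bins` quantiles of the fit
#' subset, computed with the averaging quantile convention
#' ([stats::quantile()] `type = 2`), so e.g. values `1..8` with 4 bins cut
#' at 2.5 / 4.5 / 6.5. Duplicate cut points collapse (fewer effective bins).
#' Codes are assigned by half-open intervals, right-closed:
#' `(-Inf, c1], (c1, c2], ..., (c_{k-1}, Inf)`, numbered `1..k`, and the
#' fitted cuts are reusable on unseen values.
#'
#' @param values Numeric values to code.
#' @param n_bins Number of bins (default 4).
#' @param fit Values used to fit the cut points (defaults to `values`); must
#'   contain at least `n_bins` values.
#' @return List with `codes` (integer, `1..k`), `cuts`, and `constant`
#'   (`TRUE` when the fit values admit no cut at all).
#' @export
equal_frequency_discretize <- function(values, n_bins = 4, fit = values) {
  if (length(fit) < n_bins) stop("fit subset must contain at least n_bins values")
  constant <- length(unique(fit)) == 1
  cuts <- if (constant) numeric(0) else
    unique(stats::quantile(fit, probs = seq_len(n_bins - 1) / n_bins,
                           type = 2, names = FALSE))
  codes <- findInterval(values, cuts, left.open = TRUE) + 1L
  list(codes = codes, cuts = cuts, constant = constant)
}

# Fit type-2 quantile cuts column-wise; returns list of cut vectors.
col_cuts_type2 <- function(X, n_bins) {
  probs <- seq_len(n_bins - 1) / n_bins
  Xs <- apply(X, 2, sort)
  n <- nrow(X)
  # type 2: j = floor(np), g = np - j; g == 0 -> average of order stats j, j+1
  np <- n * probs
  j <- floor(np + 1e-12)
  g0 <- abs(np - j) < 1e-12
  lapply(seq_len(ncol(X)), function(c) {
    v <- Xs[, c]
    q <- ifelse(g0, (v[pmax(j, 1)] + v[pmin(j + 1, n)]) / 2, v[pmin(j + 1, n)])
    unique(q)
  })
}

# Code a matrix column-wise against fitted cuts (codes 1..n_bins).
code_matrix <- function(X, cuts) {
  out <- matrix(1L, nrow(X), ncol(X))
  for (c in seq_len(ncol(X))) {
    if (length(cuts[[c]])) {
      out[, c] <- findInterval(X[, c], cuts[[c]], left.open = TRUE) + 1L
    }
  }
  out
}

# Per-column counts of codes 1..nb: returns nb x p matrix.
col_tabulate <- function(codes, nb) {
  p <- ncol(codes)
  matrix(tabulate(codes + nb * (col(codes) - 1L), nbins = nb * p), nrow = nb)
}

entropy_bits_counts <- function(cnt) {
  # cnt: levels x variables count matrix
  n <- colSums(cnt)
  p <- sweep(cnt, 2, pmax(n, 1), "/")
  plog <- p * log2(p)
  plog[!is.finite(plog)] <- 0
  -colSums(plog)
}

# SU of every column of `codes` with the discrete vector yv (levels 1..nby).
su_columns <- function(codes, yv, nbx, nby) {
  hy <- entropy_bits_counts(matrix(tabulate(yv, nbins = nby), ncol = 1))
  hx <- entropy_bits_counts(col_tabulate(codes, nbx))
  joint <- codes + nbx * (yv - 1L)
  hxy <- entropy_bits_counts(col_tabulate(joint, nbx * nby))
  denom <- hx + hy
  su <- ifelse(denom > 0, 2 * (hx + hy - hxy) / denom, 0)
  pmin(pmax(su, 0), 1)
}

#' Symmetric uncertainty between two discrete variables
#'
#' `SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))` with plug-in entropies in bits;
#' bounded in `[0, 1]`, and defined as 0 when both variables are constant.
#'
#' @param x,y Integer/factor code vectors of equal length.
#' @return SU in `[0, 1]`.
#' @export
symmetric_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  x <- as.integer(factor(x)); y <- as.integer(factor(y))
  su_columns(matrix(x, ncol = 1), y, nbx = max(x), nby = max(y))[1]
}

#' Fast Correlation-Based Filter (FCBF) selection
#'
#' Ranks features by SU with the label (features with `SU <= delta` are
#' dropped), then scans in rank order: feature `f` is removed when some
#' retained higher-ranked feature `g` satisfies `SU(f, g) >= SU(f, label)`
#' (the predominance test). Ties in the ranking break by feature index.
#'
#' @param codes Integer code matrix (rows = samples, columns = features),
#'   codes in `1..n_bins`.
#' @param labels 0/1 labels.
#' @param delta SU-with-label threshold (default 0).
#' @param n_bins Number of code levels (default `max(codes)`).
#' @return List with `selected` (feature indices, in rank order) and
#'   `su` (their SU with the label).
#' @export
fcbf_select <- function(codes, labels, delta = 0, n_bins = max(codes)) {
  codes <- as.matrix(codes)
  yv <- as.integer(labels) + 1L
  su_y <- su_columns(codes, yv, nbx = n_bins, nby = 2L)
  cand <- which(su_y > delta)
  if (!length(cand)) return(list(selected = integer(0), su = numeric(0)))
  ord <- cand[order(-su_y[cand], cand)]
  alive <- rep(TRUE, length(ord))
  retained <- integer(0)
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    g <- ord[i]
    retained <- c(retained, g)
    rest <- which(alive)
    rest <- rest[rest > i]
    if (length(rest)) {
      f_idx <- ord[rest]
      su_fg <- su_columns(codes[, f_idx, drop = FALSE], codes[, g],
                          nbx = n_bins, nby = n_bins)
      alive[rest[su_fg >= su_y[f_idx]]] <- FALSE
    }
  }
  list(selected = retained, su = su_y[retained])
}

#' Gaussian Naive Bayes classifier
#'
#' Per-class, per-feature Gaussians with class-frequency priors. Variances
#' are floored at `1e-9` times the largest pooled feature variance (or a
#' tiny absolute floor when everything is constant) so that degenerate
#' features cannot produce infinite densities; posteriors are computed via
#' log-sum-exp and rows sum to one.
#'
#' @param x Numeric training matrix (rows = samples).
#' @param y 0/1 training labels; both classes must be present.
#' @return An object of class `gaussian_nb`.
#' @export
gaussian_nb <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training data must contain both classes")
  mu <- var_ <- matrix(0, 2, ncol(x))
  for (ci in 1:2) {
    rows <- x[y == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(rows)
    v <- apply(rows, 2, stats::var)
    v[!is.finite(v)] <- 0
    var_[ci, ] <- v
  }
  pooled_max <- max(colMeans(var_))
  floor_ <- if (pooled_max > 0) 1e-9 * pooled_max else 1e-12
  var_ <- pmax(var_, floor_)
  structure(list(classes = classes, prior = c(mean(y == classes[1]),
                                              mean(y == classes[2])),
                 mean = mu, var = var_),
            class = "gaussian_nb")
}

#' @export
print.gaussian_nb <- function(x, ...) {
  cat(sprintf("gaussian_nb: %d features, priors %.3f / %.3f (classes %s)\n",
              ncol(x$mean), x$prior[1], x$prior[2],
              paste(x$classes, collapse = "/")))
  invisible(x)
}

#' Predict posterior class probabilities
#'
#' @param object A [gaussian_nb()] fit.
#' @param newdata Numeric matrix (rows = samples) with the same features.
#' @param ... Unused.
#' @return Matrix of posterior probabilities, one column per class; rows
#'   sum to 1.
#' @export
predict.gaussian_nb <- function(object, newdata, ...) {
  m <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  ll <- sapply(1:2, function(ci) {
    lp <- -0.5 * (log(2 * pi * object$var[ci, ])[col(m)] +
                    sweep(m, 2, object$mean[ci, ])^2 /
                    object$var[ci, ][col(m)])
    rowSums(matrix(lp, nrow(m))) + log(object$prior[ci])
  })
  ll <- matrix(ll, nrow = nrow(m))
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  colnames(post) <- as.character(object$classes)
  post
}

# Mann-Whitney AUC with midrank tie handling.
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from out-of-fold probabilities
#'
#' AUC by Mann-Whitney pair counting with midrank ties; confusion-matrix
#' metrics at the given threshold on the positive class (`1`), with
#' per-class precision/recall/F1 and their macro averages reported
#' alongside.
#'
#' @param prob Predicted probabilities for the positive class.
#' @param labels 0/1 labels (both classes present).
#' @param threshold Decision threshold (default 0.5; `prob >= threshold`
#'   predicts positive).
#' @return Named list of metrics (includes a `confusion` 2x2 table).
#' @export
classification_metrics <- function(prob, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("metrics need both classes")
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }
  pos <- prf(tp, fp, fn)
  neg <- prf(tn, fn, fp)
  list(auc = auc_mw(prob, labels),
       accuracy = (tp + tn) / length(labels),
       precision = unname(pos["precision"]), recall = unname(pos["recall"]),
       f1 = unname(pos["f1"]),
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
       precision_macro = unname((pos["precision"] + neg["precision"]) / 2),
       recall_macro = unname((pos["recall"] + neg["recall"]) / 2),
       f1_macro = unname((pos["f1"] + neg["f1"]) / 2),
       confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                          dimnames = list(pred = c("0", "1"),
                                          truth = c("0", "1"))))
}

# One train/predict round: discretize+select on (Xtr, ytr), NB-predict Xte.
# Returns positive-class probabilities for Xte plus the selection.
fit_predict_fold <- function(Xtr, ytr, Xte, cfg, selection = NULL) {
  if (is.null(selection)) {
    cuts <- col_cuts_type2(Xtr, cfg$n_bins)
    codes <- code_matrix(Xtr, cuts)
    selection <- switch(cfg$selector,
      none = {
        su <- su_columns(codes, as.integer(ytr) + 1L, cfg$n_bins, 2L)
        list(selected = seq_len(ncol(Xtr)), su = su)
      },
      rank_top_k = {
        su <- su_columns(codes, as.integer(ytr) + 1L, cfg$n_bins, 2L)
        ord <- order(-su, seq_along(su))[seq_len(min(cfg$k, length(su)))]
        list(selected = ord, su = su[ord])
      },
      fcbf = fcbf_select(codes, ytr, delta = cfg$fcbf_delta,
                         n_bins = cfg$n_bins))
  }
  sel <- selection$selected
  if (!length(sel)) {
    # empty selection: fall back to the class prior
    p1 <- mean(ytr == 1)
    return(list(prob = rep(p1, nrow(Xte)), selection = selection))
  }
  nb <- gaussian_nb(Xtr[, sel, drop = FALSE], ytr)
  post <- predict(nb, Xte[, sel, drop = FALSE])
  list(prob = post[, "1"], selection = selection)
}

#' Leakage-safe leave-one-out cross-validation of the Naive Bayes pipeline
#'
#' The central fitting function. For each of the `n` folds, discretization
#' cut points, symmetric-uncertainty ranking / FCBF selection and the
#' Gaussian Naive Bayes parameters are fitted on the `n - 1` training
#' samples only; the held-out sample is transformed with the
#' training-fitted cuts and receives one out-of-fold probability.
#' Aggregate metrics are computed once on the `n` out-of-fold scores;
#' resubstitution (train-on-all, predict-all) metrics are recorded
#' separately as an optimism reference.
#'
#' @param x A labeled [spectrum_set()] (labels required), or a numeric
#'   matrix together with `labels`.
#' @param preprocess Optional [preprocess_config()] applied to the set
#'   before modeling (every step is per-sample, so this introduces no
#'   across-sample leakage).
#' @param model A [model_config()].
#' @param labels 0/1 labels when `x` is a matrix.
#' @param seed Integer recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return An object of class `ftir_cv`.
#' @export
nb_loocv <- function(x, preprocess = NULL, model = model_config(),
                     labels = NULL, seed = 1L) {
  loocv_core(x, preprocess, model, labels, seed, leak_selection = FALSE)
}

# `leak_selection = TRUE` performs feature selection once on ALL samples
# before the folds (deliberately leaky) -- a diagnostic used to demonstrate
# that the nesting matters; not part of the exported surface.
loocv_core <- function(x, preprocess = NULL, model = model_config(),
                       labels = NULL, seed = 1L, leak_selection = FALSE) {
  if (inherits(x, "spectrum_set")) {
    if (!is.null(preprocess)) x <- apply_preprocess(x, preprocess)
    if (is.null(x$labels)) stop("labeled spectrum_set required")
    X <- x$intensities
    y <- as.integer(x$labels)
    grid <- x$wavenumbers
    ids <- x$sample_ids
    prov <- x$meta$preprocess %||% "raw"
  } else {
    X <- as.matrix(x)
    y <- as.integer(labels)
    grid <- as.numeric(colnames(X) %||% seq_len(ncol(X)))
    if (anyNA(grid)) grid <- seq_len(ncol(X))
    ids <- rownames(X) %||% paste0("S", seq_len(nrow(X)))
    prov <- "matrix input"
  }
  n <- nrow(X)
  if (n < 4) stop("LOOCV needs at least 4 samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  full_sel <- if (leak_selection) {
    cuts <- col_cuts_type2(X, model$n_bins)
    codes <- code_matrix(X, cuts)
    switch(model$selector,
      none = list(selected = seq_len(ncol(X)),
                  su = su_columns(codes, y + 1L, model$n_bins, 2L)),
      rank_top_k = {
        su <- su_columns(codes, y + 1L, model$n_bins, 2L)
        ord <- order(-su, seq_along(su))[seq_len(min(model$k, length(su)))]
        list(selected = ord, su = su[ord])
      },
      fcbf = fcbf_select(codes, y, delta = model$fcbf_delta,
                         n_bins = model$n_bins))
  } else NULL

  prob <- rep(NA_real_, n)
  sel_wn <- sel_su <- vector("list", n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y[tr])) < 2) { skipped <- c(skipped, i); next }
    fp <- fit_predict_fold(X[tr, , drop = FALSE], y[tr],
                           X[i, , drop = FALSE], model,
                           selection = full_sel)
    prob[i] <- fp$prob
    sel_wn[[i]] <- grid[fp$selection$selected]
    sel_su[[i]] <- fp$selection$su
  }
  ok <- !is.na(prob)
  metrics <- classification_metrics(prob[ok], y[ok], model$threshold)
  resub <- fit_predict_fold(X, y, X, model, selection = full_sel)
  resub_metrics <- classification_metrics(resub$prob, y, model$threshold)
  structure(list(oof = data.frame(sample_id = ids, label = y, prob = prob,
                                  stringsAsFactors = FALSE),
                 selected_wavenumbers = sel_wn, selected_su = sel_su,
                 skipped_folds = skipped,
                 metrics = metrics, resub_metrics = resub_metrics,
                 grid = grid, model = model, preprocess = prov,
                 leaky = leak_selection, seed = as.integer(seed)),
            class = "ftir_cv")
}

#' @export
print.ftir_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("ftir_cv: LOOCV over %d samples (%s%s)\n", nrow(x$oof),
              x$preprocess, if (x$leaky) "; LEAKY selection" else ""))
  cat(sprintf("  AUC %.3f | accuracy %.3f | F1 %.3f | precision %.3f | recall %.3f | specificity %.3f\n",
              m$auc, m$accuracy, m$f1, m$precision, m$recall, m$specificity))
  cat(sprintf("  resubstitution AUC %.3f\n", x$resub_metrics$auc))
  invisible(x)
}

#' @export
summary.ftir_cv <- function(object, top = 5, ...) {
  print(object)
  bands <- discriminant_band_summary(object)
  if (nrow(bands)) {
    cat("top discriminant bands (by mean SU):\n")
    print(utils::head(as.data.frame(bands), top), row.names = FALSE, digits = 3)
  }
  n_sel <- lengths(object$selected_wavenumbers)
  cat(sprintf("features selected per fold: median %g (range %d-%d)\n",
              stats::median(n_sel), min(n_sel), max(n_sel)))
  invisible(object)
}

#' ROC and reliability plots for a cross-validation result
#'
#' @param x An `ftir_cv` object.
#' @param which `"roc"`, `"reliability"` or `"both"`.
#' @param ... Unused.
#' @export
plot.ftir_cv <- function(x, which = c("both", "roc", "reliability"), ...) {
  which <- match.arg(which)
  ok <- !is.na(x$oof$prob)
  p <- x$oof$prob[ok]; y <- x$oof$label[ok]
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  }
  if (which %in% c("both", "roc")) {
    th <- sort(unique(c(-Inf, p, Inf)), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(p[y == 1] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(p[y == 0] >= t), numeric(1))
    graphics::plot(fpr, tpr, type = "s", xlab = "1 - specificity",
                   ylab = "Sensitivity",
                   main = sprintf("LOOCV ROC (AUC = %.3f)", x$metrics$auc))
    graphics::abline(0, 1, lty = 3)
  }
  if (which %in% c("both", "reliability")) {
    rb <- reliability_and_brier(p, y)
    graphics::plot(rb$bins$mean_pred, rb$bins$obs_rate, type = "b", pch = 19,
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Mean predicted probability",
                   ylab = "Observed positive fraction",
                   main = sprintf("Reliability (Brier = %.4f)", rb$brier))
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Label-permutation validity test
#'
#' Shuffles the class labels (preserving class counts), reruns the full
#' nested pipeline — including per-fold feature selection — for each
#' permutation, and reports per-permutation training (resubstitution) and
#' LOOCV AUC next to the true-label values. Deterministic under `seed`.
#'
#' @param x A labeled [spectrum_set()].
#' @param preprocess Optional [preprocess_config()].
#' @param model A [model_config()].
#' @param n_permutations Number of label permutations (default 10).
#' @param seed Integer seed for the shuffles.
#' @return An object of class `permutation_result`.
#' @export
permutation_test <- function(x, preprocess = NULL, model = model_config(),
                             n_permutations = 10, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  stopifnot(inherits(x, "spectrum_set"), !is.null(x$labels))
  if (!is.null(preprocess)) x <- apply_preprocess(x, preprocess)
  y <- as.integer(x$labels)
  true_cv <- nb_loocv(x, model = model, seed = seed)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perms <- replicate(n_permutations, sample(y), simplify = FALSE)
  res <- t(vapply(perms, function(yp) {
    xp <- x
    xp$labels <- yp
    attr(xp$labels, "class_names") <- attr(x$labels, "class_names")
    cv <- nb_loocv(xp, model = model, seed = seed)
    c(train_auc = cv$resub_metrics$auc, loocv_auc = cv$metrics$auc)
  }, numeric(2)))
  structure(list(table = data.frame(permutation = seq_len(n_permutations),
                                    train_auc = res[, "train_auc"],
                                    loocv_auc = res[, "loocv_auc"]),
                 true_train_auc = true_cv$resub_metrics$auc,
                 true_loocv_auc = true_cv$metrics$auc,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d permutations (seed %d)\n",
              x$n_permutations, x$seed))
  cat(sprintf("  true labels:     train AUC %.3f | LOOCV AUC %.3f\n",
              x$true_train_auc, x$true_loocv_auc))
  cat(sprintf("  permuted (mean): train AUC %.3f | LOOCV AUC %.3f\n",
              mean(x$table$train_auc), mean(x$table$loocv_auc)))
  cat(sprintf("  permuted LOOCV AUC range: [%.3f, %.3f]\n",
              min(x$table$loocv_auc), max(x$table$loocv_auc)))
  invisible(x)
}

#' Quantile-binned reliability table and Brier score
#'
#' Predictions are binned by quantiles of the predicted probability (ties
#' can collapse bins); each bin reports its mean predicted probability and
#' observed positive fraction. The Brier score is `mean((p - y)^2)`.
#' Under a 1:1 matched case-control design these probabilities are internal
#' discriminative scores, not population risks; the returned `note` states
#' this explicitly.
#'
#' @param prob Out-of-fold probabilities for the positive class.
#' @param labels 0/1 labels.
#' @param n_bins Number of quantile bins (default 5).
#' @return List with `bins` (data.frame: `bin`, `n`, `mean_pred`,
#'   `obs_rate`), `brier`, and `note`.
#' @export
reliability_and_brier <- function(prob, labels, n_bins = 5) {
  labels <- as.integer(labels)
  if (length(prob) < n_bins) stop("need at least n_bins predictions")
  brks <- unique(stats::quantile(prob, probs = seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE))
  bin <- if (length(brks) >= 2) {
    cut(prob, breaks = brks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(prob))
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel), mean_pred = mean(prob[sel]),
               obs_rate = mean(labels[sel]))
  }))
  list(bins = bins,
       brier = mean((prob - labels)^2),
       note = paste("Scores are internal discriminative probabilities under",
                    "case-control sampling, not population-level risks."))
}

#' Discriminant wavenumber band report
#'
#' Summarizes which wavenumbers the nested selector chose across LOOCV
#' folds: per-wavenumber selection frequency, then contiguous selected
#' wavenumbers (gap of at most `gap_steps` grid steps, and never across a
#' window gap) merged into bands with min-max bounds, sorted by mean SU
#' with the label.
#'
#' @param cv An `ftir_cv` object.
#' @param gap_steps Maximum index gap (in grid steps) merged into one band
#'   (default 2).
#' @return A data.frame of class `band_summary`: `lo`, `hi`, `center`,
#'   `n_points`, `max_freq`, `mean_su`, ordered by decreasing `mean_su`.
#' @export
discriminant_band_summary <- function(cv, gap_steps = 2) {
  stopifnot(inherits(cv, "ftir_cv"))
  grid <- cv$grid
  nfold <- sum(!is.na(cv$oof$prob))
  count <- su_sum <- su_n <- numeric(length(grid))
  for (i in seq_along(cv$selected_wavenumbers)) {
    wn <- cv$selected_wavenumbers[[i]]
    if (!length(wn)) next
    idx <- match(wn, grid)
    count[idx] <- count[idx] + 1
    su_sum[idx] <- su_sum[idx] + cv$selected_su[[i]]
    su_n[idx] <- su_n[idx] + 1
  }
  picked <- which(count > 0)
  out <- data.frame(lo = numeric(0), hi = numeric(0), center = numeric(0),
                    n_points = integer(0), max_freq = numeric(0),
                    mean_su = numeric(0))
  if (length(picked)) {
    step <- stats::median(diff(grid))
    brk <- which(diff(picked) > gap_steps |
                   diff(grid[picked]) > gap_steps * step * 1.01)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(picked))
    out <- do.call(rbind, lapply(seq_along(starts), function(k) {
      idx <- picked[starts[k]:ends[k]]
      data.frame(lo = grid[min(idx)], hi = grid[max(idx)],
                 center = (grid[min(idx)] + grid[max(idx)]) / 2,
                 n_points = length(idx),
                 max_freq = max(count[idx]) / nfold,
                 mean_su = sum(su_sum[idx]) / sum(su_n[idx]))
    }))
    out <- out[order(-out$mean_su), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("band_summary", "data.frame")
  out
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("band_summary: %d band(s)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Metric grid across preprocessing variants
#'
#' Runs the nested LOOCV pipeline once per named preprocessing variant and
#' tabulates AUC, accuracy and macro-averaged F1/precision/recall plus
#' specificity — the customary sensitivity-analysis table for serum FTIR
#' classifiers.
#'
#' @param x A labeled [spectrum_set()] on the full grid.
#' @param variants Character vector of [preprocess_variant()] names.
#' @param model A [model_config()].
#' @param wins Window set forwarded to every variant.
#' @param seed Provenance seed.
#' @return A data.frame with one row per variant and columns `variant`,
#'   `auc`, `accuracy`, `f1`, `precision`, `recall`, `specificity`.
#' @export
variant_grid <- function(x, variants = preprocess_variant_names(),
                         model = model_config(),
                         wins = windows(c(600, 1900), c(2800, 3400)),
                         seed = 1L) {
  if (!length(variants)) stop("at least one variant required")
  bad <- setdiff(variants, preprocess_variant_names())
  if (length(bad)) {
    stop("unknown variant(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(preprocess_variant_names(), collapse = ", "))
  }
  rows <- lapply(variants, function(v) {
    cv <- nb_loocv(x, preprocess = preprocess_variant(v, wins = wins),
                   model = model, seed = seed)
    m <- cv$metrics
    data.frame(variant = v, auc = m$auc, accuracy = m$accuracy,
               f1 = m$f1_macro, precision = m$precision_macro,
               recall = m$recall_macro, specificity = m$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
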