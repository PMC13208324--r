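#' Pairwise cosine distance matrix
#'
#' `d(i, j) = 1 - cos(x_i, x_j)`, in `[0, 2]`, symmetric with a zero
#' diagonal; invariant to positive per-spectrum scaling. Group labels play
#' no role: the function accepts a plain matrix or a [spectrum_set()] and
#' only ever reads intensities.
#'
#' @param x A `spectrum_set` or numeric matrix (rows = samples).
#' @return An n x n matrix of class `dist_cosine` with sample IDs as
#'   dimnames.
#' @export
cosine_distance_matrix <- function(x) {
  m <- if (inherits(x, "spectrum_set")) x$intensities else as.matrix(x)
  ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("zero-norm spectrum: ", paste(ids[nrm == 0], collapse = ", "))
  }
  u <- m / nrm
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(ids, ids)
  class(d) <- c("dist_cosine", "matrix", "array")
  d
}

#' Ward-type hierarchical clustering of a distance matrix
#'
#' Agglomeration by Lance-Williams Ward updates applied to the squared
#' input distances (via [stats::hclust()] with `method = "ward.D"` on the
#' squared dissimilarities). For cosine distances this is "Ward-type"
#' rather than true Ward — the Euclidean assumption behind Ward's variance
#' criterion does not hold — which is the standard practice for spectral
#' cosine heatmaps and is documented rather than silently altered.
#'
#' @param d Symmetric distance matrix (e.g. from
#'   [cosine_distance_matrix()]).
#' @return An `hclust` object; `$height` holds the Ward criterion on
#'   squared distances at each of the `n - 1` merges.
#' @export
agglomerative_cluster <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), nrow(d) >= 2)
  hc <- stats::hclust(stats::as.dist(d^2), method = "ward.D")
  hc$call <- NULL
  hc$method <- "ward-type (Lance-Williams on squared distances)"
  hc$dist.method <- "cosine (squared)"
  hc
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centered Gram eigen-decomposition via [stats::cmdscale()].
#' Cosine distance matrices are generally non-Euclidean, so negative
#' eigenvalues can occur; they are clipped with a warning. If fewer than
#' `dims` positive eigenvalues exist, a lower-dimensional embedding is
#' returned with a warning. Output coordinates are centered at the origin.
#'
#' @param d Symmetric distance matrix.
#' @param dims Target dimensionality (default 2).
#' @return Matrix `n x k` (`k <= dims`) with attribute `"eig"`.
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n > dims)
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  eig <- fit$eig
  tol <- 1e-9 * max(abs(eig), 1)
  if (any(eig < -tol)) {
    warning(sprintf("clipped %d negative eigenvalue(s) (non-Euclidean distances)",
                    sum(eig < -tol)))
  }
  npos <- sum(eig > tol)
  pts <- fit$points
  if (npos < dims) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d-dimensional embedding",
                    npos, npos))
    pts <- pts[, seq_len(max(npos, 1)), drop = FALSE]
  }
  pts <- sweep(pts, 2, colMeans(pts))
  rownames(pts) <- rownames(d)
  attr(pts, "eig") <- eig
  pts
}

#' t-SNE embedding
#'
#' Exact (non-approximated) t-distributed stochastic neighbor embedding for
#' the small cohorts this package targets: per-point bandwidths found by
#' bisection to match the target perplexity, symmetrized affinities, early
#' exaggeration, and momentum gradient descent from a small random
#' Gaussian initialization. Deterministic under `seed`; provenance
#' (perplexity, seed, iterations) is attached to the result. This is a
#' visualization diagnostic, not part of the inferential surface.
#'
#' @param x A `spectrum_set`, a numeric matrix (rows = samples), or a
#'   precomputed distance matrix (class `dist_cosine` or attribute-free
#'   symmetric matrix passed via `is_distance = TRUE`).
#' @param perplexity Target perplexity; must satisfy
#'   `perplexity < (n - 1) / 3`.
#' @param seed Integer seed for the initialization.
#' @param n_iter Gradient-descent iterations (default 500).
#' @param is_distance Set `TRUE` when `x` is already a distance matrix.
#' @return `n x 2` coordinate matrix with a `"provenance"` attribute.
#' @export
tsne_embed <- function(x, perplexity = 5, seed = 1, n_iter = 500,
                       is_distance = inherits(x, "dist_cosine")) {
  d <- if (is_distance) as.matrix(x) else cosine_distance_matrix(x)
  n <- nrow(d)
  if (n < 4) stop("t-SNE needs at least 4 samples")
  if (perplexity >= (n - 1) / 3) {
    stop(sprintf("perplexity %g infeasible for n = %d; try perplexity <= %g",
                 perplexity, n, floor((n - 1) / 3 - 1e-9)))
  }
  d2 <- d^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta_hi <- beta; beta <- (beta_lo + beta) / 2; next }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < 1e-7) break
      if (H > logU) {                         # too flat: increase beta
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    P[i, -i] <- exp(-di * beta) / sum(exp(-di * beta))
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    exag <- if (it <= 100) 4 else 1
    sqY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqY, sqY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (it <= 250) 0.5 else 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(d)
  attr(Y, "provenance") <- list(perplexity = perplexity, seed = seed,
                                n_iter = n_iter)
  Y
}
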