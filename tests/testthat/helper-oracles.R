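# Independent brute-force oracles. Deliberately naive (loops, closed forms),
# sharing no code with the package implementation.

# Gift-wrapping lower hull baseline: from each vertex, walk to the point of
# minimum slope. O(n^2).
oracle_rubberband <- function(x, y) {
  n <- length(x)
  verts <- 1L
  i <- 1L
  while (i < n) {
    slopes <- (y[(i + 1):n] - y[i]) / (x[(i + 1):n] - x[i])
    j <- i + which.min(slopes)
    verts <- c(verts, j)
    i <- j
  }
  baseline <- numeric(n)
  for (k in seq_len(n)) {
    seg <- findInterval(k, verts)
    a <- verts[seg]
    b <- verts[min(seg + 1, length(verts))]
    baseline[k] <- if (a == b) y[a] else
      y[a] + (y[b] - y[a]) * (x[k] - x[a]) / (x[b] - x[a])
  }
  list(baseline = baseline, corrected = y - baseline)
}

# Exhaustive pair-counting AUC with half-credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Plug-in entropy (bits) of a discrete vector, by naive tabulation.
oracle_entropy <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log2(p))
}

oracle_su <- function(x, y) {
  hx <- oracle_entropy(x); hy <- oracle_entropy(y)
  hxy <- oracle_entropy(paste(x, y))
  if (hx + hy == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}

# FCBF by direct application of the definition with naive loops.
oracle_fcbf <- function(codes, y, delta = 0) {
  p <- ncol(codes)
  su_y <- vapply(seq_len(p), function(j) oracle_su(codes[, j], y), numeric(1))
  cand <- which(su_y > delta)
  cand <- cand[order(-su_y[cand], cand)]
  retained <- integer(0)
  for (f in cand) {
    dominated <- FALSE
    for (g in retained) {
      if (oracle_su(codes[, f], codes[, g]) >= su_y[f]) { dominated <- TRUE; break }
    }
    if (!dominated) retained <- c(retained, f)
  }
  retained
}

# Naive O(n^3) Lance-Williams Ward agglomeration on squared distances;
# returns the sequence of merge heights.
oracle_ward_heights <- function(d) {
  D <- d^2
  n <- nrow(D)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      if (D[a, b] < bestv) { bestv <- D[a, b]; best <- c(a, b) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bestv
    for (k in setdiff(active, c(i, j))) {
      newd <- ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
                 size[k] * D[i, j]) / (size[i] + size[j] + size[k])
      D[i, k] <- D[k, i] <- newd
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# Naive QC metric recomputations (loops and closed-form SD/regression).
oracle_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

oracle_detrended_sd <- function(y, x) {
  n <- length(y)
  mx <- sum(x) / n; my <- sum(y) / n
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  resid <- y - (my + slope * (x - mx))
  oracle_sd(resid)
}

oracle_snr <- function(y, grid, signal = c(1600, 1700), noise = c(1800, 1900),
                       fallback = c(2000, 2200)) {
  sw <- grid >= signal[1] & grid <= signal[2]
  corr <- oracle_rubberband(grid[sw], y[sw])$corrected
  num <- max(corr)
  nw <- grid >= noise[1] & grid <= noise[2]
  den <- if (sum(nw) >= 3) oracle_detrended_sd(y[nw], grid[nw]) else NA
  if (is.na(den) || den < 1e-12) {
    fw <- grid >= fallback[1] & grid <= fallback[2]
    den <- if (sum(fw) >= 3) oracle_detrended_sd(y[fw], grid[fw]) else NA
  }
  if (is.na(den) || den < 1e-12) return(Inf)
  num / den
}

oracle_spike_count <- function(y, grid, window = c(900, 1800), thr = 6) {
  w <- y[grid >= window[1] & grid <= window[2]]
  d <- w[-1] - w[-length(w)]
  med <- sort(d)[c(ceiling(length(d) / 2), floor(length(d) / 2) + 1)]
  med <- sum(med) / 2
  madv <- abs(d - med)
  mad_raw <- sort(madv)[c(ceiling(length(madv) / 2), floor(length(madv) / 2) + 1)]
  mad_raw <- sum(mad_raw) / 2
  s <- 1.4826 * mad_raw
  if (s == 0) return(0)
  z <- (d - med) / s
  flag <- abs(z) > thr
  events <- 0
  prev <- FALSE
  for (f in flag) {
    if (f && !prev) events <- events + 1
    prev <- f
  }
  events
}

oracle_cosine_profile <- function(mat, grid, window = c(900, 1800)) {
  keep <- grid >= window[1] & grid <= window[2]
  m <- mat[, keep, drop = FALSE]
  for (i in seq_len(nrow(m))) m[i, ] <- m[i, ] / sqrt(sum(m[i, ]^2))
  ref <- apply(m, 2, function(col) {
    s <- sort(col)
    n <- length(s)
    (s[ceiling(n / 2)] + s[floor(n / 2) + 1]) / 2
  })
  sapply(seq_len(nrow(m)), function(i) {
    sum(m[i, ] * ref) / (sqrt(sum(m[i, ]^2)) * sqrt(sum(ref^2)))
  })
}

oracle_trapz <- function(x, y) {
  tot <- 0
  for (k in 2:length(x)) tot <- tot + (x[k] - x[k - 1]) * (y[k] + y[k - 1]) / 2
  tot
}

oracle_baseline_fraction <- function(y, grid, window = c(900, 1800)) {
  keep <- grid >= window[1] & grid <= window[2]
  yy <- y[keep]; xx <- grid[keep]
  bl <- oracle_rubberband(xx, yy)$baseline
  100 * oracle_trapz(xx, bl) / oracle_trapz(xx, yy)
}

# Small-cohort fixture shared across tests.
make_cohort <- function(seed = 1, n_per_class = 12, effect_scale = 1, ...) {
  generate_cohort(synthetic_truth(seed = seed, n_per_class = n_per_class,
                                  effect_scale = effect_scale, ...))
}

default_windows <- function() windows(c(600, 1900), c(2800, 3400))
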