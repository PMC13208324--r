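#' Spectral data container
#'
#' A `spectrum_set` bundles a strictly ascending wavenumber grid with a
#' samples-by-wavenumbers absorbance matrix, unique sample identifiers,
#' optional binary class labels and free-form per-sample metadata. It is the
#' currency every pipeline stage consumes and returns.
#'
#' Labels are stored internally as integers, `0` for the control class and
#' `1` for the positive class ("Start&Stop" by convention); the original
#' class names are kept in `attr(x$labels, "class_names")` as
#' `c(negative, positive)`.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   increasing after internal sorting.
#' @param intensities Numeric matrix, one row per sample, one column per
#'   wavenumber. Finite values only.
#' @param sample_ids Character vector of unique sample identifiers. Defaults
#'   to `S1..Sn`.
#' @param labels Optional class labels: either integers in `{0, 1}` or a
#'   vector with exactly two distinct values, mapped via `class_names`.
#' @param class_names Length-2 character vector `c(negative, positive)`
#'   naming the two classes. Default `c("No-Stop", "Start&Stop")`.
#' @param meta Optional list of per-sample metadata (length `n` or empty).
#'
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities,
                         sample_ids = NULL, labels = NULL,
                         class_names = c("No-Stop", "Start&Stop"),
                         meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(intensities))) {
    intensities <- matrix(as.numeric(intensities), nrow = 1L)
  }
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(wavenumbers) != ncol(intensities)) {
    stop("length(wavenumbers) must equal ncol(intensities)")
  }
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("wavenumbers must be finite")
  }
  if (anyDuplicated(wavenumbers)) {
    stop("duplicate wavenumbers are not allowed")
  }
  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  intensities <- intensities[, ord, drop = FALSE]
  if (any(!is.finite(intensities))) {
    stop("intensities must be finite (no NA/NaN/Inf)")
  }
  n <- nrow(intensities)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("length(sample_ids) must equal nrow(intensities)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.null(labels)) {
    labels <- normalize_labels(labels, class_names)
    if (length(labels) != n) stop("length(labels) must equal nrow(intensities)")
  }
  if (length(meta) && length(meta) != n) {
    if (is.null(names(meta))) stop("meta must be per-sample (length n) or named attributes")
  }
  rownames(intensities) <- sample_ids
  colnames(intensities) <- format(wavenumbers, trim = TRUE)
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 sample_ids = sample_ids, labels = labels, meta = meta),
            class = "spectrum_set")
}

# Map arbitrary two-level labels onto 0 (negative) / 1 (positive).
normalize_labels <- function(labels, class_names) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    out <- as.integer(labels)
  } else {
    lv <- unique(as.character(labels))
    if (!all(lv %in% class_names)) {
      if (length(lv) > 2) stop("labels must take exactly two values, got: ",
                               paste(lv, collapse = ", "))
      stop("labels (", paste(lv, collapse = ", "),
           ") do not match configured class names (",
           paste(class_names, collapse = ", "), ")")
    }
    out <- as.integer(as.character(labels) == class_names[2L])
  }
  attr(out, "class_names") <- class_names
  out
}

#' @export
print.spectrum_set <- function(x, ...) {
  n <- nrow(x$intensities)
  cat(sprintf("spectrum_set: %d sample%s x %d wavenumbers [%g, %g] cm^-1\n",
              n, if (n == 1) "" else "s", length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.null(x$labels)) {
    cn <- attr(x$labels, "class_names")
    cat(sprintf("labels: %d %s / %d %s (positive = %s)\n",
                sum(x$labels == 0), cn[1], sum(x$labels == 1), cn[2], cn[2]))
  }
  invisible(x)
}

#' Subset samples of a spectrum_set
#'
#' @param x A `spectrum_set`.
#' @param i Row (sample) index: integer, logical or sample-ID character.
#' @param ... Unused.
#' @return A `spectrum_set` with the selected samples.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  lab <- x$labels
  if (!is.null(lab)) {
    cn <- attr(lab, "class_names")
    lab <- lab[i]
    attr(lab, "class_names") <- cn
  }
  spectrum_set(x$wavenumbers, x$intensities[i, , drop = FALSE],
               sample_ids = x$sample_ids[i], labels = lab,
               class_names = if (!is.null(lab)) attr(lab, "class_names")
                             else c("No-Stop", "Start&Stop"),
               meta = if (length(x$meta) == nrow(x$intensities)) x$meta[i] else x$meta)
}

#' Drop class labels from a spectrum_set
#'
#' Used by the pipeline runner to hand label-free views to the QC,
#' preprocessing and unsupervised stages, so that class information cannot
#' enter any computation before the supervised stage.
#'
#' @param x A `spectrum_set`.
#' @return The same set with `labels = NULL`.
#' @export
strip_labels <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  x$labels <- NULL
  x
}

#' Plot spectra
#'
#' @param x A `spectrum_set`.
#' @param col Line colours; defaults to class labels when present.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.spectrum_set <- function(x, col = NULL, ...) {
  if (is.null(col)) col <- if (is.null(x$labels)) 1L else x$labels + 1L
  graphics::matplot(x$wavenumbers, t(x$intensities), type = "l", lty = 1,
                    col = col, xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance (a.u.)", ...)
  invisible(x)
}

#' Wavenumber window sets
#'
#' A `window_set` is an ordered list of closed wavenumber intervals
#' `[lo, hi]` in cm^-1. Overlapping or touching intervals are merged after
#' sorting, so the union is canonical.
#'
#' @param ... Numeric length-2 vectors `c(lo, hi)`, or a single list of them,
#'   or a 2-column matrix.
#' @return An object of class `window_set`: a 2-column matrix with columns
#'   `lo`, `hi`, sorted and merged.
#' @examples
#' windows(c(600, 1900), c(2800, 3400))
#' @export
windows <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.data.frame(args[[1]])) {
    args <- args[[1]]
  }
  if (length(args) == 1L && is.matrix(args[[1]])) {
    m <- args[[1]]
  } else {
    m <- do.call(rbind, lapply(args, function(w) {
      w <- as.numeric(w)
      if (length(w) != 2) stop("each window must be c(lo, hi)")
      w
    }))
  }
  if (is.null(m) || nrow(m) == 0) stop("at least one window required")
  if (any(m[, 1] >= m[, 2])) stop("every window must satisfy lo < hi")
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  if (nrow(m) > 1) for (k in 2:nrow(m)) {
    last <- nrow(merged)
    if (m[k, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], m[k, 2])
    } else {
      merged <- rbind(merged, m[k, ])
    }
  }
  dimnames(merged) <- list(NULL, c("lo", "hi"))
  structure(merged, class = c("window_set", "matrix", "array"))
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", paste(sprintf("[%g, %g]", x[, 1], x[, 2]), collapse = " U "),
      "cm^-1\n")
  invisible(x)
}

#' Logical membership of grid points in a window union
#'
#' @param grid Numeric wavenumber vector.
#' @param wins A `window_set`.
#' @return Logical vector, `TRUE` where `lo <= grid <= hi` for some window.
#' @export
in_windows <- function(grid, wins) {
  stopifnot(inherits(wins, "window_set"))
  keep <- rep(FALSE, length(grid))
  for (k in seq_len(nrow(wins))) {
    keep <- keep | (grid >= wins[k, 1] & grid <= wins[k, 2])
  }
  keep
}

#' Restrict a spectrum_set to spectral windows
#'
#' Keeps only grid points whose wavenumber lies inside the (closed) union of
#' the given windows; column order, labels and metadata are untouched.
#'
#' @param x A `spectrum_set`.
#' @param wins A `window_set`.
#' @return A restricted `spectrum_set`.
#' @export
restrict_windows <- function(x, wins) {
  stopifnot(inherits(x, "spectrum_set"))
  keep <- in_windows(x$wavenumbers, wins)
  if (!any(keep)) {
    stop("no grid point falls inside window union ",
         paste(sprintf("[%g, %g]", wins[, 1], wins[, 2]), collapse = " U "))
  }
  out <- x
  out$wavenumbers <- x$wavenumbers[keep]
  out$intensities <- x$intensities[, keep, drop = FALSE]
  out
}

#' Split a grid into contiguous segments
#'
#' After window restriction the grid may contain physical gaps (e.g.
#' 1900 -> 2800 cm^-1). Operations such as Savitzky-Golay filtering must act
#' per contiguous segment, never across a gap. A gap is any spacing larger
#' than `tol` times the median spacing.
#'
#' @param grid Ascending numeric vector.
#' @param tol Gap factor relative to median spacing (default 1.5).
#' @return List of integer index vectors, one per contiguous segment.
#' @export
grid_segments <- function(grid, tol = 1.5) {
  if (length(grid) <= 1) return(list(seq_along(grid)))
  d <- diff(grid)
  step <- stats::median(d)
  brk <- which(d > tol * step)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(grid))
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}
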