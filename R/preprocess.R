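#' Rubber-band baseline correction
#'
#' The baseline is the lower convex hull of the points `(grid, y)`, linearly
#' interpolated between hull vertices (the classic "rubber band" stretched
#' under the spectrum). The baseline never exceeds the spectrum, the
#' corrected spectrum is nonnegative, and it is exactly zero at every hull
#' vertex, including both endpoints.
#'
#' @param y Numeric spectrum.
#' @param grid Ascending wavenumber vector, same length as `y`.
#' @return List with `baseline` and `corrected` (`y - baseline`).
#' @export
rubberband_baseline <- function(y, grid) {
  n <- length(y)
  stopifnot(length(grid) == n, n >= 2)
  hull <- lower_hull_indices(grid, y)
  baseline <- stats::approx(grid[hull], y[hull], xout = grid, rule = 2)$y
  corrected <- pmax(y - baseline, 0)
  list(baseline = baseline, corrected = corrected)
}

# Andrew monotone-chain lower hull on ascending x; returns vertex indices.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- stack[top - 1L]; b <- stack[top]
      # drop b if it lies on or above segment a->i (non-right turn)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) top <- top - 1L else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  stack[seq_len(top)]
}

#' Unit vector normalization of spectrum rows
#'
#' Scales each row of a matrix (or a single vector) to unit Euclidean norm
#' over the current axis, removing multiplicative film-thickness /
#' scatter-intensity effects while preserving spectral shape.
#'
#' @param x Numeric matrix (rows = samples) or vector.
#' @param ids Optional sample IDs used in error messages.
#' @return Normalized matrix/vector.
#' @export
vector_normalize <- function(x, ids = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)
    nm <- if (!is.null(ids)) ids[bad] else if (!is.null(rownames(m))) rownames(m)[bad] else bad
    stop("zero-norm spectrum cannot be vector-normalized: ",
         paste(nm, collapse = ", "))
  }
  out <- m / nrm
  if (vec) drop(out) else out
}

#' Savitzky-Golay smoothing / derivative filter
#'
#' Local least-squares polynomial filtering with derivatives scaled per
#' cm^-1 (using the grid spacing). The grid must be uniform within a
#' relative tolerance of 1e-6; filtering is applied per row. Edge values
#' come from the terminal window fits, so output length equals input
#' length and feature indices stay aligned with wavenumbers. Filtering is
#' delegated to [signal::sgolayfilt()].
#'
#' @param x Matrix (rows = spectra) or vector.
#' @param grid Uniform ascending wavenumber vector.
#' @param order Polynomial order (default 2).
#' @param window_pts Window length in points, odd and `> order` (default 15).
#' @param deriv Derivative order 0, 1 or 2 (default 0).
#' @return Filtered matrix/vector of the same shape.
#' @export
savgol_derivative <- function(x, grid, order = 2, window_pts = 15, deriv = 0) {
  if (window_pts %% 2 != 1 || window_pts <= order) {
    stop("window_pts must be odd and greater than the polynomial order")
  }
  if (!deriv %in% 0:2) stop("deriv must be 0, 1 or 2")
  d <- diff(grid)
  h <- mean(d)
  if (length(d) && max(abs(d - h)) > 1e-6 * abs(h)) {
    stop("non-uniform grid: apply per contiguous window segment ",
         "(see grid_segments())")
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else x
  if (ncol(m) < window_pts) stop("row length must be >= window_pts")
  out <- t(apply(m, 1, signal::sgolayfilt, p = order, n = window_pts,
                 m = deriv, ts = h))
  if (vec) drop(out) else out
}

#' Mask atmospheric-contribution regions
#'
#' Replaces the CO2 asymmetric-stretch region (2300-2400 cm^-1) and the
#' water-vapor rotational band region (1790-1960 cm^-1) with a linear
#' interpolation between the values just outside each region; all other
#' points are untouched. Regions with no grid points are skipped; when a
#' region touches the grid edge the nearest available value is extended.
#'
#' @param y Numeric spectrum.
#' @param grid Ascending wavenumber vector.
#' @param regions List of length-2 vectors (defaults above).
#' @return Masked spectrum.
#' @export
atmospheric_mask <- function(y, grid,
                             regions = list(c(1790, 1960), c(2300, 2400))) {
  out <- y
  for (r in regions) {
    inside <- which(grid >= r[1] & grid <= r[2])
    if (!length(inside)) next
    lo <- min(inside) - 1L
    hi <- max(inside) + 1L
    if (lo < 1 && hi > length(grid)) next        # whole grid inside: nothing to anchor
    if (lo < 1) {
      out[inside] <- out[hi]
    } else if (hi > length(grid)) {
      out[inside] <- out[lo]
    } else {
      out[inside] <- stats::approx(grid[c(lo, hi)], out[c(lo, hi)],
                                   xout = grid[inside])$y
    }
  }
  out
}

#' Preprocessing pipeline configuration
#'
#' An ordered list of step names from `rubberband`, `vector_normalize`,
#' `savgol` (with `order`, `window_pts`, `deriv` parameters) and
#' `atmospheric_mask`, plus a window set and the stage ("before" or
#' "after" the steps) at which window restriction is applied. Steps that
#' act on the wavenumber axis (rubber band, Savitzky-Golay) operate per
#' contiguous grid segment, never across a window gap; `vector_normalize`
#' acts over the concatenated in-scope points.
#'
#' @param steps List of steps. Each step is either a character name or a
#'   list `list(name = "savgol", order = 2, window_pts = 15, deriv = 2)`.
#' @param windows A [windows()] set, or `NULL` for no restriction.
#' @param window_stage `"before"` (default) or `"after"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(steps = list(), windows = NULL,
                              window_stage = c("before", "after")) {
  window_stage <- match.arg(window_stage)
  known <- c("rubberband", "vector_normalize", "savgol", "atmospheric_mask")
  steps <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(name = s)
    if (!s$name %in% known) {
      stop("unknown step '", s$name, "'; valid steps: ",
           paste(known, collapse = ", "))
    }
    if (s$name == "savgol") {
      s$order <- s$order %||% 2
      s$window_pts <- s$window_pts %||% 15
      s$deriv <- s$deriv %||% 2
      if (s$window_pts %% 2 != 1 || s$window_pts <= s$order) {
        stop("savgol window_pts must be odd and > order")
      }
      if (!s$deriv %in% 0:2) stop("savgol deriv must be 0, 1 or 2")
    }
    s
  })
  structure(list(steps = steps, windows = windows, window_stage = window_stage),
            class = "preprocess_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

step_label <- function(s) {
  if (s$name == "savgol") {
    sprintf("savgol(o=%d,w=%d,d=%d)", s$order, s$window_pts, s$deriv)
  } else s$name
}

#' @export
print.preprocess_config <- function(x, ...) {
  lbl <- vapply(x$steps, step_label, character(1))
  cat("preprocess_config:", if (length(lbl)) paste(lbl, collapse = " -> ") else "<raw>", "\n")
  if (!is.null(x$windows)) {
    cat("  windows (", x$window_stage, " steps): ",
        paste(sprintf("[%g, %g]", x$windows[, 1], x$windows[, 2]), collapse = " U "),
        "\n", sep = "")
  }
  invisible(x)
}

# Apply one step to an intensity matrix on a (possibly gapped) grid.
apply_step <- function(step, mat, grid, ids) {
  segs <- grid_segments(grid)
  switch(step$name,
    vector_normalize = vector_normalize(mat, ids = ids),
    rubberband = {
      for (sg in segs) {
        for (i in seq_len(nrow(mat))) {
          mat[i, sg] <- rubberband_baseline(mat[i, sg], grid[sg])$corrected
        }
      }
      mat
    },
    savgol = {
      for (sg in segs) {
        if (length(sg) < step$window_pts) {
          stop("window segment of ", length(sg),
               " points is shorter than the savgol window (", step$window_pts, ")")
        }
        mat[, sg] <- savgol_derivative(mat[, sg, drop = FALSE], grid[sg],
                                       order = step$order,
                                       window_pts = step$window_pts,
                                       deriv = step$deriv)
      }
      mat
    },
    atmospheric_mask = {
      for (i in seq_len(nrow(mat))) mat[i, ] <- atmospheric_mask(mat[i, ], grid)
      mat
    },
    stop("unknown step: ", step$name))
}

#' Apply a preprocessing pipeline to a spectrum_set
#'
#' Steps are applied in declared order, identically to every sample; window
#' restriction happens at the configured stage. A provenance string naming
#' the applied steps and windows is recorded in the set's metadata.
#'
#' @param x A [spectrum_set()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `spectrum_set`.
#' @export
apply_preprocess <- function(x, cfg) {
  stopifnot(inherits(x, "spectrum_set"), inherits(cfg, "preprocess_config"))
  if (!is.null(cfg$windows) && cfg$window_stage == "before") {
    x <- restrict_windows(x, cfg$windows)
  }
  mat <- x$intensities
  for (s in cfg$steps) mat <- apply_step(s, mat, x$wavenumbers, x$sample_ids)
  x$intensities <- mat
  rownames(x$intensities) <- x$sample_ids
  if (!is.null(cfg$windows) && cfg$window_stage == "after") {
    x <- restrict_windows(x, cfg$windows)
  }
  lbl <- vapply(cfg$steps, step_label, character(1))
  x$meta$preprocess <- paste0(
    if (length(lbl)) paste(lbl, collapse = " -> ") else "raw",
    if (!is.null(cfg$windows)) {
      paste0(" | windows ", cfg$window_stage, ": ",
             paste(sprintf("[%g,%g]", cfg$windows[, 1], cfg$windows[, 2]),
                   collapse = " U "))
    } else "")
  x
}

#' Named preprocessing variants
#'
#' Shortcut configurations reproducing the standard sensitivity-analysis
#' grid for serum FTIR classification: raw spectra, atmospheric masking,
#' vector normalization, first/second Savitzky-Golay derivatives with and
#' without secondary normalization, and rubber-band baseline correction with
#' and without normalization. All variants restrict to `wins` before the
#' steps; secondary normalization therefore acts on the concatenated
#' in-window points.
#'
#' @param name One of `"raw"`, `"atmospheric"`, `"vector_norm"`, `"sg1"`,
#'   `"sg1_norm"`, `"sg2"`, `"sg2_norm"`, `"rubberband"`,
#'   `"rubberband_norm"`.
#' @param wins Window set (default fingerprint/amide 600-1900 cm^-1 plus
#'   C-H stretch 2800-3400 cm^-1).
#' @return A [preprocess_config()].
#' @export
preprocess_variant <- function(name,
                               wins = windows(c(600, 1900), c(2800, 3400))) {
  sg <- function(d) list(name = "savgol", order = 2, window_pts = 15, deriv = d)
  steps <- switch(name,
    raw             = list(),
    atmospheric     = list("atmospheric_mask"),
    vector_norm     = list("vector_normalize"),
    sg1             = list(sg(1)),
    sg1_norm        = list(sg(1), "vector_normalize"),
    sg2             = list(sg(2)),
    sg2_norm        = list(sg(2), "vector_normalize"),
    rubberband      = list("rubberband"),
    rubberband_norm = list("rubberband", "vector_normalize"),
    stop("unknown variant '", name, "'; valid: raw, atmospheric, vector_norm, ",
         "sg1, sg1_norm, sg2, sg2_norm, rubberband, rubberband_norm"))
  preprocess_config(steps = steps, windows = wins, window_stage = "before")
}

#' @rdname preprocess_variant
#' @export
preprocess_variant_names <- function() {
  c("raw", "atmospheric", "vector_norm", "sg1", "sg1_norm", "sg2", "sg2_norm",
    "rubberband", "rubberband_norm")
}
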