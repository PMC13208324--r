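#' Read a wide spectral matrix from delimited text
#'
#' The canonical exchange format is a wide table: one row per sample, one
#' column per wavenumber, with numeric wavenumbers in the header, plus
#' optional ID and label columns. Wavenumber columns are sorted ascending on
#' read (the header may be in any order); duplicate wavenumber columns and
#' duplicate sample IDs are rejected.
#'
#' @param path Path to a CSV/TSV file.
#' @param label_column Name of the label column, or `NULL` for unlabeled data.
#' @param id_column Name of the sample-ID column, or `NULL` to autogenerate
#'   IDs. Default `"sample_id"` is used when present.
#' @param class_names Length-2 character `c(negative, positive)` used to map
#'   label values.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A [spectrum_set()].
#' @export
read_spectra_table <- function(path, label_column = NULL,
                               id_column = "sample_id",
                               class_names = c("No-Stop", "Start&Stop"),
                               sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  cn <- colnames(df)
  meta_cols <- character(0)
  if (!is.null(id_column) && id_column %in% cn) meta_cols <- c(meta_cols, id_column)
  if (!is.null(label_column)) {
    if (!label_column %in% cn) stop("label column '", label_column, "' not found")
    meta_cols <- c(meta_cols, label_column)
  }
  spec_idx <- which(!(cn %in% meta_cols))
  spec_cols <- cn[spec_idx]
  wn <- suppressWarnings(as.numeric(spec_cols))
  if (anyNA(wn)) {
    stop("non-numeric header cell(s) outside declared metadata columns: ",
         paste(spec_cols[is.na(wn)], collapse = ", "))
  }
  if (anyDuplicated(wn)) {
    stop("duplicate wavenumber columns: ",
         paste(unique(wn[duplicated(wn)]), collapse = ", "))
  }
  ids <- if (!is.null(id_column) && id_column %in% cn) as.character(df[[id_column]]) else NULL
  labels <- if (!is.null(label_column)) df[[label_column]] else NULL
  mat <- as.matrix(df[, spec_idx, drop = FALSE])
  if (!is.numeric(mat)) stop("spectral cells must be numeric")
  spectrum_set(wn, mat, sample_ids = ids, labels = labels,
               class_names = class_names)
}

#' Write a spectrum_set as a wide delimited table
#'
#' Values are formatted at 17 significant digits so that
#' `read_spectra_table(write_spectra_table(x))` round-trips to full double
#' precision. A set with zero samples yields a header-only file.
#'
#' @param x A [spectrum_set()].
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "spectrum_set"))
  header <- c("sample_id",
              if (!is.null(x$labels)) "label",
              format(x$wavenumbers, digits = 17, trim = TRUE, scientific = FALSE))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  n <- nrow(x$intensities)
  if (n > 0) {
    vals <- matrix(formatC(x$intensities, digits = 17, format = "g"), nrow = n)
    for (i in seq_len(n)) {
      row <- c(x$sample_ids[i],
               if (!is.null(x$labels))
                 attr(x$labels, "class_names")[x$labels[i] + 1L],
               vals[i, ])
      writeLines(paste(row, collapse = sep), con)
    }
  }
  invisible(path)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Supports the common IR exchange subset: `##XYDATA=(X++(Y..Y))` with AFFN
#' (plain-number) lines, and `##XYPOINTS=(XY..XY)` pairs. `##XFACTOR` and
#' `##YFACTOR` are applied; a descending X axis is reversed so the returned
#' grid ascends.
#'
#' @param path Path to a JCAMP-DX file.
#' @param sample_id Sample identifier for the resulting one-row set.
#' @return A one-sample [spectrum_set()].
#' @export
read_jcampdx <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  if (is.null(ldr("TITLE"))) stop("not a JCAMP-DX file: missing ##TITLE=")
  xf <- ldr("XFACTOR"); yf <- ldr("YFACTOR")
  xfactor <- if (is.null(xf)) 1 else as.numeric(xf)
  yfactor <- if (is.null(yf)) 1 else as.numeric(yf)
  num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  parse_nums <- function(s) as.numeric(regmatches(s, gregexpr(num_re, s))[[1]])

  xy_start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  pts_start <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  block_lines <- function(start) {
    rest <- lines[(start + 1L):length(lines)]
    stop_at <- grep("^##", rest)
    if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1L)]
    rest[nzchar(trimws(rest))]
  }
  if (length(xy_start)) {
    body <- block_lines(xy_start[1])
    # X of each Y: first X on the line plus multiples of DELTAX
    dxl <- ldr("DELTAX")
    if (is.null(dxl)) {
      fx <- as.numeric(ldr("FIRSTX")); lx <- as.numeric(ldr("LASTX"))
      np <- as.numeric(ldr("NPOINTS"))
      if (anyNA(c(fx, lx, np))) stop("JCAMP-DX: need DELTAX or FIRSTX/LASTX/NPOINTS")
      deltax <- (lx - fx) / (np - 1)
    } else deltax <- as.numeric(dxl)
    # rebuild x: per line, start value + k*deltax
    x <- numeric(0); y <- numeric(0)
    for (bl in body) {
      v <- parse_nums(bl)
      if (length(v) < 2) next
      ys <- v[-1]
      x <- c(x, v[1] + (seq_along(ys) - 1L) * deltax)
      y <- c(y, ys)
    }
  } else if (length(pts_start)) {
    body <- block_lines(pts_start[1])
    v <- unlist(lapply(body, parse_nums))
    if (length(v) %% 2 != 0) stop("JCAMP-DX: XYPOINTS block has odd value count")
    x <- v[seq(1, length(v), by = 2)]
    y <- v[seq(2, length(v), by = 2)]
  } else {
    stop("JCAMP-DX: missing required ##XYDATA= or ##XYPOINTS= block")
  }
  x <- x * xfactor
  y <- y * yfactor
  if (is.null(sample_id)) {
    sample_id <- ldr("TITLE")
    if (!nzchar(sample_id)) sample_id <- "jcamp"
  }
  spectrum_set(x, matrix(y, nrow = 1), sample_ids = sample_id)
}
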