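#' Binarize the channels of an image stack
#'
#' Maps every marker channel to 0/1 pixel values, mirroring the
#' signal/noise separation step that precedes per-cell quantification:
#' per-cell "expression" is defined downstream as the fraction of positive
#' pixels, so channels must be binary before quantification.
#'
#' @param stack named list of 2-D numeric matrices of identical shape.
#' @param method per-channel threshold specification: `"otsu"` (default),
#'   `"identity"` (channel already 0/1; validated), a single number (pixels
#'   strictly above are positive), or a named list/vector mixing these,
#'   keyed by channel name.
#' @return named list of integer 0/1 matrices with attribute `thresholds`
#'   (named numeric; `NA` for identity channels).
#' @export
binarize_stack <- function(stack, method = "otsu") {
  check_stack(stack)
  chans <- names(stack)
  spec <- if (is.list(method) || (length(method) > 1L && !is.null(names(method)))) {
    if (!all(chans %in% names(method))) {
      stop("per-channel `method` must cover every channel")
    }
    as.list(method)[chans]
  } else {
    setNames(rep(list(method), length(chans)), chans)
  }
  thrs <- setNames(rep(NA_real_, length(chans)), chans)
  out <- vector("list", length(chans))
  names(out) <- chans
  for (ch in chans) {
    m <- spec[[ch]]
    img <- stack[[ch]]
    if (identical(m, "identity")) {
      if (!is_binary(img)) {
        stop(sprintf("channel '%s' is not 0/1 but method is \"identity\"", ch))
      }
      out[[ch]] <- matrix(as.integer(img), nrow(img), ncol(img))
    } else {
      thr <- if (identical(m, "otsu")) {
        otsu_threshold(img)
      } else if (is.numeric(m) && length(m) == 1L) {
        m
      } else {
        stop(sprintf("unknown binarization method for channel '%s'", ch))
      }
      thrs[[ch]] <- thr
      out[[ch]] <- matrix(as.integer(img > thr), nrow(img), ncol(img))
    }
  }
  attr(out, "thresholds") <- thrs
  out
}

check_stack <- function(stack) {
  if (!is.list(stack) || is.null(names(stack)) || !length(stack)) {
    stop("stack must be a non-empty named list of matrices")
  }
  dims <- lapply(stack, dim)
  for (d in dims) {
    if (is.null(d)) stop("stack channels must be 2-D matrices")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("stack channels must share one shape")
  }
  invisible(TRUE)
}

#' Quantify cells: positive-pixel fractions per marker
#'
#' For each cell in the label mask and each binary marker channel, computes
#' the relative frequency of positive pixels inside the cell — the per-cell
#' expression value of binarized IMC data (a cell with half its pixels
#' positive scores 0.5). Also reports area (px) and the centroid in um
#' (pixel centres; the pixel in row 1, column 1 is centred at (0.5, 0.5)).
#'
#' @param mask integer label matrix (0 = background).
#' @param binary named list of binary (0/1) channel matrices matching the
#'   mask's shape.
#' @param roi_id,sample_id identifiers stored with every cell.
#' @return a `cell_table` data.frame: `cell_id`, `roi_id`, `sample_id`,
#'   `x`, `y`, `area`, then one column per marker with fractions in [0, 1].
#'   Marker columns are recorded in attribute `markers`. An empty mask
#'   yields a 0-row table with a warning.
#' @export
quantify_cells <- function(mask, binary, roi_id = "roi1",
                           sample_id = "sample1") {
  stopifnot_2d(mask, "mask")
  check_stack(binary)
  if (!all(dim(binary[[1]]) == dim(mask))) {
    stop("mask and channels must share one shape")
  }
  for (ch in names(binary)) {
    if (!is_binary(binary[[ch]])) {
      stop(sprintf("channel '%s' is not binary", ch))
    }
  }
  markers <- names(binary)
  inside <- which(mask > 0)
  if (!length(inside)) {
    warning("empty mask: returning a 0-row cell table")
    tbl <- data.frame(cell_id = integer(), roi_id = character(),
                      sample_id = character(), x = numeric(), y = numeric(),
                      area = integer())
    for (m in markers) tbl[[m]] <- numeric()
    return(as_cell_table(tbl, markers))
  }
  lab <- mask[inside]
  ids <- sort(unique(lab))
  area <- as.vector(rowsum(rep(1L, length(inside)), lab))
  rr <- (inside - 1L) %% nrow(mask)   # 0-based row -> y
  cc <- (inside - 1L) %/% nrow(mask)  # 0-based col -> x
  x <- as.vector(rowsum(cc + 0.5, lab)) / area
  y <- as.vector(rowsum(rr + 0.5, lab)) / area
  tbl <- data.frame(cell_id = ids, roi_id = roi_id, sample_id = sample_id,
                    x = x, y = y, area = as.integer(area),
                    stringsAsFactors = FALSE)
  for (m in markers) {
    pos <- as.vector(rowsum(as.numeric(binary[[m]][inside]), lab))
    tbl[[m]] <- pos / area
  }
  as_cell_table(tbl, markers)
}

as_cell_table <- function(tbl, markers) {
  attr(tbl, "markers") <- markers
  class(tbl) <- c("cell_table", class(tbl))
  tbl
}

#' Marker columns of a cell table
#' @param table a `cell_table` (or any data.frame with a `markers` attribute).
#' @return character vector of marker column names.
#' @export
cell_markers <- function(table) {
  m <- attr(table, "markers")
  if (is.null(m)) {
    m <- setdiff(names(table), c("cell_id", "roi_id", "sample_id", "x", "y",
                                 "area", "cluster", "true_x", "true_y"))
  }
  m
}

#' Bind cell tables from several ROIs/samples
#' @param ... `cell_table` objects sharing marker columns.
#' @return a single `cell_table`.
#' @export
bind_cell_tables <- function(...) {
  tbls <- list(...)
  if (length(tbls) == 1L && is.list(tbls[[1]]) && !is.data.frame(tbls[[1]])) {
    tbls <- tbls[[1]]
  }
  markers <- cell_markers(tbls[[1]])
  for (t in tbls) {
    if (!identical(cell_markers(t), markers)) {
      stop("cell tables have differing marker sets")
    }
  }
  as_cell_table(do.call(rbind, lapply(tbls, as.data.frame)), markers)
}

#' Write a cell table to CSV or FCS
#'
#' CSV keeps every column; FCS 3.0 stores the numeric columns (`cell_id`,
#' `x`, `y`, `area` and the marker fractions) as one float32 event per
#' cell, one parameter per column — the format in which per-cell binarized
#' marker expression is conventionally exchanged with cytometry tools.
#'
#' @param table a `cell_table`.
#' @param path output file path.
#' @param format `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (!length(cell_markers(table))) stop("cell table has no marker columns")
  if (format == "csv") {
    write.csv(as.data.frame(table), path, row.names = FALSE)
  } else {
    num <- vapply(table, is.numeric, logical(1))
    write_fcs(as.data.frame(table)[, num, drop = FALSE], path)
  }
  invisible(path)
}

#' Read a cell table written by [write_cell_table()]
#' @param path CSV file path.
#' @param markers optional marker column names; defaults to every column
#'   after `area`.
#' @return a `cell_table`.
#' @export
read_cell_table <- function(path, markers = NULL) {
  tbl <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(markers)) {
    i <- match("area", names(tbl))
    markers <- setdiff(names(tbl)[seq_len(ncol(tbl)) > i],
                       c("cluster", "true_x", "true_y"))
  }
  as_cell_table(tbl, markers)
}
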