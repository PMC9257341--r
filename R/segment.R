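#' Segment nuclei from a DNA channel
#'
#' Thresholds the DNA channel and labels connected components
#' (4-connectivity) as primary objects, dropping components smaller than
#' `min_area`. Labels are renumbered 1..n in raster-scan order (top-left
#' origin, row-major) of each component's first pixel, so the labelling is
#' independent of the component-search order.
#'
#' @param dna 2-D non-negative numeric matrix (the DNA channel).
#' @param threshold `"otsu"` (default) for Otsu's threshold on the channel,
#'   or a fixed numeric intensity; pixels strictly above the threshold are
#'   foreground.
#' @param min_area minimum component area in pixels; smaller components are
#'   removed.
#' @return integer label matrix (0 = background), class `label_mask` with
#'   attribute `threshold`.
#' @export
segment_nuclei <- function(dna, threshold = "otsu", min_area = 10L) {
  stopifnot_2d(dna, "dna")
  if (any(dna < 0)) stop("dna must be non-negative")
  if (min_area < 0) stop("min_area must be non-negative")
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(dna)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else {
    stop("threshold must be \"otsu\" or a single number")
  }
  bin <- dna > thr
  if (!any(bin)) {
    out <- matrix(0L, nrow(dna), ncol(dna))
    attr(out, "threshold") <- thr
    class(out) <- c("label_mask", class(out))
    return(out)
  }
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(dna), ncol(dna))
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_area)
  relab <- integer(max(lab) + 1L)
  if (length(keep)) {
    # order surviving components by raster-scan position of first pixel
    rs <- raster_first_pixel(lab, keep)
    relab[keep[order(rs)] + 1L] <- seq_along(keep)
  }
  out <- matrix(relab[lab + 1L], nrow(dna), ncol(dna))
  attr(out, "threshold") <- thr
  class(out) <- c("label_mask", class(out))
  out
}

# min row-major linear index per label (top-left origin, rows scan first)
raster_first_pixel <- function(lab, labels) {
  idx <- which(lab %in% labels)
  rr <- (idx - 1L) %% nrow(lab)          # 0-based row
  cc <- (idx - 1L) %/% nrow(lab)         # 0-based col
  rm_idx <- rr * ncol(lab) + cc
  vapply(labels, function(l) min(rm_idx[lab[idx] == l]), numeric(1))
}

#' Otsu threshold of an image
#'
#' Finds the threshold maximizing between-class variance on a 256-bin
#' histogram (via EBImage). Returns a value on the image's intensity scale;
#' foreground is `pixel > threshold`.
#'
#' @param x 2-D numeric matrix.
#' @return a single threshold value.
#' @export
otsu_threshold <- function(x) {
  stopifnot_2d(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])  # flat image: nothing above threshold
  sc <- (x - rng[1]) / (rng[2] - rng[1])
  t01 <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1), levels = 256L)
  rng[1] + t01 * (rng[2] - rng[1])
}

#' Expand mask labels by a Euclidean distance
#'
#' Every background pixel within Euclidean distance `distance` of a labeled
#' pixel is claimed by the label of its nearest labeled pixel
#' (pixel-to-pixel distance over integer offsets); when two labels are
#' equally near, the lower label id wins. Original labeled pixels never
#' change and labels never merge — expanded cells abut along their shared
#' frontier. This reproduces the mask-construction step in which
#' DNA-derived primary objects are grown by 2 px (2 um) so that membrane
#' marker signal falls inside each cell.
#'
#' @param mask integer label matrix (0 = background).
#' @param distance expansion distance in pixels (>= 0); 0 returns the input.
#' @return expanded label matrix of the same shape and class.
#' @export
expand_labels <- function(mask, distance = 2) {
  stopifnot_2d(mask, "mask")
  if (distance < 0) stop("distance must be non-negative")
  out <- mask
  if (distance == 0 || !any(mask > 0)) return(out)
  H <- nrow(mask); W <- ncol(mask)
  src <- which(mask > 0)
  src_r <- (src - 1L) %% H
  src_c <- (src - 1L) %/% H
  src_l <- mask[src]
  best <- matrix(Inf, H, W)
  best[src] <- 0
  off <- disk_offsets(distance)
  off <- off[off$d2 > 0, , drop = FALSE]
  for (d2 in unique(off$d2)) {
    grp <- off[off$d2 == d2, , drop = FALSE]
    idx_all <- integer(0); lab_all <- integer(0)
    for (k in seq_len(nrow(grp))) {
      rr <- src_r + grp$dy[k]; cc <- src_c + grp$dx[k]
      inb <- rr >= 0 & rr < H & cc >= 0 & cc < W
      idx_all <- c(idx_all, cc[inb] * H + rr[inb] + 1L)
      lab_all <- c(lab_all, src_l[inb])
    }
    o <- order(idx_all, lab_all)
    idx_all <- idx_all[o]; lab_all <- lab_all[o]
    keep <- !duplicated(idx_all)
    idx <- idx_all[keep]; lab <- lab_all[keep]
    sel <- d2 < best[idx]
    out[idx[sel]] <- lab[sel]
    best[idx[sel]] <- d2
  }
  out
}

#' Match segmented labels to ground-truth labels by majority overlap
#'
#' For each label of `mask`, finds the ground-truth label covering the
#' largest share of its pixels. Used to align a segmentation with the
#' generator's ground truth when evaluating recovery.
#'
#' @param mask segmented label matrix.
#' @param truth ground-truth label matrix of the same shape.
#' @return named integer vector: `truth` label (or `NA` if the cell
#'   overlaps no ground-truth pixel) for each mask label.
#' @export
match_labels <- function(mask, truth) {
  if (!all(dim(mask) == dim(truth))) stop("shape mismatch")
  ids <- sort(unique(mask[mask > 0]))
  both <- mask > 0 & truth > 0
  out <- setNames(rep(NA_integer_, length(ids)), ids)
  if (any(both)) {
    ov <- table(mask[both], truth[both])
    hit <- rownames(ov)
    out[hit] <- as.integer(colnames(ov)[apply(ov, 1, which.max)])
  }
  out
}
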