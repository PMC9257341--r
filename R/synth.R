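#' Simulate a marked point pattern of cells
#'
#' Generates cell positions (continuous coordinates, 1 unit = 1 um) and
#' cluster labels inside a rectangular field, optionally planting pairwise
#' spatial structure between two clusters:
#'
#' * `csr`: complete spatial randomness — independent uniform positions and
#'   independent multinomial labels.
#' * `attract`: a two-type Thomas-style construction. A Poisson number of
#'   parents (expectation `n_parents`) is placed uniformly; each parent
#'   spawns one cell of each member of the planted pair, displaced by an
#'   isotropic Gaussian with standard deviation `sigma` um (reflected at the
#'   field boundary). The remaining cells are CSR with multinomial labels.
#' * `repel`: sequential hard-core rejection — a candidate position is
#'   rejected while it lies within `hardcore` um of an already placed cell
#'   of the opposing planted cluster (or of any cell when `pair` is `NULL`,
#'   giving an all-cell minimum spacing useful for non-overlapping nuclei).
#'
#' @param n_cells number of cells to place.
#' @param freqs named numeric vector of cluster probabilities; must sum to 1
#'   (tolerance 1e-9).
#' @param field `c(width, height)` of the field in pixels (= um).
#' @param interaction list with `mode` one of `"csr"`, `"attract"`,
#'   `"repel"`; for `attract` also `pair` (two cluster names), `sigma` (um)
#'   and `n_parents` (expected parent count); for `repel` also `hardcore`
#'   (um), optional `pair` and optional `max_tries` (default 200 per cell).
#' @param seed integer seed; identical inputs give an identical pattern.
#' @return an object of class `point_pattern`: a list with `points`
#'   (data.frame `x`, `y`, `label`), `field`, `clusters`, `interaction`,
#'   `seed`.
#' @export
simulate_pattern <- function(n_cells, freqs, field = c(500, 500),
                             interaction = list(mode = "csr"), seed = 1L) {
  if (is.null(names(freqs)) || any(names(freqs) == "")) {
    stop("`freqs` must be a named vector of cluster probabilities")
  }
  if (abs(sum(freqs) - 1) > 1e-9) stop("`freqs` must sum to 1")
  if (any(freqs < 0)) stop("`freqs` must be non-negative")
  if (length(field) != 2L || any(field <= 0)) {
    stop("`field` must be two positive dimensions (width, height)")
  }
  mode <- match.arg(interaction$mode %||% "csr", c("csr", "attract", "repel"))
  w <- field[[1]]; h <- field[[2]]
  clusters <- names(freqs)

  pts <- with_seed(seed, {
    if (n_cells == 0L) {
      data.frame(x = numeric(), y = numeric(), label = character(),
                 stringsAsFactors = FALSE)
    } else if (mode == "csr") {
      data.frame(
        x = runif(n_cells, 0, w), y = runif(n_cells, 0, h),
        label = sample(clusters, n_cells, replace = TRUE, prob = freqs),
        stringsAsFactors = FALSE
      )
    } else if (mode == "attract") {
      pair <- interaction$pair
      sigma <- interaction$sigma
      if (is.null(pair) || length(pair) != 2L || !all(pair %in% clusters)) {
        stop("attract mode needs `pair`: two clusters present in `freqs`")
      }
      if (is.null(sigma) || sigma <= 0) stop("attract mode needs `sigma` > 0")
      if (is.null(interaction$n_parents)) {
        stop("attract mode needs `n_parents` (expected parent count)")
      }
      np <- min(rpois(1L, interaction$n_parents), floor(n_cells / 2))
      px <- runif(np, 0, w); py <- runif(np, 0, h)
      ox <- reflect_into(rep(px, 2L) + rnorm(2L * np, 0, sigma), w)
      oy <- reflect_into(rep(py, 2L) + rnorm(2L * np, 0, sigma), h)
      n_rest <- n_cells - 2L * np
      data.frame(
        x = c(ox, runif(n_rest, 0, w)),
        y = c(oy, runif(n_rest, 0, h)),
        label = c(rep(pair, each = np),
                  sample(clusters, n_rest, replace = TRUE, prob = freqs)),
        stringsAsFactors = FALSE
      )
    } else {
      hc <- interaction$hardcore
      if (is.null(hc) || hc <= 0) stop("repel mode needs `hardcore` > 0")
      place_hardcore(n_cells, clusters, freqs, w, h, hc,
                     pair = interaction$pair,
                     max_tries = interaction$max_tries %||% 200L)
    }
  })
  structure(list(points = pts, field = c(width = w, height = h),
                 clusters = clusters, interaction = interaction,
                 seed = as.integer(seed)),
            class = "point_pattern")
}

# reflect coordinates at 0 and at `len` until inside [0, len)
reflect_into <- function(x, len) {
  x <- x %% (2 * len)
  x <- ifelse(x >= len, 2 * len - x, x)
  pmin(x, len * (1 - 1e-12))
}

# sequential hard-core placement with grid-bucket neighbour lookup.
# the hard-core constraint applies between `pair[1]` and `pair[2]` labels,
# or between all cells when pair is NULL.
place_hardcore <- function(n, clusters, freqs, w, h, hc, pair, max_tries) {
  labels <- sample(clusters, n, replace = TRUE, prob = freqs)
  if (!is.null(pair)) {
    if (length(pair) != 2L || !all(pair %in% clusters)) {
      stop("repel `pair` must name two clusters in `freqs`")
    }
  }
  cs <- hc  # grid cell size
  nbx <- max(1L, ceiling(w / cs)); nby <- max(1L, ceiling(h / cs))
  buckets <- vector("list", nbx * nby)
  xs <- numeric(n); ys <- numeric(n)
  bkey <- function(x, y) {
    pmin(floor(x / cs), nbx - 1) * nby + pmin(floor(y / cs), nby - 1) + 1
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    constrained <- is.null(pair) || labels[i] %in% pair
    other <- if (is.null(pair)) NULL else setdiff(pair, labels[i])
    for (try in seq_len(max_tries)) {
      cx <- runif(1, 0, w); cy <- runif(1, 0, h)
      ok <- TRUE
      if (constrained && i > 1L) {
        bx <- min(floor(cx / cs), nbx - 1); by <- min(floor(cy / cs), nby - 1)
        for (dx in -1:1) for (dy in -1:1) {
          jx <- bx + dx; jy <- by + dy
          if (jx < 0 || jy < 0 || jx >= nbx || jy >= nby) next
          cand <- buckets[[jx * nby + jy + 1]]
          if (!length(cand)) next
          if (!is.null(pair)) cand <- cand[labels[cand] %in% other]
          if (!length(cand)) next
          if (any((xs[cand] - cx)^2 + (ys[cand] - cy)^2 < hc^2)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        xs[i] <- cx; ys[i] <- cy
        k <- bkey(cx, cy)
        buckets[[k]] <- c(buckets[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0(
        "hard-core placement infeasible: cell %d of %d could not be placed ",
        "after %d tries (hardcore = %g um in a %g x %g field)"),
        i, n, max_tries, hc, w, h))
    }
  }
  data.frame(x = xs, y = ys, label = labels, stringsAsFactors = FALSE)
}

#' Rasterize a point pattern into an IMC-like image stack with ground truth
#'
#' Each cell is drawn as a nucleus disk (integer pixel offsets with
#' `dx^2 + dy^2 <= r^2` around the cell's pixel). The DNA channel is positive
#' exactly on the nucleus disks. The ground-truth label mask covers the
#' union of disks, with overlapping pixels assigned to the nearest nucleus
#' centre (ties to the lower cell id). Marker channels are positive on the
#' membrane-expanded footprint (`panel$expand` px) of every cell whose
#' cluster is positive for that marker, then corrupted by the panel's
#' per-channel false-positive / false-negative pixel noise. The ground-truth
#' cell table holds positive-pixel fractions quantified on the nucleus mask
#' plus the true cluster and the true (continuous) centre.
#'
#' @param pattern a `point_pattern` from [simulate_pattern()].
#' @param panel a `panel_spec`.
#' @param seed integer seed for the pixel noise.
#' @param roi_id,sample_id identifiers recorded in the ground-truth table.
#' @return list with `stack` (named list of integer 0/1 matrices, `DNA`
#'   first), `mask` (ground-truth label matrix), `table` (ground-truth
#'   `cell_table` with `cluster`, `true_x`, `true_y` columns).
#' @export
rasterize_pattern <- function(pattern, panel, seed = 1L,
                              roi_id = "roi1", sample_id = "sample1") {
  stopifnot(inherits(pattern, "point_pattern"), inherits(panel, "panel_spec"))
  missing_cl <- setdiff(unique(pattern$points$label), names(panel$clusters))
  if (length(missing_cl)) {
    stop("panel is missing cluster(s): ", paste(missing_cl, collapse = ", "))
  }
  w <- pattern$field[["width"]]; h <- pattern$field[["height"]]
  W <- as.integer(ceiling(w)); H <- as.integer(ceiling(h))
  pts <- pattern$points
  n <- nrow(pts)
  r <- panel$nucleus_radius

  mask <- draw_nucleus_mask(pts$x, pts$y, W, H, r)
  footprint <- expand_labels(mask, panel$expand)

  chans <- c("DNA", panel$markers)
  pos_of <- lapply(panel$markers, function(m) {
    which(vapply(panel$clusters[pts$label],
                 function(cl) m %in% cl$positive, logical(1)))
  })
  names(pos_of) <- panel$markers

  stack <- with_seed(seed, {
    out <- vector("list", length(chans))
    names(out) <- chans
    for (ch in chans) {
      img <- if (ch == "DNA") {
        matrix(as.integer(mask > 0), H, W)
      } else {
        ids <- pos_of[[ch]]
        lut <- integer(n + 1L)  # footprint value 0..n -> 0/1
        lut[ids + 1L] <- 1L
        matrix(lut[footprint + 1L], H, W)
      }
      fp <- panel$fp_rate[[ch]]; fn <- panel$fn_rate[[ch]]
      if (fp > 0) {
        i0 <- which(img == 0L)
        img[i0[runif(length(i0)) < fp]] <- 1L
      }
      if (fn > 0) {
        i1 <- which(img == 1L)
        img[i1[runif(length(i1)) < fn]] <- 0L
      }
      out[[ch]] <- img
    }
    out
  })

  tbl <- quantify_cells(mask, stack[panel$markers],
                        roi_id = roi_id, sample_id = sample_id)
  # quantification is on the noiseless geometry's nucleus mask: all ids exist
  tbl$cluster <- pts$label[tbl$cell_id]
  tbl$true_x <- pts$x[tbl$cell_id]
  tbl$true_y <- pts$y[tbl$cell_id]
  list(stack = stack, mask = mask, table = tbl)
}

# union-of-disks label mask; overlap -> nearest centre (by pixel offset
# distance), ties -> lower cell id
draw_nucleus_mask <- function(x, y, W, H, r) {
  mask <- matrix(0L, H, W)
  if (!length(x)) return(mask)
  off <- disk_offsets(r)
  px <- floor(x); py <- floor(y)  # 0-based pixel coords
  if (any(px < 0 | py < 0 | px >= W | py >= H)) {
    stop("pattern points outside the field")
  }
  best <- matrix(Inf, H, W)
  ids <- seq_along(x)
  for (d2 in unique(off$d2)) {
    grp <- off[off$d2 == d2, , drop = FALSE]
    idx_all <- integer(0); id_all <- integer(0)
    for (k in seq_len(nrow(grp))) {
      cc <- px + grp$dx[k]; rr <- py + grp$dy[k]
      inb <- cc >= 0 & cc < W & rr >= 0 & rr < H
      idx_all <- c(idx_all, cc[inb] * H + rr[inb] + 1L)
      id_all <- c(id_all, ids[inb])
    }
    o <- order(idx_all, id_all)
    idx_all <- idx_all[o]; id_all <- id_all[o]
    keep <- !duplicated(idx_all)
    idx <- idx_all[keep]; id <- id_all[keep]
    sel <- d2 < best[idx]
    mask[idx[sel]] <- id[sel]
    best[idx[sel]] <- d2
  }
  mask
}
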