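#' Build a radius-based cell neighbor graph
#'
#' Two cells are neighbors when they lie within the proximity radius
#' (default 10 px = 10 um, at which the first ring of surrounding cells is
#' captured without an intervening cell). In `centroid` mode the Euclidean
#' centroid distance is used; in `boundary` mode the minimum distance
#' between the two cells' mask pixels, so touching or membrane-adjacent
#' cells are neighbors regardless of size. The comparison is inclusive
#' (distance <= radius). Edges never cross ROI boundaries, and adjacency
#' depends only on geometry, never on phenotype labels.
#'
#' @param cells a `cell_table` (columns `x`, `y`, `roi_id`, `sample_id`).
#' @param radius proximity radius in pixels (> 0); default 10.
#' @param mode `"boundary"` (default; requires `masks`) or `"centroid"`.
#' @param masks for boundary mode: a label matrix, or a named list of label
#'   matrices keyed by `roi_id`, whose labels are the table's `cell_id`s.
#' @return a `neighbor_graph`: list with `n`, `edges` (data.frame `i`, `j`
#'   of row indices into `cells`, `i < j`), `roi_id`, `sample_id`,
#'   `radius`, `mode`.
#' @export
build_neighbor_graph <- function(cells, radius = 10,
                                 mode = c("boundary", "centroid"),
                                 masks = NULL) {
  mode <- match.arg(mode)
  if (radius <= 0) stop("radius must be positive")
  if (mode == "boundary" && is.null(masks)) {
    stop("boundary mode requires `masks`")
  }
  df <- as.data.frame(cells)
  if (anyNA(df$x) || anyNA(df$y)) stop("cells with missing coordinates")
  roi <- as.character(df$roi_id %||% rep("roi1", nrow(df)))
  if (is.matrix(masks)) masks <- setNames(list(masks), unique(roi))
  edges_list <- list()
  for (r in unique(roi)) {
    idx <- which(roi == r)
    e <- if (mode == "centroid") {
      radius_pairs(df$x[idx], df$y[idx], radius)
    } else {
      if (!r %in% names(masks)) stop("no mask for ROI ", r)
      boundary_pairs(df$x[idx], df$y[idx], df$cell_id[idx],
                     masks[[r]], radius)
    }
    if (nrow(e)) {
      edges_list[[r]] <- data.frame(i = idx[e$i], j = idx[e$j])
    }
  }
  edges <- if (length(edges_list)) {
    do.call(rbind, edges_list)
  } else {
    data.frame(i = integer(), j = integer())
  }
  rownames(edges) <- NULL
  structure(list(
    n = nrow(df), edges = edges, roi_id = roi,
    sample_id = as.character(df$sample_id %||% rep("sample1", nrow(df))),
    radius = radius, mode = mode
  ), class = "neighbor_graph")
}

# all pairs with centroid distance <= r, via grid buckets (exact)
radius_pairs <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(data.frame(i = integer(), j = integer()))
  bx <- floor(x / r); by <- floor(y / r)
  key <- paste(bx, by)
  groups <- split(seq_len(n), key)
  ij_i <- integer(0); ij_j <- integer(0)
  keys <- names(groups)
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys) assign(k, groups[[k]], envir = keymap)
  bxy <- do.call(rbind, strsplit(keys, " "))
  gbx <- as.numeric(bxy[, 1]); gby <- as.numeric(bxy[, 2])
  # half-neighbourhood so each bin pair is visited once
  offs <- list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))
  for (g in seq_along(keys)) {
    a <- groups[[g]]
    for (o in offs) {
      k2 <- paste(gbx[g] + o[1], gby[g] + o[2])
      b <- if (identical(o, c(0, 0))) a else {
        if (!exists(k2, envir = keymap, inherits = FALSE)) next
        get(k2, envir = keymap, inherits = FALSE)
      }
      if (identical(o, c(0, 0))) {
        if (length(a) < 2L) next
        prs <- which(outer(a, a, "<"), arr.ind = TRUE)
        ii <- a[prs[, 1]]; jj <- a[prs[, 2]]
      } else {
        ii <- rep(a, each = length(b)); jj <- rep(b, length(a))
      }
      d2 <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2
      sel <- d2 <= r^2
      ij_i <- c(ij_i, pmin(ii[sel], jj[sel]))
      ij_j <- c(ij_j, pmax(ii[sel], jj[sel]))
    }
  }
  unique(data.frame(i = ij_i, j = ij_j))
}

# pairs whose minimum mask-pixel distance is <= r; candidates pruned by
# centroid distance <= r + bounding radii, then checked exactly
boundary_pairs <- function(x, y, cell_id, mask, r) {
  n <- length(x)
  if (n < 2L) return(data.frame(i = integer(), j = integer()))
  idx <- which(mask > 0)
  lab <- mask[idx]
  pr <- (idx - 1L) %% nrow(mask) + 0.5
  pc <- (idx - 1L) %/% nrow(mask) + 0.5
  pix <- split(data.frame(px = pc, py = pr), lab)
  brad <- numeric(n)
  for (k in seq_len(n)) {
    p <- pix[[as.character(cell_id[k])]]
    if (is.null(p)) stop("cell_id ", cell_id[k], " absent from mask")
    brad[k] <- sqrt(max((p$px - x[k])^2 + (p$py - y[k])^2))
  }
  cand <- radius_pairs(x, y, r + 2 * max(brad))
  keep <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    i <- cand$i[e]; j <- cand$j[e]
    cd <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (cd > r + brad[i] + brad[j]) next
    a <- pix[[as.character(cell_id[i])]]
    b <- pix[[as.character(cell_id[j])]]
    d2 <- outer(a$px, b$px, "-")^2 + outer(a$py, b$py, "-")^2
    keep[e] <- min(d2) <= r^2
  }
  cand[keep, , drop = FALSE]
}

# block-diagonal (per-ROI by construction) sparse adjacency
graph_adjacency <- function(graph) {
  n <- graph$n
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                       x = 1, dims = c(n, n))
}

# observed counts: for each (sample, clusterA, clusterB), the number of A
# cells with >= 1 B neighbor; rows ordered sample-major (all clusters of
# sample 1, then sample 2, ...), rownames "<sample>\r<cluster>"
observed_counts <- function(A, labels, sample_id, clusters, samples) {
  K <- length(clusters)
  L <- matrix(0, length(labels), K)
  L[cbind(seq_along(labels), match(labels, clusters))] <- 1
  hasB <- as.matrix(A %*% L) > 0
  num0 <- rowsum(hasB + 0, paste(sample_id, labels, sep = "\r"))
  rows <- as.vector(outer(clusters, samples,
                          function(cl, s) paste(s, cl, sep = "\r")))
  num <- matrix(0, length(rows), K, dimnames = list(rows, clusters))
  hit <- intersect(rownames(num0), rows)
  num[hit, ] <- num0[hit, , drop = FALSE]
  num
}

#' Observed, expected and corrected microenvironment percentages
#'
#' For every ordered cluster pair (A, B) and sample: the observed
#' microenvironment is the fraction of A cells having at least one B cell
#' within the proximity radius, pooled over the sample's ROIs (count of A
#' cells with a co-localized B divided by the number of A cells in the
#' sample). The expected value is the product of the two clusters'
#' frequencies over the chosen denominator — the chance of finding random
#' cells in the microenvironment — and the corrected value is observed
#' minus expected.
#'
#' @param graph a `neighbor_graph`.
#' @param assign a `phenotype_assignment` or a character label vector
#'   aligned with the graph's cells.
#' @param denominator clusters forming the frequency denominator (default:
#'   all observed clusters).
#' @return data.frame `sample_id`, `cluster_a`, `cluster_b`, `n_a`,
#'   `observed`, `expected`, `corrected`; rows for clusters absent from a
#'   sample carry `NA` observed values.
#' @export
microenvironment_matrix <- function(graph, assign, denominator = NULL) {
  labels <- if (inherits(assign, "phenotype_assignment")) {
    assign$cluster
  } else {
    as.character(assign)
  }
  if (length(labels) != graph$n) stop("labels do not match the graph")
  clusters <- sort(unique(labels))
  denominator <- denominator %||% clusters
  samples <- unique(graph$sample_id)
  A <- graph_adjacency(graph)
  num <- observed_counts(A, labels, graph$sample_id, clusters, samples)
  out <- list()
  for (s in samples) {
    ns <- vapply(clusters, function(cl) {
      sum(graph$sample_id == s & labels == cl)
    }, numeric(1))
    denom_n <- sum(ns[intersect(clusters, denominator)])
    f <- setNames(rep(NA_real_, length(clusters)), clusters)
    if (denom_n > 0) {
      f[denominator[denominator %in% clusters]] <-
        ns[denominator[denominator %in% clusters]] / denom_n
    }
    numb <- num[paste(s, clusters, sep = "\r"), , drop = FALSE]
    obs <- sweep(numb, 1, ifelse(ns > 0, ns, NA), "/")
    g <- expand.grid(cluster_b = clusters, cluster_a = clusters,
                     stringsAsFactors = FALSE)[, 2:1]
    g$sample_id <- s
    g$n_a <- ns[g$cluster_a]
    g$observed <- obs[cbind(match(g$cluster_a, clusters),
                            match(g$cluster_b, clusters))]
    g$expected <- f[g$cluster_a] * f[g$cluster_b]
    g$corrected <- g$observed - g$expected
    out[[s]] <- g[, c("sample_id", "cluster_a", "cluster_b", "n_a",
                      "observed", "expected", "corrected")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation z-scores for microenvironment enrichment
#'
#' Tests whether the observed co-localization percentages could occur with
#' random cell placement: phenotype labels are shuffled uniformly within
#' each ROI (preserving composition and geometry), the observed
#' percentages are recomputed per permutation and pooled per sample, and
#' `z = (observed - mean_perm) / sd_perm`. Pairs whose permutation
#' distribution is degenerate (`sd = 0`) get `z = 0` (conservative) and
#' are flagged. Significance uses the two-sided normal cutoff 1.96
#' (p < 0.05).
#'
#' @param graph a `neighbor_graph` (geometry is never permuted).
#' @param assign labels as in [microenvironment_matrix()].
#' @param n_perm number of permutations (>= 2); default 1000.
#' @param seed integer seed (mandatory for reproducibility).
#' @param cutoff absolute z cutoff for the significance flag.
#' @return data.frame `sample_id`, `cluster_a`, `cluster_b`, `observed`,
#'   `perm_mean`, `perm_sd`, `z`, `significant`, `sd_zero`, `n_perm`,
#'   `seed`.
#' @export
permutation_z <- function(graph, assign, n_perm = 1000L, seed,
                          cutoff = 1.96) {
  if (n_perm < 2L) stop("n_perm must be >= 2")
  if (missing(seed)) stop("`seed` is required")
  labels <- if (inherits(assign, "phenotype_assignment")) {
    assign$cluster
  } else {
    as.character(assign)
  }
  if (length(labels) != graph$n) stop("labels do not match the graph")
  clusters <- sort(unique(labels))
  samples <- unique(graph$sample_id)
  A <- graph_adjacency(graph)
  ns <- matrix(0, length(samples), length(clusters),
               dimnames = list(samples, clusters))
  for (s in samples) {
    for (cl in clusters) {
      ns[s, cl] <- sum(graph$sample_id == s & labels == cl)
    }
  }
  n_a_vec <- as.vector(t(ns))  # sample-major, matching observed_counts rows
  obs_of <- function(lab) {
    num <- observed_counts(A, lab, graph$sample_id, clusters, samples)
    num / ifelse(n_a_vec > 0, n_a_vec, NA)
  }
  real <- obs_of(labels)
  roi_split <- split(seq_len(graph$n), graph$roi_id)
  sums <- real * 0; sq <- real * 0
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      lab <- labels
      for (idx in roi_split) lab[idx] <- lab[idx][sample.int(length(idx))]
      o <- obs_of(lab)
      sums <- sums + o
      sq <- sq + o^2
    }
  })
  m <- sums / n_perm
  v <- (sq - n_perm * m^2) / (n_perm - 1)
  sdp <- sqrt(pmax(v, 0))
  z <- (real - m) / sdp
  z[!is.finite(z)] <- 0
  sdp[!is.finite(sdp)] <- 0
  out <- list()
  for (s in samples) {
    g <- expand.grid(cluster_b = clusters, cluster_a = clusters,
                     stringsAsFactors = FALSE)[, 2:1]
    ij <- cbind(match(paste(s, g$cluster_a, sep = "\r"), rownames(real)),
                match(g$cluster_b, clusters))
    out[[s]] <- data.frame(
      sample_id = s, cluster_a = g$cluster_a, cluster_b = g$cluster_b,
      observed = real[ij], perm_mean = m[ij], perm_sd = sdp[ij],
      z = z[ij], significant = abs(z[ij]) >= cutoff & sdp[ij] > 0,
      sd_zero = sdp[ij] == 0, n_perm = as.integer(n_perm),
      seed = as.integer(seed), stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full microenvironment analysis for one cell table
#'
#' Convenience wrapper: builds the neighbor graph, computes observed /
#' expected / corrected percentages and permutation z-scores, and merges
#' them into one long table.
#'
#' @inheritParams build_neighbor_graph
#' @inheritParams permutation_z
#' @param denominator clusters for the frequency denominator.
#' @return long data.frame with observed, expected, corrected, z,
#'   significance and provenance columns.
#' @export
microenvironment_analysis <- function(cells, assign, radius = 10,
                                      mode = c("boundary", "centroid"),
                                      masks = NULL, denominator = NULL,
                                      n_perm = 1000L, seed) {
  mode <- match.arg(mode)
  graph <- build_neighbor_graph(cells, radius = radius, mode = mode,
                                masks = masks)
  base <- microenvironment_matrix(graph, assign, denominator = denominator)
  pz <- permutation_z(graph, assign, n_perm = n_perm, seed = seed)
  merge(base, pz[, c("sample_id", "cluster_a", "cluster_b", "z",
                     "significant", "sd_zero", "n_perm", "seed")],
        by = c("sample_id", "cluster_a", "cluster_b"), sort = FALSE)
}
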