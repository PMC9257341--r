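#' Build a gating tree node
#'
#' A node matches a cell when all of `all_of` are positive, at least one of
#' `any_of` is positive (if `any_of` is non-empty), and none of `none_of`
#' is positive, where "positive" means the cell's positive-pixel fraction
#' for that marker is at or above the config's threshold. The special rule
#' `"no_marker"` matches cells with no positive marker at all.
#'
#' @param name cluster label assigned when the node is a leaf (and the
#'   merge target when children are merged upward).
#' @param all_of,any_of,none_of marker name vectors.
#' @param children list of child nodes, tried in order; a cell matching the
#'   node but no child keeps the node's own label.
#' @param special `NULL` or `"no_marker"`.
#' @return a `gate_node` list.
#' @export
gate_node <- function(name, all_of = character(), any_of = character(),
                      none_of = character(), children = list(),
                      special = NULL) {
  structure(list(name = name, all_of = all_of, any_of = any_of,
                 none_of = none_of, children = children, special = special),
            class = "gate_node")
}

#' Hierarchical gating configuration
#'
#' @param root a `gate_node` whose children are the top-level gates; cells
#'   matching no top-level gate receive the `fallback` label.
#' @param threshold positivity cutoff on positive-pixel fractions
#'   (fraction >= threshold is positive). Default 0.25.
#' @param fallback label for cells matching no gate at the top level.
#' @return a `gating_config`.
#' @export
gating_config <- function(root, threshold = 0.25, fallback = "unknown") {
  structure(list(root = root, threshold = threshold, fallback = fallback),
            class = "gating_config")
}

#' Default decidua gating hierarchy
#'
#' Encodes the phenotype hierarchy used for decidual IMC data on binarized
#' marker fractions:
#' cells without any positive marker are `background`; keratin/HLA-G
#' positive cells are `trophoblast`; vimentin/aSMA positive CD45-negative
#' cells are `stromal`; CD45+ cells split into lineages — myeloid
#' (CD14/CD68/CD163), NK (CD56/CD7 without myeloid markers), T (CD3; then
#' CD4+, CD8+, double-negative), granulocyte (CD66b/CD15). Myeloid cells
#' subcluster into a CD14- CD204+ HLA-DR+ CD11c+ monocyte-derived-DC-like
#' leaf (`MoDC`), a CD14+CD56+ leaf (`dM3`), and the four
#' HLA-DR x DC-SIGN combinations (`dM1` = DR-SIGN+, `dM4` = DR-SIGN-,
#' `dM2` = DR+SIGN+, `dM5` = DR+SIGN-). The DR/SIGN-to-id map is a
#' convention and can be overridden by editing the returned tree.
#'
#' @param threshold positivity cutoff on fractions (default 0.25).
#' @param nk_subsets if `TRUE`, adds optional CD69/CD11c/CD103-based NK
#'   leaves (tissue-resident `dNK_CD69` vs `dNK_CD69neg`).
#' @return a `gating_config`.
#' @export
decidua_gating <- function(threshold = 0.25, nk_subsets = FALSE) {
  myeloid_children <- list(
    gate_node("MoDC", all_of = c("CD204", "HLA-DR", "CD11c"),
              none_of = "CD14"),
    gate_node("dM3", all_of = c("CD14", "CD56")),
    gate_node("dM1", all_of = "DC-SIGN", none_of = "HLA-DR"),
    gate_node("dM4", none_of = c("DC-SIGN", "HLA-DR")),
    gate_node("dM2", all_of = c("HLA-DR", "DC-SIGN")),
    gate_node("dM5", all_of = "HLA-DR", none_of = "DC-SIGN")
  )
  nk_children <- if (nk_subsets) {
    list(gate_node("dNK_CD69", all_of = "CD69"),
         gate_node("dNK_CD69neg", none_of = "CD69"))
  } else {
    list()
  }
  t_children <- list(
    gate_node("T_CD4", all_of = "CD4", none_of = "CD8a"),
    gate_node("T_CD8", all_of = "CD8a", none_of = "CD4"),
    gate_node("T_DN", none_of = c("CD4", "CD8a"))
  )
  immune <- gate_node(
    "immune", all_of = "CD45",
    children = list(
      gate_node("myeloid", any_of = c("CD14", "CD68", "CD163"),
                children = myeloid_children),
      gate_node("NK", any_of = c("CD56", "CD7"),
                none_of = c("CD14", "CD68", "CD163"),
                children = nk_children),
      gate_node("T", all_of = "CD3", children = t_children),
      gate_node("granulocyte", any_of = c("CD66b", "CD15"))
    )
  )
  root <- gate_node(
    "all", children = list(
      gate_node("background", special = "no_marker"),
      immune,
      gate_node("trophoblast", any_of = c("keratin", "HLA-G")),
      gate_node("stromal", any_of = c("vimentin", "aSMA"), none_of = "CD45")
    )
  )
  gating_config(root, threshold = threshold)
}

config_markers <- function(node) {
  unique(c(node$all_of, node$any_of, node$none_of,
           unlist(lapply(node$children, config_markers))))
}

# parent label of every node label in the tree (root children -> fallback)
config_parents <- function(config) {
  walk <- function(node, parent) {
    out <- setNames(parent, node$name)
    for (ch in node$children) out <- c(out, walk(ch, node$name))
    out
  }
  p <- unlist(lapply(config$root$children,
                     function(ch) walk(ch, config$fallback)))
  c(p, setNames(NA_character_, config$fallback))
}

# labels under the named node (inclusive)
config_subtree <- function(config, name) {
  found <- NULL
  walk <- function(node) {
    if (node$name == name) {
      found <<- node
      return(invisible())
    }
    for (ch in node$children) walk(ch)
  }
  walk(config$root)
  if (is.null(found)) return(character())
  collect <- function(node) {
    c(node$name, unlist(lapply(node$children, collect)))
  }
  collect(found)
}

#' Assign phenotypes by hierarchical gating
#'
#' Deterministic top-down assignment: at each level, the sibling gates are
#' tried in their declared order and a cell descends into the first gate it
#' satisfies; a cell satisfying no sibling keeps the enclosing node's label
#' (or the config's fallback, `"unknown"`, at the top level).
#'
#' @param table a `cell_table` with one fraction column per marker.
#' @param config a `gating_config` (default [decidua_gating()]); every
#'   marker named by the config must be a column of `table`.
#' @return a `phenotype_assignment`: list with `cluster` (label per cell,
#'   aligned with `table` rows), `cells` (the id columns of `table`),
#'   `config`.
#' @export
gate_cells <- function(table, config = decidua_gating()) {
  stopifnot(inherits(config, "gating_config"))
  markers <- cell_markers(table)
  need <- config_markers(config$root)
  miss <- setdiff(need, markers)
  if (length(miss)) {
    stop("config markers absent from table: ", paste(miss, collapse = ", "))
  }
  frac <- as.matrix(as.data.frame(table)[, markers, drop = FALSE])
  P <- frac >= config$threshold
  n <- nrow(P)
  labels <- rep(config$fallback, n)
  match_node <- function(node, idx) {
    if (identical(node$special, "no_marker")) {
      return(idx[rowSums(P[idx, , drop = FALSE]) == 0])
    }
    ok <- rep(TRUE, length(idx))
    for (m in node$all_of) ok <- ok & P[idx, m]
    if (length(node$any_of)) {
      any_ok <- rep(FALSE, length(idx))
      for (m in node$any_of) any_ok <- any_ok | P[idx, m]
      ok <- ok & any_ok
    }
    for (m in node$none_of) ok <- ok & !P[idx, m]
    idx[ok]
  }
  descend <- function(node, idx) {
    if (!length(idx)) return(invisible())
    labels[idx] <<- node$name
    rest <- idx
    for (ch in node$children) {
      hit <- match_node(ch, rest)
      descend(ch, hit)
      rest <- setdiff(rest, hit)
    }
  }
  rest <- seq_len(n)
  for (ch in config$root$children) {
    hit <- match_node(ch, rest)
    descend(ch, hit)
    rest <- setdiff(rest, hit)
  }
  cells <- as.data.frame(table)[, intersect(
    c("cell_id", "roi_id", "sample_id"), names(table)), drop = FALSE]
  structure(list(cluster = labels, cells = cells, config = config),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  cat("phenotype_assignment:", length(x$cluster), "cells\n")
  print(sort(table(x$cluster), decreasing = TRUE))
  invisible(x)
}

#' Merge small clusters into their parents
#'
#' A reliably defined cluster needs more than `min_cells` cells pooled
#' across samples; any leaf at or below that size is relabeled to its
#' parent in the gating hierarchy, repeatedly, until every remaining label
#' exceeds the minimum (or has no parent left to merge into).
#'
#' @param assign a `phenotype_assignment`.
#' @param min_cells minimum pooled cluster size (default 100); clusters
#'   with `<= min_cells` cells are merged.
#' @return the updated `phenotype_assignment`.
#' @export
enforce_min_cluster_size <- function(assign, min_cells = 100L) {
  stopifnot(inherits(assign, "phenotype_assignment"))
  parents <- config_parents(assign$config)
  depth <- setNames(numeric(length(parents)), names(parents))
  for (l in names(parents)) {
    d <- 0; p <- l
    while (!is.na(parents[p])) {
      d <- d + 1
      p <- parents[[p]]
    }
    depth[[l]] <- d
  }
  labels <- assign$cluster
  repeat {
    cnt <- table(labels)
    small <- names(cnt)[cnt <= min_cells]
    small <- small[!is.na(parents[small]) & small %in% names(parents)]
    if (!length(small)) break
    # deepest (then smallest) first, so sibling leaves pool into their
    # parent before the parent itself is judged
    small <- small[order(-depth[small], cnt[small])]
    l <- small[[1]]
    labels[labels == l] <- parents[[l]]
  }
  assign$cluster <- labels
  assign
}

#' Per-sample cluster frequencies over a denominator
#'
#' Computes, per sample, `f_C = count(C) / count(denominator)` for every
#' cluster in the denominator set — e.g. immune cluster frequencies within
#' all immune plus trophoblast cells, the denominator used by the
#' microenvironment expectation.
#'
#' @param assign a `phenotype_assignment`.
#' @param denominator character vector of cluster labels forming the
#'   denominator (default: all observed labels).
#' @return data.frame `sample_id`, `cluster`, `n`, `freq`; samples whose
#'   denominator is empty get `NA` frequencies and a warning (never a
#'   silent zero). Frequencies over the denominator sum to 1 per sample.
#' @export
compute_frequencies <- function(assign, denominator = NULL) {
  stopifnot(inherits(assign, "phenotype_assignment"))
  labels <- assign$cluster
  sample_id <- as.character(assign$cells$sample_id %||%
                              rep("sample1", length(labels)))
  denominator <- denominator %||% sort(unique(labels))
  samples <- unique(sample_id)
  out <- expand.grid(cluster = denominator, sample_id = samples,
                     stringsAsFactors = FALSE)[, 2:1]
  out$n <- mapply(function(s, cl) sum(sample_id == s & labels == cl),
                  out$sample_id, out$cluster)
  denom <- vapply(out$sample_id,
                  function(s) sum(sample_id == s & labels %in% denominator),
                  numeric(1))
  out$freq <- ifelse(denom > 0, out$n / denom, NA_real_)
  if (any(denom == 0)) {
    warning("empty denominator in sample(s): ",
            paste(unique(out$sample_id[denom == 0]), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Immune-to-trophoblast cell ratio
#'
#' The ratio of immune cells to trophoblasts detected in a sample,
#' reported to three decimals. Either pass the two counts directly, or a
#' `phenotype_assignment` (immune = every label under the `immune` node of
#' its gating tree; trophoblast = the `trophoblast` label), in which case
#' one ratio per sample is returned.
#'
#' @param immune immune cell count(s), or a `phenotype_assignment`.
#' @param trophoblast trophoblast count(s) (ignored when `immune` is an
#'   assignment).
#' @return named numeric ratio(s), rounded to 3 decimals; zero trophoblasts
#'   give `NA` with a warning.
#' @export
immune_trophoblast_ratio <- function(immune, trophoblast = NULL) {
  if (inherits(immune, "phenotype_assignment")) {
    assign <- immune
    imm_labels <- config_subtree(assign$config, "immune")
    sample_id <- as.character(assign$cells$sample_id %||%
                                rep("sample1", length(assign$cluster)))
    samples <- unique(sample_id)
    imm <- vapply(samples, function(s) {
      sum(sample_id == s & assign$cluster %in% imm_labels)
    }, numeric(1))
    tro <- vapply(samples, function(s) {
      sum(sample_id == s & assign$cluster == "trophoblast")
    }, numeric(1))
    return(immune_trophoblast_ratio(setNames(imm, samples), tro))
  }
  if (any(trophoblast == 0)) {
    warning("zero trophoblasts: ratio undefined for ",
            sum(trophoblast == 0), " sample(s)")
  }
  out <- ifelse(trophoblast > 0, round(immune / trophoblast, 3), NA_real_)
  if (!is.null(names(immune))) names(out) <- names(immune)
  out
}

#' Reference decidual sample table
#'
#' Per-sample measurement details for thirteen decidua basalis samples
#' across the three trimesters (suction curettage / surgical abortion /
#' delivery material): number of ROIs ablated, total area measured
#' (including background), and the number of immune cells and trophoblasts
#' detected. Used as reference input for ratio computations and worked
#' examples.
#'
#' @return data.frame with columns `sample_id`, `trimester`, `rois`,
#'   `area_mm2`, `n_immune`, `n_trophoblast`.
#' @export
decidua_samples <- function() {
  data.frame(
    sample_id = c("2307", "2317", "2331", "2177", "2268", "2280", "2297",
                  "2324", "2366", "2374", "2394", "2427", "2398"),
    trimester = c("first", "first", "first", "second", "second", "second",
                  "second", "second", "term", "term", "term", "term", "term"),
    rois = c(5L, 5L, 7L, 8L, 8L, 7L, 7L, 7L, 6L, 12L, 9L, 8L, 9L),
    area_mm2 = c(4.62, 6.71, 4.53, 4.76, 6.87, 3.95, 6.87, 5.82, 2.25,
                 4.85, 8.93, 6.28, 6.7),
    n_immune = c(5926L, 7326L, 3939L, 1511L, 2974L, 2983L, 10190L, 6489L,
                 1041L, 2514L, 4244L, 1912L, 1820L),
    n_trophoblast = c(5225L, 6680L, 3612L, 6243L, 4739L, 2898L, 4390L,
                      5202L, 489L, 1003L, 2772L, 2819L, 5856L),
    stringsAsFactors = FALSE
  )
}
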