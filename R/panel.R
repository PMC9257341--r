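#' Define a marker panel for synthetic IMC images
#'
#' A panel declares the marker channels, the expected marker profile of each
#' phenotype cluster (which markers its cells are positive / negative for),
#' the nucleus radius used to draw cells, the membrane expansion distance,
#' and per-channel pixel noise rates.
#'
#' @param markers character vector of marker channel names (excluding the
#'   DNA channel, which is always present).
#' @param clusters named list; each element is a list with components
#'   `positive` (markers the cluster expresses) and optionally `negative`
#'   (defaults to all remaining panel markers). Positive and negative sets
#'   must be disjoint subsets of the panel.
#' @param nucleus_radius nucleus disk radius in pixels (1 px = 1 um).
#' @param expand membrane expansion distance in pixels applied to the cell
#'   footprint on which marker signal is painted.
#' @param fp_rate,fn_rate per-channel false-positive / false-negative pixel
#'   noise rates in `[0, 1)`. Either a single number applied to every
#'   channel (including DNA) or a named vector keyed by channel name.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(markers, clusters, nucleus_radius = 4, expand = 2,
                       fp_rate = 0, fn_rate = 0) {
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop("duplicate marker names in panel")
  if ("DNA" %in% markers) stop("'DNA' is implicit; do not list it as a marker")
  if (is.null(names(clusters)) || any(names(clusters) == "")) {
    stop("`clusters` must be a named list")
  }
  clusters <- lapply(clusters, function(cl) {
    pos <- as.character(cl$positive %||% character())
    neg <- as.character(cl$negative %||% setdiff(markers, pos))
    if (!all(pos %in% markers) || !all(neg %in% markers)) {
      stop("cluster marker not in panel")
    }
    if (length(intersect(pos, neg))) {
      stop("positive and negative marker sets overlap")
    }
    list(positive = pos, negative = neg)
  })
  expand_rate <- function(r, what) {
    if (any(r < 0) || any(r >= 1)) stop(sprintf("%s must be in [0, 1)", what))
    chans <- c("DNA", markers)
    if (is.null(names(r))) {
      setNames(rep_len(r, length(chans)), chans)
    } else {
      out <- setNames(numeric(length(chans)), chans)
      if (!all(names(r) %in% chans)) stop("noise rate for unknown channel")
      out[names(r)] <- r
      out
    }
  }
  structure(list(
    markers = markers, clusters = clusters,
    nucleus_radius = nucleus_radius, expand = expand,
    fp_rate = expand_rate(fp_rate, "fp_rate"),
    fn_rate = expand_rate(fn_rate, "fn_rate")
  ), class = "panel_spec")
}

#' Default decidua-like synthetic panel
#'
#' A reduced marker panel mimicking the lineage-defining channels of a
#' decidual IMC panel: a myeloid compartment (CD45/CD14/CD68/CD163 with
#' HLA-DR and DC-SIGN), NK cells (CD56/CD7), T cells (CD3/CD4/CD8a),
#' granulocytes (CD66b/CD15), HLA-G+/keratin+ trophoblasts and
#' vimentin+/aSMA+ stromal cells. The default clusters are one
#' representative leaf per lineage so that hierarchical gating of a
#' noiseless rendering reproduces the generator labels exactly.
#'
#' @inheritParams panel_spec
#' @param clusters optional named list overriding the default cluster
#'   profiles.
#' @return a `panel_spec`.
#' @export
default_panel <- function(fp_rate = 0, fn_rate = 0, clusters = NULL,
                          nucleus_radius = 4, expand = 2) {
  markers <- c(
    "CD45", "CD14", "CD68", "CD163", "HLA-DR", "DC-SIGN", "CD204", "CD11c",
    "CD56", "CD7", "CD3", "CD4", "CD8a", "CD66b", "CD15",
    "keratin", "HLA-G", "vimentin", "aSMA"
  )
  if (is.null(clusters)) {
    clusters <- list(
      dM2 = list(positive = c("CD45", "CD14", "CD68", "CD163",
                              "HLA-DR", "DC-SIGN")),
      NK = list(positive = c("CD45", "CD56", "CD7")),
      T_CD4 = list(positive = c("CD45", "CD3", "CD4")),
      granulocyte = list(positive = c("CD45", "CD66b", "CD15")),
      trophoblast = list(positive = c("keratin", "HLA-G")),
      stromal = list(positive = c("vimentin", "aSMA"))
    )
  }
  panel_spec(markers, clusters, nucleus_radius = nucleus_radius,
             expand = expand, fp_rate = fp_rate, fn_rate = fn_rate)
}
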