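# Seeded benchmark studies on synthetic ROIs. The defaults ARE the study
# conditions (field sizes, cell counts, noise rates, permutation depth);
# they are fixed design choices of the package's validation suite, not
# tuning knobs. See the methods vignette for the rationale behind each.

#' Type-I error of the permutation test under spatial randomness
#'
#' Simulates completely spatially random (CSR) samples — uniform positions,
#' independent multinomial labels — and runs the microenvironment
#' permutation test on each. Under CSR no pair is truly enriched, so the
#' fraction of pair tests with |z| at or above the cutoff estimates the
#' test's type-I error and should sit near the nominal 5%.
#'
#' @param n_reps number of independent CSR samples.
#' @param n_cells cells per sample.
#' @param freqs cluster frequencies.
#' @param field field dimensions in px.
#' @param radius proximity radius (px).
#' @param n_perm permutations per sample.
#' @param cutoff absolute z cutoff (1.96 = two-sided 5%).
#' @param seed integer seed governing all replicates.
#' @return list: `rate` (fraction of significant pair tests), `n_tests`,
#'   `z` (all z-scores).
#' @export
run_null_calibration <- function(n_reps = 200L, n_cells = 2000L,
                                 freqs = c(A = 0.5, B = 0.3, C = 0.2),
                                 field = c(500, 500), radius = 10,
                                 n_perm = 500L, cutoff = 1.96, seed = 1L) {
  zs <- numeric(0)
  for (r in seq_len(n_reps)) {
    pat <- simulate_pattern(n_cells, freqs, field, seed = seed + 7L * r)
    tab <- pattern_table(pat)
    g <- build_neighbor_graph(tab, radius, mode = "centroid")
    pz <- permutation_z(g, pat$points$label, n_perm = n_perm,
                        seed = seed + 7L * r + 3L, cutoff = cutoff)
    zs <- c(zs, pz$z)
  }
  list(rate = mean(abs(zs) >= cutoff), n_tests = length(zs), z = zs)
}

#' Power to detect a planted attraction
#'
#' Simulates samples with a planted A-B attraction (Thomas-style pairs,
#' Gaussian displacement `sigma`) and asks, per replicate, whether the
#' corrected microenvironment percentage of the planted ordered pair is
#' positive, whether its permutation z reaches the cutoff, and whether the
#' planted pair carries the largest z of all ordered pairs.
#'
#' @param n_reps replicates.
#' @param n_cells cells per sample.
#' @param n_parents expected number of planted parent pairs.
#' @param sigma offspring displacement SD in um.
#' @param freqs cluster frequencies for the non-planted remainder.
#' @inheritParams run_null_calibration
#' @return list: `power` (fraction with corrected > 0 and z >= cutoff),
#'   `top_rate` (fraction where the planted pair has the top z),
#'   `detail` (per-replicate data.frame), `corrected` (matrix of corrected
#'   values, ordered pairs x replicates).
#' @export
run_power_study <- function(n_reps = 100L, n_cells = 1000L,
                            n_parents = 250, sigma = 3,
                            freqs = c(A = 0.3, B = 0.3, C = 0.4),
                            field = c(500, 500), radius = 10,
                            n_perm = 500L, cutoff = 1.96, seed = 1L) {
  inter <- list(mode = "attract", pair = c("A", "B"), sigma = sigma,
                n_parents = n_parents)
  detail <- vector("list", n_reps)
  corr <- NULL
  for (r in seq_len(n_reps)) {
    pat <- simulate_pattern(n_cells, freqs, field, inter,
                            seed = seed + 11L * r)
    tab <- pattern_table(pat)
    g <- build_neighbor_graph(tab, radius, mode = "centroid")
    m <- microenvironment_matrix(g, pat$points$label)
    pz <- permutation_z(g, pat$points$label, n_perm = n_perm,
                        seed = seed + 11L * r + 5L, cutoff = cutoff)
    key <- paste0(pz$cluster_a, "->", pz$cluster_b)
    if (is.null(corr)) {
      corr <- matrix(NA_real_, length(key), n_reps, dimnames = list(key, NULL))
    }
    corr[key, r] <- m$corrected[match(key, paste0(m$cluster_a, "->",
                                                  m$cluster_b))]
    iab <- which(pz$cluster_a == "A" & pz$cluster_b == "B")
    detail[[r]] <- data.frame(
      rep = r,
      corrected_ab = m$corrected[match("A->B", paste0(m$cluster_a, "->",
                                                      m$cluster_b))],
      z_ab = pz$z[iab],
      top_pair = key[which.max(pz$z)])
  }
  detail <- do.call(rbind, detail)
  list(
    power = mean(detail$corrected_ab > 0 & detail$z_ab >= cutoff),
    # both orderings of the planted pair carry the same interaction
    top_rate = mean(detail$top_pair %in% c("A->B", "B->A")),
    detail = detail, corrected = corr
  )
}

#' Phenotype recovery on synthetic images
#'
#' Renders a synthetic ROI with the default decidua-like panel and planted
#' lineage frequencies, then measures the fraction of cells whose gated
#' phenotype equals the generator's ground truth.
#'
#' With `pipeline = TRUE` (noise-free use) the full chain runs: nuclei are
#' segmented from the DNA channel, expanded by 2 px, quantified, gated,
#' and matched to the ground truth by majority mask overlap. With
#' `pipeline = FALSE` the ground-truth mask is quantified against the
#' (possibly noisy) binarized channels, isolating the gating step.
#'
#' @param n_cells cells in the ROI.
#' @param freqs planted frequencies over the default panel's clusters.
#' @param field field size in px (cells are spaced >= 10 um apart so that
#'   nuclei never touch and segmentation is exact).
#' @param noise per-pixel false-positive and false-negative rate applied
#'   to every channel.
#' @param pipeline run the full segmentation pipeline (see above).
#' @param seed integer seed.
#' @return list: `recovery` (fraction of cells with correct label),
#'   `n_cells`, `assignment`, `truth`.
#' @export
run_phenotype_recovery <- function(n_cells = 600L,
                                   freqs = c(dM2 = 0.4, NK = 0.3,
                                             T_CD4 = 0.1, trophoblast = 0.2),
                                   field = c(500, 500), noise = 0,
                                   pipeline = (noise == 0), seed = 1L) {
  pat <- simulate_pattern(n_cells, freqs, field,
                          list(mode = "repel", hardcore = 10,
                               max_tries = 500L), seed = seed)
  pan <- default_panel(fp_rate = noise, fn_rate = noise)
  ras <- rasterize_pattern(pat, pan, seed = seed + 1L)
  if (pipeline) {
    seg <- segment_nuclei(ras$stack$DNA)
    mask <- expand_labels(seg, pan$expand)
    bin <- binarize_stack(ras$stack[pan$markers], "identity")
    tab <- quantify_cells(mask, bin)
    assign <- gate_cells(tab)
    map <- match_labels(seg, ras$mask)
    truth <- ras$table$cluster[match(map[as.character(tab$cell_id)],
                                     ras$table$cell_id)]
  } else {
    assign <- gate_cells(ras$table)
    truth <- ras$table$cluster
  }
  list(recovery = mean(assign$cluster == truth),
       n_cells = length(truth), assignment = assign, truth = truth)
}

#' Cell table of a point pattern (no rasterization)
#'
#' Treats the pattern's continuous positions as cell centroids, for
#' centroid-mode spatial analyses that do not need images.
#'
#' @param pattern a `point_pattern`.
#' @param roi_id,sample_id identifiers.
#' @return a `cell_table` without marker columns.
#' @export
pattern_table <- function(pattern, roi_id = "roi1", sample_id = "sample1") {
  pts <- pattern$points
  tbl <- data.frame(cell_id = seq_len(nrow(pts)),
                    roi_id = rep_len(roi_id, nrow(pts)),
                    sample_id = rep_len(sample_id, nrow(pts)),
                    x = pts$x, y = pts$y, area = rep_len(1L, nrow(pts)),
                    stringsAsFactors = FALSE)
  as_cell_table(tbl, character())
}
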