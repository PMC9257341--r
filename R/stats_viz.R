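#' Row-wise z-scores of a matrix
#'
#' Standardizes each row to mean 0 and (sample) standard deviation 1 —
#' the per-row z-score showing how many SD each sample lies above or below
#' the row mean, as used to render corrected microenvironment heatmaps.
#' Missing values are excluded from the row mean/SD and propagated to the
#' output; constant rows become all zeros and are flagged.
#'
#' @param m numeric matrix (rows = features/pairs, columns = samples),
#'   every row with at least 2 non-missing values.
#' @return matrix of z-scores with attribute `constant_rows` (logical per
#'   row).
#' @export
row_zscores <- function(m) {
  m <- as.matrix(m)
  nn <- rowSums(!is.na(m))
  if (any(nn < 2)) {
    stop("every row needs at least 2 non-missing values")
  }
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  const <- s == 0
  s[const] <- 1
  z <- (m - mu) / s
  z[const & !is.na(z)] <- 0  # const recycles along columns (row flag)
  attr(z, "constant_rows") <- const
  z
}

#' Nonparametric group comparisons of cluster frequencies
#'
#' * `two_group`: two-sided Mann-Whitney (Wilcoxon rank-sum) test; exact
#'   when both groups have at most 8 observations and no ties, otherwise
#'   the normal approximation with tie correction.
#' * `k_group_independent`: Kruskal-Wallis test with Dunn's post-hoc
#'   pairwise comparisons.
#' * `k_group_repeated`: Friedman test (complete blocks required) with
#'   Dunn's post-hoc pairwise comparisons.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @param design `"two_group"`, `"k_group_independent"` or
#'   `"k_group_repeated"`.
#' @param blocks block (subject) label per observation, required for the
#'   repeated design; every block must contain each group exactly once.
#' @param adjust p-adjustment: for `two_group`, the method applied across
#'   the declared family (`family_size`); for the k-group designs, the
#'   method applied over the post-hoc pairwise family (default `"holm"`).
#' @param family_size size of the comparison family for Bonferroni-style
#'   adjustment of a single two-group test (e.g. 3 when the same contrast
#'   is tested in three trimesters). Default 1.
#' @return data.frame with `comparison`, `test`, `statistic`, `p`,
#'   `p_adjusted`, `adjust_method`. For k-group designs the first row is
#'   the omnibus test, followed by the pairwise post-hoc rows.
#' @export
compare_groups <- function(values, groups,
                           design = c("two_group", "k_group_independent",
                                      "k_group_repeated"),
                           blocks = NULL, adjust = NULL, family_size = 1L) {
  design <- match.arg(design)
  groups <- as.character(groups)
  if (any(table(groups) < 2)) stop("every group needs >= 2 observations")
  if (design == "two_group") {
    adjust <- adjust %||% "bonferroni"
    gl <- unique(groups)
    if (length(gl) != 2L) stop("two_group design needs exactly 2 groups")
    a <- values[groups == gl[1]]; b <- values[groups == gl[2]]
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = !exact))
    # fully tied data have zero rank variance: no evidence of separation
    if (is.nan(wt$p.value)) wt$p.value <- 1
    p_adj <- if (adjust == "bonferroni") {
      min(1, family_size * wt$p.value)
    } else {
      p.adjust(wt$p.value, method = adjust, n = family_size)
    }
    return(data.frame(
      comparison = paste(gl, collapse = " vs "),
      test = paste0("Mann-Whitney (", if (exact) "exact" else "normal approx.",
                    ")"),
      statistic = unname(wt$statistic), p = wt$p.value,
      p_adjusted = p_adj, adjust_method = adjust,
      stringsAsFactors = FALSE))
  }
  adjust <- adjust %||% "holm"
  if (design == "k_group_independent") {
    kw <- kruskal.test(values, factor(groups))
    ph <- dunn_posthoc_kw(values, groups)
    omnibus <- data.frame(
      comparison = "omnibus", test = "Kruskal-Wallis",
      statistic = unname(kw$statistic), p = kw$p.value,
      p_adjusted = NA_real_, adjust_method = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    if (is.null(blocks)) stop("repeated design requires `blocks`")
    tab <- table(blocks, groups)
    if (any(tab != 1L)) stop("repeated design requires complete blocks")
    y <- tapply(values, list(blocks, groups), identity)
    fr <- friedman.test(y)
    ph <- dunn_posthoc_friedman(y)
    omnibus <- data.frame(
      comparison = "omnibus", test = "Friedman",
      statistic = unname(fr$statistic), p = fr$p.value,
      p_adjusted = NA_real_, adjust_method = NA_character_,
      stringsAsFactors = FALSE)
  }
  ph$p_adjusted <- p.adjust(ph$p, method = adjust)
  ph$adjust_method <- adjust
  rbind(omnibus, ph)
}

# Dunn's post-hoc z tests after Kruskal-Wallis: pairwise differences of
# mean ranks over the pooled ranking, variance with tie correction
dunn_posthoc_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  gl <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)[gl]
  n <- tapply(r, groups, length)[gl]
  ties <- table(values)
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  out <- list()
  for (i in seq_along(gl)) {
    for (j in seq_along(gl)) {
      if (j <= i) next
      se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / n[i] + 1 / n[j]))
      z <- (rbar[i] - rbar[j]) / se
      out[[length(out) + 1L]] <- data.frame(
        comparison = paste(gl[i], "vs", gl[j]), test = "Dunn",
        statistic = unname(z), p = 2 * pnorm(-abs(unname(z))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Dunn's post-hoc after Friedman: differences of within-block rank sums,
# SE = sqrt(n k (k+1) / 6)
dunn_posthoc_friedman <- function(y) {
  ranks <- t(apply(y, 1, rank))
  n <- nrow(y); k <- ncol(y)
  rs <- colSums(ranks)
  gl <- colnames(y)
  se <- sqrt(n * k * (k + 1) / 6)
  out <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      z <- (rs[i] - rs[j]) / se
      out[[length(out) + 1L]] <- data.frame(
        comparison = paste(gl[i], "vs", gl[j]), test = "Dunn (Friedman)",
        statistic = unname(z), p = 2 * pnorm(-abs(unname(z))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Clustered heatmap of row z-scored microenvironment values
#'
#' Renders the corrected microenvironment matrix (rows = cluster pairs or
#' clusters, columns = samples) as a row-z-scored heatmap with average
#' linkage on Euclidean distances and a diverging blue-white-red palette.
#'
#' @param m numeric matrix; rows are z-scored before plotting.
#' @param file optional output file (`.png` or `.pdf`); `NULL` plots to the
#'   active device.
#' @param cluster_rows,cluster_cols passed to [pheatmap::pheatmap()].
#' @param ... further arguments for [pheatmap::pheatmap()].
#' @return the row z-score matrix, invisibly.
#' @export
microenv_heatmap <- function(m, file = NULL, cluster_rows = TRUE,
                             cluster_cols = FALSE, ...) {
  z <- row_zscores(m)
  pal <- colorRampPalette(c("#1f3a93", "white", "#b03a2e"))(101)
  lim <- max(abs(z), na.rm = TRUE)
  pheatmap::pheatmap(
    z, color = pal, breaks = seq(-lim, lim, length.out = 102),
    clustering_method = "average",
    clustering_distance_rows = "euclidean",
    cluster_rows = cluster_rows, cluster_cols = cluster_cols,
    filename = file %||% NA, ...)
  invisible(z)
}

#' Long-to-wide corrected microenvironment matrix
#'
#' Reshapes the long result of [microenvironment_analysis()] into a
#' (cluster pair) x (sample) matrix of corrected percentages, the input
#' expected by [microenv_heatmap()].
#'
#' @param result long data.frame with `sample_id`, `cluster_a`,
#'   `cluster_b` and a value column.
#' @param value which column to spread (default `"corrected"`).
#' @return numeric matrix, rows named `"A->B"`.
#' @export
microenv_wide <- function(result, value = "corrected") {
  pair <- paste0(result$cluster_a, "->", result$cluster_b)
  samples <- unique(result$sample_id)
  pairs <- unique(pair)
  m <- matrix(NA_real_, length(pairs), length(samples),
              dimnames = list(pairs, samples))
  m[cbind(match(pair, pairs), match(result$sample_id, samples))] <-
    result[[value]]
  m
}
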