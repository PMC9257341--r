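# shared builders for synthetic fixtures (everything generated in code)

toy_cell_table <- function(x, y, roi_id = "r1", sample_id = "s1") {
  tbl <- data.frame(cell_id = seq_along(x), roi_id = roi_id,
                    sample_id = sample_id, x = x, y = y, area = 1L,
                    stringsAsFactors = FALSE)
  attr(tbl, "markers") <- character()
  class(tbl) <- c("cell_table", class(tbl))
  tbl
}

# fraction table with named marker columns, one row per cell
toy_fraction_table <- function(frac, roi_id = "r1", sample_id = "s1") {
  n <- nrow(frac)
  tbl <- data.frame(cell_id = seq_len(n), roi_id = rep_len(roi_id, n),
                    sample_id = rep_len(sample_id, n), x = numeric(n),
                    y = numeric(n), area = rep_len(1L, n),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (m in colnames(frac)) tbl[[m]] <- frac[, m]
  attr(tbl, "markers") <- colnames(frac)
  class(tbl) <- c("cell_table", class(tbl))
  tbl
}

# zero-fraction matrix over the default panel markers
panel_frac <- function(n, panel = default_panel()) {
  matrix(0, n, length(panel$markers),
         dimnames = list(NULL, panel$markers))
}

# assignment object from bare labels (no gating tree semantics needed)
toy_assignment <- function(labels, sample_id = "s1") {
  structure(list(
    cluster = labels,
    cells = data.frame(cell_id = seq_along(labels),
                       sample_id = rep_len(sample_id, length(labels))),
    config = gating_config(gate_node("all", children = list()))
  ), class = "phenotype_assignment")
}

# non-overlapping pattern suitable for exact segmentation recovery
spaced_pattern <- function(n, freqs, field = c(500, 500), seed = 1) {
  simulate_pattern(n, freqs, field,
                   interaction = list(mode = "repel", hardcore = 10,
                                      max_tries = 500L),
                   seed = seed)
}
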