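#!/usr/bin/env Rscript
# Gate every segmented cell through the decidua hierarchy, merge clusters
# below the 100-cell reliability floor, and tabulate per-sample
# frequencies (within immune + trophoblast cells) and the
# immune/trophoblast ratio.

library(imcmicroenv)

dirc <- "results/cohort"
cells <- read_cell_table(file.path(dirc, "cells.csv"))
assign <- gate_cells(cells)
assign <- enforce_min_cluster_size(assign, min_cells = 100L)

lab <- data.frame(cells[, c("cell_id", "roi_id", "sample_id")],
                  cluster = assign$cluster)
write.csv(lab, file.path(dirc, "phenotypes.csv"), row.names = FALSE)

# frequencies within immune + trophoblast cells, the denominator the
# microenvironment expectation uses
immune_labels <- c("dM1", "dM2", "dM3", "dM4", "dM5", "MoDC", "NK", "T",
                   "T_CD4", "T_CD8", "T_DN", "granulocyte", "myeloid",
                   "immune")
denom <- intersect(unique(assign$cluster), c(immune_labels, "trophoblast"))
freq <- compute_frequencies(assign, denominator = denom)
write.csv(freq, file.path(dirc, "frequencies.csv"), row.names = FALSE)

ratio <- immune_trophoblast_ratio(assign)
write.csv(data.frame(sample_id = names(ratio), ratio = unname(ratio)),
          file.path(dirc, "ratios.csv"), row.names = FALSE)

cat("cluster sizes after the 100-cell floor:\n")
print(sort(table(assign$cluster), decreasing = TRUE))
cat("immune/trophoblast ratios per sample:\n")
print(round(ratio, 3))
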