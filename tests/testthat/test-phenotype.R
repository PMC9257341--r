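test_that("gating routes cells through the decidua hierarchy", {
  pan <- default_panel()
  frac <- panel_frac(6, pan)
  # 1: nothing positive -> background
  frac[2, c("CD45", "CD14", "DC-SIGN")] <- c(0.9, 0.8, 0.8)  # DR- SIGN+
  frac[3, c("keratin", "HLA-G")] <- c(0.6, 0.9)
  frac[4, c("vimentin")] <- 0.5
  frac[5, c("CD45", "CD3", "CD8a")] <- c(0.9, 0.5, 0.4)
  frac[6, c("CD45")] <- 0.9  # CD45+ but no lineage marker
  a <- gate_cells(toy_fraction_table(frac))
  expect_equal(a$cluster,
               c("background", "dM1", "trophoblast", "stromal", "T_CD8",
                 "immune"))
})

test_that("every cell receives exactly one leaf label (partition)", {
  set.seed(14)
  pan <- default_panel()
  frac <- matrix(runif(200 * length(pan$markers)), 200,
                 dimnames = list(NULL, pan$markers))
  a <- gate_cells(toy_fraction_table(frac))
  expect_length(a$cluster, 200L)
  expect_false(anyNA(a$cluster))
  expect_error(
    gate_cells(toy_fraction_table(frac[, 1:3])),
    "absent from table")
})

test_that("gating recovers generator labels perfectly without noise", {
  pat <- spaced_pattern(400,
                        c(dM2 = 0.4, NK = 0.3, T_CD4 = 0.1, trophoblast = 0.2),
                        field = c(500, 500), seed = 31)
  ras <- rasterize_pattern(pat, default_panel(), seed = 32)
  a <- gate_cells(ras$table)
  expect_equal(mean(a$cluster == ras$table$cluster), 1)
})

test_that("planted cluster frequencies are recovered within 0.03 under noise", {
  pat <- simulate_pattern(
    5000, c(dM2 = 0.4, NK = 0.3, T_CD4 = 0.1, trophoblast = 0.2),
    field = c(1000, 1000), seed = 41)
  pan <- default_panel(fp_rate = 0.05, fn_rate = 0.05)
  ras <- rasterize_pattern(pat, pan, seed = 42)
  a <- gate_cells(ras$table)
  f <- table(factor(a$cluster,
                    levels = c("dM2", "NK", "T_CD4", "trophoblast"))) /
    length(a$cluster)
  planted <- c(dM2 = 0.4, NK = 0.3, T_CD4 = 0.1, trophoblast = 0.2)
  expect_true(all(abs(f[names(planted)] - planted) <= 0.03))
})

test_that("small clusters merge upward until stable", {
  cfg <- decidua_gating()
  # all clusters comfortably large: nothing changes
  big <- toy_assignment(rep(c("dM1", "NK", "trophoblast"), each = 150))
  big$config <- cfg
  expect_equal(enforce_min_cluster_size(big)$cluster, big$cluster)
  # a 40-cell T sub-leaf merges into the T lineage
  a <- toy_assignment(c(rep("T_CD4", 40), rep("T", 100), rep("T_CD8", 150),
                        rep("NK", 200)))
  a$config <- cfg
  m <- enforce_min_cluster_size(a)
  expect_equal(sum(m$cluster == "T"), 140L)
  expect_equal(sum(m$cluster == "T_CD8"), 150L)
  # two 60-cell siblings pool into a surviving 120-cell parent
  b <- toy_assignment(c(rep("T_CD4", 60), rep("T_CD8", 60), rep("NK", 200)))
  b$config <- cfg
  mb <- enforce_min_cluster_size(b)
  expect_equal(sum(mb$cluster == "T"), 120L)
  expect_false(any(mb$cluster %in% c("T_CD4", "T_CD8")))
})

test_that("frequencies normalize over the chosen denominator", {
  a <- toy_assignment(rep("A", 50))
  expect_equal(compute_frequencies(a)$freq, 1)
  b <- toy_assignment(c(rep("A", 30), rep("B", 70)))
  f <- compute_frequencies(b)
  expect_equal(f$freq[f$cluster == "A"], 0.3)
  expect_equal(f$freq[f$cluster == "B"], 0.7)
  # many clusters, random counts: frequencies sum to 1 exactly
  set.seed(5)
  labs <- sample(paste0("c", 1:16), 3000, TRUE)
  f16 <- compute_frequencies(toy_assignment(labs))
  expect_lt(abs(sum(f16$freq) - 1), 1e-12)
  # empty denominator is flagged, not silently zero
  expect_warning(fe <- compute_frequencies(b, denominator = "Z"),
                 "empty denominator")
  expect_true(all(is.na(fe$freq)))
})

test_that("frequencies ignore cell order and ids", {
  set.seed(6)
  labs <- sample(c("A", "B", "C"), 500, TRUE)
  perm <- sample.int(500)
  f1 <- compute_frequencies(toy_assignment(labs))
  f2 <- compute_frequencies(toy_assignment(labs[perm]))
  expect_equal(f1, f2)
})

test_that("immune/trophoblast ratios reproduce the reference samples", {
  ref <- decidua_samples()
  r <- immune_trophoblast_ratio(
    setNames(ref$n_immune, ref$sample_id), ref$n_trophoblast)
  expect_equal(r[["2307"]], 1.134)
  expect_equal(r[["2317"]], 1.097)
  expect_equal(r[["2297"]], 2.321)
  expect_equal(r[["2374"]], 2.506)
  expect_equal(r[["2398"]], 0.311)
  expect_equal(immune_trophoblast_ratio(500, 500), 1.000)
  expect_warning(z <- immune_trophoblast_ratio(10, 0), "zero trophoblasts")
  expect_true(is.na(z))
})

test_that("assignment-level ratio counts the immune subtree", {
  a <- toy_assignment(c(rep("dM1", 30), rep("NK", 20), rep("T", 10),
                        rep("trophoblast", 40), rep("stromal", 25)))
  a$config <- decidua_gating()
  expect_equal(unname(immune_trophoblast_ratio(a)), round(60 / 40, 3))
})
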