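test_that("the proximity radius is inclusive and self-free", {
  tab <- toy_cell_table(x = c(0, 10), y = c(0, 0))
  g <- build_neighbor_graph(tab, radius = 10, mode = "centroid")
  expect_equal(nrow(g$edges), 1L)  # distance exactly 10 counts
  g1 <- build_neighbor_graph(toy_cell_table(5, 5), 10, mode = "centroid")
  expect_equal(nrow(g1$edges), 0L)
  expect_error(build_neighbor_graph(tab, radius = 0, mode = "centroid"),
               "positive")
  expect_error(build_neighbor_graph(tab, radius = 10, mode = "boundary"),
               "requires")
  bad <- tab
  bad$x[1] <- NA
  expect_error(build_neighbor_graph(bad, 10, mode = "centroid"), "missing")
})

test_that("centroid graphs equal the all-pairs scan on random instances", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 500
    x <- runif(n, 0, 300)
    y <- runif(n, 0, 300)
    g <- build_neighbor_graph(toy_cell_table(x, y), 10, mode = "centroid")
    got <- g$edges[order(g$edges$i, g$edges$j), ]
    want <- bf_edges(x, y, 10)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("edges never cross ROI boundaries", {
  tab <- toy_cell_table(x = c(0, 5, 0, 5), y = c(0, 0, 0, 0),
                        roi_id = c("r1", "r1", "r2", "r2"))
  g <- build_neighbor_graph(tab, 10, mode = "centroid")
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$roi_id[g$edges$i] == g$roi_id[g$edges$j]))
})

test_that("boundary mode links touching cells that centroids miss", {
  # two long cells whose centroids are 11 px apart but masks 3 px apart
  mask <- matrix(0L, 20, 30)
  mask[10, 2:11] <- 1L
  mask[10, 15:24] <- 2L
  tab <- quantify_cells(mask, list(dummy = matrix(0L, 20, 30)))
  expect_gt(sqrt(diff(tab$x)^2 + diff(tab$y)^2), 10)
  gc <- build_neighbor_graph(tab, 10, mode = "centroid")
  expect_equal(nrow(gc$edges), 0L)
  gb <- build_neighbor_graph(tab, 10, mode = "boundary", masks = mask)
  expect_equal(nrow(gb$edges), 1L)
  expect_equal(bf_min_label_distance(mask, 1, 2), 4)
  gb3 <- build_neighbor_graph(tab, 3, mode = "boundary", masks = mask)
  expect_equal(nrow(gb3$edges), 0L)
})

test_that("observed/expected/corrected follow the stated recipe", {
  # hand-enumerated 4-cell instance: only A1-B1 are within the radius
  tab <- toy_cell_table(x = c(0, 5, 100, 200), y = c(0, 0, 0, 0))
  g <- build_neighbor_graph(tab, 10, mode = "centroid")
  m <- microenvironment_matrix(g, c("A", "B", "A", "B"))
  ab <- m[m$cluster_a == "A" & m$cluster_b == "B", ]
  expect_equal(ab$observed, 0.5)
  expect_equal(ab$expected, 0.25)
  expect_equal(ab$corrected, 0.25)
  # saturated one-type field
  tab2 <- toy_cell_table(x = c(0, 5, 10), y = c(0, 0, 0))
  g2 <- build_neighbor_graph(tab2, 10, mode = "centroid")
  m2 <- microenvironment_matrix(g2, c("A", "A", "A"))
  expect_equal(m2$observed, 1)
  expect_equal(m2$expected, 1)
  expect_equal(m2$corrected, 0)
  # empty graph: observed 0, corrected = -expected
  tab3 <- toy_cell_table(x = c(0, 100), y = c(0, 0))
  g3 <- build_neighbor_graph(tab3, 10, mode = "centroid")
  m3 <- microenvironment_matrix(g3, c("A", "B"))
  expect_true(all(m3$observed == 0))
  expect_equal(m3$corrected, -m3$expected)
})

test_that("observed percentages equal brute-force counting", {
  set.seed(77)
  n <- 300
  tab <- toy_cell_table(runif(n, 0, 250), runif(n, 0, 250))
  labels <- sample(c("A", "B", "C"), n, TRUE)
  g <- build_neighbor_graph(tab, 10, mode = "centroid")
  m <- microenvironment_matrix(g, labels)
  for (a in c("A", "B", "C")) {
    for (b in c("A", "B", "C")) {
      expect_equal(m$observed[m$cluster_a == a & m$cluster_b == b],
                   bf_observed(g$edges, labels, a, b))
    }
  }
  expect_true(all(m$observed >= 0 & m$observed <= 1))
  expect_true(all(m$expected >= 0 & m$expected <= 1))
  expect_true(all(m$corrected >= -1 & m$corrected <= 1))
})

test_that("rigid motion of all cells changes nothing", {
  set.seed(13)
  n <- 200
  x <- runif(n, 0, 200)
  y <- runif(n, 0, 200)
  labels <- sample(c("A", "B"), n, TRUE)
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 50
  yr <- sin(th) * x + cos(th) * y + 1000
  g1 <- build_neighbor_graph(toy_cell_table(x, y), 10, mode = "centroid")
  g2 <- build_neighbor_graph(toy_cell_table(xr, yr), 10, mode = "centroid")
  m1 <- microenvironment_matrix(g1, labels)
  m2 <- microenvironment_matrix(g2, labels)
  expect_equal(m1$observed, m2$observed)
  z1 <- permutation_z(g1, labels, n_perm = 200, seed = 4)
  z2 <- permutation_z(g2, labels, n_perm = 200, seed = 4)
  expect_equal(z1$z, z2$z)
})

test_that("sampled permutation z matches exact enumeration on a tiny line", {
  # 6 cells on a line; adjacency: consecutive cells only
  tab <- toy_cell_table(x = seq(0, 50, by = 10), y = rep(0, 6))
  g <- build_neighbor_graph(tab, 10, mode = "centroid")
  labels <- c("A", "A", "A", "B", "B", "B")
  arr <- bf_label_arrangements(labels)
  expect_length(arr, 20L)
  obs_ab <- vapply(arr, function(l) bf_observed(g$edges, l, "A", "B"),
                   numeric(1))
  real <- bf_observed(g$edges, labels, "A", "B")
  z_exact <- (real - mean(obs_ab)) / sd(obs_ab)
  pz <- permutation_z(g, labels, n_perm = 10000, seed = 99)
  z_samp <- pz$z[pz$cluster_a == "A" & pz$cluster_b == "B"]
  expect_lt(abs(z_samp - z_exact), 0.1)
})

test_that("permutation machinery honours seeds and degenerate inputs", {
  set.seed(55)
  tab <- toy_cell_table(runif(50, 0, 100), runif(50, 0, 100))
  labels <- sample(c("A", "B"), 50, TRUE)
  g <- build_neighbor_graph(tab, 10, mode = "centroid")
  p1 <- permutation_z(g, labels, n_perm = 100, seed = 7)
  p2 <- permutation_z(g, labels, n_perm = 100, seed = 7)
  expect_identical(p1, p2)
  expect_error(permutation_z(g, labels, n_perm = 1, seed = 7), ">= 2")
  expect_error(permutation_z(g, labels, n_perm = 100), "required")
  # empty graph: every permuted observed is 0 -> z = 0, flagged
  tabe <- toy_cell_table(c(0, 100), c(0, 0))
  ge <- build_neighbor_graph(tabe, 10, mode = "centroid")
  pe <- permutation_z(ge, c("A", "B"), n_perm = 50, seed = 1)
  expect_true(all(pe$z == 0))
  expect_true(all(pe$sd_zero))
  expect_false(any(pe$significant))
})

test_that("per-ROI shuffling pools counts per sample", {
  # two ROIs of one sample with different densities: permutation keeps
  # each ROI's composition, and observed pools over both
  tab <- toy_cell_table(
    x = c(0, 5, 10, 0, 50, 100), y = rep(0, 6),
    roi_id = rep(c("r1", "r2"), each = 3), sample_id = "s1")
  labels <- c("A", "B", "A", "B", "A", "B")
  g <- build_neighbor_graph(tab, 10, mode = "centroid")
  m <- microenvironment_matrix(g, labels)
  # A cells with a B neighbour: cell1 (r1), cell3 (r1); r2 has no edges
  expect_equal(m$observed[m$cluster_a == "A" & m$cluster_b == "B"], 2 / 3)
  pz <- permutation_z(g, labels, n_perm = 500, seed = 3)
  expect_true(all(is.finite(pz$z)))
})
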