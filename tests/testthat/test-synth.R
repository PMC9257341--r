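test_that("empty and degenerate patterns are handled", {
  p <- simulate_pattern(0, c(A = 1), seed = 1)
  expect_equal(nrow(p$points), 0L)
  expect_error(simulate_pattern(10, c(A = 0.5, B = 0.4), seed = 1),
               "sum to 1")
  expect_error(simulate_pattern(10, c(A = 1), field = c(0, 10), seed = 1),
               "positive")
})

test_that("patterns are deterministic under a seed", {
  a <- simulate_pattern(500, c(A = 0.6, B = 0.4), seed = 42)
  b <- simulate_pattern(500, c(A = 0.6, B = 0.4), seed = 42)
  expect_identical(a, b)
  pan <- default_panel(fp_rate = 0.02, fn_rate = 0.02,
                       clusters = list(A = list(positive = "CD45"),
                                       B = list(positive = "CD3")))
  ra <- rasterize_pattern(spaced_pattern(60, c(A = 0.5, B = 0.5),
                                         field = c(200, 200)), pan, seed = 7)
  rb <- rasterize_pattern(spaced_pattern(60, c(A = 0.5, B = 0.5),
                                         field = c(200, 200)), pan, seed = 7)
  expect_identical(ra, rb)
})

test_that("CSR label frequencies converge to the requested mix", {
  p <- simulate_pattern(10000, c(A = 0.5, B = 0.5), seed = 1)
  f <- table(p$points$label) / 10000
  expect_lt(abs(f[["A"]] - 0.5), 0.02)
  expect_lt(abs(f[["B"]] - 0.5), 0.02)
})

test_that("planted attraction shortens nearest A-to-B distances", {
  freqs <- c(A = 0.3, B = 0.3, C = 0.4)
  att <- simulate_pattern(
    1000, freqs, field = c(500, 500),
    interaction = list(mode = "attract", pair = c("A", "B"), sigma = 3,
                       n_parents = 200), seed = 5)
  csr <- simulate_pattern(1000, freqs, field = c(500, 500), seed = 5)
  med_nn <- function(p) {
    a <- p$points[p$points$label == "A", ]
    b <- p$points[p$points$label == "B", ]
    median(vapply(seq_len(nrow(a)), function(i) {
      sqrt(min((b$x - a$x[i])^2 + (b$y - a$y[i])^2))
    }, numeric(1)))
  }
  expect_lt(med_nn(att), med_nn(csr))
})

test_that("stronger attraction never loses planted contacts", {
  contact_frac <- function(n_parents) {
    p <- simulate_pattern(
      1000, c(A = 0.3, B = 0.3, C = 0.4), field = c(500, 500),
      interaction = list(mode = "attract", pair = c("A", "B"), sigma = 3,
                         n_parents = n_parents), seed = 11)
    a <- p$points[p$points$label == "A", ]
    b <- p$points[p$points$label == "B", ]
    mean(vapply(seq_len(nrow(a)), function(i) {
      any((b$x - a$x[i])^2 + (b$y - a$y[i])^2 <= 100)
    }, logical(1)))
  }
  fr <- vapply(c(50, 150, 300), contact_frac, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("hard-core repulsion enforces the minimum spacing and fails loudly", {
  p <- simulate_pattern(
    200, c(A = 0.5, B = 0.5), field = c(300, 300),
    interaction = list(mode = "repel", hardcore = 8, pair = c("A", "B")),
    seed = 2)
  a <- p$points[p$points$label == "A", ]
  b <- p$points[p$points$label == "B", ]
  dmin <- sqrt(min(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2))
  expect_gte(dmin, 8)
  expect_error(
    simulate_pattern(500, c(A = 1), field = c(30, 30),
                     interaction = list(mode = "repel", hardcore = 10,
                                        max_tries = 50L), seed = 3),
    "infeasible")
})

test_that("rasterization paints disks, footprints and ground truth", {
  pan <- default_panel(clusters = list(A = list(positive = "CD45"),
                                       B = list(positive = "CD3")))
  pts <- data.frame(x = c(20.5, 60.5, 100.5), y = c(20.5, 20.5, 60.5),
                    label = c("A", "A", "B"), stringsAsFactors = FALSE)
  pat <- structure(list(points = pts, field = c(width = 128, height = 128),
                        clusters = c("A", "B"),
                        interaction = list(mode = "csr"), seed = 1L),
                   class = "point_pattern")
  ras <- rasterize_pattern(pat, pan, seed = 1)
  disk_px <- nrow(disk_offsets(pan$nucleus_radius))
  expect_equal(sort(unique(as.vector(ras$mask[ras$mask > 0]))), 1:3)
  expect_equal(sum(ras$stack$DNA), 3 * disk_px)
  # noiseless: every positive marker of a cell's cluster scores fraction 1
  expect_equal(ras$table$CD45, c(1, 1, 0))
  expect_equal(ras$table$CD3, c(0, 0, 1))
  expect_equal(ras$table$cluster, c("A", "A", "B"))
  expect_error(rasterize_pattern(
    structure(list(points = data.frame(x = 1, y = 1, label = "Z"),
                   field = c(width = 64, height = 64), clusters = "Z",
                   interaction = list(mode = "csr"), seed = 1L),
              class = "point_pattern"), pan),
    "missing cluster")
})

test_that("false-negative pixel noise thins fractions binomially", {
  pan <- default_panel(fn_rate = c(CD45 = 0.5),
                       clusters = list(A = list(positive = "CD45")))
  pat <- spaced_pattern(150, c(A = 1), field = c(400, 400), seed = 9)
  ras <- rasterize_pattern(pat, pan, seed = 10)
  # mean positive fraction ~ Binomial(area, 0.5) expectation
  expect_lt(abs(mean(ras$table$CD45) - 0.5), 0.02)
  # direct pixel recount for a handful of cells
  for (k in c(1, 50, 150)) {
    inside <- ras$mask == k
    expect_equal(ras$table$CD45[ras$table$cell_id == k],
                 sum(ras$stack$CD45[inside]) / sum(inside))
  }
})

test_that("panel validation rejects malformed specs", {
  expect_error(panel_spec("CD45", list(A = list(positive = "CD3"))),
               "not in panel")
  expect_error(panel_spec("CD45", list(A = list(positive = "CD45",
                                                negative = "CD45"))),
               "overlap")
  expect_error(default_panel(fp_rate = 1.2), "\\[0, 1\\)")
})

test_that("a YAML config drives ROI generation end to end", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "panel:",
    "  markers: [CD45, CD3]",
    "  nucleus_radius: 3",
    "clusters:",
    "  A: {positive: [CD45]}",
    "  B: {positive: [CD3]}",
    "freqs: {A: 0.6, B: 0.4}",
    "n_cells: 30",
    "field: [128, 128]",
    "interaction: {mode: repel, hardcore: 10}",
    "seed: 5"), cfg)
  out <- tempfile()
  ras <- generate_roi(cfg, out)
  expect_equal(nrow(ras$table), 30L)
  expect_setequal(unique(ras$table$cluster), c("A", "B"))
  stack <- read_image_stack(file.path(out, "roi1.tiff"))
  expect_equal(names(stack), c("DNA", "CD45", "CD3"))
  expect_equal(read_label_mask(file.path(out, "roi1_mask.tiff")),
               matrix(as.integer(ras$mask), 128))
})
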