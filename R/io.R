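#' Write an image stack as a multipage TIFF
#'
#' One 16-bit page per channel. The `tiff` package does not persist
#' per-page description tags, so channel names are written to a sidecar
#' text file `<path>.channels.txt` (one name per line) which
#' [read_image_stack()] reads back.
#'
#' @param stack named list of 2-D numeric matrices (integer counts or 0/1).
#' @param path output TIFF path.
#' @param max_value intensity mapped to the 16-bit maximum (default:
#'   the stack's maximum, at least 1).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, max_value = NULL) {
  check_stack(stack)
  mx <- max_value %||% max(1, vapply(stack, max, numeric(1)))
  pages <- lapply(stack, function(ch) ch / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  writeLines(names(stack), paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path TIFF path.
#' @param max_value intensity scale used when writing (default 1: channels
#'   come back on a 0..1 scale, binarized data unchanged).
#' @return named list of numeric matrices.
#' @export
read_image_stack <- function(path, max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".channels.txt")
  nm <- if (file.exists(side)) readLines(side) else paste0("ch", seq_along(pages))
  stack <- lapply(pages, function(p) round(p * 65535) / 65535 * max_value)
  setNames(stack, nm)
}

#' Write a label mask as a 16-bit single-page TIFF
#' @param mask integer label matrix (labels must fit in 16 bits).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot_2d(mask, "mask")
  if (max(mask) > 65535) stop("labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "LZW")
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#' @param path TIFF path.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a synthetic-study configuration from YAML
#'
#' The YAML document has keys `panel` (markers, nucleus_radius, expand,
#' fp_rate, fn_rate), `clusters` (name -> positive/negative marker lists),
#' `interaction` (mode and its parameters), `freqs`, `n_cells`, `field`
#' and `seed`. Returns the assembled generator inputs.
#'
#' @param path YAML file path.
#' @return list with `panel` (a `panel_spec`), `n_cells`, `freqs`,
#'   `field`, `interaction`, `seed`.
#' @export
read_synth_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  panel <- panel_spec(
    markers = cfg$panel$markers,
    clusters = cfg$clusters,
    nucleus_radius = cfg$panel$nucleus_radius %||% 4,
    expand = cfg$panel$expand %||% 2,
    fp_rate = unlist(cfg$panel$fp_rate %||% 0),
    fn_rate = unlist(cfg$panel$fn_rate %||% 0)
  )
  list(
    panel = panel,
    n_cells = cfg$n_cells,
    freqs = unlist(cfg$freqs),
    field = unlist(cfg$field %||% c(500, 500)),
    interaction = cfg$interaction %||% list(mode = "csr"),
    seed = cfg$seed %||% 1L
  )
}

#' Run the synthetic generator from a YAML configuration
#'
#' Simulates the pattern, rasterizes it, and writes the image stack, the
#' ground-truth label mask and the ground-truth cell table into `out_dir`.
#'
#' @param config path to a YAML file for [read_synth_config()].
#' @param out_dir output directory (created if needed).
#' @param roi_id,sample_id identifiers for the generated ROI.
#' @return invisibly, the list returned by [rasterize_pattern()].
#' @export
generate_roi <- function(config, out_dir, roi_id = "roi1",
                         sample_id = "sample1") {
  cfg <- read_synth_config(config)
  pat <- simulate_pattern(cfg$n_cells, cfg$freqs, cfg$field,
                          cfg$interaction, seed = cfg$seed)
  ras <- rasterize_pattern(pat, cfg$panel, seed = cfg$seed + 1L,
                           roi_id = roi_id, sample_id = sample_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_image_stack(ras$stack, file.path(out_dir, paste0(roi_id, ".tiff")))
  write_label_mask(ras$mask, file.path(out_dir, paste0(roi_id, "_mask.tiff")))
  write_cell_table(ras$table, file.path(out_dir, paste0(roi_id, "_cells.csv")))
  invisible(ras)
}
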