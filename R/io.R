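# Serialization of pipeline artifacts: image stacks as multi-page 32-bit
# float TIFF with a JSON sidecar manifest, molecule tables as CSV, label
# volumes as TIFF, filter models and calibrations as JSON. Stage outputs
# round-trip exactly enough for every stage to be individually re-runnable
# from disk.

# TIFF stores values scaled into [0, 1]; the affine (offset, scale) per
# file lives in the manifest.
write_float_tiff <- function(arr, path) {
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  lo <- min(arr)
  hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[3]), function(k) (arr[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none",
                  reduce = FALSE)
  list(offset = lo, scale = scale)
}

read_float_tiff <- function(path, offset, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale + offset
  arr
}

#' Write a stack set to disk (TIFF + JSON manifest)
#'
#' One multi-page float TIFF per (FOV, bit), one single-page TIFF per
#' (FOV, round) bead image, and a `manifest.json` carrying the optics,
#' FOV layout, per-file scaling and normalization state. Mirrored by
#' [read_stacks()].
#'
#' @param bs a `bitstacks` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_stacks <- function(bs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (f in names(bs$stacks)) {
    for (b in seq_along(bs$stacks[[f]])) {
      fn <- sprintf("fov%s_bit%02d.tif", f, b)
      sc <- write_float_tiff(bs$stacks[[f]][[b]], file.path(dir, fn))
      files[[length(files) + 1]] <- c(list(kind = "stack", fov = f, bit = b,
                                           file = fn), sc)
    }
    for (r in seq_along(bs$beads[[f]])) {
      fn <- sprintf("fov%s_beads_round%02d.tif", f, r)
      sc <- write_float_tiff(bs$beads[[f]][[r]], file.path(dir, fn))
      files[[length(files) + 1]] <- c(list(kind = "beads", fov = f, round = r,
                                           file = fn), sc)
    }
  }
  opt <- unclass(bs$optics)
  # named atomic vectors lose their names in JSON; store as objects
  opt$psf_sigma_xy_px <- as.list(opt$psf_sigma_xy_px)
  opt$psf_sigma_z_planes <- as.list(opt$psf_sigma_z_planes)
  manifest <- list(
    dims = stack_dims(bs),
    optics = opt,
    fov_layout = as.list(bs$fov_layout),
    median_scale = bs$median_scale,
    preprocessed = isTRUE(bs$preprocessed),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Read a stack set written by [write_stacks()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `bitstacks` object.
#' @export
read_stacks <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  opt <- man$optics
  optics <- optics_config(
    n_bits = opt$n_bits, pixel_size_um = opt$pixel_size_um,
    z_step_um = opt$z_step_um,
    psf_sigma_xy_px = unlist(opt$psf_sigma_xy_px),
    psf_sigma_z_planes = unlist(opt$psf_sigma_z_planes),
    channel_of_bit = unlist(opt$channel_of_bit),
    chromatic_z_offset_planes = opt$chromatic_z_offset_planes)
  files <- man$files
  fovs <- unique(vapply(files, function(x) as.character(x$fov), character(1)))
  stacks <- list()
  beads <- list()
  for (f in fovs) {
    stacks[[f]] <- list()
    beads[[f]] <- list()
  }
  for (x in files) {
    arr <- read_float_tiff(file.path(dir, x$file), x$offset, x$scale)
    if (x$kind == "stack") {
      stacks[[as.character(x$fov)]][[x$bit]] <- arr
    } else {
      beads[[as.character(x$fov)]][[x$round]] <- arr[, , 1]
    }
  }
  bs <- list(stacks = stacks, beads = beads, optics = optics,
             median_scale = vapply(man$median_scale, function(v) {
               if (is.null(v)) NA_real_ else as.numeric(v)
             }, numeric(1)),
             valid = NULL,
             fov_layout = as.data.frame(lapply(man$fov_layout, unlist)))
  bs$preprocessed <- isTRUE(man$preprocessed)
  class(bs) <- "bitstacks"
  bs
}

#' Write / read a 3D integer label volume as TIFF
#'
#' @param labels 3D integer array.
#' @param path TIFF path.
#' @return `path` invisibly; [read_labels_tiff()] returns the array.
#' @export
write_labels_tiff <- function(labels, path) {
  mx <- max(1, max(labels))
  pages <- lapply(seq_len(dim(labels)[3]), function(k) labels[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(max_label = mx), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  mx <- jsonlite::read_json(paste0(path, ".json"))$max_label
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * mx))
  arr
}

#' Write / read a molecule table as CSV
#'
#' Columns are fixed and documented: 0-based `z_plane`, pixel centroids in
#' continuous pixel coordinates, global positions in micrometers.
#' @param mols molecule data.frame.
#' @param path CSV path.
#' @return `path` invisibly; [read_molecules()] returns the data.frame.
#' @export
write_molecules <- function(mols, path) {
  utils::write.csv(mols, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_molecules
#' @export
read_molecules <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a filter model to JSON
#'
#' @param model a `filter_model` from [adaptive_filter()].
#' @param path JSON path.
#' @return `path` invisibly.
#' @export
write_filter_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
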