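# Pixel-vector barcode decoding: each pixel's intensity vector across the
# imaging bits is compared, after L2 normalization, against the unit-
# normalized barcode vectors (coding AND blank entries); adjacent pixels
# with the same assigned barcode aggregate into putative molecules, and
# duplicates of the same molecule captured in adjacent z planes are
# collapsed.

#' Decode one z-plane of registered per-bit images
#'
#' For each pixel: the magnitude is the L2 norm of its intensity vector
#' over all bits (on the median-normalized scale); pixels below
#' `min_intensity` are left unassigned; otherwise the pixel is assigned to
#' the codebook entry (coding or blank) whose unit barcode vector is
#' nearest in Euclidean distance to the pixel's unit intensity vector, and
#' unassigned again if that distance exceeds `max_distance`. Distance ties
#' break towards the lowest entry index.
#'
#' @param planes list of n_bits co-registered 2D matrices.
#' @param cb a `merfish_codebook`.
#' @param max_distance maximum Euclidean distance to the nearest unit
#'   barcode (default 0.65).
#' @param min_intensity minimum pixel-vector magnitude (default 10).
#' @param valid optional logical matrix of decodable pixels (registration
#'   validity mask).
#' @return a `pixel_decode_maps` list: `barcode` (entry index, -1 =
#'   unassigned), `distance`, `magnitude`, `valid`.
#' @export
decode_plane <- function(planes, cb, max_distance = 0.65, min_intensity = 10,
                         valid = NULL) {
  stopifnot(inherits(cb, "merfish_codebook"))
  if (length(planes) != cb$n_bits) {
    stop(sprintf("got %d bit images but the codebook has %d bits",
                 length(planes), cb$n_bits))
  }
  d <- dim(planes[[1]])
  npix <- prod(d)
  P <- matrix(unlist(lapply(planes, as.numeric), use.names = FALSE), npix)
  mag <- sqrt(rowSums(P * P))
  V <- cb$unit_vectors
  barcode <- rep(-1L, npix)
  dist <- rep(NA_real_, npix)
  ok <- mag > 0
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  if (any(ok)) {
    U <- P[ok, , drop = FALSE] / mag[ok]
    dots <- U %*% t(V)
    best <- max.col(dots, ties.method = "first")
    bd <- pmin(pmax(dots[cbind(seq_along(best), best)], -1), 1)
    dd <- sqrt(pmax(2 - 2 * bd, 0))
    dist[ok] <- dd
    assign_ok <- mag[ok] >= min_intensity & dd <= max_distance & as.vector(valid)[ok]
    barcode[ok][assign_ok] <- as.integer(best[assign_ok])
  }
  out <- list(barcode = matrix(barcode, d[1], d[2]),
              distance = matrix(dist, d[1], d[2]),
              magnitude = matrix(mag, d[1], d[2]),
              valid = valid)
  class(out) <- "pixel_decode_maps"
  out
}

#' Aggregate same-barcode pixels into putative molecules
#'
#' Connected components (within each z-plane, 4-neighbor by default) among
#' pixels assigned the same barcode become putative RNA molecules with
#' area, magnitude-weighted centroid, mean magnitude and mean barcode
#' distance. Components of different barcodes never merge; 3D merging is
#' handled separately by [dedup_across_z()].
#'
#' @param maps one `pixel_decode_maps` or a list of them (one per z-plane,
#'   plane k taken as 0-based z index k-1).
#' @param connectivity 4 or 8.
#' @param cb optional codebook used to annotate gene names / blank flags.
#' @param fov fov id recorded per molecule.
#' @return a molecule `data.frame` (one row per putative molecule).
#' @export
aggregate_molecules <- function(maps, connectivity = 4, cb = NULL, fov = 1L) {
  if (inherits(maps, "pixel_decode_maps")) maps <- list(maps)
  rows <- list()
  for (k in seq_along(maps)) {
    mp <- maps[[k]]
    bar <- mp$barcode
    bar[bar < 0] <- 0L
    comp <- label_components(bar, connectivity)
    ncomp <- max(comp)
    if (ncomp == 0) next
    idx <- which(comp > 0)
    cid <- comp[idx]
    w <- mp$magnitude[idx]
    x <- (row(bar))[idx] - 0.5
    y <- (col(bar))[idx] - 0.5
    area <- tabulate(cid, ncomp)
    sw <- as.vector(rowsum(w, cid))
    cx <- as.vector(rowsum(w * x, cid)) / sw
    cy <- as.vector(rowsum(w * y, cid)) / sw
    mean_int <- sw / area
    mean_dist <- as.vector(rowsum(mp$distance[idx], cid)) / area
    bc <- bar[idx][match(seq_len(ncomp), cid)]
    rows[[length(rows) + 1]] <- data.frame(
      barcode_index = as.integer(bc), fov = as.integer(fov),
      z_plane = k - 1L, x_px = cx, y_px = cy, area_px = as.integer(area),
      mean_intensity = mean_int, mean_distance = mean_dist)
  }
  mols <- if (length(rows)) do.call(rbind, rows) else data.frame(
    barcode_index = integer(0), fov = integer(0), z_plane = integer(0),
    x_px = numeric(0), y_px = numeric(0), area_px = integer(0),
    mean_intensity = numeric(0), mean_distance = numeric(0))
  if (!is.null(cb)) {
    mols$gene <- cb$entries$name[mols$barcode_index]
    mols$is_blank <- cb$entries$is_blank[mols$barcode_index]
  }
  rownames(mols) <- NULL
  mols
}

#' Remove duplicate molecules captured in adjacent z planes
#'
#' Molecules with identical barcode, z planes differing by exactly 1 and
#' lateral centroid distance <= `xy_radius_px` are linked; within each
#' connected chain exactly one molecule is kept (largest area, then highest
#' mean intensity, then lowest z, then lowest row index). Molecules in
#' non-adjacent planes (a z gap) are never linked.
#'
#' @param mols molecule data.frame from [aggregate_molecules()].
#' @param xy_radius_px lateral matching radius in pixels.
#' @return deduplicated molecule data.frame.
#' @export
dedup_across_z <- function(mols, xy_radius_px = 1.5) {
  n <- nrow(mols)
  if (n <= 1) return(mols)
  edges <- list()
  key <- paste(mols$fov, mols$barcode_index)
  for (g in split(seq_len(n), key)) {
    if (length(g) < 2) next
    z <- mols$z_plane[g]
    for (zz in sort(unique(z))) {
      a <- g[z == zz]
      b <- g[z == zz + 1]
      if (length(a) == 0 || length(b) == 0) next
      dx <- outer(mols$x_px[a], mols$x_px[b], "-")
      dy <- outer(mols$y_px[a], mols$y_px[b], "-")
      hit <- which(dx * dx + dy * dy <= xy_radius_px^2, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        edges[[length(edges) + 1]] <- cbind(a[hit[, 1]], b[hit[, 2]])
      }
    }
  }
  if (length(edges) == 0) return(mols)
  E <- do.call(rbind, edges)
  gr <- igraph::graph_from_edgelist(cbind(as.character(E[, 1]),
                                          as.character(E[, 2])),
                                    directed = FALSE)
  comp <- igraph::components(gr)
  member <- split(as.integer(igraph::V(gr)$name), comp$membership)
  drop <- unlist(lapply(member, function(ix) {
    o <- order(-mols$area_px[ix], -mols$mean_intensity[ix], mols$z_plane[ix], ix)
    ix[o[-1]]
  }), use.names = FALSE)
  out <- mols[setdiff(seq_len(n), drop), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map molecule centroids to global physical coordinates
#'
#' Applies each FOV's origin plus its stitching translation (consumed as
#' input, e.g. exported from a stitching tool) and converts pixels to
#' micrometers: x_um = origin + shift + x_px * pixel_size, and
#' z_um = z_plane * z_step.
#'
#' @param mols molecule data.frame.
#' @param fov_layout data.frame(fov, origin_x_um, origin_y_um) with
#'   optional shift_x_um / shift_y_um stitching corrections.
#' @param optics an [optics_config()].
#' @return molecule data.frame with x_um, y_um, z_um columns.
#' @export
to_global_coords <- function(mols, fov_layout, optics) {
  m <- match(mols$fov, fov_layout$fov)
  if (anyNA(m)) {
    stop("missing stitching transform for fov(s): ",
         paste(unique(mols$fov[is.na(m)]), collapse = ", "))
  }
  sx <- if ("shift_x_um" %in% names(fov_layout)) fov_layout$shift_x_um else 0
  sy <- if ("shift_y_um" %in% names(fov_layout)) fov_layout$shift_y_um else 0
  mols$x_um <- fov_layout$origin_x_um[m] + rep(sx, length.out = nrow(fov_layout))[m] +
    mols$x_px * optics$pixel_size_um
  mols$y_um <- fov_layout$origin_y_um[m] + rep(sy, length.out = nrow(fov_layout))[m] +
    mols$y_px * optics$pixel_size_um
  mols$z_um <- mols$z_plane * optics$z_step_um
  mols
}

#' Decode all planes of a preprocessed stack set
#'
#' Runs [decode_plane()] on every z-plane of every FOV and aggregates
#' molecules, annotating gene names and global coordinates.
#'
#' @param bs preprocessed `bitstacks`.
#' @param cb a `merfish_codebook`.
#' @param max_distance,min_intensity decoder gates.
#' @param connectivity aggregation connectivity.
#' @return molecule data.frame.
#' @export
decode_stacks <- function(bs, cb, max_distance = 0.65, min_intensity = 10,
                          connectivity = 4) {
  d <- stack_dims(bs)
  all_mols <- list()
  for (f in names(bs$stacks)) {
    maps <- vector("list", d[3])
    vmask <- bs$valid[[f]]
    for (k in seq_len(d[3])) {
      planes <- lapply(bs$stacks[[f]], function(st) st[, , k])
      vk <- if (!is.null(vmask)) {
        matrix(vmask[((k - 1) * d[1] * d[2] + 1):(k * d[1] * d[2])], d[1], d[2])
      } else NULL
      maps[[k]] <- decode_plane(planes, cb, max_distance, min_intensity, vk)
    }
    all_mols[[f]] <- aggregate_molecules(maps, connectivity, cb,
                                         fov = as.integer(f))
  }
  mols <- do.call(rbind, all_mols)
  rownames(mols) <- NULL
  to_global_coords(mols, bs$fov_layout, bs$optics)
}
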