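# Segmented-cell handling: build cell sets from 3D label volumes, remove
# duplicate cells arising from the ~10% FOV overlap, assign decoded
# molecules to cells, apply cell-level quality control and build the
# normalized cell-by-gene matrix.

# Encode integer global voxel coordinates as a single double (exact up to
# 2^53); used for fast overlap and point-in-cell lookups.
voxel_key <- function(gx, gy, gz) {
  gx + gy * 2^20 + gz * 2^40
}

#' Build a cell set from a 3D label volume
#'
#' Computes per-cell volume (voxel count times voxel volume), centroid in
#' global micrometers, z extent (number of z sections containing the
#' cell), and the set of occupied voxels on the global acquisition grid.
#'
#' @param labels 3D integer label array (0 = background).
#' @param optics an [optics_config()] (voxel geometry).
#' @param fov fov id recorded per cell.
#' @param origin_um c(x, y) origin of this FOV in the global frame.
#' @param id_offset added to label values to form globally unique ids.
#' @return a `cell_set`: list(cells = data.frame, vox = list of voxel-key
#'   vectors, optics).
#' @export
cell_set_from_labels <- function(labels, optics, fov = 1L,
                                 origin_um = c(0, 0), id_offset = 0L) {
  d <- dim(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    cells <- data.frame(id = integer(0), fov = integer(0), volume_um3 = numeric(0),
                        x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                        z_extent = integer(0), n_voxels = integer(0))
    out <- list(cells = cells, vox = list(), optics = optics)
    class(out) <- "cell_set"
    return(out)
  }
  lab <- labels[idx]
  ix <- ((idx - 1L) %% d[1])
  iy <- ((idx - 1L) %/% d[1]) %% d[2]
  iz <- (idx - 1L) %/% (d[1] * d[2])
  gx0 <- round(origin_um[1] / optics$pixel_size_um)
  gy0 <- round(origin_um[2] / optics$pixel_size_um)
  gx <- ix + gx0
  gy <- iy + gy0
  keys <- voxel_key(gx, gy, iz)
  u <- sort(unique(lab))
  voxel_um3 <- optics$pixel_size_um^2 * optics$z_step_um
  grp <- match(lab, u)
  n_vox <- tabulate(grp, length(u))
  cx <- as.vector(rowsum(gx + 0.5, grp)) / n_vox * optics$pixel_size_um
  cy <- as.vector(rowsum(gy + 0.5, grp)) / n_vox * optics$pixel_size_um
  cz <- as.vector(rowsum(iz + 0.5, grp)) / n_vox * optics$z_step_um
  z_extent <- vapply(split(iz, grp), function(z) length(unique(z)), integer(1))
  cells <- data.frame(
    id = as.integer(u + id_offset), fov = as.integer(fov),
    volume_um3 = n_vox * voxel_um3,
    x_um = cx, y_um = cy, z_um = cz,
    z_extent = as.integer(z_extent), n_voxels = n_vox)
  out <- list(cells = cells, vox = split(keys, grp), optics = optics)
  names(out$vox) <- as.character(cells$id)
  class(out) <- "cell_set"
  out
}

#' Combine cell sets from several FOVs into one global set
#'
#' @param ... `cell_set` objects with globally unique cell ids.
#' @return a combined `cell_set`.
#' @export
combine_cell_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  out <- list(cells = do.call(rbind, lapply(sets, `[[`, "cells")),
              vox = do.call(c, lapply(sets, `[[`, "vox")),
              optics = sets[[1]]$optics)
  if (anyDuplicated(out$cells$id)) stop("cell ids must be globally unique")
  rownames(out$cells) <- NULL
  class(out) <- "cell_set"
  out
}

#' Remove duplicate cells across overlapping FOVs
#'
#' For each cell the `k` nearest neighboring cells (by centroid distance)
#' are examined; for each neighbor the overlapping volume is computed on
#' the voxel grid and divided by the smaller of the two cell volumes. Pairs
#' with overlap ratio above `overlap_threshold` are resolved in order of
#' descending ratio by removing the smaller-volume member (volume ties keep
#' the lower id). The surviving set has no pair above the threshold among
#' the examined neighbors, and the operation is idempotent.
#'
#' @param cs a `cell_set` in a common global frame.
#' @param k number of nearest neighbors examined per cell.
#' @param overlap_threshold duplicate ratio threshold (default 0.40).
#' @return deduplicated `cell_set` with a `removed_ids` attribute.
#' @export
dedup_cells <- function(cs, k = 10, overlap_threshold = 0.40) {
  stopifnot(inherits(cs, "cell_set"))
  n <- nrow(cs$cells)
  if (length(cs$vox) != n) stop("cells lack voxel geometry; cannot compute overlaps")
  if (n < 2) return(cs)
  pos <- as.matrix(cs$cells[, c("x_um", "y_um", "z_um")])
  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf
  cand <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(min(k, n - 1))]
    cand[i, nb] <- TRUE
  }
  pairs <- which(cand | t(cand), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(cs)
  ratio <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    ov <- sum(cs$vox[[i]] %in% cs$vox[[j]])
    ratio[p] <- ov / min(cs$cells$n_voxels[i], cs$cells$n_voxels[j])
  }
  sel <- ratio > overlap_threshold
  pairs <- pairs[sel, , drop = FALSE]
  ratio <- ratio[sel]
  alive <- rep(TRUE, n)
  if (nrow(pairs) > 0) {
    o <- order(-ratio, pairs[, 1], pairs[, 2])
    for (p in o) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (!alive[i] || !alive[j]) next
      vi <- cs$cells$volume_um3[i]; vj <- cs$cells$volume_um3[j]
      loser <- if (vi < vj) i else if (vj < vi) j else max(i, j)
      alive[loser] <- FALSE
    }
  }
  removed <- cs$cells$id[!alive]
  out <- list(cells = cs$cells[alive, , drop = FALSE],
              vox = cs$vox[alive], optics = cs$optics)
  rownames(out$cells) <- NULL
  class(out) <- "cell_set"
  attr(out, "removed_ids") <- removed
  out
}

#' Assign molecules to cells and build the cell-by-gene matrix
#'
#' A molecule is counted for a cell iff the voxel containing its global
#' (x, y, z) position belongs to that cell's segmentation; molecules in
#' background (or outside every FOV) are tallied as unassigned. Blank
#' entries are excluded from the matrix columns, which follow the codebook
#' coding-entry order.
#'
#' @param mols molecule data.frame with global x_um, y_um, z_um and gene.
#' @param cs a deduplicated `cell_set`.
#' @param cb a `merfish_codebook`.
#' @return integer matrix cells x genes with attributes `unassigned`
#'   (count) and `cells` (the cell metadata rows).
#' @export
assign_molecules <- function(mols, cs, cb) {
  stopifnot(inherits(cs, "cell_set"), inherits(cb, "merfish_codebook"))
  genes <- cb$entries$name[!cb$entries$is_blank]
  ids <- cs$cells$id
  mat <- matrix(0L, nrow = length(ids), ncol = length(genes),
                dimnames = list(as.character(ids), genes))
  mols <- mols[!mols$is_blank, , drop = FALSE]
  if (nrow(mols) > 0) {
    gx <- floor(mols$x_um / cs$optics$pixel_size_um)
    gy <- floor(mols$y_um / cs$optics$pixel_size_um)
    gz <- floor(mols$z_um / cs$optics$z_step_um + 1e-9)
    keys <- voxel_key(gx, gy, gz)
    all_keys <- unlist(cs$vox, use.names = FALSE)
    owner <- rep(seq_along(cs$vox), lengths(cs$vox))
    hit <- match(keys, all_keys)
    cell_row <- ifelse(is.na(hit), NA_integer_, owner[hit])
    gcol <- match(mols$gene, genes)
    ok <- !is.na(cell_row) & !is.na(gcol)
    if (any(ok)) {
      tab <- table(factor(cell_row[ok], levels = seq_along(ids)),
                   factor(gcol[ok], levels = seq_along(genes)))
      mat <- mat + matrix(as.integer(tab), nrow = length(ids),
                          dimnames = dimnames(mat))
    }
    attr(mat, "unassigned") <- sum(!ok)
  } else {
    attr(mat, "unassigned") <- 0L
  }
  attr(mat, "cells") <- cs$cells
  mat
}

#' Cell-level quality control
#'
#' Excludes cells with small volume (< `min_volume`), low total RNA count
#' (< `min_counts`), or captured in fewer than `min_z` or more than
#' `max_z` adjacent z sections; the retained cells satisfy all predicates.
#' Per-cell exclusion reasons are recorded in the `exclusions` attribute.
#'
#' @param mat cell-by-gene count matrix from [assign_molecules()].
#' @param cells cell metadata (rows aligned with `mat`); taken from the
#'   matrix attribute when NULL.
#' @param min_volume minimum volume (default 100, the printed threshold).
#' @param min_counts minimum total RNA count (default 30).
#' @param min_z,max_z allowed z-extent range in 1 um sections (5-40).
#' @return the filtered matrix with updated `cells` and `exclusions`
#'   attributes.
#' @export
qc_cells <- function(mat, cells = NULL, min_volume = 100, min_counts = 30,
                     min_z = 5, max_z = 40) {
  if (is.null(cells)) cells <- attr(mat, "cells")
  stopifnot(nrow(mat) == nrow(cells))
  counts <- rowSums(mat)
  bad_vol <- cells$volume_um3 < min_volume
  bad_cnt <- counts < min_counts
  bad_z <- cells$z_extent < min_z | cells$z_extent > max_z
  keep <- !(bad_vol | bad_cnt | bad_z)
  reasons <- mapply(function(v, c2, z) {
    paste(c(if (v) "small_volume", if (c2) "low_counts", if (z) "z_extent"),
          collapse = ";")
  }, bad_vol, bad_cnt, bad_z)
  excl <- data.frame(id = cells$id[!keep], reason = reasons[!keep],
                     stringsAsFactors = FALSE)
  out <- mat[keep, , drop = FALSE]
  attr(out, "cells") <- cells[keep, , drop = FALSE]
  attr(out, "unassigned") <- attr(mat, "unassigned")
  attr(out, "exclusions") <- excl
  out
}

#' Library-size normalization with log transform
#'
#' Divides each cell's counts by its total, multiplies by `scale` (10,000
#' by default, so every cell carries the same total), then applies
#' log(1 + x). Every pre-log row sums to `scale` exactly.
#'
#' @param mat QC'd cell-by-gene count matrix.
#' @param scale target total per cell.
#' @param log_base base of the log transform (natural log by default).
#' @return real-valued normalized matrix.
#' @export
normalize_matrix <- function(mat, scale = 10000, log_base = exp(1)) {
  rs <- rowSums(mat)
  if (any(rs == 0)) {
    stop("zero-count cell row(s): ",
         paste(utils::head(rownames(mat)[rs == 0]), collapse = ", "))
  }
  log1p(mat / rs * scale) / log(log_base)
}

#' Export a cell-by-gene matrix as MatrixMarket + TSV sidecars
#'
#' @param mat cell-by-gene matrix.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cell_by_gene <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- Matrix::Matrix(unclass(mat)[, , drop = FALSE], sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = colnames(mat)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  cells <- attr(mat, "cells")
  if (!is.null(cells)) {
    utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(data.frame(id = rownames(mat)),
                       file.path(dir, "cells.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
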