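# Cell sets, duplicate-cell removal, molecule assignment, QC and matrix
# normalization.

# Two z planes, two 4-voxel square cells side by side.
small_cell_set <- function() {
  oc <- optics_config(2, pixel_size_um = 1, z_step_um = 1)
  lab <- array(0L, c(8, 8, 3))
  lab[2:3, 2:3, 1:2] <- 1L
  lab[6:7, 6:7, 2] <- 2L
  cell_set_from_labels(lab, oc)
}

test_that("cell statistics derive from the label volume", {
  cs <- small_cell_set()
  expect_equal(cs$cells$n_voxels, c(8L, 4L))
  expect_equal(cs$cells$volume_um3, c(8, 4))
  expect_equal(cs$cells$z_extent, c(2L, 1L))
  expect_equal(cs$cells$x_um[1], 2)  # voxels 2:3 -> centres 1.5 and 2.5
  expect_equal(cs$cells$z_um[1], 1)
})

# Build a cell set whose per-cell voxel sets are given explicitly (in two
# overlapping FOVs), to control pairwise overlap ratios exactly.
cells_from_voxels <- function(vox_list, volumes = NULL) {
  oc <- optics_config(2, pixel_size_um = 1, z_step_um = 1)
  cells <- do.call(rbind, lapply(seq_along(vox_list), function(i) {
    v <- vox_list[[i]]
    data.frame(id = i, fov = 1L, volume_um3 = nrow(v),
               x_um = mean(v[, 1]) + 0.5, y_um = mean(v[, 2]) + 0.5,
               z_um = mean(v[, 3]) + 0.5,
               z_extent = length(unique(v[, 3])), n_voxels = nrow(v))
  }))
  if (!is.null(volumes)) cells$volume_um3 <- volumes
  out <- list(cells = cells,
              vox = lapply(vox_list, function(v) {
                merfish3d:::voxel_key(v[, 1], v[, 2], v[, 3])
              }),
              optics = oc)
  names(out$vox) <- as.character(cells$id)
  class(out) <- "cell_set"
  out
}

box_vox <- function(x0, nx, y0 = 0, ny = 4, z0 = 0, nz = 2) {
  as.matrix(expand.grid(x = x0:(x0 + nx - 1), y = y0:(y0 + ny - 1),
                        z = z0:(z0 + nz - 1)))
}

test_that("identical cells collapse to one and disjoint cells persist", {
  cs <- cells_from_voxels(list(box_vox(0, 4), box_vox(0, 4)))
  dd <- dedup_cells(cs)
  expect_equal(nrow(dd$cells), 1L)
  expect_equal(dd$cells$id, 1L)  # volume tie keeps the lower id
  cs2 <- cells_from_voxels(list(box_vox(0, 4), box_vox(50, 4)))
  expect_equal(nrow(dedup_cells(cs2)$cells), 2L)
})

test_that("overlap ratios straddling 40% resolve like the pairwise oracle", {
  # cells A (8 cols), B (6 cols), C (4 cols) with designed overlaps
  A <- box_vox(0, 8)
  B <- box_vox(5, 6)    # overlap with A: 3 cols / min 6 = 0.5
  C <- box_vox(9, 4)    # overlap with B: 2 cols / min 4 = 0.5; with A: 0
  cs <- cells_from_voxels(list(A, B, C))
  dd <- dedup_cells(cs)
  expect_equal(sort(dd$cells$id), sort(oracle_dedup_cells(cs, 0.4)))
  # the survivor set has no remaining pair above threshold
  expect_equal(nrow(dedup_cells(dd)$cells), nrow(dd$cells))
  # randomized battery against the oracle
  set.seed(13)
  for (rep in 1:5) {
    vox <- lapply(1:6, function(i) {
      x0 <- sample(0:10, 1)
      box_vox(x0, sample(3:7, 1))
    })
    cs_r <- cells_from_voxels(vox)
    dd_r <- dedup_cells(cs_r)
    expect_equal(sort(dd_r$cells$id), sort(oracle_dedup_cells(cs_r, 0.4)))
    # idempotence
    expect_equal(dedup_cells(dd_r)$cells, dd_r$cells)
  }
})

test_that("molecules are assigned by voxel lookup and conserved", {
  cs <- small_cell_set()
  cb <- tiny_codebook()
  mols <- data.frame(
    gene = c("g1", "g1", "g2", "g3"),
    is_blank = FALSE,
    x_um = c(2.1, 6.5, 2.5, 0.2),   # cell1, cell2, cell1, background
    y_um = c(2.1, 6.5, 2.9, 0.2),
    z_um = c(0.5, 1.5, 1.5, 0.5))
  mat <- assign_molecules(mols, cs, cb)
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(unname(mat["1", c("g1", "g2", "g3")]), c(1L, 1L, 0L))
  expect_equal(unname(mat["2", "g1"]), 1L)
  expect_equal(attr(mat, "unassigned"), 1L)
  expect_equal(sum(mat) + attr(mat, "unassigned"), nrow(mols))
  # blank molecules never enter the matrix
  mols_b <- rbind(mols, data.frame(gene = "blank1", is_blank = TRUE,
                                   x_um = 2.1, y_um = 2.1, z_um = 0.5))
  expect_equal(sum(assign_molecules(mols_b, cs, cb)), sum(mat))
  expect_false("blank1" %in% colnames(mat))
})

qc_fixture <- function() {
  # 12 cells enumerating volume / counts / z-extent edge cases
  cells <- data.frame(
    id = 1:12,
    fov = 1L,
    volume_um3 = c(99, 100, 150, 150, 150, 150, 150, 150, 150, 150, 101, 99),
    x_um = 0, y_um = 0, z_um = 0,
    z_extent = c(10, 10, 4, 5, 40, 41, 10, 10, 10, 10, 5, 4),
    n_voxels = 1L)
  counts <- c(50, 50, 50, 50, 50, 50, 29, 30, 31, 0, 50, 10)
  mat <- matrix(0L, 12, 2, dimnames = list(as.character(1:12), c("g1", "g2")))
  mat[, 1] <- as.integer(ceiling(counts / 2))
  mat[, 2] <- as.integer(floor(counts / 2))
  attr(mat, "cells") <- cells
  list(mat = mat, cells = cells, counts = counts)
}

test_that("QC keeps exactly the predicate-satisfying cells", {
  fx <- qc_fixture()
  keep_oracle <- with(fx, which(cells$volume_um3 >= 100 & counts >= 30 &
                                  cells$z_extent >= 5 & cells$z_extent <= 40))
  qc <- qc_cells(fx$mat)
  expect_equal(as.integer(rownames(qc)), keep_oracle)
  # printed-threshold edges: volume 99 out, counts 30 in, z 5 and 40 in
  expect_false("1" %in% rownames(qc))
  expect_true("8" %in% rownames(qc))
  expect_true("4" %in% rownames(qc))
  expect_true("5" %in% rownames(qc))
  expect_false("6" %in% rownames(qc))
  ex <- attr(qc, "exclusions")
  expect_equal(sort(ex$id), sort(setdiff(1:12, keep_oracle)))
  expect_match(ex$reason[ex$id == 12], "small_volume;low_counts;z_extent")
  # no-op thresholds are the identity
  qc0 <- qc_cells(fx$mat, min_volume = 0, min_counts = 0, min_z = 0,
                  max_z = Inf)
  expect_equal(nrow(qc0), 12L)
})

test_that("normalization scales every cell to 10,000 then logs", {
  m <- matrix(c(3, 7), 1, 2, dimnames = list("c1", c("g1", "g2")))
  nm <- normalize_matrix(m)
  expect_equal(as.vector(expm1(nm)), c(3000, 7000))
  one <- matrix(17, 1, 1, dimnames = list("c1", "g1"))
  expect_equal(as.vector(expm1(normalize_matrix(one))), 10000)
  set.seed(3)
  rnd <- matrix(rpois(60, 20) + 1L, 6, 10)
  pre_log <- expm1(normalize_matrix(rnd))
  expect_true(all(abs(rowSums(pre_log) - 10000) < 1e-6))
  bad <- matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(normalize_matrix(bad), "zero-count")
  # base-2 option
  expect_equal(normalize_matrix(m, log_base = 2), nm / log(2))
})
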