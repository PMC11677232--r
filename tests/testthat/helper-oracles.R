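# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation
# paths they check.

# Write a codebook CSV from raw columns and load it through the public API.
codebook_from_table <- function(name, barcode, is_blank) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(name = name, barcode = barcode,
                              is_blank = is_blank),
                   path, row.names = FALSE, quote = FALSE)
  load_codebook(path)
}

tiny_codebook <- function() {
  codebook_from_table(
    name = c("g1", "g2", "g3", "blank1"),
    barcode = c("1100", "0110", "0011", "1001"),
    is_blank = c(FALSE, FALSE, FALSE, TRUE))
}

# Exhaustive nearest-entry pixel decoder: for every pixel, scan all
# codebook entries and apply both gates literally.
oracle_decode <- function(planes, cb, max_distance, min_intensity) {
  d <- dim(planes[[1]])
  V <- cb$unit_vectors
  bar <- matrix(-1L, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- vapply(planes, function(p) p[i, j], numeric(1))
      mag <- sqrt(sum(v^2))
      if (mag < min_intensity || mag == 0) next
      u <- v / mag
      dists <- vapply(seq_len(nrow(V)), function(e) sqrt(sum((u - V[e, ])^2)),
                      numeric(1))
      best <- which.min(dists)
      if (dists[best] <= max_distance) bar[i, j] <- best
    }
  }
  bar
}

# Recursive flood fill component counter over equal positive values.
oracle_components <- function(m, connectivity = 4) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  nbrs <- if (connectivity == 4) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  count <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(m[i, j]) || m[i, j] <= 0 || seen[i, j]) next
    count <- count + 1
    stack <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (s in nbrs) {
        a <- p[1] + s[1]; b <- p[2] + s[2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc && !seen[a, b] &&
            !is.na(m[a, b]) && m[a, b] == m[i, j] && m[a, b] > 0) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1]] <- c(a, b)
        }
      }
    }
  }
  count
}

# Brute-force z-duplicate survivor set: scan every molecule pair, link
# same-barcode adjacent-z close pairs, take connected groups by repeated
# expansion, keep one per group by the stated policy.
oracle_dedup_z <- function(mols, xy_radius_px) {
  n <- nrow(mols)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (mols$barcode_index[i] == mols$barcode_index[j] &&
        mols$fov[i] == mols$fov[j] &&
        abs(mols$z_plane[i] - mols$z_plane[j]) == 1 &&
        sqrt((mols$x_px[i] - mols$x_px[j])^2 +
               (mols$y_px[i] - mols$y_px[j])^2) <= xy_radius_px) {
      adj[i, j] <- TRUE
    }
  }
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && group[j] != group[i]) {
        g <- min(group[i], group[j])
        group[group == group[i] | group == group[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- integer(0)
  for (g in unique(group)) {
    ix <- which(group == g)
    o <- order(-mols$area_px[ix], -mols$mean_intensity[ix], mols$z_plane[ix], ix)
    keep <- c(keep, ix[o[1]])
  }
  sort(keep)
}

# Exhaustive pairwise duplicate-cell resolution: all pairs (not just kNN),
# ratios recomputed from voxel sets, resolved in descending-ratio order by
# removing the smaller cell (ties keep the lower id).
oracle_dedup_cells <- function(cs, threshold) {
  n <- nrow(cs$cells)
  pr <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- length(intersect(cs$vox[[i]], cs$vox[[j]]))
    ratio <- ov / min(length(cs$vox[[i]]), length(cs$vox[[j]]))
    if (ratio > threshold) pr[[length(pr) + 1]] <- c(i, j, ratio)
  }
  alive <- rep(TRUE, n)
  if (length(pr) > 0) {
    M <- do.call(rbind, pr)
    M <- M[order(-M[, 3], M[, 1], M[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(M))) {
      i <- M[r, 1]; j <- M[r, 2]
      if (!alive[i] || !alive[j]) next
      vi <- cs$cells$volume_um3[i]; vj <- cs$cells$volume_um3[j]
      loser <- if (vi < vj) i else if (vj < vi) j else max(i, j)
      alive[loser] <- FALSE
    }
  }
  cs$cells$id[alive]
}

# O(n^2) nearest-neighbor scan.
oracle_nn <- function(cells, focal_idx, scope_idx) {
  out <- data.frame(id = integer(0), nn_id = integer(0), d = numeric(0))
  for (i in focal_idx) {
    best <- NA; bd <- Inf
    for (j in scope_idx) {
      if (j == i) next
      dd <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2 +
                   (cells$z[i] - cells$z[j])^2)
      if (dd < bd) { bd <- dd; best <- j }
    }
    out <- rbind(out, data.frame(id = cells$id[i], nn_id = cells$id[best], d = bd))
  }
  out
}

# Molecule table builder for filter/dedup tests.
make_mols <- function(barcode_index = 1L, z_plane, x_px, y_px, area_px = 2,
                      mean_intensity = 20, mean_distance = 0.2,
                      is_blank = FALSE, fov = 1L) {
  n <- max(length(barcode_index), length(z_plane), length(x_px),
           length(y_px), length(area_px), length(mean_intensity),
           length(mean_distance), length(is_blank))
  barcode_index <- rep_len(barcode_index, n)
  z_plane <- rep_len(z_plane, n)
  x_px <- rep_len(x_px, n)
  y_px <- rep_len(y_px, n)
  data.frame(barcode_index = barcode_index, fov = rep_len(fov, n),
             z_plane = z_plane, x_px = x_px, y_px = y_px,
             area_px = rep_len(area_px, n),
             mean_intensity = rep_len(mean_intensity, n),
             mean_distance = rep_len(mean_distance, n),
             is_blank = rep_len(is_blank, n))
}
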