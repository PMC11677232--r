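# Synthetic 3D imaging model: ground-truthed multi-bit z-stacks, fiducial
# bead images and toy segmentations emulating a thick-tissue confocal
# MERFISH acquisition. Every downstream stage of the package is testable
# against the ground truth planted here.
#
# Imaging model: each RNA molecule contributes a separable 3D Gaussian
# (the PSF stand-in) to exactly the ON bits of its gene's barcode; bits in
# the second color channel are rendered with an axial chromatic offset;
# each imaging round is translated by that round's stage drift; cellular
# background and Poisson shot noise plus Gaussian read noise are added
# last. Blank barcodes never receive planted signal, so any decoded blank
# is a decoding error by construction.

#' Optical configuration of the simulated microscope
#'
#' @param n_bits number of imaging bits (two per hybridization round).
#' @param pixel_size_um lateral pixel size, micrometers.
#' @param z_step_um axial step between z planes, micrometers (1 um here,
#'   matching thick-tissue confocal acquisition).
#' @param psf_sigma_xy_px lateral Gaussian PSF sigma per channel, pixels
#'   (named vector over channels A/B, or one value for both).
#' @param psf_sigma_z_planes axial PSF sigma per channel, in z planes.
#' @param channel_of_bit character vector mapping each bit to channel
#'   "A" (~650 nm) or "B" (~560 nm); default alternates A,B within each
#'   round (two-color readout, two bits per round).
#' @param chromatic_z_offset_planes axial chromatic offset of channel B
#'   relative to channel A, in planes.
#' @return an `optics_config` list.
#' @export
optics_config <- function(n_bits,
                          pixel_size_um = 0.167,
                          z_step_um = 1.0,
                          psf_sigma_xy_px = c(A = 1.3, B = 1.3),
                          psf_sigma_z_planes = c(A = 0.9, B = 0.9),
                          channel_of_bit = NULL,
                          chromatic_z_offset_planes = 0) {
  stopifnot(pixel_size_um > 0, z_step_um > 0,
            all(psf_sigma_xy_px > 0), all(psf_sigma_z_planes > 0))
  if (length(psf_sigma_xy_px) == 1) psf_sigma_xy_px <- c(A = unname(psf_sigma_xy_px), B = unname(psf_sigma_xy_px))
  if (length(psf_sigma_z_planes) == 1) psf_sigma_z_planes <- c(A = unname(psf_sigma_z_planes), B = unname(psf_sigma_z_planes))
  if (is.null(channel_of_bit)) {
    channel_of_bit <- rep(c("A", "B"), length.out = n_bits)
  }
  stopifnot(length(channel_of_bit) == n_bits,
            all(channel_of_bit %in% c("A", "B")))
  out <- list(
    n_bits = as.integer(n_bits),
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    psf_sigma_xy_px = psf_sigma_xy_px,
    psf_sigma_z_planes = psf_sigma_z_planes,
    channel_of_bit = channel_of_bit,
    round_of_bit = as.integer(ceiling(seq_len(n_bits) / 2)),
    chromatic_z_offset_planes = chromatic_z_offset_planes
  )
  class(out) <- "optics_config"
  out
}

#' Signal amplitude needed for a target peak signal-to-noise ratio
#'
#' The simulator's noise model is Poisson shot noise on
#' (signal + background) plus Gaussian read noise, so the background noise
#' standard deviation is sqrt(background + read_sigma^2) and
#' brightness = snr * sqrt(background + read_sigma^2).
#' @param snr target peak SNR.
#' @param background_level mean background, photons.
#' @param read_sigma read noise standard deviation, photons.
#' @return peak brightness in photons.
#' @export
brightness_for_snr <- function(snr, background_level, read_sigma) {
  snr * sqrt(background_level + read_sigma^2)
}

#' Plant a ground-truth molecule, bead and drift configuration
#'
#' Molecules are uniform in the imaged volume with genes uniform over the
#' non-blank codebook entries (blanks never receive signal); fiducial beads
#' are uniform at the coverslip plane; per-round stage drifts are uniform
#' in \[-drift_mag, drift_mag\]^2 with round 1 as the zero-drift reference.
#'
#' @param cb a `merfish_codebook`.
#' @param density_per_100um2_per_plane expected molecules per 100 um^2 of
#'   field area per z plane.
#' @param volume_px integer c(nx, ny, nz) of the simulated volume.
#' @param optics an [optics_config()].
#' @param n_beads number of fiducial beads.
#' @param drift_mag_px max per-round drift magnitude per axis, pixels.
#' @param seed integer seed (fixed seed => identical truth).
#' @param brightness peak molecule brightness, photons.
#' @param brightness_cv lognormal coefficient of variation of brightness.
#' @param n_cells optional number of toy cells to place (0 = none).
#' @param cell_radius_um_range radius range for toy cells, micrometers.
#' @return a `ground_truth` list with molecules, beads, drift_per_round,
#'   cell info and the fov layout.
#' @export
plant_truth <- function(cb, density_per_100um2_per_plane, volume_px, optics,
                        n_beads = 30, drift_mag_px = 2, seed = 1,
                        brightness = brightness_for_snr(10, 1, 1),
                        brightness_cv = 0.1,
                        n_cells = 0, cell_radius_um_range = c(3, 5)) {
  stopifnot(inherits(cb, "merfish_codebook"),
            density_per_100um2_per_plane >= 0, length(volume_px) == 3)
  coding <- which(!cb$entries$is_blank)
  if (length(coding) == 0) stop("codebook has no coding entries to plant")
  nx <- volume_px[1]; ny <- volume_px[2]; nz <- volume_px[3]
  area_um2 <- nx * ny * optics$pixel_size_um^2
  lambda <- density_per_100um2_per_plane * area_um2 / 100^2 * nz
  n_rounds <- max(optics$round_of_bit)
  with_seed(stage_seed(seed, "plant_truth"), {
    n_mol <- stats::rpois(1, lambda)
    mol <- data.frame(
      entry = if (n_mol > 0) sample(coding, n_mol, replace = TRUE) else integer(0),
      x_px = stats::runif(n_mol, 0, nx),
      y_px = stats::runif(n_mol, 0, ny),
      z_px = stats::runif(n_mol, 0, nz),
      brightness = brightness * exp(stats::rnorm(n_mol, 0, brightness_cv) -
                                      brightness_cv^2 / 2)
    )
    mol$gene <- cb$entries$name[mol$entry]
    mol$x_um <- mol$x_px * optics$pixel_size_um
    mol$y_um <- mol$y_px * optics$pixel_size_um
    mol$z_um <- mol$z_px * optics$z_step_um
    beads <- data.frame(x_px = stats::runif(n_beads, 2, nx - 2),
                        y_px = stats::runif(n_beads, 2, ny - 2))
    drift <- data.frame(
      round = seq_len(n_rounds),
      dx_px = c(0, stats::runif(n_rounds - 1, -drift_mag_px, drift_mag_px)),
      dy_px = c(0, stats::runif(n_rounds - 1, -drift_mag_px, drift_mag_px))
    )
    cells <- NULL
    if (n_cells > 0) {
      cells <- render_cells(volume_px, n_cells, cell_radius_um_range, optics,
                            seed = stage_seed(seed, "truth_cells"))
    }
    out <- list(molecules = mol, beads = beads, drift_per_round = drift,
                cells = cells, volume_px = volume_px,
                fov_layout = data.frame(fov = 1L, origin_x_um = 0, origin_y_um = 0))
    class(out) <- "ground_truth"
    out
  })
}

# Add one separable 3D Gaussian of peak `amp` at (x, y, z) (continuous
# pixel coords) into `stack`, truncated at 3.5 sigma.
add_spot <- function(stack, x, y, z, amp, sx, sy, sz) {
  d <- dim(stack)
  rx <- ceiling(3.5 * sx); ry <- ceiling(3.5 * sy); rz <- ceiling(3.5 * sz)
  # pixel i (1-based) has centre coordinate i - 0.5
  ix <- max(1, floor(x - rx)):min(d[1], ceiling(x + rx) + 1)
  iy <- max(1, floor(y - ry)):min(d[2], ceiling(y + ry) + 1)
  iz <- max(1, floor(z - rz)):min(d[3], ceiling(z + rz) + 1)
  if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0) return(stack)
  gx <- exp(-((ix - 0.5) - x)^2 / (2 * sx^2))
  gy <- exp(-((iy - 0.5) - y)^2 / (2 * sy^2))
  gz <- exp(-((iz - 0.5) - z)^2 / (2 * sz^2))
  patch <- (amp * outer(gx, gy)) %o% gz
  stack[ix, iy, iz] <- stack[ix, iy, iz] + patch
  stack
}

add_spot2d <- function(im, x, y, amp, s) {
  d <- dim(im)
  r <- ceiling(3.5 * s)
  ix <- max(1, floor(x - r)):min(d[1], ceiling(x + r) + 1)
  iy <- max(1, floor(y - r)):min(d[2], ceiling(y + r) + 1)
  if (length(ix) == 0 || length(iy) == 0) return(im)
  gx <- exp(-((ix - 0.5) - x)^2 / (2 * s^2))
  gy <- exp(-((iy - 0.5) - y)^2 / (2 * s^2))
  im[ix, iy] <- im[ix, iy] + amp * outer(gx, gy)
  im
}

apply_noise <- function(arr, poisson_on, read_sigma, add_bg) {
  x <- arr + add_bg
  if (poisson_on) {
    x[] <- stats::rpois(length(x), pmax(x, 0))
  }
  if (read_sigma > 0) {
    x <- x + stats::rnorm(length(x), 0, read_sigma)
  }
  x
}

#' Render per-bit 3D image stacks and per-round bead images
#'
#' Renders the planted ground truth through the imaging model: molecule
#' Gaussians in the ON bits of their barcodes (channel-B bits offset along
#' z by the chromatic aberration, each round translated by its drift,
#' per-round photobleaching decay applied to the signal), a flat cellular
#' background (optionally plus a wide out-of-focus blob), and
#' Poisson + read noise applied last. Bead images are rendered per round
#' with the same drift and noise model.
#'
#' @param truth a [plant_truth()] result.
#' @param cb the codebook used to plant the truth.
#' @param optics an [optics_config()].
#' @param background_level mean cellular background, photons.
#' @param noise list(poisson_on =, read_sigma =).
#' @param seed integer seed for the noise draw.
#' @param bleach_per_round multiplicative signal decay per round.
#' @param bg_blob_amp,bg_blob_sigma_px optional wide Gaussian background
#'   blob (out-of-focus haze stand-in) amplitude / sigma.
#' @param z_gel_shift_per_round_px optional linear-in-z lateral shift per
#'   round (depth-dependent gel displacement failure mode), pixels at the
#'   deepest plane.
#' @param bead_brightness peak bead amplitude, photons.
#' @return a `bitstacks` object (stacks, bead images, metadata).
#' @export
render_stacks <- function(truth, cb, optics,
                          background_level = 1,
                          noise = list(poisson_on = TRUE, read_sigma = 1),
                          seed = 1,
                          bleach_per_round = 1.0,
                          bg_blob_amp = 0, bg_blob_sigma_px = 40,
                          z_gel_shift_per_round_px = 0,
                          bead_brightness = 300) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cb, "merfish_codebook"))
  d <- truth$volume_px
  n_bits <- cb$n_bits
  n_rounds <- max(optics$round_of_bit)
  stopifnot(nrow(truth$drift_per_round) == n_rounds)
  W <- cb$barcode_matrix
  bg_blob <- NULL
  if (bg_blob_amp > 0) {
    cx <- d[1] / 2; cy <- d[2] / 2
    gx <- exp(-((seq_len(d[1]) - 0.5) - cx)^2 / (2 * bg_blob_sigma_px^2))
    gy <- exp(-((seq_len(d[2]) - 0.5) - cy)^2 / (2 * bg_blob_sigma_px^2))
    bg_blob <- bg_blob_amp * outer(gx, gy)
  }
  stacks <- vector("list", n_bits)
  for (b in seq_len(n_bits)) {
    ch <- optics$channel_of_bit[b]
    rnd <- optics$round_of_bit[b]
    dr <- truth$drift_per_round[rnd, ]
    sx <- optics$psf_sigma_xy_px[[ch]]
    sz <- optics$psf_sigma_z_planes[[ch]]
    zoff <- if (ch == "B") optics$chromatic_z_offset_planes else 0
    decay <- bleach_per_round^(rnd - 1)
    st <- array(0, d)
    on <- which(W[, b] == 1)
    sel <- truth$molecules$entry %in% on
    if (any(sel)) {
      m <- truth$molecules[sel, ]
      for (i in seq_len(nrow(m))) {
        gel <- z_gel_shift_per_round_px * (rnd - 1) * m$z_px[i] / d[3]
        st <- add_spot(st,
                       m$x_px[i] + dr$dx_px + gel,
                       m$y_px[i] + dr$dy_px,
                       m$z_px[i] + zoff,
                       m$brightness[i] * decay, sx, sx, sz)
      }
    }
    if (!is.null(bg_blob)) {
      st <- st + as.vector(bg_blob)
    }
    stacks[[b]] <- with_seed(stage_seed(seed, paste0("noise_bit", b)),
                             apply_noise(st, noise$poisson_on, noise$read_sigma,
                                         background_level))
  }
  beads <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    dr <- truth$drift_per_round[r, ]
    im <- matrix(0, d[1], d[2])
    for (i in seq_len(nrow(truth$beads))) {
      im <- add_spot2d(im, truth$beads$x_px[i] + dr$dx_px,
                       truth$beads$y_px[i] + dr$dy_px,
                       bead_brightness, optics$psf_sigma_xy_px[["A"]])
    }
    beads[[r]] <- with_seed(stage_seed(seed, paste0("noise_beads", r)),
                            apply_noise(im, noise$poisson_on, noise$read_sigma,
                                        background_level))
  }
  bs <- list(
    stacks = list(`1` = stacks),
    beads = list(`1` = beads),
    optics = optics,
    median_scale = rep(NA_real_, n_bits),
    valid = NULL,
    fov_layout = truth$fov_layout
  )
  class(bs) <- "bitstacks"
  bs
}

#' Render bead z-stacks in both color channels
#'
#' Calibration acquisition for the axial chromatic offset: the same bead
#' field imaged as a z-stack in channels A and B, with channel B offset
#' along z by the optics' chromatic term.
#'
#' @param beads data.frame with x_px, y_px.
#' @param optics an [optics_config()].
#' @param volume_px c(nx, ny, nz).
#' @param z_bead_planes bead axial position (continuous plane coords);
#'   default mid-stack.
#' @param background_level,noise,seed,bead_brightness as in
#'   [render_stacks()].
#' @return list(A = zstack, B = zstack).
#' @export
render_bead_zstacks <- function(beads, optics, volume_px,
                                z_bead_planes = volume_px[3] / 2,
                                background_level = 1,
                                noise = list(poisson_on = TRUE, read_sigma = 1),
                                seed = 1, bead_brightness = 300) {
  out <- list()
  for (ch in c("A", "B")) {
    zoff <- if (ch == "B") optics$chromatic_z_offset_planes else 0
    st <- array(0, volume_px)
    for (i in seq_len(nrow(beads))) {
      st <- add_spot(st, beads$x_px[i], beads$y_px[i], z_bead_planes + zoff,
                     bead_brightness,
                     optics$psf_sigma_xy_px[[ch]], optics$psf_sigma_xy_px[[ch]],
                     optics$psf_sigma_z_planes[[ch]])
    }
    out[[ch]] <- with_seed(stage_seed(seed, paste0("noise_beadz", ch)),
                           apply_noise(st, noise$poisson_on, noise$read_sigma,
                                       background_level))
  }
  out
}

#' Render a toy 3D cell segmentation
#'
#' Places non-overlapping ellipsoidal cells in the volume and returns the
#' integer label volume, per-cell voxel volumes and per-z boundary polygons
#' (convex hulls of the voxel centres of each label in each plane).
#'
#' @param volume_px c(nx, ny, nz).
#' @param n_cells number of cells to place.
#' @param radius_range_um cell radius range, micrometers.
#' @param optics an [optics_config()] (voxel geometry).
#' @param seed integer seed.
#' @param max_tries placement attempts per cell before failing.
#' @return list(labels = 3D integer array, volumes_um3, centers_px,
#'   polygons).
#' @export
render_cells <- function(volume_px, n_cells, radius_range_um = c(3, 5),
                         optics = optics_config(2), seed = 1, max_tries = 200) {
  stopifnot(n_cells >= 0)
  labels <- array(0L, volume_px)
  if (n_cells == 0) {
    return(list(labels = labels, volumes_um3 = numeric(0),
                centers_px = matrix(numeric(0), 0, 3), polygons = list()))
  }
  px <- optics$pixel_size_um
  zs <- optics$z_step_um
  centers <- matrix(0, n_cells, 3)
  radii <- matrix(0, n_cells, 3)  # rx_px, ry_px, rz_planes
  with_seed(stage_seed(seed, "render_cells"), {
    placed <- 0
    tries <- 0
    while (placed < n_cells) {
      tries <- tries + 1
      if (tries > max_tries * n_cells) {
        stop(sprintf("could not place %d non-overlapping cells (placed %d)",
                     n_cells, placed))
      }
      r_um <- stats::runif(1, radius_range_um[1], radius_range_um[2])
      rx <- r_um / px
      rz <- r_um / zs
      cx <- stats::runif(1, rx + 1, volume_px[1] - rx - 1)
      cy <- stats::runif(1, rx + 1, volume_px[2] - rx - 1)
      cz <- stats::runif(1, max(1, rz * 0.3), volume_px[3] - max(1, rz * 0.3))
      ok <- TRUE
      if (placed > 0) {
        for (j in seq_len(placed)) {
          sep <- sqrt(sum((c(cx, cy) - centers[j, 1:2])^2)) * px
          sepz <- abs(cz - centers[j, 3]) * zs
          if (sep < (r_um + radii[j, 1] * px) &&
              sepz < (r_um + radii[j, 3] * zs)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      placed <- placed + 1
      centers[placed, ] <- c(cx, cy, cz)
      radii[placed, ] <- c(rx, rx, rz)
    }
  })
  xg <- seq_len(volume_px[1]) - 0.5
  yg <- seq_len(volume_px[2]) - 0.5
  for (i in seq_len(n_cells)) {
    for (k in seq_len(volume_px[3])) {
      zc <- k - 0.5
      u <- 1 - ((zc - centers[i, 3]) / radii[i, 3])^2
      if (u <= 0) next
      rr2 <- u * radii[i, 1]^2
      dx2 <- (xg - centers[i, 1])^2
      dy2 <- (yg - centers[i, 2])^2
      inside <- outer(dx2, dy2, "+") <= rr2
      plane <- labels[, , k]
      inside <- inside & plane == 0L
      plane[inside] <- i
      labels[, , k] <- plane
    }
  }
  voxel_um3 <- px^2 * zs
  counts <- tabulate(labels[labels > 0], nbins = n_cells)
  polygons <- lapply(seq_len(n_cells), function(i) {
    out <- list()
    for (k in seq_len(volume_px[3])) {
      w <- which(labels[, , k] == i, arr.ind = TRUE)
      if (nrow(w) < 3) next
      pts <- cbind(w[, 1] - 0.5, w[, 2] - 0.5)
      h <- grDevices::chull(pts)
      out[[as.character(k - 1)]] <- pts[h, , drop = FALSE]
    }
    out
  })
  list(labels = labels, volumes_um3 = counts * voxel_um3,
       centers_px = centers, polygons = polygons)
}

#' Simulate a cortex-like cell-type point pattern
#'
#' Scatters cells of several subclasses uniformly in a 3D box and plants,
#' for selected subclasses, tightly juxtaposed same-type pairs at a short
#' distance, emulating the spatial signature of interneuron pairing. Used
#' to exercise the nearest-neighbor statistics.
#'
#' @param n_cells number of background cells.
#' @param box_um c(x, y, z) box size, micrometers.
#' @param subclasses character vector of subclass names.
#' @param probs subclass sampling probabilities.
#' @param paired_subclasses subclasses that receive planted pairs.
#' @param n_pairs planted pairs per paired subclass.
#' @param pair_distance_um separation of planted pairs.
#' @param seed integer seed.
#' @return data.frame(id, x, y, z, subclass).
#' @export
simulate_cell_map <- function(n_cells = 600, box_um = c(300, 300, 100),
                              subclasses = c("Pvalb", "Sst", "Vip", "Lamp5", "Exc"),
                              probs = c(0.08, 0.08, 0.05, 0.04, 0.75),
                              paired_subclasses = c("Pvalb", "Sst"),
                              n_pairs = 25, pair_distance_um = 7,
                              seed = 1) {
  with_seed(stage_seed(seed, "cell_map"), {
    lab <- sample(subclasses, n_cells, replace = TRUE, prob = probs)
    pos <- cbind(stats::runif(n_cells, 0, box_um[1]),
                 stats::runif(n_cells, 0, box_um[2]),
                 stats::runif(n_cells, 0, box_um[3]))
    for (s in paired_subclasses) {
      anchor <- cbind(stats::runif(n_pairs, 10, box_um[1] - 10),
                      stats::runif(n_pairs, 10, box_um[2] - 10),
                      stats::runif(n_pairs, 10, box_um[3] - 10))
      dirs <- matrix(stats::rnorm(n_pairs * 3), n_pairs, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      partner <- anchor + dirs * pair_distance_um
      pos <- rbind(pos, anchor, partner)
      lab <- c(lab, rep(s, 2 * n_pairs))
    }
    data.frame(id = seq_len(nrow(pos)), x = pos[, 1], y = pos[, 2],
               z = pos[, 3], subclass = lab, stringsAsFactors = FALSE)
  })
}
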