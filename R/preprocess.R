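# Preprocessing of per-bit z-stacks ahead of pixel decoding: fiducial-bead
# drift registration, axial chromatic alignment, per-bit median intensity
# normalization, high-pass background removal, Lucy-Richardson
# deconvolution and a final low-pass.
#
# Order of operations in preprocess_stacks(): registration (drift +
# chromatic) -> per-bit median normalization -> high-pass -> RL -> low-pass.
# Normalization must see the unfiltered background: the pooled median of a
# high-passed, zero-clipped image is ~0 and would make the scale undefined.

stack_dims <- function(bs) dim(bs$stacks[[1]][[1]])

n_bits_of <- function(bs) length(bs$stacks[[1]])

#' Normalize each bit by its median intensity pooled over all FOVs
#'
#' Divides every stack of a bit by the median intensity of that bit pooled
#' across all FOVs (restricted to registration-valid voxels when a validity
#' mask is present), removing intensity variation between hybridization
#' rounds and color channels. The applied scale accumulates in
#' `median_scale`; after normalization the pooled median of every bit is 1,
#' so the operation is idempotent.
#'
#' @param bs a `bitstacks` object.
#' @return the normalized `bitstacks`.
#' @export
normalize_bit_medians <- function(bs) {
  stopifnot(inherits(bs, "bitstacks"))
  nb <- n_bits_of(bs)
  for (b in seq_len(nb)) {
    vals <- unlist(lapply(names(bs$stacks), function(f) {
      st <- bs$stacks[[f]][[b]]
      if (!is.null(bs$valid) && !is.null(bs$valid[[f]])) st[bs$valid[[f]]] else as.vector(st)
    }), use.names = FALSE)
    med <- stats::median(vals)
    if (!is.finite(med) || med <= 0) {
      stop(sprintf("bit %d has non-positive pooled median intensity (%g); cannot normalize",
                   b, med))
    }
    for (f in names(bs$stacks)) {
      bs$stacks[[f]][[b]] <- bs$stacks[[f]][[b]] / med
    }
    bs$median_scale[b] <- if (is.na(bs$median_scale[b])) med else bs$median_scale[b] * med
  }
  bs
}

#' High-pass filter (background removal)
#'
#' Subtracts a Gaussian blur of the image from the image and clips at zero,
#' removing smooth cellular background while preserving spot-scale
#' structure. 3D inputs are filtered plane by plane.
#'
#' @param image 2D matrix or 3D array.
#' @param sigma_px blur sigma in pixels.
#' @return filtered image, same shape.
#' @export
high_pass <- function(image, sigma_px = 3) {
  stopifnot(sigma_px > 0)
  if (length(dim(image)) == 3) {
    for (k in seq_len(dim(image)[3])) {
      image[, , k] <- high_pass(image[, , k], sigma_px)
    }
    return(image)
  }
  pmax(image - gaussian_blur2d(image, sigma_px), 0)
}

#' Low-pass filter
#'
#' Gaussian blur used after deconvolution to absorb small movements in the
#' apparent centroid of RNA spots between imaging rounds. 3D inputs are
#' filtered plane by plane.
#'
#' @param image 2D matrix or 3D array.
#' @param sigma_px blur sigma in pixels.
#' @return blurred image, same shape.
#' @export
low_pass <- function(image, sigma_px = 1) {
  stopifnot(sigma_px > 0)
  if (length(dim(image)) == 3) {
    for (k in seq_len(dim(image)[3])) {
      image[, , k] <- low_pass(image[, , k], sigma_px)
    }
    return(image)
  }
  gaussian_blur2d(image, sigma_px)
}

#' Lucy-Richardson deconvolution
#'
#' Standard multiplicative-update Richardson-Lucy iteration to tighten RNA
#' spots, with replicate image boundaries. The PSF must be a nonnegative
#' odd-sized kernel summing to 1; the estimate stays nonnegative and flux
#' is approximately conserved for interior spots.
#'
#' @param image nonnegative 2D matrix.
#' @param psf nonnegative kernel summing to 1 (odd dimensions).
#' @param n_iter number of iterations (0 returns the input).
#' @return deconvolved image.
#' @export
lucy_richardson <- function(image, psf, n_iter = 20) {
  if (any(psf < 0)) stop("psf must be nonnegative")
  if (abs(sum(psf) - 1) > 1e-6) stop("psf must sum to 1")
  if (nrow(psf) %% 2 == 0 || ncol(psf) %% 2 == 0) stop("psf must have odd dimensions")
  if (n_iter == 0) return(image)
  eps <- 1e-12
  psf_flip <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))), drop = FALSE]
  est <- pmax(image, 0)
  for (i in seq_len(n_iter)) {
    denom <- conv2_psf(est, psf)
    ratio <- image / pmax(denom, eps)
    ratio[denom <= eps & image <= eps] <- 0
    est <- est * conv2_psf(ratio, psf_flip)
  }
  est
}

#' Gaussian PSF kernel for deconvolution
#'
#' @param sigma_px Gaussian sigma in pixels.
#' @param radius kernel half-width.
#' @return normalized 2D kernel matrix.
#' @export
gaussian_psf <- function(sigma_px, radius = ceiling(3 * sigma_px)) {
  k <- gaussian_kernel(sigma_px, radius)
  K <- outer(k, k)
  K / sum(K)
}

#' Estimate x-y stage drift between two fiducial bead images
#'
#' Phase correlation with matrix-DFT subpixel refinement: returns the
#' translation (dx, dy) such that `bead_round` matches `bead_ref` shifted
#' by (+dx, +dy). Ties between equal correlation peaks break towards the
#' smallest shift magnitude. A weak correlation peak sets a low-confidence
#' flag rather than raising an error.
#'
#' @param bead_ref reference-round bead image (matrix).
#' @param bead_round bead image of the round to align.
#' @param upsample subpixel refinement factor.
#' @param min_peak normalized correlation peak below which the estimate is
#'   flagged low-confidence.
#' @return list(dx_px, dy_px, peak, low_confidence).
#' @export
estimate_drift <- function(bead_ref, bead_round, upsample = 20, min_peak = 0.03) {
  stopifnot(all(dim(bead_ref) == dim(bead_round)))
  nr <- nrow(bead_ref)
  nc <- ncol(bead_ref)
  F1 <- stats::fft(bead_ref - mean(bead_ref))
  F2 <- stats::fft(bead_round - mean(bead_round))
  Qraw <- F2 * Conj(F1)
  Q <- Qraw / pmax(Mod(Qraw), 1e-12)
  r <- Re(stats::fft(Q, inverse = TRUE)) / (nr * nc)
  pk <- which(r == max(r), arr.ind = TRUE)
  # wrap to signed shifts, tie-break on smallest magnitude
  cand <- cbind(ifelse(pk[, 1] - 1 > nr / 2, pk[, 1] - 1 - nr, pk[, 1] - 1),
                ifelse(pk[, 2] - 1 > nc / 2, pk[, 2] - 1 - nc, pk[, 2] - 1))
  best <- which.min(rowSums(cand^2))
  d0 <- cand[best, ]
  peak_norm <- max(r)
  # refined evaluation on an upsampled local grid; the unwhitened
  # cross-spectrum is used here (matched-filter refinement is more
  # accurate than whitened phase correlation under noise)
  k1 <- ((0:(nr - 1) + floor(nr / 2)) %% nr) - floor(nr / 2)
  k2 <- ((0:(nc - 1) + floor(nc / 2)) %% nc) - floor(nc / 2)
  u <- d0[1] + seq(-1, 1, by = 1 / upsample)
  v <- d0[2] + seq(-1, 1, by = 1 / upsample)
  W1 <- exp(2i * pi * outer(u, k1) / nr)
  W2 <- exp(2i * pi * outer(v, k2) / nc)
  CC <- Re(W1 %*% Qraw %*% t(W2))
  mx <- max(CC)
  hits <- which(CC > mx * (1 - 1e-12), arr.ind = TRUE)
  sh <- cbind(u[hits[, 1]], v[hits[, 2]])
  bi <- which.min(rowSums(sh^2))
  list(dx_px = sh[bi, 1], dy_px = sh[bi, 2], peak = peak_norm,
       low_confidence = peak_norm < min_peak)
}

#' Estimate per-round drift for every FOV of a stack set
#'
#' Round 1 is the zero-drift reference.
#' @param bs a `bitstacks` object with bead images.
#' @return data.frame(fov, round, dx_px, dy_px, peak, low_confidence).
#' @export
estimate_drift_all <- function(bs) {
  out <- list()
  for (f in names(bs$beads)) {
    ref <- bs$beads[[f]][[1]]
    for (r in seq_along(bs$beads[[f]])) {
      if (r == 1) {
        est <- list(dx_px = 0, dy_px = 0, peak = 1, low_confidence = FALSE)
      } else {
        est <- estimate_drift(ref, bs$beads[[f]][[r]])
      }
      out[[length(out) + 1]] <- data.frame(
        fov = as.integer(f), round = r, dx_px = est$dx_px, dy_px = est$dy_px,
        peak = est$peak, low_confidence = est$low_confidence)
    }
  }
  do.call(rbind, out)
}

#' Calibrate the axial chromatic offset between the two color channels
#'
#' Detects beads in the channel-A stack, computes a background-subtracted
#' intensity-weighted axial centroid per bead in both channels, and returns
#' the mean z offset (channel B minus channel A).
#'
#' @param beads_chanA,beads_chanB bead z-stacks of the same field.
#' @param min_beads minimum matched beads required.
#' @param window lateral half-width of the per-bead integration window.
#' @return list(z_offset_planes, n_beads, per_bead) of class
#'   `chromatic_calibration`.
#' @export
calibrate_chromatic_z <- function(beads_chanA, beads_chanB, min_beads = 3,
                                  window = 2) {
  stopifnot(all(dim(beads_chanA) == dim(beads_chanB)))
  d <- dim(beads_chanA)
  mp <- apply(beads_chanA, c(1, 2), max)
  thr <- stats::median(mp) + 6 * stats::mad(mp)
  if (!is.finite(thr) || thr <= stats::median(mp)) thr <- stats::median(mp) + 0.25 * (max(mp) - stats::median(mp))
  # local maxima above threshold, greedy minimum separation
  is_max <- mp >= thr
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    is_max <- is_max & mp >= shift_int(mp, s[1], s[2], -Inf)
  }
  pk <- which(is_max, arr.ind = TRUE)
  if (nrow(pk) > 0) {
    pk <- pk[order(-mp[pk]), , drop = FALSE]
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))) {
      if (!keep[i]) next
      if (i < nrow(pk)) {
        later <- (i + 1):nrow(pk)
        too_close <- (pk[later, 1] - pk[i, 1])^2 + (pk[later, 2] - pk[i, 2])^2 < 25
        keep[later][too_close] <- FALSE
      }
    }
    pk <- pk[keep, , drop = FALSE]
    if (nrow(pk) > 50) pk <- pk[1:50, , drop = FALSE]
  }
  centroid_z <- function(st, x, y) {
    ix <- max(1, x - window):min(d[1], x + window)
    iy <- max(1, y - window):min(d[2], y + window)
    prof <- apply(st[ix, iy, , drop = FALSE], 3, sum)
    w <- pmax(prof - min(prof), 0)
    if (sum(w) <= 0) return(NA_real_)
    sum(seq_along(w) * w) / sum(w)
  }
  offs <- numeric(0)
  per_bead <- list()
  for (i in seq_len(nrow(pk))) {
    za <- centroid_z(beads_chanA, pk[i, 1], pk[i, 2])
    zb <- centroid_z(beads_chanB, pk[i, 1], pk[i, 2])
    if (is.finite(za) && is.finite(zb)) {
      offs <- c(offs, zb - za)
      per_bead[[length(per_bead) + 1]] <- data.frame(
        x_px = pk[i, 1], y_px = pk[i, 2], z_A = za, z_B = zb)
    }
  }
  if (length(offs) < min_beads) {
    stop(sprintf("chromatic calibration needs >= %d matched beads, found %d",
                 min_beads, length(offs)))
  }
  out <- list(z_offset_planes = mean(offs), n_beads = length(offs),
              per_bead = do.call(rbind, per_bead))
  class(out) <- "chromatic_calibration"
  out
}

#' Apply drift and chromatic registration to all stacks
#'
#' Each stack is translated laterally by the inverse of its round's drift
#' (bilinear interpolation) and, for channel-B bits, shifted along z by the
#' inverse chromatic offset (linear interpolation). Out-of-range voxels are
#' zero-filled and recorded in a per-FOV validity mask which the decoder
#' honours.
#'
#' @param bs a `bitstacks` object.
#' @param drift data.frame(fov, round, dx_px, dy_px) as from
#'   [estimate_drift_all()].
#' @param chroma optional `chromatic_calibration`.
#' @return registered `bitstacks` with `$valid` masks.
#' @export
apply_registration <- function(bs, drift, chroma = NULL) {
  stopifnot(inherits(bs, "bitstacks"))
  d <- stack_dims(bs)
  zoff <- if (is.null(chroma)) 0 else chroma$z_offset_planes
  bs$valid <- list()
  for (f in names(bs$stacks)) {
    fnum <- as.integer(f)
    valid <- array(TRUE, d)
    for (b in seq_len(n_bits_of(bs))) {
      rnd <- bs$optics$round_of_bit[b]
      row <- drift[drift$fov == fnum & drift$round == rnd, ]
      if (nrow(row) != 1) {
        stop(sprintf("missing drift estimate for fov %s round %d", f, rnd))
      }
      st <- bs$stacks[[f]][[b]]
      if (abs(row$dx_px) > 1e-12 || abs(row$dy_px) > 1e-12) {
        for (k in seq_len(d[3])) {
          st[, , k] <- translate_xy(st[, , k], -row$dx_px, -row$dy_px)
        }
        vm <- translate_valid(d[1], d[2], -row$dx_px, -row$dy_px)
        valid <- valid & as.vector(vm)
      }
      if (bs$optics$channel_of_bit[b] == "B" && abs(zoff) > 1e-12) {
        st <- shift_z(st, -zoff)
        vz <- shift_z_valid(d[3], -zoff)
        valid <- valid & rep(vz, each = d[1] * d[2])
      }
      bs$stacks[[f]][[b]] <- st
    }
    bs$valid[[f]] <- valid
  }
  bs$drift <- drift
  bs$chromatic <- chroma
  bs
}

#' Run the full preprocessing chain
#'
#' Drift estimation from bead images (unless provided), registration
#' (drift + optional chromatic), per-bit median normalization, then per
#' plane: high-pass, Lucy-Richardson deconvolution (20 iterations by
#' default) and low-pass. Deterministic for fixed inputs.
#'
#' @param bs a `bitstacks` object from the simulator or from disk.
#' @param drift optional precomputed drift table; estimated from the bead
#'   images when NULL.
#' @param chroma optional `chromatic_calibration`.
#' @param high_pass_sigma,low_pass_sigma filter scales, pixels.
#' @param rl_iter Lucy-Richardson iterations.
#' @param rl_psf optional PSF kernel; defaults to the per-channel Gaussian
#'   PSF of the optics.
#' @return preprocessed `bitstacks`.
#' @export
preprocess_stacks <- function(bs, drift = NULL, chroma = NULL,
                              high_pass_sigma = 3, low_pass_sigma = 1,
                              rl_iter = 20, rl_psf = NULL) {
  if (is.null(drift)) drift <- estimate_drift_all(bs)
  bs <- apply_registration(bs, drift, chroma)
  bs <- normalize_bit_medians(bs)
  d <- stack_dims(bs)
  for (f in names(bs$stacks)) {
    for (b in seq_len(n_bits_of(bs))) {
      ch <- bs$optics$channel_of_bit[b]
      psf <- if (is.null(rl_psf)) gaussian_psf(bs$optics$psf_sigma_xy_px[[ch]]) else rl_psf
      st <- bs$stacks[[f]][[b]]
      for (k in seq_len(d[3])) {
        pl <- high_pass(st[, , k], high_pass_sigma)
        if (rl_iter > 0) pl <- lucy_richardson(pl, psf, rl_iter)
        st[, , k] <- low_pass(pl, low_pass_sigma)
      }
      bs$stacks[[f]][[b]] <- st
    }
  }
  bs$preprocessed <- TRUE
  bs
}
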