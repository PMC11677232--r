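# Intensity normalization, spatial filters, Lucy-Richardson deconvolution
# and registration (drift + chromatic).

make_bs <- function(stacks_per_bit, n_bits = length(stacks_per_bit),
                    optics = optics_config(n_bits)) {
  bs <- list(stacks = list(`1` = stacks_per_bit),
             beads = list(`1` = list(matrix(1, dim(stacks_per_bit[[1]])[1],
                                            dim(stacks_per_bit[[1]])[2]))),
             optics = optics, median_scale = rep(NA_real_, n_bits),
             valid = NULL,
             fov_layout = data.frame(fov = 1L, origin_x_um = 0, origin_y_um = 0))
  class(bs) <- "bitstacks"
  bs
}

test_that("median normalization rescales each bit to pooled median 1", {
  st1 <- array(4, c(8, 8, 2))
  set.seed(1)
  st2 <- array(stats::rexp(128, 1 / 10), c(8, 8, 2))
  bs <- make_bs(list(st1, st2), optics = optics_config(2))
  out <- normalize_bit_medians(bs)
  expect_true(all(out$stacks[[1]][[1]] == 1))
  expect_equal(out$median_scale[1], 4)
  expect_equal(median(as.vector(out$stacks[[1]][[2]])), 1)
  # scale invariance: a bit twice as bright normalizes to the same stacks
  bs2 <- make_bs(list(2 * st1, st2), optics = optics_config(2))
  out2 <- normalize_bit_medians(bs2)
  expect_equal(out2$stacks[[1]][[1]], out$stacks[[1]][[1]])
  # idempotence
  out3 <- normalize_bit_medians(out)
  expect_equal(out3$stacks[[1]][[2]], out$stacks[[1]][[2]])
  expect_equal(out3$median_scale, out$median_scale)
})

test_that("zero-median bits are rejected by name", {
  bs <- make_bs(list(array(0, c(4, 4, 1)), array(1, c(4, 4, 1))),
                optics = optics_config(2))
  expect_error(normalize_bit_medians(bs), "bit 1")
})

test_that("high-pass removes constant background and keeps spikes", {
  expect_lt(max(high_pass(matrix(7, 16, 16), 3)), 1e-12)
  im <- matrix(10, 31, 31)
  im[16, 16] <- im[16, 16] + 100
  hp <- high_pass(im, 3)
  # spike preserved up to the blur's own leakage at the centre pixel (< 5%)
  expect_gt(hp[16, 16], 95)
  expect_lt(hp[16, 16], 100)
  expect_lt(max(hp[-16, ]), 1)
  # very large sigma approaches mean subtraction
  hp_inf <- high_pass(im, 1e4)
  expect_equal(hp_inf, pmax(im - mean(im), 0), tolerance = 1e-3)
})

test_that("low-pass preserves flux and vanishes for tiny sigma", {
  im <- matrix(0, 21, 21)
  im[11, 11] <- 5
  lp <- low_pass(im, 1.5)
  expect_equal(sum(lp), 5, tolerance = 1e-9)
  expect_lt(max(lp), 5)
  expect_lt(max(abs(low_pass(im, 0.2) - im)), 1e-3 * max(im))
  # jittered twin spots correlate better after blurring
  a <- merfish3d:::add_spot2d(matrix(0, 32, 32), 16, 16, 10, 1.2)
  b <- merfish3d:::add_spot2d(matrix(0, 32, 32), 17, 16, 10, 1.2)
  expect_gt(cor(as.vector(low_pass(a, 1)), as.vector(low_pass(b, 1))),
            cor(as.vector(a), as.vector(b)))
})

test_that("Lucy-Richardson fixes points, sharpens blurred spots, keeps flux", {
  idk <- matrix(0, 3, 3); idk[2, 2] <- 1
  im <- merfish3d:::add_spot2d(matrix(0, 33, 33), 17, 17, 8, 2)
  expect_equal(lucy_richardson(im, idk, 7), im, tolerance = 1e-10)
  expect_identical(lucy_richardson(im, gaussian_psf(1.3), 0), im)
  dec <- lucy_richardson(im, gaussian_psf(1.3), 20)
  expect_gt(max(dec), max(im))
  fwhm <- function(x) sum(x >= max(x) / 2)
  expect_lt(fwhm(dec), fwhm(im))
  expect_equal(sum(dec), sum(im), tolerance = 0.01)
  expect_true(all(dec >= 0))
  expect_error(lucy_richardson(im, matrix(1, 3, 3), 5), "sum to 1")
  expect_error(lucy_richardson(im, -idk, 5), "nonnegative")
})

drifted_bead_field <- function(dx, dy, seed = 2, noise = TRUE) {
  set.seed(seed)
  xs <- runif(20, 6, 58); ys <- runif(20, 6, 58)
  render <- function(ddx, ddy) {
    im <- matrix(0, 64, 64)
    for (i in seq_along(xs)) {
      im <- merfish3d:::add_spot2d(im, xs[i] + ddx, ys[i] + ddy, 200, 1.3)
    }
    if (noise) im <- im + matrix(stats::rnorm(64 * 64, 2, 1.2), 64, 64)
    im
  }
  list(ref = render(0, 0), moved = render(dx, dy))
}

test_that("drift estimation recovers planted integer and subpixel shifts", {
  f <- drifted_bead_field(0, 0)
  e0 <- estimate_drift(f$ref, f$ref)
  expect_equal(c(e0$dx_px, e0$dy_px), c(0, 0))
  f1 <- drifted_bead_field(3, -2, noise = FALSE)
  e1 <- estimate_drift(f1$ref, f1$moved)
  expect_equal(c(e1$dx_px, e1$dy_px), c(3, -2))
  f2 <- drifted_bead_field(1.4, -0.6)
  e2 <- estimate_drift(f2$ref, f2$moved)
  expect_lt(max(abs(c(e2$dx_px - 1.4, e2$dy_px + 0.6))), 0.2)
  # planted shift via image interpolation rather than re-rendering
  sh <- merfish3d:::translate_xy(f$ref, 1.4, -0.6)
  e3 <- estimate_drift(f$ref, sh)
  expect_lt(max(abs(c(e3$dx_px - 1.4, e3$dy_px + 0.6))), 0.2)
  expect_false(e2$low_confidence)
})

test_that("chromatic z calibration recovers planted plane offsets", {
  set.seed(3)
  beads <- data.frame(x_px = runif(9, 6, 42), y_px = runif(9, 6, 42))
  for (off in c(0, 2, 0.5)) {
    oc <- optics_config(4, chromatic_z_offset_planes = off)
    bz <- render_bead_zstacks(beads, oc, c(48, 48, 12), seed = 4)
    cal <- calibrate_chromatic_z(bz$A, bz$B)
    tol <- if (off == 2) 0.1 else 0.2
    expect_lt(abs(cal$z_offset_planes - off), tol + 1e-12)
  }
  expect_error(calibrate_chromatic_z(array(1, c(20, 20, 4)),
                                     array(1, c(20, 20, 4))),
               ">= 3 matched beads")
})

test_that("registration inverts planted drift and chromatic offsets", {
  cb <- codebook_from_table(c("g1", "g2"), c("1100", "0011"), c(FALSE, FALSE))
  oc <- optics_config(4, chromatic_z_offset_planes = 2)
  tr <- plant_truth(cb, 600, c(48, 48, 9), oc, n_beads = 15, drift_mag_px = 4,
                    seed = 6)
  bs <- render_stacks(tr, cb, oc, seed = 7)
  est <- estimate_drift_all(bs)
  expect_lt(max(abs(est$dx_px - tr$drift_per_round$dx_px[est$round])), 0.2)
  expect_lt(max(abs(est$dy_px - tr$drift_per_round$dy_px[est$round])), 0.2)
  cal <- list(z_offset_planes = 2)
  reg <- apply_registration(bs, est, cal)
  # residual drift after correcting the bead images with the estimates
  for (r in 2:nrow(est)) {
    fixed <- merfish3d:::translate_xy(bs$beads[[1]][[r]],
                                      -est$dx_px[r], -est$dy_px[r])
    res <- estimate_drift(bs$beads[[1]][[1]], fixed)
    expect_lt(sqrt(res$dx_px^2 + res$dy_px^2), 0.2)
  }
  # after z correction, per-molecule argmax z agrees across channels
  m <- tr$molecules[tr$molecules$entry == 2, ][1, ]  # g2: bits 3 (A) + 4 (B)
  win <- function(st) {
    ix <- max(1, round(m$x_px) - 1):min(48, round(m$x_px) + 1)
    iy <- max(1, round(m$y_px) - 1):min(48, round(m$y_px) + 1)
    which.max(apply(st[ix, iy, , drop = FALSE], 3, max))
  }
  if (m$z_px > 2.5 && m$z_px < 6.5) {
    expect_equal(win(reg$stacks[[1]][[4]]), win(reg$stacks[[1]][[3]]))
  }
  # zero drift and offset leave stacks untouched
  zero <- data.frame(fov = 1L, round = 1:2, dx_px = 0, dy_px = 0)
  bs0 <- render_stacks(plant_truth(cb, 300, c(24, 24, 4),
                                   optics_config(4), drift_mag_px = 0,
                                   seed = 1),
                       cb, optics_config(4), seed = 2)
  reg0 <- apply_registration(bs0, zero, NULL)
  expect_equal(reg0$stacks[[1]][[1]], bs0$stacks[[1]][[1]])
  expect_error(apply_registration(bs0, zero[1, ], NULL), "missing drift")
})

test_that("the preprocessing chain is deterministic", {
  cb <- codebook_from_table(c("g1", "g2"), c("1100", "0011"), c(FALSE, FALSE))
  oc <- optics_config(4)
  tr <- plant_truth(cb, 600, c(32, 32, 4), oc, seed = 8)
  bs <- render_stacks(tr, cb, oc, seed = 9)
  p1 <- preprocess_stacks(bs, rl_iter = 5)
  p2 <- preprocess_stacks(bs, rl_iter = 5)
  expect_identical(p1$stacks, p2$stacks)
  expect_identical(p1$drift, p2$drift)
})
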