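# Patch-pair construction, L1 training of the pluggable denoiser, and SNR
# measurement.

test_that("patch tiling arithmetic and the 80/20 split are exact", {
  im <- matrix(runif(256 * 256), 256, 256)
  pp128 <- make_patch_pairs(list(im), list(im), patch = 128, stride = 128,
                            seed = 1)
  expect_length(pp128$low, 4L)
  pp64 <- make_patch_pairs(list(im), list(im), patch = 128, stride = 64,
                           seed = 1)
  expect_length(pp64$low, 9L)
  # 10 pairs -> 8 train, 2 eval
  ims <- replicate(10, matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  pp <- make_patch_pairs(ims, ims, patch = 64, stride = 64, seed = 2)
  expect_length(pp$low, 10L)
  expect_equal(as.vector(table(pp$split)), c(8L, 2L))
  # identical low == high inputs give zero L1 everywhere
  expect_equal(merfish3d:::l1_loss(linear_conv_denoiser(3), pp$low, pp$high), 0)
  # shape mismatch is an alignment error
  expect_error(make_patch_pairs(list(im), list(im[1:100, ])), "mismatched")
  # reproducible under a fixed seed
  pp2 <- make_patch_pairs(ims, ims, patch = 64, stride = 64, seed = 2)
  expect_identical(pp$split, pp2$split)
  expect_identical(pp$source_id, pp2$source_id)
})

test_that("training reaches the identity and additive-bias optima", {
  set.seed(61)
  ims <- replicate(6, matrix(runif(48 * 48, 0, 1), 48, 48), simplify = FALSE)
  # identity case: starts at the optimum, stays there
  pp <- make_patch_pairs(ims, ims, patch = 24, stride = 24, seed = 3)
  tr <- train_denoiser(pp, denoiser_spec(batch_size = 4, steps_per_epoch = 5),
                       epochs = 2, seed = 1)
  expect_equal(tr$eval_l1, 0, tolerance = 1e-12)
  # additive constant bias: closed-form optimum is adding c
  c0 <- 0.27
  his <- lapply(ims, function(m) m + c0)
  ppb <- make_patch_pairs(ims, his, patch = 24, stride = 24, seed = 4)
  trb <- train_denoiser(ppb, denoiser_spec(batch_size = 4, steps_per_epoch = 5),
                        epochs = 4, seed = 1)
  expect_lt(trb$eval_l1, 0.01)
  expect_equal(trb$model$bias, c0, tolerance = 0.05)
  expect_error(train_denoiser(structure(list(low = list(), high = list(),
                                             split = factor(character(0),
                                                            c("train", "eval"))),
                                        class = "patch_pair_set")),
               "empty train split")
})

test_that("training loss is monotone and noise cannot beat the median bound", {
  set.seed(62)
  lows <- replicate(6, matrix(runif(32 * 32), 32, 32), simplify = FALSE)
  highs <- replicate(6, matrix(0.4 + 0.1 * runif(32 * 32), 32, 32),
                     simplify = FALSE)
  pp <- make_patch_pairs(lows, highs, patch = 16, stride = 16, seed = 5)
  tr <- train_denoiser(pp, denoiser_spec(batch_size = 6, steps_per_epoch = 8),
                       epochs = 5, seed = 2)
  expect_true(all(diff(tr$train_history) <= 1e-12))
  # per-patch median predictor is the L1-optimal per-patch constant
  ev <- which(pp$split == "eval")
  med_l1 <- mean(vapply(ev, function(i) {
    mean(abs(pp$high[[i]] - stats::median(pp$high[[i]])))
  }, numeric(1)))
  expect_gte(tr$eval_l1, med_l1 - 1e-9)
})

test_that("SNR measurement behaves on identical, smoothed and clean stacks", {
  cb <- tiny_codebook()
  oc <- optics_config(4)
  tr <- plant_truth(cb, 900, c(48, 48, 5), oc, drift_mag_px = 0, seed = 9,
                    brightness = 30)
  bs <- render_stacks(tr, cb, oc, background_level = 4,
                      noise = list(poisson_on = TRUE, read_sigma = 2),
                      seed = 10)
  spots <- tr$molecules[cb$barcode_matrix[tr$molecules$entry, 1] == 1, ]
  st <- bs$stacks[[1]][[1]]
  same <- snr_gain(st, st, spots)
  expect_equal(same$snr_raw, same$snr_enhanced)
  smoothed <- st
  for (k in 1:5) smoothed[, , k] <- merfish3d:::gaussian_blur2d(st[, , k], 1.2)
  sm <- snr_gain(st, smoothed, spots)
  expect_gt(sm$snr_enhanced, sm$snr_raw)
  clean <- render_stacks(tr, cb, oc, background_level = 4,
                         noise = list(poisson_on = FALSE, read_sigma = 0),
                         seed = 10)$stacks[[1]][[1]]
  expect_equal(snr_gain(clean, clean, spots)$snr_raw, Inf)
  big <- data.frame(x_px = 24, y_px = 24, z_px = c(0.5, 1.5, 2.5, 3.5, 4.5))
  expect_error(snr_gain(st, st, big, exclusion_radius_px = 100),
               "no signal-free")
})

# Noise-limited regime: dim spots (peak 6 photons) over a structured
# cellular-background blob with strong read noise, so decoding is limited
# by the distance gate and denoising has signal to recover. The linear
# model's affine offset rescales absolute intensities, so the comparison
# decodes both arms with the magnitude gate disabled and the distance gate
# doing the work (the gate threshold is a scale convention, not part of
# what enhancement should be judged on).
test_that("denoising low-SNR stacks does not hurt decoding recall", {
  cb <- synth_codebook(8, 3, 2, n_coding = 10, n_blank = 2, seed = 2)
  oc <- optics_config(8)
  recalls <- vapply(1:5, function(s) {
    tr <- plant_truth(cb, 350, c(64, 64, 5), oc, drift_mag_px = 0,
                      seed = 100 + s, brightness = 6)
    args <- list(truth = tr, cb = cb, optics = oc, background_level = 1,
                 bg_blob_amp = 6, bg_blob_sigma_px = 18)
    noisy <- do.call(render_stacks,
                     c(args, list(noise = list(poisson_on = TRUE,
                                               read_sigma = 3),
                                  seed = 200 + s)))
    clean <- do.call(render_stacks,
                     c(args, list(noise = list(poisson_on = FALSE,
                                               read_sigma = 0),
                                  seed = 200 + s)))
    run <- function(bs) {
      bs <- preprocess_stacks(bs, rl_iter = 10)
      mols <- drop_single_pixel(decode_stacks(bs, cb, min_intensity = 0))
      match_molecules(mols, tr$molecules)$recall
    }
    raw_recall <- run(noisy)
    den <- noisy
    for (ch in c("A", "B")) {
      bits <- which(oc$channel_of_bit == ch)
      pl <- function(bss) unlist(lapply(bits, function(b) {
        lapply(seq_len(5), function(k) bss$stacks[[1]][[b]][, , k])
      }), recursive = FALSE)
      pp <- make_patch_pairs(pl(noisy), pl(clean), patch = 32, stride = 32,
                             seed = s)
      trn <- train_denoiser(pp, denoiser_spec(batch_size = 10,
                                              steps_per_epoch = 12),
                            epochs = 4, seed = s)
      for (b in bits) {
        den$stacks[[1]][[b]] <- denoise_stack(trn$model,
                                              den$stacks[[1]][[b]])
      }
    }
    run(den) - raw_recall
  }, numeric(1))
  expect_gte(mean(recalls), 0)
})
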