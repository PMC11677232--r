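# Contract-level signal-to-noise enhancement: paired-patch dataset
# construction from co-registered low/high-SNR image pairs, an 80/20
# train/eval split, training of a pluggable denoiser under a mean absolute
# difference (L1) loss with the stated hyperparameters, and SNR
# evaluation. The reference model is a small linear convolution regressor;
# any regressor with the same predict interface can be plugged in. SNR
# enhancement is an optional pipeline stage, off by default: decoding must
# be correct without it.

#' Denoiser training hyperparameters
#'
#' @param kernel_size convolution kernel size (default 3).
#' @param batch_size patches per training step (default 10).
#' @param steps_per_epoch training steps per epoch (default 50).
#' @param loss only "l1" (mean absolute difference) is supported.
#' @param per_channel train one model per color channel.
#' @return a `denoiser_spec` list.
#' @export
denoiser_spec <- function(kernel_size = 3, batch_size = 10,
                          steps_per_epoch = 50, loss = "l1",
                          per_channel = TRUE) {
  stopifnot(kernel_size %% 2 == 1, loss == "l1")
  out <- list(kernel_size = kernel_size, batch_size = batch_size,
              steps_per_epoch = steps_per_epoch, loss = loss,
              per_channel = per_channel)
  class(out) <- "denoiser_spec"
  out
}

#' Build co-registered low/high-SNR patch pairs with an 80/20 split
#'
#' Randomly selects up to `n_source_pairs` image pairs (seeded), tiles
#' each into overlapping square patches at `stride`, and tags each patch
#' pair train/eval at 80/20 by a seeded shuffle.
#'
#' @param low_images,high_images aligned lists of matrices (same shapes
#'   pairwise).
#' @param n_source_pairs image pairs to draw (default 50).
#' @param patch patch side length (default 128).
#' @param stride tiling stride (default 64, 50% overlap).
#' @param seed integer seed.
#' @return a `patch_pair_set`: lists `low`, `high`, `source_id`, factor
#'   `split`.
#' @export
make_patch_pairs <- function(low_images, high_images, n_source_pairs = 50,
                             patch = 128, stride = 64, seed = 1) {
  stopifnot(length(low_images) == length(high_images))
  for (i in seq_along(low_images)) {
    if (!all(dim(low_images[[i]]) == dim(high_images[[i]]))) {
      stop(sprintf("low/high image pair %d have mismatched shapes", i))
    }
  }
  sel <- with_seed(stage_seed(seed, "patch_sources"), {
    if (length(low_images) > n_source_pairs) {
      sample(seq_along(low_images), n_source_pairs)
    } else seq_along(low_images)
  })
  low <- list(); high <- list(); src <- integer(0)
  for (i in sel) {
    d <- dim(low_images[[i]])
    if (any(d < patch)) next
    rs <- seq(1, d[1] - patch + 1, by = stride)
    cs <- seq(1, d[2] - patch + 1, by = stride)
    for (r in rs) for (cc in cs) {
      low[[length(low) + 1]] <- low_images[[i]][r:(r + patch - 1), cc:(cc + patch - 1)]
      high[[length(high) + 1]] <- high_images[[i]][r:(r + patch - 1), cc:(cc + patch - 1)]
      src <- c(src, i)
    }
  }
  n <- length(low)
  if (n == 0) stop("no patches could be extracted (images smaller than the patch size?)")
  split <- with_seed(stage_seed(seed, "patch_split"), {
    o <- sample.int(n)
    tags <- rep("eval", n)
    tags[o[seq_len(round(0.8 * n))]] <- "train"
    factor(tags, levels = c("train", "eval"))
  })
  out <- list(low = low, high = high, source_id = src, split = split)
  class(out) <- "patch_pair_set"
  out
}

#' Reference linear convolution denoiser
#'
#' A single linear convolution (kernel initialized to the identity) plus a
#' bias; convex under the L1 loss, which makes training behaviour exactly
#' checkable.
#' @param kernel_size odd kernel side length.
#' @return a `linear_conv_denoiser` model.
#' @export
linear_conv_denoiser <- function(kernel_size = 3) {
  stopifnot(kernel_size %% 2 == 1)
  K <- matrix(0, kernel_size, kernel_size)
  c0 <- (kernel_size + 1) / 2
  K[c0, c0] <- 1
  out <- list(kernel = K, bias = 0, kernel_size = kernel_size)
  class(out) <- "linear_conv_denoiser"
  out
}

# Clamped-index (replicate boundary) integer shift used for the model's
# convolution features.
shift_clamped <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Apply a denoiser model to an image
#'
#' @param model a `linear_conv_denoiser` (or any object with a
#'   `predict_denoiser` method).
#' @param image 2D matrix.
#' @return denoised matrix.
#' @export
predict_denoiser <- function(model, image) {
  UseMethod("predict_denoiser")
}

#' @export
predict_denoiser.linear_conv_denoiser <- function(model, image) {
  c0 <- (model$kernel_size + 1) / 2
  out <- matrix(model$bias, nrow(image), ncol(image))
  for (u in seq_len(model$kernel_size)) {
    for (v in seq_len(model$kernel_size)) {
      if (model$kernel[u, v] != 0) {
        out <- out + model$kernel[u, v] * shift_clamped(image, u - c0, v - c0)
      }
    }
  }
  out
}

l1_loss <- function(model, low, high, idx = seq_along(low)) {
  tot <- 0; npx <- 0
  for (i in idx) {
    tot <- tot + sum(abs(predict_denoiser(model, low[[i]]) - high[[i]]))
    npx <- npx + length(low[[i]])
  }
  tot / npx
}

#' Train a denoiser on the train split under the L1 loss
#'
#' Coordinate-wise training of the pluggable model: on each step a seeded
#' batch of train patches is drawn and every model coordinate (bias, then
#' kernel entries) takes its exact L1-optimal update (a weighted median
#' line search). At each epoch end the full train-split loss is evaluated
#' and the epoch is rolled back if it did not improve, so the recorded
#' epoch-loss history is non-increasing — exact for this convex model.
#'
#' @param pairs a `patch_pair_set`.
#' @param spec a [denoiser_spec()].
#' @param epochs training epochs.
#' @param model initial model (default the linear convolution regressor).
#' @param seed integer seed for batch sampling.
#' @return list(model, eval_l1, train_history).
#' @export
train_denoiser <- function(pairs, spec = denoiser_spec(), epochs = 10,
                           model = linear_conv_denoiser(spec$kernel_size),
                           seed = 1) {
  tr <- which(pairs$split == "train")
  ev <- which(pairs$split == "eval")
  if (length(tr) == 0) stop("empty train split")
  c0 <- (model$kernel_size + 1) / 2
  coords <- rbind(c(0, 0), as.matrix(expand.grid(seq_len(model$kernel_size),
                                                 seq_len(model$kernel_size))))
  history <- l1_loss(model, pairs$low, pairs$high, tr)
  for (ep in seq_len(epochs)) {
    saved <- model
    for (st in seq_len(spec$steps_per_epoch)) {
      batch <- with_seed(stage_seed(seed, sprintf("batch_%d_%d", ep, st)), {
        tr[sample.int(length(tr), min(spec$batch_size, length(tr)))]
      })
      lows <- pairs$low[batch]
      highs <- pairs$high[batch]
      preds <- lapply(lows, function(p) predict_denoiser(model, p))
      for (ci in seq_len(nrow(coords))) {
        is_bias <- ci == 1
        feats <- if (is_bias) {
          lapply(lows, function(p) matrix(1, nrow(p), ncol(p)))
        } else {
          u <- coords[ci, 1]; v <- coords[ci, 2]
          lapply(lows, function(p) shift_clamped(p, u - c0, v - c0))
        }
        r <- unlist(mapply(function(h, p) as.numeric(h - p), highs, preds,
                           SIMPLIFY = FALSE))
        a <- unlist(lapply(feats, as.numeric))
        nz <- abs(a) > 1e-12
        if (!any(nz)) next
        delta <- weighted_median(r[nz] / a[nz], abs(a[nz]))
        if (!is.finite(delta) || delta == 0) next
        if (is_bias) model$bias <- model$bias + delta
        else model$kernel[coords[ci, 1], coords[ci, 2]] <-
            model$kernel[coords[ci, 1], coords[ci, 2]] + delta
        preds <- mapply(function(p, f) p + delta * f, preds, feats,
                        SIMPLIFY = FALSE)
      }
    }
    loss <- l1_loss(model, pairs$low, pairs$high, tr)
    if (loss > history[length(history)] + 1e-12) {
      model <- saved
      loss <- history[length(history)]
    }
    history <- c(history, loss)
  }
  eval_l1 <- if (length(ev) > 0) l1_loss(model, pairs$low, pairs$high, ev) else NA_real_
  list(model = model, eval_l1 = eval_l1, train_history = history)
}

#' Denoise every plane of a z-stack
#'
#' @param model trained denoiser.
#' @param stack 3D array.
#' @return denoised stack.
#' @export
denoise_stack <- function(model, stack) {
  for (k in seq_len(dim(stack)[3])) {
    stack[, , k] <- predict_denoiser(model, stack[, , k])
  }
  stack
}

#' Peak signal-to-noise ratio before and after enhancement
#'
#' SNR = (mean peak signal over the planted spots - median background) /
#' robust standard deviation (MAD) of signal-free voxels; voxels within
#' `exclusion_radius_px` (and one z plane) of any spot are excluded from
#' the background. A zero-noise background reports an infinite SNR.
#'
#' @param raw_stack,enhanced_stack 3D arrays (pass the same array twice to
#'   measure one stack).
#' @param truth_spots data.frame(x_px, y_px, z_px) of planted spots.
#' @param exclusion_radius_px radius defining signal-free voxels.
#' @return list(snr_raw, snr_enhanced).
#' @export
snr_gain <- function(raw_stack, enhanced_stack, truth_spots,
                     exclusion_radius_px = 4) {
  stopifnot(nrow(truth_spots) > 0,
            all(dim(raw_stack) == dim(enhanced_stack)))
  d <- dim(raw_stack)
  free <- array(TRUE, d)
  r <- ceiling(exclusion_radius_px)
  for (i in seq_len(nrow(truth_spots))) {
    ix <- max(1, floor(truth_spots$x_px[i] - r)):min(d[1], ceiling(truth_spots$x_px[i] + r))
    iy <- max(1, floor(truth_spots$y_px[i] - r)):min(d[2], ceiling(truth_spots$y_px[i] + r))
    iz <- max(1, floor(truth_spots$z_px[i] + 0.5 - 1)):min(d[3], ceiling(truth_spots$z_px[i] + 0.5 + 1))
    free[ix, iy, iz] <- FALSE
  }
  if (!any(free)) stop("no signal-free voxels left for the noise estimate")
  one_snr <- function(st) {
    peaks <- vapply(seq_len(nrow(truth_spots)), function(i) {
      ix <- max(1, round(truth_spots$x_px[i]) - 1):min(d[1], round(truth_spots$x_px[i]) + 1)
      iy <- max(1, round(truth_spots$y_px[i]) - 1):min(d[2], round(truth_spots$y_px[i]) + 1)
      iz <- max(1, round(truth_spots$z_px[i] + 0.5) - 1):min(d[3], round(truth_spots$z_px[i] + 0.5) + 1)
      max(st[ix, iy, iz])
    }, numeric(1))
    bg <- st[free]
    s <- stats::mad(bg)
    if (s == 0) return(Inf)
    (mean(peaks) - stats::median(bg)) / s
  }
  list(snr_raw = one_snr(raw_stack), snr_enhanced = one_snr(enhanced_stack))
}
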