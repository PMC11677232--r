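# End-to-end benchmark harnesses on the synthetic imaging model: decode a
# ground-truthed simulation and measure blank-based misidentification,
# recall and precision against the planted molecules. These are the
# package's own calibration experiments; tests and the acceptance script
# run them at fixed seeds.

#' Match decoded molecules to planted ground truth
#'
#' Greedy same-gene matching: a decoded molecule matches a planted one
#' when their lateral centroid distance is at most `tol_px` and their z
#' positions differ by at most one plane; candidate pairs are consumed in
#' order of increasing lateral distance, each molecule matching at most
#' once.
#'
#' @param decoded molecule data.frame (x_px, y_px, z_plane, gene).
#' @param truth planted molecule data.frame (x_px, y_px, z_px, gene).
#' @param tol_px lateral matching tolerance, pixels.
#' @return list(n_matched, recall, precision).
#' @export
match_molecules <- function(decoded, truth, tol_px = 1) {
  if (nrow(decoded) == 0 || nrow(truth) == 0) {
    return(list(n_matched = 0L,
                recall = if (nrow(truth)) 0 else NA_real_,
                precision = if (nrow(decoded)) 0 else NA_real_))
  }
  n_matched <- 0L
  for (g in unique(truth$gene)) {
    ti <- which(truth$gene == g)
    di <- which(decoded$gene == g)
    if (length(di) == 0) next
    dx <- outer(decoded$x_px[di], truth$x_px[ti], "-")
    dy <- outer(decoded$y_px[di], truth$y_px[ti], "-")
    dz <- abs(outer(decoded$z_plane[di] + 0.5, truth$z_px[ti], "-"))
    dd <- sqrt(dx^2 + dy^2)
    cand <- which(dd <= tol_px & dz <= 1.5, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    cand <- cand[order(dd[cand]), , drop = FALSE]
    used_d <- logical(length(di))
    used_t <- logical(length(ti))
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; b <- cand[r, 2]
      if (!used_d[a] && !used_t[b]) {
        used_d[a] <- TRUE
        used_t[b] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(n_matched = n_matched,
       recall = n_matched / nrow(truth),
       precision = n_matched / nrow(decoded))
}

run_decode_chain <- function(seed, cb, volume_px, density, snr,
                             background_level, read_sigma, drift_mag_px,
                             target_rate, high_pass_sigma = 3,
                             low_pass_sigma = 1, rl_iter = 20,
                             max_distance = 0.65, min_intensity = 10,
                             dedup_xy_radius_px = 1.5) {
  optics <- optics_config(cb$n_bits)
  bright <- brightness_for_snr(snr, background_level, read_sigma)
  truth <- plant_truth(cb, density, volume_px, optics,
                       drift_mag_px = drift_mag_px,
                       seed = stage_seed(seed, "bench_truth"),
                       brightness = bright)
  bs <- render_stacks(truth, cb, optics, background_level = background_level,
                      noise = list(poisson_on = TRUE, read_sigma = read_sigma),
                      seed = stage_seed(seed, "bench_render"))
  bs <- preprocess_stacks(bs, high_pass_sigma = high_pass_sigma,
                          low_pass_sigma = low_pass_sigma, rl_iter = rl_iter)
  mols <- decode_stacks(bs, cb, max_distance = max_distance,
                        min_intensity = min_intensity)
  mols <- drop_single_pixel(mols)
  fl <- adaptive_filter(mols, cb, target_rate = target_rate)
  final <- dedup_across_z(fl$molecules, xy_radius_px = dedup_xy_radius_px)
  list(truth = truth, raw = mols, filtered = final, model = fl$model)
}

#' Blank-barcode misidentification calibration benchmark
#'
#' Full synthetic run at the package's calibration conditions: a 16-bit
#' constant-weight-4 codebook (40 coding + 10 blank entries, minimum
#' Hamming distance 4, codebook seed 1), ~2,000 molecules planted for
#' coding entries only at peak SNR 8 with per-round drift, then
#' preprocessing, pixel decoding (0.65 / 10 gates), single-pixel removal,
#' adaptive filtering at the 5% target and cross-z deduplication. Reports
#' the per-entry-normalized blank misidentification rate (as a
#' percentage) of the final molecule list and the retained fraction of
#' planted molecules.
#'
#' @param seed master seed for planting and noise.
#' @param volume_px,density_per_100um2_per_plane simulated volume and
#'   molecule density (defaults give ~2,000 molecules).
#' @param snr peak signal-to-noise ratio of planted spots.
#' @param target_rate misidentification target (default 0.05).
#' @return list(misid_rate_pct, retention, n_planted, n_final, model).
#' @export
misid_benchmark <- function(seed = 1, volume_px = c(320, 320, 10),
                            density_per_100um2_per_plane = 700, snr = 8,
                            target_rate = 0.05) {
  cb <- synth_codebook(16, 4, 4, n_coding = 40, n_blank = 10, seed = 1)
  res <- run_decode_chain(seed, cb, volume_px, density_per_100um2_per_plane,
                          snr = snr, background_level = 1, read_sigma = 1,
                          drift_mag_px = 2, target_rate = target_rate)
  mm <- match_molecules(res$filtered, res$truth$molecules)
  list(misid_rate_pct = 100 * misid_rate(res$filtered, cb),
       retention = mm$recall,
       n_planted = nrow(res$truth$molecules),
       n_final = nrow(res$filtered),
       model = res$model)
}

#' End-to-end molecule recovery benchmark
#'
#' Render, preprocess, decode and filter a lower-density, higher-SNR
#' simulation and measure recall and precision of the final molecule list
#' against the planted truth with 1-pixel position matching.
#'
#' @param seed master seed.
#' @param volume_px,density_per_100um2_per_plane,snr simulation scale.
#' @return list(recall, precision, n_planted, n_final).
#' @export
recovery_benchmark <- function(seed = 1, volume_px = c(256, 256, 8),
                               density_per_100um2_per_plane = 280, snr = 12) {
  cb <- synth_codebook(16, 4, 4, n_coding = 40, n_blank = 10, seed = 1)
  res <- run_decode_chain(seed, cb, volume_px, density_per_100um2_per_plane,
                          snr = snr, background_level = 1, read_sigma = 1,
                          drift_mag_px = 2, target_rate = 0.05)
  mm <- match_molecules(res$filtered, res$truth$molecules)
  list(recall = mm$recall, precision = mm$precision,
       n_planted = nrow(res$truth$molecules), n_final = nrow(res$filtered))
}
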