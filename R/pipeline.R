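# Pipeline driver: configuration with validated defaults mirroring every
# stage parameter, individually re-runnable stages writing serialized
# artifacts, and a run-all chain with a JSON run report. All randomness
# flows from the single config seed via named substreams (stage_seed), so
# a rerun with the same config is byte-identical.

#' Default pipeline configuration
#'
#' Every stage parameter with its default: decoder gates (max_distance
#' 0.65, min_intensity 10), misidentification target 0.05, cell dedup
#' (k = 10, overlap 0.40), QC thresholds (volume 100 / counts 30 / z 5-40),
#' 10,000 library-size scaling, and the spatial gate of 20 self pairs.
#'
#' @param seed master seed.
#' @param outdir output directory for artifacts.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, outdir = "merfish_run") {
  list(
    seed = seed,
    outdir = outdir,
    simulate = list(
      volume_px = c(160, 160, 12),
      density_per_100um2_per_plane = 1000,
      n_beads = 25,
      drift_mag_px = 2,
      snr = 10,
      background_level = 1,
      read_sigma = 1,
      brightness_cv = 0.1,
      chromatic_z_offset_planes = 0,
      n_cells = 2,
      cell_radius_um_range = c(4.2, 5),
      codebook = list(n_bits = 16, weight = 4, min_hd = 4,
                      n_coding = 12, n_blank = 4, seed = 1)
    ),
    restoration = list(enabled = FALSE, epochs = 3, patch = 32, stride = 16,
                       n_source_pairs = 50),
    preprocess = list(high_pass_sigma = 3, low_pass_sigma = 1, rl_iter = 20),
    decode = list(max_distance = 0.65, min_intensity = 10, connectivity = 4,
                  dedup_xy_radius_px = 1.5),
    filter = list(target_rate = 0.05, n_bins = c(20, 20, 10)),
    cells = list(k = 10, overlap_threshold = 0.40, min_volume = 100,
                 min_counts = 30, min_z = 5, max_z = 40, scale = 10000),
    spatial = list(enabled = TRUE, source = "synthetic_map", n_cells = 400,
                   min_self_pairs = 20, n_starts = 5)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (!k %in% names(base)) stop("unknown config key: ", k)
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Validate (and complete) a pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()] values; thresholds are range-checked.
#'
#' @param config partial or full configuration list.
#' @return completed configuration.
#' @export
validate_config <- function(config) {
  cfg <- merge_config(default_config(), config)
  with(cfg$decode, stopifnot(max_distance >= 0, min_intensity >= 0,
                             connectivity %in% c(4, 8)))
  stopifnot(cfg$filter$target_rate > 0, cfg$filter$target_rate < 1,
            cfg$cells$overlap_threshold > 0, cfg$cells$overlap_threshold <= 1,
            cfg$cells$min_z >= 1, cfg$cells$max_z >= cfg$cells$min_z,
            cfg$spatial$min_self_pairs >= 1)
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list for writing.
#' @return [load_config()] returns the validated configuration.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

pipeline_paths <- function(outdir) {
  list(
    codebook = file.path(outdir, "codebook.csv"),
    truth_molecules = file.path(outdir, "truth_molecules.csv"),
    truth_drift = file.path(outdir, "truth_drift.csv"),
    stacks_raw = file.path(outdir, "stacks_raw"),
    labels = file.path(outdir, "labels.tif"),
    stacks_proc = file.path(outdir, "stacks_proc"),
    drift_est = file.path(outdir, "drift_estimate.csv"),
    molecules_raw = file.path(outdir, "molecules_raw.csv"),
    molecules_filtered = file.path(outdir, "molecules_filtered.csv"),
    filter_model = file.path(outdir, "filter_model.json"),
    cells = file.path(outdir, "cells.csv"),
    matrix_raw = file.path(outdir, "matrix_raw"),
    matrix_qc = file.path(outdir, "matrix_qc"),
    matrix_norm = file.path(outdir, "matrix_norm"),
    spatial_cells = file.path(outdir, "spatial_cells.csv"),
    spatial_stats = file.path(outdir, "spatial_self_other.csv"),
    mixture_fit = file.path(outdir, "mixture_fit.json"),
    report = file.path(outdir, "report.json")
  )
}

#' Run one pipeline stage from serialized artifacts
#'
#' Stages: `simulate`, `restore`, `preprocess`, `decode`, `filter`,
#' `cells`, `matrix`, `spatial`. Each reads its inputs from the
#' configuration's output directory (written by the previous stage) and
#' writes its own artifacts there; [run_pipeline()] chains them.
#'
#' @param stage stage name.
#' @param config validated configuration.
#' @return stage summary list, invisibly.
#' @export
run_stage <- function(stage, config) {
  cfg <- validate_config(config)
  p <- pipeline_paths(cfg$outdir)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  need <- function(path, what) {
    if (!file.exists(path)) {
      stop(sprintf("stage '%s' needs missing input artifact: %s (%s)",
                   stage, path, what))
    }
  }
  summary <- switch(
    stage,
    simulate = {
      sc <- cfg$simulate
      cbk <- sc$codebook
      cb <- synth_codebook(cbk$n_bits, cbk$weight, cbk$min_hd, cbk$n_coding,
                           cbk$n_blank, seed = cbk$seed)
      write_codebook(cb, p$codebook)
      optics <- optics_config(cbk$n_bits,
                              chromatic_z_offset_planes = sc$chromatic_z_offset_planes)
      bright <- brightness_for_snr(sc$snr, sc$background_level, sc$read_sigma)
      truth <- plant_truth(cb, sc$density_per_100um2_per_plane, sc$volume_px,
                           optics, n_beads = sc$n_beads,
                           drift_mag_px = sc$drift_mag_px,
                           seed = stage_seed(cfg$seed, "truth"),
                           brightness = bright, brightness_cv = sc$brightness_cv,
                           n_cells = sc$n_cells,
                           cell_radius_um_range = sc$cell_radius_um_range)
      bs <- render_stacks(truth, cb, optics,
                          background_level = sc$background_level,
                          noise = list(poisson_on = TRUE,
                                       read_sigma = sc$read_sigma),
                          seed = stage_seed(cfg$seed, "render"))
      write_molecules(truth$molecules, p$truth_molecules)
      utils::write.csv(truth$drift_per_round, p$truth_drift, row.names = FALSE)
      write_stacks(bs, p$stacks_raw)
      if (!is.null(truth$cells)) write_labels_tiff(truth$cells$labels, p$labels)
      list(planted_molecules = nrow(truth$molecules),
           n_cells = sc$n_cells, n_bits = cbk$n_bits)
    },
    restore = {
      if (!cfg$restoration$enabled) {
        list(skipped = TRUE)
      } else {
        need(file.path(p$stacks_raw, "manifest.json"), "raw stacks")
        bs <- read_stacks(p$stacks_raw)
        rc <- cfg$restoration
        for (ch in unique(bs$optics$channel_of_bit)) {
          bits <- which(bs$optics$channel_of_bit == ch)
          planes_low <- list(); planes_high <- list()
          for (f in names(bs$stacks)) for (b in bits) {
            st <- bs$stacks[[f]][[b]]
            for (k in seq_len(dim(st)[3])) {
              planes_low[[length(planes_low) + 1]] <- st[, , k]
              planes_high[[length(planes_high) + 1]] <-
                gaussian_blur2d(st[, , k], 0.8)
            }
          }
          pp <- make_patch_pairs(planes_low, planes_high,
                                 n_source_pairs = rc$n_source_pairs,
                                 patch = rc$patch, stride = rc$stride,
                                 seed = stage_seed(cfg$seed, paste0("patches", ch)))
          tr <- train_denoiser(pp, denoiser_spec(), epochs = rc$epochs,
                               seed = stage_seed(cfg$seed, paste0("train", ch)))
          for (f in names(bs$stacks)) for (b in bits) {
            bs$stacks[[f]][[b]] <- denoise_stack(tr$model, bs$stacks[[f]][[b]])
          }
        }
        write_stacks(bs, p$stacks_raw)
        list(enabled = TRUE)
      }
    },
    preprocess = {
      need(file.path(p$stacks_raw, "manifest.json"), "raw stacks")
      bs <- read_stacks(p$stacks_raw)
      pc <- cfg$preprocess
      bs <- preprocess_stacks(bs, high_pass_sigma = pc$high_pass_sigma,
                              low_pass_sigma = pc$low_pass_sigma,
                              rl_iter = pc$rl_iter)
      utils::write.csv(bs$drift, p$drift_est, row.names = FALSE)
      write_stacks(bs, p$stacks_proc)
      list(n_rounds = max(bs$optics$round_of_bit),
           max_drift = max(abs(c(bs$drift$dx_px, bs$drift$dy_px))))
    },
    decode = {
      need(file.path(p$stacks_proc, "manifest.json"), "preprocessed stacks")
      need(p$codebook, "codebook")
      bs <- read_stacks(p$stacks_proc)
      cb <- load_codebook(p$codebook)
      dc <- cfg$decode
      mols <- decode_stacks(bs, cb, max_distance = dc$max_distance,
                            min_intensity = dc$min_intensity,
                            connectivity = dc$connectivity)
      write_molecules(mols, p$molecules_raw)
      list(decoded = nrow(mols), blank_rate = misid_rate(mols, cb))
    },
    filter = {
      need(p$molecules_raw, "raw molecules")
      need(p$codebook, "codebook")
      cb <- load_codebook(p$codebook)
      mols <- read_molecules(p$molecules_raw)
      n0 <- nrow(mols)
      mols <- drop_single_pixel(mols)
      fl <- adaptive_filter(mols, cb, target_rate = cfg$filter$target_rate,
                            n_bins = cfg$filter$n_bins)
      final <- dedup_across_z(fl$molecules,
                              xy_radius_px = cfg$decode$dedup_xy_radius_px)
      write_molecules(final, p$molecules_filtered)
      write_filter_model(fl$model, p$filter_model)
      list(decoded = n0, multi_pixel = nrow(mols),
           accepted = nrow(fl$molecules), rejected = n0 - nrow(fl$molecules),
           after_z_dedup = nrow(final),
           misid_rate = fl$model$achieved_misid_rate)
    },
    cells = {
      need(p$labels, "segmentation labels")
      need(p$molecules_filtered, "filtered molecules")
      need(p$codebook, "codebook")
      cb <- load_codebook(p$codebook)
      labels <- read_labels_tiff(p$labels)
      optics <- read_stacks(p$stacks_raw)$optics
      cs <- cell_set_from_labels(labels, optics)
      n_before <- nrow(cs$cells)
      cs <- dedup_cells(cs, k = cfg$cells$k,
                        overlap_threshold = cfg$cells$overlap_threshold)
      mols <- read_molecules(p$molecules_filtered)
      mat <- assign_molecules(mols, cs, cb)
      utils::write.csv(cs$cells, p$cells, row.names = FALSE)
      write_cell_by_gene(mat, p$matrix_raw)
      list(cells = n_before, after_dedup = nrow(cs$cells),
           assigned = sum(mat), unassigned = attr(mat, "unassigned"))
    },
    matrix = {
      need(file.path(p$matrix_raw, "matrix.mtx"), "raw cell-by-gene matrix")
      mat <- as.matrix(Matrix::readMM(file.path(p$matrix_raw, "matrix.mtx")))
      genes <- utils::read.table(file.path(p$matrix_raw, "genes.tsv"))$V1
      cells <- utils::read.table(file.path(p$matrix_raw, "cells.tsv"),
                                 header = TRUE)
      dimnames(mat) <- list(as.character(cells$id), genes)
      attr(mat, "cells") <- cells
      qc <- qc_cells(mat, cells, min_volume = cfg$cells$min_volume,
                     min_counts = cfg$cells$min_counts,
                     min_z = cfg$cells$min_z, max_z = cfg$cells$max_z)
      write_cell_by_gene(qc, p$matrix_qc)
      if (nrow(qc) > 0) {
        norm <- normalize_matrix(qc, scale = cfg$cells$scale)
        attr(norm, "cells") <- attr(qc, "cells")
        write_cell_by_gene(norm, p$matrix_norm)
      }
      list(cells_in = nrow(mat), cells_qc = nrow(qc),
           excluded = nrow(mat) - nrow(qc))
    },
    spatial = {
      if (!cfg$spatial$enabled) {
        list(skipped = TRUE)
      } else {
        cmap <- if (cfg$spatial$source == "synthetic_map") {
          simulate_cell_map(n_cells = cfg$spatial$n_cells,
                            seed = stage_seed(cfg$seed, "spatial_map"))
        } else {
          need(p$cells, "cell table")
          cells <- utils::read.csv(p$cells)
          data.frame(id = cells$id, x = cells$x_um, y = cells$y_um,
                     z = cells$z_um,
                     subclass = rep(c("A", "B"), length.out = nrow(cells)))
        }
        utils::write.csv(cmap, p$spatial_cells, row.names = FALSE)
        inh <- setdiff(unique(cmap$subclass), "Exc")
        pairs <- nn_pairs(cmap, focal_labels = inh, neighbor_scope = "all")
        st <- tryCatch(self_other_test(pairs,
                                       min_self_pairs = cfg$spatial$min_self_pairs),
                       warning = function(w) data.frame())
        utils::write.csv(st, p$spatial_stats, row.names = FALSE)
        fit_ok <- FALSE
        pairs_inh <- tryCatch(nn_pairs(cmap, focal_labels = inh,
                                       neighbor_scope = "focal_only"),
                              error = function(e) NULL)
        if (!is.null(pairs_inh) && nrow(pairs_inh) >= 10) {
          fit <- fit_two_gaussians(pairs_inh$distance_um,
                                   n_starts = cfg$spatial$n_starts,
                                   seed = stage_seed(cfg$seed, "gmm"))
          jsonlite::write_json(unclass(fit)[c("weights", "means", "sds",
                                              "loglik", "converged")],
                               p$mixture_fit, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
          fit_ok <- TRUE
        }
        list(n_focal = nrow(pairs), tested_subclasses = nrow(st),
             mixture_fitted = fit_ok)
      }
    },
    stop("unknown stage: ", stage)
  )
  invisible(summary)
}

#' Run the full pipeline
#'
#' Chains simulate, (optional) restore, preprocess, decode, filter, cells,
#' matrix and spatial, then writes a JSON run report with the stage
#' parameters and reconciling counts. Reruns with the same configuration
#' produce byte-identical artifacts.
#'
#' @param config configuration list (validated and completed).
#' @return named list of stage summaries, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config)
  stages <- c("simulate", "restore", "preprocess", "decode", "filter",
              "cells", "matrix", "spatial")
  out <- list()
  for (s in stages) {
    message("[merfish3d] stage: ", s)
    out[[s]] <- run_stage(s, cfg)
  }
  report <- list(package = "merfish3d",
                 version = as.character(utils::packageVersion("merfish3d")),
                 seed = cfg$seed, config = cfg, stages = out)
  jsonlite::write_json(report, pipeline_paths(cfg$outdir)$report,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
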