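# Blank-barcode misidentification calibration and adaptive filtering of
# putative molecules. Blank codewords carry no real signal, so the rate at
# which decoded molecules land on blanks, normalized per codebook entry,
# estimates the false-identification rate of the molecule list; the
# adaptive filter accepts regions of (intensity, distance, area) feature
# space in order of increasing blank content until the target rate would
# be exceeded.

#' Per-entry-normalized blank misidentification rate
#'
#' rate = (N_blank / B_blank) / (N_total / B_total), where N are decoded
#' molecule counts and B are codebook entry counts. The normalization makes
#' the rate dimensionless and independent of codebook size: it is 1 when
#' blanks are decoded as often per entry as the average entry, and 0 when
#' no blanks are decoded.
#'
#' @param mols molecule data.frame with an `is_blank` column.
#' @param cb a `merfish_codebook` with at least one blank entry.
#' @return the misidentification rate (0 for an empty molecule list).
#' @export
misid_rate <- function(mols, cb) {
  stopifnot(inherits(cb, "merfish_codebook"))
  b_blank <- n_blank_entries(cb)
  if (b_blank == 0) stop("codebook has no blank entries; misidentification rate undefined")
  b_total <- nrow(cb$entries)
  n_total <- nrow(mols)
  if (n_total == 0) return(0)
  n_blank <- sum(mols$is_blank)
  (n_blank / b_blank) / (n_total / b_total)
}

#' Remove single-pixel molecules
#'
#' Putative RNAs containing only one pixel mostly arise from spurious
#' barcodes generated by random fluorescence fluctuations and carry a
#' higher misidentification rate; exactly the molecules with
#' `area_px >= 2` survive.
#'
#' @param mols molecule data.frame.
#' @return filtered data.frame.
#' @export
drop_single_pixel <- function(mols) {
  out <- mols[mols$area_px >= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adaptive misidentification-rate filter
#'
#' Histograms molecules in (log10 mean intensity, mean barcode distance,
#' area) feature space, ranks bins by ascending blank fraction (ties by
#' bin index; empty bins last among zero-fraction bins), and accepts bins
#' greedily while the cumulative per-entry-normalized misidentification
#' rate of the accepted molecules stays at or below `target_rate`. If even
#' the single best bin exceeds the target, that bin alone is accepted and
#' the model is flagged.
#'
#' @param mols molecule data.frame with mean_intensity, mean_distance,
#'   area_px and is_blank columns.
#' @param cb a `merfish_codebook` with blank entries.
#' @param target_rate target misidentification rate (default 0.05).
#' @param n_bins bins per feature axis c(intensity, distance, area).
#' @param area_cap_q area quantile at which the area feature is capped.
#' @return list(molecules = accepted rows, model = filter model with bin
#'   edges, accepted-bin mask, per-bin blank fraction, achieved rate and
#'   the flagged indicator).
#' @export
adaptive_filter <- function(mols, cb, target_rate = 0.05,
                            n_bins = c(20, 20, 10), area_cap_q = 0.99) {
  stopifnot(inherits(cb, "merfish_codebook"),
            target_rate > 0, target_rate < 1)
  if (n_blank_entries(cb) == 0) {
    stop("adaptive filtering requires blank entries in the codebook")
  }
  n <- nrow(mols)
  if (n == 0) {
    model <- list(edges = NULL, accepted = logical(0), blank_frac = numeric(0),
                  achieved_misid_rate = 0, flagged = FALSE,
                  target_rate = target_rate)
    class(model) <- "filter_model"
    return(list(molecules = mols, model = model))
  }
  area_cap <- stats::quantile(mols$area_px, area_cap_q, names = FALSE)
  feats <- cbind(log10(pmax(mols$mean_intensity, 1e-12)),
                 mols$mean_distance,
                 pmin(mols$area_px, area_cap))
  edges <- lapply(1:3, function(j) {
    rng <- range(feats[, j])
    if (rng[2] - rng[1] < 1e-12) rng[2] <- rng[1] + 1e-12
    seq(rng[1], rng[2], length.out = n_bins[j] + 1)
  })
  n_bins <- as.integer(n_bins)
  bin_of <- vapply(1:3, function(j) {
    b <- findInterval(feats[, j], edges[[j]], rightmost.closed = TRUE)
    as.integer(pmin(pmax(b, 1L), n_bins[j]))
  }, integer(n))
  bin_id <- (bin_of[, 1] - 1L) + n_bins[1] * (bin_of[, 2] - 1L) +
    n_bins[1] * n_bins[2] * (bin_of[, 3] - 1L) + 1L
  nb <- prod(n_bins)
  n_tot <- tabulate(bin_id, nb)
  n_blank <- tabulate(bin_id[mols$is_blank], nb)
  blank_frac <- ifelse(n_tot > 0, n_blank / pmax(n_tot, 1), 0)
  ord <- order(blank_frac, n_tot == 0, seq_len(nb))
  b_blank <- n_blank_entries(cb)
  b_total <- nrow(cb$entries)
  cum_tot <- cumsum(n_tot[ord])
  cum_blank <- cumsum(n_blank[ord])
  rate_k <- ifelse(cum_tot > 0,
                   (cum_blank / b_blank) / (cum_tot / b_total), 0)
  ok <- rate_k <= target_rate
  k_star <- if (!ok[1]) 0L else max(which(cumsum(!ok) == 0))
  flagged <- k_star == 0L
  if (flagged) {
    # even the best bin exceeds the target: keep it alone, flagged
    k_star <- which(n_tot[ord] > 0)[1]
  }
  accepted_bins <- rep(FALSE, nb)
  accepted_bins[ord[seq_len(k_star)]] <- TRUE
  keep <- accepted_bins[bin_id]
  out <- mols[keep, , drop = FALSE]
  rownames(out) <- NULL
  achieved <- misid_rate(out, cb)
  model <- list(edges = edges, n_bins = n_bins, area_cap = area_cap,
                accepted = accepted_bins, blank_frac = blank_frac,
                achieved_misid_rate = achieved, flagged = flagged,
                target_rate = target_rate)
  class(model) <- "filter_model"
  list(molecules = out, model = model)
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf("adaptive filter model: %d/%d bins accepted, achieved misid rate %.4f (target %.2f)%s\n",
              sum(x$accepted), length(x$accepted), x$achieved_misid_rate,
              x$target_rate, if (isTRUE(x$flagged)) " [FLAGGED: target unattainable]" else ""))
  invisible(x)
}
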