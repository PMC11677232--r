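# Misidentification-rate estimation, single-pixel removal and the
# adaptive blank-calibrated filter.

test_that("misid_rate implements the per-entry-normalized blank rate", {
  cb <- synth_codebook(16, 4, 2, n_coding = 200, n_blank = 10, seed = 1)
  # worked arithmetic: N_blank=10, B_blank=10, N_total=2010, B_total=210
  mols <- make_mols(barcode_index = c(rep(1L, 2000), rep(201L, 10)),
                    z_plane = 0L, x_px = 1, y_px = 1,
                    is_blank = c(rep(FALSE, 2000), rep(TRUE, 10)))
  expect_equal(misid_rate(mols, cb), (10 / 10) / (2010 / 210))
  # no blank molecules -> 0; empty list -> 0
  expect_equal(misid_rate(mols[!mols$is_blank, ], cb), 0)
  expect_equal(misid_rate(mols[0, ], cb), 0)
  # counts uniform across all entries -> exactly 1
  uni <- make_mols(barcode_index = seq_len(210), z_plane = 0L,
                   x_px = 1, y_px = 1, is_blank = cb$entries$is_blank)
  expect_equal(misid_rate(uni, cb), 1)
  cb_nb <- codebook_from_table(c("a", "b"), c("10", "01"), c(FALSE, FALSE))
  expect_error(misid_rate(mols, cb_nb), "no blank entries")
})

test_that("single-pixel molecules are removed exactly", {
  mols <- make_mols(1L, z_plane = 0:3, x_px = 1:4, y_px = 1,
                    area_px = c(1L, 2L, 3L, 1L))
  expect_equal(drop_single_pixel(mols)$area_px, c(2L, 3L))
  all2 <- make_mols(1L, z_plane = 0:2, x_px = 1:3, y_px = 1, area_px = 2L)
  expect_equal(drop_single_pixel(all2), all2)
  set.seed(5)
  rnd <- make_mols(1L, z_plane = 0L, x_px = runif(50), y_px = 1,
                   area_px = sample(1:5, 50, replace = TRUE))
  expect_equal(drop_single_pixel(rnd), rnd[rnd$area_px >= 2, ],
               ignore_attr = TRUE)
})

filter_codebook <- function() {
  codebook_from_table(c("g1", "g2", "g3", "Blank-1", "Blank-2"),
                      c("1100", "0110", "0011", "1001", "1010"),
                      c(FALSE, FALSE, FALSE, TRUE, TRUE))
}

test_that("blanks confined to poor bins are rejected at the 5% target", {
  cb <- filter_codebook()
  set.seed(9)
  good <- make_mols(sample(1:3, 400, replace = TRUE), z_plane = 0L,
                    x_px = runif(400), y_px = 1,
                    mean_intensity = runif(400, 30, 60),
                    mean_distance = runif(400, 0.05, 0.25))
  bad <- make_mols(sample(4:5, 60, replace = TRUE), z_plane = 0L,
                   x_px = runif(60), y_px = 1,
                   mean_intensity = runif(60, 10, 15),
                   mean_distance = runif(60, 0.5, 0.65), is_blank = TRUE)
  res <- adaptive_filter(rbind(good, bad), cb, target_rate = 0.05)
  expect_lte(res$model$achieved_misid_rate, 0.05)
  # nearly all blanks sit in rejected bins; the accepted remainder is
  # bounded by the 5% budget
  expect_lt(sum(res$molecules$is_blank), 10)
  expect_gte(nrow(res$molecules), 390)
  expect_false(res$model$flagged)
  # the filter never increases the rate
  expect_lte(misid_rate(res$molecules, cb), misid_rate(rbind(good, bad), cb))
})

test_that("with zero decoded blanks every bin is accepted", {
  cb <- filter_codebook()
  mols <- make_mols(c(1L, 2L, 3L), z_plane = 0L, x_px = 1:3, y_px = 1)
  res <- adaptive_filter(mols, cb)
  expect_equal(nrow(res$molecules), 3L)
  expect_equal(res$model$achieved_misid_rate, 0)
  cb_nb <- codebook_from_table(c("a", "b"), c("10", "01"), c(FALSE, FALSE))
  expect_error(adaptive_filter(mols, cb_nb), "blank entries")
})

# Independent greedy oracle at 2x2x2 bins: recompute the histogram and the
# greedy prefix directly from the definition.
oracle_adaptive <- function(mols, cb, target) {
  area_cap <- stats::quantile(mols$area_px, 0.99, names = FALSE)
  f <- cbind(log10(mols$mean_intensity), mols$mean_distance,
             pmin(mols$area_px, area_cap))
  bin1 <- function(v) {
    r <- range(v); if (r[2] - r[1] < 1e-12) r[2] <- r[1] + 1e-12
    mid <- (r[1] + r[2]) / 2
    ifelse(v < mid, 1L, 2L)
  }
  b <- (bin1(f[, 1]) - 1L) + 2L * (bin1(f[, 2]) - 1L) + 4L * (bin1(f[, 3]) - 1L) + 1L
  tot <- tabulate(b, 8); blk <- tabulate(b[mols$is_blank], 8)
  frac <- ifelse(tot > 0, blk / pmax(tot, 1), 0)
  ord <- order(frac, tot == 0, 1:8)
  bb <- sum(cb$entries$is_blank); bt <- nrow(cb$entries)
  acc <- logical(8); cb_ <- 0; ct <- 0
  for (k in ord) {
    nb2 <- cb_ + blk[k]; nt2 <- ct + tot[k]
    if (nt2 > 0 && (nb2 / bb) / (nt2 / bt) > target) break
    acc[k] <- TRUE; cb_ <- nb2; ct <- nt2
  }
  # target unattainable even for the best bin: keep that bin alone
  if (!any(acc)) acc[ord[which(tot[ord] > 0)[1]]] <- TRUE
  which(acc[b])
}

test_that("small filtering problems match the exhaustive greedy oracle", {
  cb <- filter_codebook()
  for (seed in 1:4) {
    set.seed(seed)
    n <- 150
    mols <- make_mols(sample(1:5, n, replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.05, 0.05)),
                      z_plane = 0L, x_px = runif(n), y_px = 1,
                      area_px = sample(2:8, n, replace = TRUE),
                      mean_intensity = exp(runif(n, 2.5, 4.5)),
                      mean_distance = runif(n, 0, 0.65))
    mols$is_blank <- mols$barcode_index >= 4
    # blanks skew towards high distance, as decoding noise does
    mols$mean_distance[mols$is_blank] <- runif(sum(mols$is_blank), 0.35, 0.65)
    res <- adaptive_filter(mols, cb, target_rate = 0.05, n_bins = c(2, 2, 2))
    expect_equal(sort(match(do.call(paste, res$molecules),
                            do.call(paste, mols))),
                 sort(oracle_adaptive(mols, cb, 0.05)))
  }
})

test_that("lowering the target never enlarges the accepted set", {
  cb <- filter_codebook()
  set.seed(21)
  n <- 400
  mols <- make_mols(sample(1:5, n, replace = TRUE, prob = c(rep(0.3, 3), 0.05, 0.05)),
                    z_plane = 0L, x_px = runif(n), y_px = 1,
                    area_px = sample(2:8, n, replace = TRUE),
                    mean_intensity = exp(runif(n, 2.5, 4.5)),
                    mean_distance = runif(n, 0, 0.65))
  mols$is_blank <- mols$barcode_index >= 4
  keys <- function(res) do.call(paste, res$molecules)
  r10 <- adaptive_filter(mols, cb, target_rate = 0.10)
  r05 <- adaptive_filter(mols, cb, target_rate = 0.05)
  r01 <- adaptive_filter(mols, cb, target_rate = 0.01)
  expect_true(all(keys(r05) %in% keys(r10)))
  expect_true(all(keys(r01) %in% keys(r05)))
  expect_lte(r05$model$achieved_misid_rate, 0.05)
})
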