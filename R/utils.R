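# Internal numeric helpers shared across the imaging pipeline.
#
# Image arrays are indexed [x, y, z]: the first array index is the x pixel
# coordinate, the second y, the third the z plane. Continuous pixel
# coordinates run from 0 to n along each axis, so the centre of 1-based
# pixel i sits at coordinate i - 0.5 and physical positions are
# coordinate * pixel_size_um (voxel centres at (i + 0.5) * pixel_size for
# 0-based i).

.merfish_cache <- new.env(parent = emptyenv())

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so library functions never perturb user-level
#' random streams.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage substream seed from a master seed
#'
#' All pipeline randomness flows from a single master seed through named
#' substreams, so reruns are byte-stable and stages are independently
#' re-runnable. The derived value always stays below 2^31 - 1.
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483629)
}

# Discrete, normalized 1D Gaussian kernel.
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded row-normalized blur operator for one axis; rows near the border
# renormalize the truncated kernel (flux-preserving in the interior).
blur_matrix <- function(n, sigma) {
  key <- paste0("blur", n, "_", signif(sigma, 10))
  hit <- .merfish_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- min(ceiling(3 * sigma), n - 1)
  k <- gaussian_kernel(sigma, r)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    A[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  .merfish_cache[[key]] <- A
  A
}

# Separable 2D Gaussian blur with truncated-renormalized boundaries.
gaussian_blur2d <- function(im, sigma) {
  if (sigma <= 0) return(im)
  A <- blur_matrix(nrow(im), sigma)
  B <- blur_matrix(ncol(im), sigma)
  A %*% im %*% t(B)
}

# 2D convolution with an arbitrary odd-sized kernel, replicate boundary,
# FFT-backed with a cached optical transfer function.
conv2_psf <- function(im, psf) {
  kr <- (nrow(psf) - 1L) %/% 2L
  kc <- (ncol(psf) - 1L) %/% 2L
  nr <- nrow(im)
  nc <- ncol(im)
  pr <- nr + 2L * kr
  pc <- nc + 2L * kc
  ri <- c(rep(1L, kr), seq_len(nr), rep(nr, kr))
  ci <- c(rep(1L, kc), seq_len(nc), rep(nc, kc))
  P <- im[ri, ci, drop = FALSE]
  key <- paste0("otf", pr, "x", pc, "_",
                paste(signif(as.numeric(psf), 8), collapse = ","))
  OTF <- .merfish_cache[[key]]
  if (is.null(OTF)) {
    K0 <- matrix(0, pr, pc)
    rr <- ((seq_len(nrow(psf)) - 1L - kr) %% pr) + 1L
    cc <- ((seq_len(ncol(psf)) - 1L - kc) %% pc) + 1L
    K0[rr, cc] <- psf
    OTF <- stats::fft(K0)
    .merfish_cache[[key]] <- OTF
  }
  out <- Re(stats::fft(stats::fft(P) * OTF, inverse = TRUE)) / (pr * pc)
  out[(kr + 1L):(kr + nr), (kc + 1L):(kc + nc), drop = FALSE]
}

# Subpixel bilinear translation: content moves by (+dx, +dy) pixels along
# the first/second index; uncovered pixels are filled with `fill`.
translate_xy <- function(im, dx, dy, fill = 0) {
  nr <- nrow(im)
  nc <- ncol(im)
  sr <- seq_len(nr) - dx
  sc <- seq_len(nc) - dy
  r0 <- floor(sr)
  fr <- sr - r0
  c0 <- floor(sc)
  fc <- sc - c0
  grab_rows <- function(idx) {
    out <- matrix(fill, length(idx), nc)
    ok <- idx >= 1 & idx <= nr
    if (any(ok)) out[ok, ] <- im[idx[ok], , drop = FALSE]
    out
  }
  M <- grab_rows(r0) * (1 - fr) + grab_rows(r0 + 1) * fr
  grab_cols <- function(mm, idx) {
    out <- matrix(fill, nr, length(idx))
    ok <- idx >= 1 & idx <= nc
    if (any(ok)) out[, ok] <- mm[, idx[ok], drop = FALSE]
    out
  }
  grab_cols(M, c0) * rep(1 - fc, each = nr) + grab_cols(M, c0 + 1) * rep(fc, each = nr)
}

# Validity mask of a translation: TRUE where the interpolated value draws
# only on in-range source pixels.
translate_valid <- function(nr, nc, dx, dy) {
  v <- translate_xy(matrix(1, nr, nc), dx, dy, fill = 0)
  v > 1 - 1e-9
}

# Linear interpolation of a z-stack along z by +dz planes (content moves
# towards larger plane index); out-of-range planes fill with `fill`.
shift_z <- function(stack, dz, fill = 0) {
  d <- dim(stack)
  nz <- d[3]
  out <- array(fill, d)
  blank <- matrix(fill, d[1], d[2])
  for (k in seq_len(nz)) {
    s <- k - dz
    s0 <- floor(s)
    f <- s - s0
    a <- if (s0 >= 1 && s0 <= nz) stack[, , s0] else blank
    b <- if (s0 + 1 >= 1 && s0 + 1 <= nz) stack[, , s0 + 1] else blank
    out[, , k] <- (1 - f) * a + f * b
  }
  out
}

shift_z_valid <- function(nz, dz) {
  k <- seq_len(nz)
  s <- k - dz
  s0 <- floor(s)
  f <- s - s0
  ifelse(abs(f) < 1e-12, s0 >= 1 & s0 <= nz, s0 >= 1 & s0 + 1 <= nz)
}

# Integer shift of a matrix with constant fill (no interpolation).
shift_int <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

#' Label connected components of equal positive values
#'
#' Computes connected components of a label image where two pixels are
#' connected when they are neighbors (4- or 8-connectivity) and carry the
#' same positive value. Pixels with value <= 0 or NA are background.
#' Implemented by iterated minimum-label propagation with path compression;
#' component ids are renumbered 1..K in column-major order of first
#' occurrence, so the labeling is deterministic.
#'
#' @param m integer matrix of per-pixel class values.
#' @param connectivity 4 or 8.
#' @return integer matrix of component ids (0 = background).
#' @export
label_components <- function(m, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(m)
  nc <- ncol(m)
  mm <- m
  mm[is.na(mm)] <- 0L
  fg <- mm > 0
  L <- matrix(seq_len(nr * nc), nr, nc)
  L[!fg] <- 0L
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    prev <- L
    for (s in shifts) {
      Ls <- shift_int(L, s[1], s[2], 0L)
      ms <- shift_int(mm, s[1], s[2], 0L)
      link <- fg & Ls > 0 & ms == mm
      if (any(link)) {
        L[link] <- pmin(L[link], Ls[link])
      }
    }
    # path compression: jump each pixel's label to its label's label
    repeat {
      idx <- which(L > 0)
      if (length(idx) == 0) break
      jumped <- L[L[idx]]
      if (all(jumped == L[idx])) break
      L[idx] <- jumped
    }
    if (identical(prev, L)) break
  }
  ids <- L[L > 0]
  u <- unique(ids)
  out <- matrix(0L, nr, nc)
  out[L > 0] <- match(ids, u)
  out
}

# Weighted median (lower weighted median; exact for the L1 line search).
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}
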