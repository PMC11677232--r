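# Nearest-neighbor distance machinery for 3D cell-type maps: to-self /
# to-other classification of each cell's nearest neighbor, one-sided
# rank-sum tests with Benjamini-Hochberg correction gated on a minimum
# number of self-self pairs, and two-component Gaussian mixture fits of
# nearest-neighbor distance distributions.

#' Nearest-neighbor pairs for focal cells
#'
#' For each focal cell, finds the nearest other cell (3D Euclidean
#' distance on centroids, micrometers) within the candidate scope and
#' classifies the pair as `to_self` when both share the subclass label and
#' `to_other` otherwise. With `neighbor_scope = "all"` the candidate set is
#' every cell in the table (e.g. all neurons); with `"focal_only"` it is
#' restricted to cells of the focal labels (the regardless-of-subtype
#' distance-distribution analysis).
#'
#' @param cells data.frame(id, x, y, z, subclass).
#' @param focal_labels subclasses whose cells get a nearest-neighbor
#'   record; default all labels.
#' @param neighbor_scope "all" or "focal_only".
#' @return data.frame(id, subclass, nn_id, nn_subclass, distance_um,
#'   category).
#' @export
nn_pairs <- function(cells, focal_labels = NULL,
                     neighbor_scope = c("all", "focal_only")) {
  neighbor_scope <- match.arg(neighbor_scope)
  stopifnot(all(c("id", "x", "y", "z", "subclass") %in% names(cells)))
  if (is.null(focal_labels)) focal_labels <- unique(cells$subclass)
  focal <- which(cells$subclass %in% focal_labels)
  scope <- if (neighbor_scope == "all") seq_len(nrow(cells)) else focal
  if (length(scope) < 2) stop("neighbor scope must contain at least 2 cells")
  pos <- as.matrix(cells[, c("x", "y", "z")])
  out <- vector("list", length(focal))
  spos <- pos[scope, , drop = FALSE]
  for (i in seq_along(focal)) {
    fi <- focal[i]
    d2 <- (spos[, 1] - pos[fi, 1])^2 + (spos[, 2] - pos[fi, 2])^2 +
      (spos[, 3] - pos[fi, 3])^2
    d2[scope == fi] <- Inf
    j <- scope[which.min(d2)]
    out[[i]] <- data.frame(
      id = cells$id[fi], subclass = cells$subclass[fi],
      nn_id = cells$id[j], nn_subclass = cells$subclass[j],
      distance_um = sqrt(min(d2)),
      category = if (cells$subclass[j] == cells$subclass[fi]) "to_self" else "to_other",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gated one-sided rank-sum tests of to-self vs to-other distances
#'
#' Per focal subclass, tests whether to-self nearest-neighbor distances
#' are stochastically smaller than to-other distances (Wilcoxon rank-sum,
#' one-sided; exact for small samples without ties, normal approximation
#' with tie correction otherwise), then adjusts across tested subclasses
#' by the Benjamini-Hochberg procedure. Subclasses with fewer than
#' `min_self_pairs` self-self pairs (or no to-other pairs) are excluded
#' before testing.
#'
#' @param pairs output of [nn_pairs()].
#' @param min_self_pairs minimum number of to-self pairs (default 20).
#' @return data.frame(subclass, n_self, n_other, p, fdr); zero rows (with
#'   a warning) when nothing is testable.
#' @export
self_other_test <- function(pairs, min_self_pairs = 20) {
  res <- list()
  for (s in sort(unique(pairs$subclass))) {
    pp <- pairs[pairs$subclass == s, ]
    d_self <- pp$distance_um[pp$category == "to_self"]
    d_other <- pp$distance_um[pp$category == "to_other"]
    if (length(d_self) < min_self_pairs || length(d_other) < 1) next
    p <- suppressWarnings(
      stats::wilcox.test(d_self, d_other, alternative = "less")$p.value)
    res[[length(res) + 1]] <- data.frame(
      subclass = s, n_self = length(d_self), n_other = length(d_other),
      p = p, stringsAsFactors = FALSE)
  }
  if (length(res) == 0) {
    warning("no subclass passed the self-pair gate; empty result")
    return(data.frame(subclass = character(0), n_self = integer(0),
                      n_other = integer(0), p = numeric(0), fdr = numeric(0)))
  }
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Two-component Gaussian mixture fit by EM
#'
#' Maximum-likelihood fit of a two-component univariate Gaussian mixture
#' via expectation-maximization with seeded restarts (a median split plus
#' random quantile splits). Component variances are floored to avoid
#' degenerate collapse; components are returned ordered by mean. The
#' per-iteration log-likelihood of the best start is recorded and is
#' non-decreasing.
#'
#' @param distances numeric observations (>= 10).
#' @param n_starts number of EM restarts.
#' @param seed integer seed for the random restarts.
#' @param max_iter,tol EM stopping controls.
#' @return a `mixture_fit`: weights, means, sds, loglik, converged,
#'   ll_trace.
#' @export
fit_two_gaussians <- function(distances, n_starts = 5, seed = 1,
                              max_iter = 500, tol = 1e-8) {
  x <- as.numeric(distances)
  if (length(x) < 10) stop("mixture fitting needs at least 10 observations")
  n <- length(x)
  sdx <- stats::sd(x)
  if (sdx == 0) {
    out <- list(weights = c(0.5, 0.5), means = c(x[1], x[1]),
                sds = rep(1e-6, 2), loglik = sum(stats::dnorm(x, x[1], 1e-6, log = TRUE) + log(0.5)),
                converged = TRUE, ll_trace = numeric(0))
    class(out) <- "mixture_fit"
    return(out)
  }
  var_floor <- max(1e-12, (1e-3 * sdx)^2)
  loglik_of <- function(w, mu, sg) {
    la <- stats::dnorm(x, mu[1], sg[1], log = TRUE) + log(w[1])
    lb <- stats::dnorm(x, mu[2], sg[2], log = TRUE) + log(w[2])
    m <- pmax(la, lb)
    sum(m + log(exp(la - m) + exp(lb - m)))
  }
  run_em <- function(mu0, sg0, w0) {
    w <- w0; mu <- mu0; sg <- sg0
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      la <- stats::dnorm(x, mu[1], sg[1], log = TRUE) + log(w[1])
      lb <- stats::dnorm(x, mu[2], sg[2], log = TRUE) + log(w[2])
      m <- pmax(la, lb)
      denom <- exp(la - m) + exp(lb - m)
      r1 <- exp(la - m) / denom
      r2 <- 1 - r1
      n1 <- sum(r1); n2 <- sum(r2)
      if (n1 < 1e-10 || n2 < 1e-10) break
      w <- c(n1, n2) / n
      mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
      sg <- sqrt(pmax(c(sum(r1 * (x - mu[1])^2) / n1,
                        sum(r2 * (x - mu[2])^2) / n2), var_floor))
      ll <- loglik_of(w, mu, sg)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_prev) && ll - ll_prev < tol * (abs(ll_prev) + 1)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    list(w = w, mu = mu, sg = sg,
         ll = if (length(ll_trace)) ll_trace[length(ll_trace)] else -Inf,
         ll_trace = ll_trace, converged = converged)
  }
  starts <- list(list(split = stats::median(x)))
  extra <- with_seed(stage_seed(seed, "gmm_starts"), {
    lapply(seq_len(max(0, n_starts - 1)), function(i) {
      list(split = stats::quantile(x, stats::runif(1, 0.15, 0.85), names = FALSE))
    })
  })
  starts <- c(starts, extra)
  best <- NULL
  for (s in starts) {
    lo <- x <= s$split
    if (sum(lo) < 2 || sum(!lo) < 2) {
      o <- order(x)
      lo <- seq_len(n) %in% o[seq_len(max(2, floor(n / 2)))]
    }
    mu0 <- c(mean(x[lo]), mean(x[!lo]))
    sg0 <- sqrt(pmax(c(stats::var(x[lo]), stats::var(x[!lo])), var_floor))
    sg0[!is.finite(sg0)] <- sdx
    fit <- run_em(mu0, sg0, c(mean(lo), mean(!lo)))
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  o <- order(best$mu)
  out <- list(weights = best$w[o], means = best$mu[o], sds = best$sg[o],
              loglik = best$ll, converged = best$converged,
              ll_trace = best$ll_trace)
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("two-Gaussian mixture: w = (%.3f, %.3f), mu = (%.2f, %.2f), sd = (%.2f, %.2f), loglik = %.2f%s\n",
              x$weights[1], x$weights[2], x$means[1], x$means[2],
              x$sds[1], x$sds[2], x$loglik,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}
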