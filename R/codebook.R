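# Codebook handling: the table mapping genes (and blank controls) to
# fixed-length binary barcodes read out over sequential imaging bits.
# Blank barcodes are valid codewords assigned to no gene; molecules decoded
# as blanks estimate the misidentification rate downstream.

new_codebook <- function(name, barcode, is_blank) {
  name <- as.character(name)
  barcode <- as.character(barcode)
  is_blank <- as.logical(is_blank)
  n <- length(name)
  if (n == 0) stop("codebook has no entries")
  if (length(unique(nchar(barcode))) != 1) {
    stop("ragged barcode lengths: all barcodes must have the same number of bits")
  }
  if (any(grepl("[^01]", barcode))) {
    stop("barcodes must be strings of 0/1")
  }
  n_bits <- nchar(barcode[1])
  dup <- duplicated(barcode) | duplicated(barcode, fromLast = TRUE)
  if (any(dup)) {
    d <- which(dup)[1:2]
    stop(sprintf("duplicate barcode '%s' shared by entries '%s' and '%s'",
                 barcode[d[1]], name[d[1]], name[d[2]]))
  }
  W <- t(vapply(strsplit(barcode, ""),
                function(b) as.numeric(b == "1"), numeric(n_bits)))
  wt <- rowSums(W)
  if (any(wt == 0)) {
    stop(sprintf("all-zero barcode for entry '%s': each barcode needs at least one ON bit",
                 name[which(wt == 0)[1]]))
  }
  if (!any(!is_blank)) stop("codebook must contain at least one non-blank entry")
  cb <- list(
    entries = data.frame(name = name, barcode = barcode, is_blank = is_blank,
                         stringsAsFactors = FALSE),
    n_bits = as.integer(n_bits),
    barcode_matrix = W,
    unit_vectors = W / sqrt(wt)
  )
  class(cb) <- "merfish_codebook"
  cb
}

#' Load a codebook from CSV
#'
#' Reads a codebook table with columns `name`, `barcode` (a 0/1 string,
#' first character = bit 1 = first imaging bit) and `is_blank`, validates
#' it, and precomputes the L2-unit-normalized barcode vectors used by the
#' pixel decoder. Entry order is preserved.
#'
#' @param path path to the CSV file.
#' @return a `merfish_codebook` object.
#' @export
load_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(barcode = "character"))
  need <- c("name", "barcode", "is_blank")
  if (!all(need %in% names(tab))) {
    stop("codebook CSV must have columns name, barcode, is_blank")
  }
  new_codebook(tab$name, tab$barcode, tab$is_blank)
}

#' Write a codebook to CSV
#'
#' Mirrors [load_codebook()] bit-exactly: a written codebook reloads to an
#' identical object.
#' @param cb a `merfish_codebook`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "merfish_codebook"))
  utils::write.csv(cb$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Unit-normalized barcode vectors
#'
#' Each barcode, viewed as a 0/1 vector over the imaging bits, divided by
#' its L2 norm; the decoder compares these against unit-normalized pixel
#' intensity vectors.
#' @param cb a `merfish_codebook`.
#' @return numeric matrix, one unit row vector per entry.
#' @export
unit_barcode_vectors <- function(cb) {
  stopifnot(inherits(cb, "merfish_codebook"))
  cb$unit_vectors
}

n_blank_entries <- function(cb) sum(cb$entries$is_blank)
n_coding_entries <- function(cb) sum(!cb$entries$is_blank)

#' @export
print.merfish_codebook <- function(x, ...) {
  cat(sprintf("MERFISH codebook: %d entries (%d coding, %d blank), %d bits\n",
              nrow(x$entries), n_coding_entries(x), n_blank_entries(x), x$n_bits))
  invisible(x)
}

#' Generate a constant-weight codebook with a minimum Hamming distance
#'
#' Seeded greedy random search (with restarts) for a set of constant-weight
#' binary words at pairwise Hamming distance >= `min_hd`. The first
#' `n_coding` selected words become gene entries (`Gene-001`, ...) and the
#' next `n_blank` become blank controls (`Blank-1`, ...). Deterministic for
#' a fixed seed. This is a test/simulation generator, not an optimal
#' error-correcting-code designer.
#'
#' @param n_bits barcode length.
#' @param weight number of ON bits per barcode.
#' @param min_hd minimum pairwise Hamming distance.
#' @param n_coding,n_blank number of gene / blank entries.
#' @param seed integer seed.
#' @param n_restarts greedy restarts before giving up.
#' @return a `merfish_codebook`.
#' @export
synth_codebook <- function(n_bits, weight, min_hd, n_coding, n_blank,
                           seed = 1, n_restarts = 25) {
  stopifnot(n_bits >= 1, weight >= 1, weight <= n_bits,
            n_coding >= 1, n_blank >= 0, min_hd >= 0)
  n_want <- n_coding + n_blank
  n_words <- choose(n_bits, weight)
  # enumerate candidates when feasible, otherwise sample a large seeded pool
  if (n_words <= 2e5) {
    comb <- utils::combn(n_bits, weight)
    cand <- matrix(0, ncol(comb), n_bits)
    cand[cbind(rep(seq_len(ncol(comb)), each = weight), as.vector(comb))] <- 1
  } else {
    cand <- with_seed(stage_seed(seed, "codebook_pool"), {
      t(replicate(2e5, {
        v <- numeric(n_bits)
        v[sample.int(n_bits, weight)] <- 1
        v
      }))
    })
    cand <- cand[!duplicated(cand), , drop = FALSE]
  }
  best_found <- 0
  pick <- NULL
  for (r in seq_len(n_restarts)) {
    ord <- with_seed(stage_seed(seed, paste0("codebook_try", r)),
                     sample.int(nrow(cand)))
    kept <- integer(0)
    K <- matrix(0, 0, n_bits)
    for (i in ord) {
      w <- cand[i, ]
      if (nrow(K) > 0) {
        # constant weight: HD = 2 * (weight - overlap)
        hd <- 2 * (weight - as.vector(K %*% w))
        if (any(hd < min_hd)) next
      }
      kept <- c(kept, i)
      K <- rbind(K, w)
      if (length(kept) == n_want) break
    }
    best_found <- max(best_found, length(kept))
    if (length(kept) == n_want) {
      pick <- K
      break
    }
  }
  if (is.null(pick)) {
    stop(sprintf(paste0("cannot build %d words of weight %d at Hamming distance ",
                        ">= %d in %d bits: best search found only %d"),
                 n_want, weight, min_hd, n_bits, best_found))
  }
  words <- apply(pick, 1, function(v) paste(as.integer(v), collapse = ""))
  name <- c(sprintf("Gene-%03d", seq_len(n_coding)),
            if (n_blank > 0) sprintf("Blank-%d", seq_len(n_blank)))
  new_codebook(name, words, c(rep(FALSE, n_coding), rep(TRUE, n_blank)))
}
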