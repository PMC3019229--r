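## Site-level feature construction.
##
## Each candidate site is described by 20 scalars: the seed-type one-hot
## (9), the duplex alignment's total and positions-13-16 pairing scores,
## AU fraction within 30 nt upstream and downstream of the seed match,
## log-scaled distance from the stop codon and to the nearest UTR end,
## relative position within the UTR, log UTR length, a binary long-UTR
## (> 2000 nt) flag, the AU fraction of the seed match itself, and the GC
## fraction of the 20-nt site region. Distances and lengths use
## log10(1 + x) to bound the dynamic range before min/max normalization.

SITE_FEATURE_NAMES <- c(
  paste0("st_", c("8mer", "7mer-A1", "7mer-m8", "6mer",
                  "GUM", "GUT", "LP", "BM", "BT")),
  "duplex_total", "duplex_13_16",
  "au_up_30", "au_down_30",
  "log_dist_stop", "log_dist_end", "rel_pos",
  "log_utr_len", "long_utr_flag",
  "seed_au", "site_gc")

SITE_SCHEMA_VERSION <- "site-features-1"

FEATURE_GROUPS <- list(
  seed_type = paste0("st_", c("8mer", "7mer-A1", "7mer-m8", "6mer",
                              "GUM", "GUT", "LP", "BM", "BT")),
  duplex = c("duplex_total", "duplex_13_16"),
  au_context = c("au_up_30", "au_down_30"),
  position = c("log_dist_stop", "log_dist_end", "rel_pos"),
  utr_length = c("log_utr_len", "long_utr_flag"),
  composition = c("seed_au", "site_gc"))

frac_of <- function(codes, bases) {
  if (!length(codes)) return(0.5) # empty window: uninformative midpoint
  mean(codes %in% bases)
}

#' Compute the raw feature vector for one target site
#'
#' @param seed_type,seed_start,seed_end site fields (1-based inclusive UTR
#'   coordinates of the seed match).
#' @param utr the transcript's 3' UTR sequence.
#' @param mirna the miRNA sequence.
#' @param duplex optional precomputed [align_duplex()] result.
#' @return named numeric vector of length 20 (see
#'   `mirsvm:::SITE_FEATURE_NAMES`).
#' @export
compute_site_features <- function(seed_type, seed_start, seed_end, utr,
                                  mirna, duplex = NULL) {
  u <- encode_rna(normalize_rna(utr, "utr"))
  L <- length(u)
  if (is.null(duplex)) {
    duplex <- align_duplex(mirna, seed_type, seed_start, utr)
  }
  onehot <- as.numeric(SEED_TYPE_NAMES == seed_type)
  if (sum(onehot) != 1) stop("unknown seed type: ", seed_type)

  up <- if (seed_start > 1L) u[max(1L, seed_start - 30L):(seed_start - 1L)]
        else integer(0)
  down <- if (seed_end < L) u[(seed_end + 1L):min(L, seed_end + 30L)]
          else integer(0)
  au <- c(1L, 4L)
  site_end <- if (seed_type %in% c("8mer", "7mer-A1")) seed_end
              else min(L, seed_end + 1L)
  site_region <- u[max(1L, site_end - 19L):site_end]

  v <- c(onehot,
         duplex$total_score,
         duplex$score_13_16,
         frac_of(up, au),
         frac_of(down, au),
         log10(seed_start),                       # log10(1 + dist from stop)
         log10(1 + min(seed_start - 1L, L - seed_end)),
         seed_start / L,
         log10(1 + L),
         as.numeric(L > 2000L),
         frac_of(u[seed_start:seed_end], au),
         frac_of(site_region, c(2L, 3L)))
  names(v) <- SITE_FEATURE_NAMES
  v
}

#' Build the site feature matrix for a resolved site table
#'
#' Runs the duplex aligner and [compute_site_features()] for every site.
#'
#' @param sites resolved site table (see [scan_pairs()]).
#' @param mirnas,utrs named character vectors of sequences.
#' @return numeric matrix, one row per site, columns in the fixed feature
#'   order.
#' @export
site_feature_matrix <- function(sites, mirnas, utrs) {
  n <- nrow(sites)
  out <- matrix(0, n, length(SITE_FEATURE_NAMES),
                dimnames = list(NULL, SITE_FEATURE_NAMES))
  if (!n) return(out)
  for (i in seq_len(n)) {
    out[i, ] <- compute_site_features(
      sites$seed_type[i], sites$seed_start[i], sites$seed_end[i],
      utrs[[sites$transcript_id[i]]], mirnas[[sites$mirna_id[i]]])
  }
  out
}

#' Fit a per-feature min/max normalizer
#'
#' Records each feature's minimum and maximum over the training vectors; the
#' derived transform maps the training range linearly onto \[-1, 1\].
#'
#' @param x numeric matrix of raw feature vectors (rows = observations,
#'   named columns).
#' @return object of class `mirsvm_normalizer`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("cannot fit a normalizer on zero vectors")
  if (is.null(colnames(x))) stop("feature columns must be named")
  out <- list(min = apply(x, 2L, min), max = apply(x, 2L, max),
              features = colnames(x))
  class(out) <- "mirsvm_normalizer"
  out
}

#' Apply a fitted normalizer
#'
#' Maps each feature with `v' = 2 (v - min) / (max - min) - 1`. Values
#' outside the training range are clamped to \[-1, 1\], and a degenerate
#' feature (max = min on the training data) maps to 0.
#'
#' @param norm a `mirsvm_normalizer`.
#' @param x raw feature matrix (or single named vector) with the same
#'   feature columns.
#' @return normalized matrix in \[-1, 1\].
#' @export
apply_normalizer <- function(norm, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !identical(colnames(x), norm$features)) {
    stop("feature names do not match the fitted normalizer")
  }
  rng <- norm$max - norm$min
  out <- x
  for (j in seq_along(norm$features)) {
    if (rng[j] == 0) {
      out[, j] <- 0
    } else {
      out[, j] <- pmin(1, pmax(-1, 2 * (x[, j] - norm$min[j]) / rng[j] - 1))
    }
  }
  out
}

#' @export
print.mirsvm_normalizer <- function(x, ...) {
  cat(sprintf("min/max normalizer for %d features -> [-1, 1]\n",
              length(x$features)))
  invisible(x)
}
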