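## mRNA-level feature construction.
##
## The number of target sites varies between genes but the SVM needs a
## fixed-length vector, so each gene's site discriminant values are encoded
## as a 16-bin distribution: one bin counts lower-extreme values (more than
## two standard deviations below the training distribution's mean), 14 bins
## cover percentile ranges of the extreme-trimmed distribution with high
## resolution in the upper tail (25.00, 43.75, 57.81, 68.36, 76.27, 82.20,
## 86.65, 89.99, 92.49, 94.37, 95.78, 97.19, 98.6 and 100 percentiles), and
## one bin counts upper-extreme values. The remaining features describe site
## count, UTR length, site density, a binary "< 7 sites" flag, site spacing
## (cooperative sites sit 17-35 nt apart), and the strongest single site.

BINNER_PERCENTILES <- c(25.00, 43.75, 57.81, 68.36, 76.27, 82.20, 86.65,
                        89.99, 92.49, 94.37, 95.78, 97.19, 98.6, 100) / 100

MRNA_FEATURE_NAMES <- c(
  "n_extreme_low", paste0("bin_", sprintf("%02d", 1:14)), "n_extreme_high",
  "n_sites", "log_utr_len", "site_density", "few_sites_flag",
  "n_pairs_17_35", "log_min_pair_dist", "max_discriminant")

MRNA_SCHEMA_VERSION <- "mrna-features-1"

## Pairwise seed-start distances beyond this cap are uninformative; genes
## with a single site take the cap value.
MIN_PAIR_DIST_CAP <- 1000L

#' Fit the discriminant-value binner
#'
#' Computes the mean and standard deviation of the training discriminant
#' distribution, removes extremes (values more than two standard deviations
#' from the mean), and places 14 percentile cut points (linear interpolation
#' between order statistics) on the remainder.
#'
#' @param values training discriminant values (all sites pooled; >= 20).
#' @return object of class `discriminant_binner` with `mean`, `sd`, and 14
#'   non-decreasing `cuts`. A zero-variance input yields a degenerate binner
#'   whose interior mass falls in the first bin.
#' @export
fit_binner <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 20L) stop("need at least 20 discriminant values")
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0) {
    out <- list(mean = m, sd = 0, cuts = rep(m, 14L))
  } else {
    keep <- values >= m - 2 * s & values <= m + 2 * s
    out <- list(mean = m, sd = s,
                cuts = unname(stats::quantile(values[keep],
                                              probs = BINNER_PERCENTILES,
                                              type = 7)))
  }
  class(out) <- "discriminant_binner"
  out
}

#' @export
print.discriminant_binner <- function(x, ...) {
  cat(sprintf("discriminant binner: mean %.4g, sd %.4g\n", x$mean, x$sd))
  cat("  cuts:", paste(sprintf("%.3g", x$cuts), collapse = " "), "\n")
  invisible(x)
}

#' Bin a gene's site discriminants
#'
#' Counts how many of a gene's discriminant values fall below the lower
#' extreme threshold (mean - 2 sd), within each of the 14 percentile bins
#' (half-open, closed at the upper cut; a value exactly at a cut point goes
#' to the lower-indexed bin), or above the upper extreme threshold
#' (mean + 2 sd). Unseen values beyond the last cut but within the extreme
#' thresholds are clamped into the last interior bin, so the 16 counts
#' always sum to the number of values.
#'
#' @param binner a fitted [fit_binner()] object.
#' @param values a gene's site discriminant values (possibly empty).
#' @return integer vector of 16 counts.
#' @export
bin_values <- function(binner, values) {
  counts <- integer(16L)
  if (!length(values)) return(counts)
  lo <- binner$mean - 2 * binner$sd
  hi <- binner$mean + 2 * binner$sd
  for (v in as.numeric(values)) {
    if (v < lo) {
      counts[1L] <- counts[1L] + 1L
    } else if (v > hi) {
      counts[16L] <- counts[16L] + 1L
    } else {
      j <- which(v <= binner$cuts)
      j <- if (length(j)) j[1L] else 14L
      counts[1L + j] <- counts[1L + j] + 1L
    }
  }
  counts
}

#' Compute the mRNA-level feature vector for one gene
#'
#' @param seed_starts seed start coordinates of the gene's resolved sites.
#' @param discriminants the matching site discriminant values (out-of-fold
#'   values during training; final-model scores at prediction time).
#' @param utr_len 3' UTR length in nt.
#' @param binner a fitted [fit_binner()] object.
#' @return named numeric vector of 23 scalars.
#' @export
compute_mrna_features <- function(seed_starts, discriminants, utr_len,
                                  binner) {
  n <- length(discriminants)
  if (n == 0L) stop("gene has zero sites; exclude zero-site genes upstream")
  if (length(seed_starts) != n) {
    stop("seed_starts and discriminants lengths differ")
  }
  counts <- bin_values(binner, discriminants)
  if (n >= 2L) {
    d <- abs(as.numeric(stats::dist(matrix(seed_starts, ncol = 1L))))
    n_coop <- sum(d >= 17 & d <= 35)
    min_d <- min(d)
  } else {
    n_coop <- 0
    min_d <- MIN_PAIR_DIST_CAP
  }
  v <- c(counts,
         n,
         log10(1 + utr_len),
         n / utr_len,
         as.numeric(n < 7L),
         n_coop,
         log10(1 + min(min_d, MIN_PAIR_DIST_CAP)),
         max(discriminants))
  names(v) <- MRNA_FEATURE_NAMES
  v
}

#' Build per-gene mRNA feature matrix from a scored site table
#'
#' Groups a resolved, discriminant-scored site table by (transcript, miRNA)
#' pair and computes the mRNA-level features for every pair with at least
#' one site.
#'
#' @param sites site table with columns `transcript_id`, `mirna_id`,
#'   `seed_start`, `discriminant`.
#' @param utrs named character vector of UTR sequences.
#' @param binner a fitted [fit_binner()] object.
#' @return list with `meta` (data.frame: `transcript_id`, `mirna_id`,
#'   `n_sites`) and `x` (feature matrix, one row per pair).
#' @export
mrna_feature_matrix <- function(sites, utrs, binner) {
  key <- paste(sites$transcript_id, sites$mirna_id, sep = "\r")
  groups <- split(seq_len(nrow(sites)), key)
  ## order groups as first encountered, for reproducibility
  groups <- groups[unique(key)]
  n <- length(groups)
  x <- matrix(0, n, length(MRNA_FEATURE_NAMES),
              dimnames = list(NULL, MRNA_FEATURE_NAMES))
  meta <- data.frame(transcript_id = character(n), mirna_id = character(n),
                     n_sites = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    idx <- groups[[i]]
    tid <- sites$transcript_id[idx[1L]]
    meta$transcript_id[i] <- tid
    meta$mirna_id[i] <- sites$mirna_id[idx[1L]]
    meta$n_sites[i] <- length(idx)
    x[i, ] <- compute_mrna_features(sites$seed_start[idx],
                                    sites$discriminant[idx],
                                    nchar(utrs[[tid]]), binner)
  }
  list(meta = meta, x = x)
}

#' Assemble the labeled mRNA-level training set
#'
#' Positives are down-regulated genes with at least one resolved site.
#' Negatives are a random sample (up to `negative_cap`) of unaffected genes
#' with at least one site, plus up to `n_extra_high` randomly selected
#' unaffected genes with more than 7 sites. The extra high-site-count
#' negatives counteract the scarcity of true targets among genes with many
#' candidate sites, which plain random sampling under a training-set size
#' cap would otherwise under-represent.
#'
#' @param gene_features result of [mrna_feature_matrix()].
#' @param labels label table (see [read_label_table()]).
#' @param seed integer seed for the sampling.
#' @param negative_cap maximum number of base negatives (default 4000).
#' @param n_extra_high number of extra `> 7`-site negatives (default 1000;
#'   all such genes are used when fewer exist).
#' @return list with `x` (feature matrix), `y` (factor pos/neg), `meta`.
#' @export
assemble_training_set <- function(gene_features, labels, seed = 1L,
                                  negative_cap = 4000L,
                                  n_extra_high = 1000L) {
  meta <- gene_features$meta
  key <- paste(meta$transcript_id, meta$mirna_id, sep = "\r")
  lab_key <- paste(labels$transcript_id, labels$mirna_id, sep = "\r")
  lab <- labels$label[match(key, lab_key)]
  if (anyNA(lab)) stop("missing labels for ", sum(is.na(lab)), " gene(s)")

  pos <- which(lab == "down_regulated")
  if (!length(pos)) stop("no positive (down-regulated) genes with sites")
  neg_all <- which(lab == "unaffected")
  high <- neg_all[meta$n_sites[neg_all] > 7L]

  set.seed(seed)
  extra <- if (length(high) > n_extra_high) {
    sample(high, n_extra_high)
  } else high
  ## base negatives come from the <= 7-site pool; the > 7-site genes enter
  ## only through the explicit augmentation above
  rest <- setdiff(neg_all, high)
  base <- if (length(rest) > negative_cap) sample(rest, negative_cap) else rest
  neg <- sort(c(base, extra))

  sel <- c(pos, neg)
  list(x = gene_features$x[sel, , drop = FALSE],
       y = factor(c(rep("pos", length(pos)), rep("neg", length(neg))),
                  levels = c("pos", "neg")),
       meta = meta[sel, , drop = FALSE])
}
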