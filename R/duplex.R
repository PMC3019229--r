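## 3' supplementary pairing.
##
## The miRNA 3' region (positions 9 up to 20) is globally aligned against
## the UTR flank 5' of the seed match, i.e. the target bases that would sit
## opposite those miRNA positions in the duplex. Pairing is antiparallel, so
## the aligner works on the miRNA read 5'->3' and the flank read 3'->5',
## scoring each aligned column by its base-pair class: Watson-Crick +5,
## G:U wobble +1, other mismatch -4; affine gaps cost 10 to open plus 0.5
## per gapped position. These are EMBOSS-needle-like gap penalties with a
## complementarity-based substitution scheme, exposed in the package config.

DUPLEX_DEFAULTS <- list(match = 5, gu = 1, mismatch = -4,
                        gap_open = 10, gap_ext = 0.5)

## Pair score between a miRNA base and a target base (integer codes)
pair_score <- function(q, t, par) {
  cls <- PAIR_CLASS[cbind(t, q)]
  ifelse(cls == 0L, par$match, ifelse(cls == 3L, par$mismatch, par$gu))
}

## Global affine-gap alignment of integer-coded a (miRNA side) vs b (target
## side, already reversed so b[1] pairs a[1]). Traceback prefers diagonal,
## then up (gap in b), then left (gap in a). Returns aligned index vectors
## (0 = gap) and the total score.
nw_pair_align <- function(a, b, par = DUPLEX_DEFAULTS) {
  n <- length(a); m <- length(b)
  go <- par$gap_open; ge <- par$gap_ext
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L) # ends with a[i] over gap
  Y <- matrix(NEG, n + 1L, m + 1L) # ends with gap over b[j]
  M[1L, 1L] <- 0
  if (n >= 1L) X[2:(n + 1L), 1L] <- -(go + ge * (1:n))
  if (m >= 1L) Y[1L, 2:(m + 1L)] <- -(go + ge * (1:m))
  for (i in seq_len(n)) {
    si <- pair_score(rep(a[i], m), b, par)
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- si[j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - (go + ge),
                               X[i, j + 1L] - ge,
                               Y[i, j + 1L] - (go + ge))
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - (go + ge),
                               Y[i + 1L, j] - ge,
                               X[i + 1L, j] - (go + ge))
    }
  }
  total <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  ## traceback, preferring diagonal, then up, then left (and the same order
  ## when choosing the predecessor state)
  ai <- integer(0); bi <- integer(0)
  i <- n; j <- m
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  eq <- function(x, y) abs(x - y) < 1e-9
  while (i > 0L || j > 0L) {
    if (state == 1L) { # M: a[i] paired with b[j]
      ai <- c(i, ai); bi <- c(j, bi)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(eq(prev, max(prev)))
    } else if (state == 2L) { # X: a[i] over gap
      ai <- c(i, ai); bi <- c(0L, bi)
      cand <- c(M[i, j + 1L] - (go + ge), X[i, j + 1L] - ge,
                Y[i, j + 1L] - (go + ge))
      i <- i - 1L
      state <- which.max(eq(cand, max(cand)))
    } else { # Y: gap over b[j]
      ai <- c(0L, ai); bi <- c(j, bi)
      cand <- c(M[i + 1L, j] - (go + ge), X[i + 1L, j] - (go + ge),
                Y[i + 1L, j] - ge)
      j <- j - 1L
      state <- which.max(eq(cand, max(cand)))
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  list(ai = ai, bi = bi, total = total)
}

## UTR flank coordinates for a site: bases opposite miRNA positions
## 9..min(L, 20), immediately 5' of the seed match. For the 6-nt seed span
## types (6mer, 7mer-A1) miRNA position 8 is unpaired and one spacer base is
## skipped.
flank_range <- function(seed_type, seed_start, mirna_len) {
  skip <- if (seed_type %in% c("6mer", "7mer-A1")) 1L else 0L
  n_flank <- max(0L, min(mirna_len, 20L) - 8L)
  flank_end <- seed_start - 1L - skip
  flank_start <- max(1L, flank_end - n_flank + 1L)
  if (flank_end < flank_start) return(c(1L, 0L))
  c(flank_start, flank_end)
}

#' Align a miRNA 3' region to a site's upstream flank
#'
#' Quantifies supplementary pairing between miRNA positions 9-20 and the UTR
#' bases 5' of the seed match via a global Needleman-Wunsch alignment
#' (Watson-Crick +5, G:U +1, mismatch -4, gap open 10, gap extend 0.5).
#' `score_13_16` restricts the pairing score to alignment columns whose
#' miRNA base originates from positions 13-16, the region with the strongest
#' known contribution to supplementary pairing.
#'
#' @param mirna miRNA sequence, 5' to 3' RNA.
#' @param seed_type seed type name of the site.
#' @param seed_start 1-based UTR coordinate of the seed match start.
#' @param utr the UTR sequence.
#' @param par scoring parameters; see `DUPLEX_DEFAULTS` in the source.
#' @return list of class `duplex_alignment` with `aligned_mirna`,
#'   `aligned_target_rc` (reverse-complemented flank, gapped), `total_score`,
#'   and `score_13_16`. An empty flank yields a zero-score alignment.
#' @export
align_duplex <- function(mirna, seed_type, seed_start, utr,
                         par = DUPLEX_DEFAULTS) {
  m <- encode_rna(normalize_rna(mirna, "mirna"))
  u <- encode_rna(normalize_rna(utr, "utr"))
  L <- length(m)
  a <- if (L >= 9L) m[9L:min(L, 20L)] else integer(0)
  fr <- flank_range(seed_type, seed_start, L)
  b_target <- if (fr[2L] >= fr[1L]) rev(u[fr[1L]:fr[2L]]) else integer(0)

  if (length(a) == 0L || length(b_target) == 0L) {
    res <- list(aligned_mirna = decode_rna(a),
                aligned_target_rc = "",
                total_score = 0, score_13_16 = 0)
    class(res) <- "duplex_alignment"
    return(res)
  }
  al <- nw_pair_align(a, b_target, par)
  mir_chars <- ifelse(al$ai == 0L, "-", RNA_BASES[a[pmax(al$ai, 1L)]])
  ## reverse complement of the flank, column-wise
  rc_chars <- ifelse(al$bi == 0L, "-",
                     RNA_BASES[WC_PARTNER[b_target[pmax(al$bi, 1L)]]])
  ## pairing score restricted to columns from miRNA positions 13-16
  paired <- al$ai > 0L & al$bi > 0L
  mir_pos <- ifelse(al$ai > 0L, 8L + al$ai, NA_integer_)
  sel <- paired & !is.na(mir_pos) & mir_pos >= 13L & mir_pos <= 16L
  s1316 <- if (any(sel)) {
    sum(pair_score(a[al$ai[sel]], b_target[al$bi[sel]], par))
  } else 0
  res <- list(aligned_mirna = paste(mir_chars, collapse = ""),
              aligned_target_rc = paste(rc_chars, collapse = ""),
              total_score = al$total, score_13_16 = s1316)
  class(res) <- "duplex_alignment"
  res
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat("duplex alignment (miRNA 3' region vs site flank)\n")
  cat("  miRNA 9->:", x$aligned_mirna, "\n")
  cat("  target rc:", x$aligned_target_rc, "\n")
  cat(sprintf("  total score %.1f; positions 13-16 score %.1f\n",
              x$total_score, x$score_13_16))
  invisible(x)
}
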