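## Seed-match scanning.
##
## Nine seed types are recognised in a 3' UTR, all anchored on the miRNA
## seed (5' positions 2-7, extendable to 8). Pairing is antiparallel, so a
## UTR window read 5'->3' pairs the miRNA seed read 3'->5': the leftmost
## window base sits opposite the highest miRNA position, and the base
## opposite miRNA position 1 is the UTR base immediately 3' of the window.
##
## Exact/wobble/loop types are defined over miRNA positions 2-8 (2-7 for the
## 6-nt types) with at most one defect; bulge types add or remove one base.
## The defect may not sit at a seed-terminal position (a terminal bulge or
## loop is indistinguishable from a shorter exact match).

SEED_TYPE_NAMES <- c("8mer", "7mer-A1", "7mer-m8", "6mer",
                     "GUM", "GUT", "LP", "BM", "BT")
SEED_PRECEDENCE <- c("8mer" = 0L, "7mer-A1" = 0L, "7mer-m8" = 0L,
                     "6mer" = 0L, "GUM" = 1L, "GUT" = 2L, "LP" = 3L,
                     "BM" = 4L, "BT" = 5L)
SEED_GROUP <- c("8mer" = "stringent", "7mer-A1" = "stringent",
                "7mer-m8" = "stringent", "6mer" = "non_stringent",
                "GUM" = "non_stringent", "GUT" = "non_stringent",
                "LP" = "non_stringent", "BM" = "non_stringent",
                "BT" = "non_stringent")

## First 1-based UTR position at which a seed match may start: sites are
## excluded from the first 15 nt after the stop codon.
MIN_SEED_START <- 16L

#' Seed type table
#'
#' The nine seed-match definitions with their group and overlap precedence.
#' Lower `precedence` wins when overlapping sites conflict; the four
#' rank-0 types (8mer, 7mer-A1, 7mer-m8, 6mer) are additionally allowed to
#' overlap each other.
#'
#' @return data.frame with columns `name`, `group`, `precedence`.
#' @export
seed_types <- function() {
  data.frame(name = SEED_TYPE_NAMES,
             group = unname(SEED_GROUP[SEED_TYPE_NAMES]),
             precedence = unname(SEED_PRECEDENCE[SEED_TYPE_NAMES]),
             stringsAsFactors = FALSE)
}

## Seed-match length on the target for each type
seed_match_len <- function(type) {
  c("8mer" = 8L, "7mer-A1" = 7L, "7mer-m8" = 7L, "6mer" = 6L,
    "GUM" = 7L, "GUT" = 7L, "LP" = 7L, "BM" = 6L, "BT" = 8L)[type]
}

## Window length (paired region, excluding the position-1 A) per type
seed_window_len <- function(type) {
  c("8mer" = 7L, "7mer-A1" = 6L, "7mer-m8" = 7L, "6mer" = 6L,
    "GUM" = 7L, "GUT" = 7L, "LP" = 7L, "BM" = 6L, "BT" = 8L)[type]
}

#' Classify one UTR window against a miRNA seed
#'
#' Determines which, if any, of the nine seed types a UTR window satisfies,
#' returning the single highest-precedence type. The window is the stretch of
#' target bases paired with the miRNA seed, read 5' to 3' on the UTR;
#' `next_upstream_base` is the UTR base immediately 3' of the window, which
#' sits opposite miRNA position 1 and upgrades a perfect match to 7mer-A1 or
#' 8mer when it is an A.
#'
#' Definitions (all pairing antiparallel, "WC" = Watson-Crick):
#' \itemize{
#'   \item 6mer: WC complement of miRNA 2-7 (6-nt window).
#'   \item 7mer-m8: WC complement of miRNA 2-8 (7-nt window).
#'   \item 7mer-A1 / 8mer: the above with target A opposite position 1.
#'   \item GUM / GUT: miRNA 2-8 with exactly one G:U wobble, the U on the
#'     miRNA (GUM) or on the target (GUT); all other positions WC.
#'   \item LP: miRNA 2-8 with exactly one internal (positions 3-7) non-WC,
#'     non-G:U mismatch.
#'   \item BM: one internal miRNA seed base (positions 3-7) unpaired; the
#'     6-nt window WC-pairs the remaining positions of 2-8.
#'   \item BT: one extra unpaired target base inside the match; the 8-nt
#'     window minus that base WC-pairs miRNA 2-8.
#' }
#'
#' @param mirna miRNA sequence, 5' to 3' RNA (length >= 8).
#' @param window UTR window, 5' to 3' RNA, 6-8 nt.
#' @param next_upstream_base single UTR base 3' of the window, or `NULL`.
#' @return seed type name, or `NA_character_` if no definition is met.
#' @examples
#' classify_window("UAGCUUAUCAGACUGAUGUUGA", "AUAAGCU", "A")  # 8mer
#' @export
classify_window <- function(mirna, window, next_upstream_base = NULL) {
  m <- encode_rna(normalize_rna(mirna, "mirna"))
  if (length(m) < 8L) stop("miRNA shorter than 8 nt")
  w <- encode_rna(normalize_rna(window, "window"))
  nw <- length(w)
  up_a <- !is.null(next_upstream_base) && length(next_upstream_base) == 1L &&
    !is.na(next_upstream_base) && nzchar(next_upstream_base) &&
    toupper(next_upstream_base) == "A"
  if (nw < 6L || nw > 8L) return(NA_character_)

  cls7 <- function(w) PAIR_CLASS[cbind(w, m[8:2])] # window vs positions 8..2
  if (nw == 7L) {
    cl <- cls7(w)
    n_wc <- sum(cl == 0L)
    if (n_wc == 7L) return(if (up_a) "8mer" else "7mer-m8")
    if (n_wc == 6L) {
      d <- which(cl != 0L)
      if (cl[d] == 1L) return("GUM")
      if (cl[d] == 2L) return("GUT")
      ## loop must be internal: window index d pairs miRNA position 9 - d
      if (cl[d] == 3L && (9L - d) >= 3L && (9L - d) <= 7L) return("LP")
    }
    return(NA_character_)
  }
  if (nw == 6L) {
    cl6 <- PAIR_CLASS[cbind(w, m[7:2])]
    if (all(cl6 == 0L)) return(if (up_a) "7mer-A1" else "6mer")
    ## BM: miRNA position b in 3..7 bulged out, rest of 2-8 WC-paired
    for (b in 3:7) {
      patt <- m[setdiff(8:2, b)]
      if (all(PAIR_CLASS[cbind(w, patt)] == 0L)) return("BM")
    }
    return(NA_character_)
  }
  ## nw == 8: BT, inserted target base at an internal window offset
  for (p in 2:7) {
    if (all(PAIR_CLASS[cbind(w[-p], m[8:2])] == 0L)) return("BT")
  }
  NA_character_
}

## Among the four rank-0 types, a seed match fully contained in another
## rank-0 match is the same pairing reported at a shorter type (every 8mer
## contains a 7mer-A1, for instance), so only the longest representative is
## kept; genuinely partial overlaps among rank-0 sites remain allowed.
filter_contained_rank0 <- function(sites) {
  idx0 <- which(sites$precedence == 0L)
  if (length(idx0) <= 1L) return(sites)
  s <- sites[idx0, , drop = FALSE]
  len <- s$seed_end - s$seed_start + 1L
  ord <- order(-len, match(s$seed_type, SEED_TYPE_NAMES), s$seed_start)
  kept <- integer(0)
  drop <- logical(nrow(s))
  for (i in ord) {
    contained <- FALSE
    for (k in kept) {
      if (s$seed_start[k] <= s$seed_start[i] &&
          s$seed_end[k] >= s$seed_end[i]) {
        contained <- TRUE
        break
      }
    }
    if (contained) drop[i] <- TRUE else kept <- c(kept, i)
  }
  if (!any(drop)) return(sites)
  sites[-idx0[drop], , drop = FALSE]
}

## Empty site table with the canonical column set
empty_sites <- function() {
  data.frame(transcript_id = character(0), mirna_id = character(0),
             seed_type = character(0), seed_start = integer(0),
             seed_end = integer(0), precedence = integer(0),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate seed-match sites in a 3' UTR
#'
#' Scans every UTR window of 6-8 nt whose seed match starts at position
#' `>= 16` (sites within the first 15 nt after the stop codon are excluded)
#' and reports every window that satisfies a seed-type definition, labelled
#' with its highest-precedence type. Overlaps are not resolved here; see
#' [resolve_overlaps()].
#'
#' Coordinates are 1-based inclusive on the UTR. `seed_start`/`seed_end`
#' delimit the seed match on the target, including the A opposite miRNA
#' position 1 for 8mer and 7mer-A1 sites.
#'
#' Within the rank-0 group (8mer, 7mer-A1, 7mer-m8, 6mer) a match whose
#' seed interval is fully contained in another rank-0 match is the same
#' pairing at a shorter type and is not reported separately; partial
#' overlaps are kept.
#'
#' @param mirna miRNA sequence, 5' to 3' (DNA or RNA; normalized).
#' @param utr 3' UTR sequence, 5' to 3' starting after the stop codon.
#' @param mirna_id,transcript_id identifiers copied into the output.
#' @return data.frame of candidate sites in left-to-right order with columns
#'   `transcript_id`, `mirna_id`, `seed_type`, `seed_start`, `seed_end`,
#'   `precedence`.
#' @export
scan_candidate_sites <- function(mirna, utr, mirna_id = "mirna",
                                 transcript_id = "utr") {
  m <- encode_rna(normalize_rna(mirna, mirna_id))
  if (length(m) < 16L) stop("miRNA shorter than 16 nt: ", mirna_id)
  u <- encode_rna(normalize_rna(utr, transcript_id))
  L <- length(u)
  if (L < MIN_SEED_START + 5L) return(empty_sites())

  hits_start <- integer(0); hits_type <- character(0); hits_end <- integer(0)
  add <- function(starts, type, match_len) {
    if (length(starts)) {
      hits_start <<- c(hits_start, starts)
      hits_end <<- c(hits_end, starts + match_len - 1L)
      hits_type <<- c(hits_type, rep(type, length(starts)))
    }
  }

  ## --- 7-nt windows (miRNA 2-8) ---
  s7 <- MIN_SEED_START:(L - 6L)
  if (length(s7) && s7[1L] <= s7[length(s7)]) {
    n <- length(s7)
    n_wc <- integer(n); n_gum <- integer(n); n_gut <- integer(n)
    n_mm <- integer(n); n_mm_int <- integer(n)
    for (j in 0:6) {
      cl <- PAIR_CLASS[cbind(u[s7 + j], m[8L - j])]
      n_wc <- n_wc + (cl == 0L)
      n_gum <- n_gum + (cl == 1L)
      n_gut <- n_gut + (cl == 2L)
      mm <- (cl == 3L)
      n_mm <- n_mm + mm
      if ((8L - j) >= 3L && (8L - j) <= 7L) n_mm_int <- n_mm_int + mm
    }
    perfect <- n_wc == 7L
    ## 8mer needs target A opposite miRNA position 1 (3' of the window)
    up_a <- (s7 + 7L) <= L & u[pmin(s7 + 7L, L)] == 1L
    add(s7[perfect & up_a], "8mer", 8L)
    add(s7[perfect & !up_a], "7mer-m8", 7L)
    one_off <- n_wc == 6L
    add(s7[one_off & n_gum == 1L], "GUM", 7L)
    add(s7[one_off & n_gut == 1L], "GUT", 7L)
    add(s7[one_off & n_mm == 1L & n_mm_int == 1L], "LP", 7L)
  }

  ## --- 6-nt windows (miRNA 2-7 exact, or 2-8 with one bulged miRNA base) ---
  s6 <- MIN_SEED_START:(L - 5L)
  if (length(s6)) {
    n <- length(s6)
    wc6 <- rep(TRUE, n)
    for (j in 0:5) wc6 <- wc6 & (PAIR_CLASS[cbind(u[s6 + j], m[7L - j])] == 0L)
    up_a <- (s6 + 6L) <= L & u[pmin(s6 + 6L, L)] == 1L
    add(s6[wc6 & up_a], "7mer-A1", 7L)
    add(s6[wc6 & !up_a], "6mer", 6L)
    bm <- rep(FALSE, n)
    for (b in 3:7) {
      patt <- m[setdiff(8:2, b)]
      ok <- rep(TRUE, n)
      for (j in 0:5) ok <- ok & (PAIR_CLASS[cbind(u[s6 + j], patt[j + 1L])] == 0L)
      bm <- bm | ok
    }
    add(s6[bm & !wc6], "BM", 6L)
  }

  ## --- 8-nt windows (one extra target base inside a 2-8 match) ---
  if (L - 7L >= MIN_SEED_START) {
    s8 <- MIN_SEED_START:(L - 7L)
    n <- length(s8)
    bt <- rep(FALSE, n)
    for (p in 2:7) {
      keep <- setdiff(1:8, p)
      ok <- rep(TRUE, n)
      for (k in seq_along(keep)) {
        ok <- ok & (PAIR_CLASS[cbind(u[s8 + keep[k] - 1L], m[9L - k])] == 0L)
      }
      bt <- bt | ok
    }
    add(s8[bt], "BT", 8L)
  }

  if (!length(hits_start)) return(empty_sites())
  out <- data.frame(transcript_id = transcript_id, mirna_id = mirna_id,
                    seed_type = hits_type, seed_start = hits_start,
                    seed_end = hits_end,
                    precedence = unname(SEED_PRECEDENCE[hits_type]),
                    stringsAsFactors = FALSE)
  out <- filter_contained_rank0(out)
  ord <- order(out$seed_start, match(out$seed_type, SEED_TYPE_NAMES),
               out$seed_end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping candidate sites by seed-type precedence
#'
#' Overlap (sharing at least one UTR position of the seed match) is only
#' allowed among the four rank-0 types (8mer, 7mer-A1, 7mer-m8, 6mer). Among
#' any other overlapping conflict the higher-precedence type survives
#' (8mer = 7mer-A1 = 7mer-m8 = 6mer > GUM > GUT > LP > BM > BT), with ties
#' broken by smaller `seed_start` and then the fixed type order. The result
#' is independent of the input row order, and resolving twice is a no-op.
#'
#' @param sites candidate site table for one (miRNA, transcript) pair, as
#'   returned by [scan_candidate_sites()].
#' @return the surviving sites, in left-to-right order.
#' @export
resolve_overlaps <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  sites <- filter_contained_rank0(sites)
  ord <- order(sites$precedence, sites$seed_start,
               match(sites$seed_type, SEED_TYPE_NAMES), sites$seed_end)
  s <- sites[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(s))) {
    ok <- TRUE
    for (k in kept) {
      overlaps <- s$seed_start[i] <= s$seed_end[k] &&
        s$seed_end[i] >= s$seed_start[k]
      if (overlaps && !(s$precedence[i] == 0L && s$precedence[k] == 0L)) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- s[kept, , drop = FALSE]
  ## drop exact duplicate rows (same site found twice in a permuted input)
  out <- unique(out)
  ord2 <- order(out$seed_start, match(out$seed_type, SEED_TYPE_NAMES),
                out$seed_end)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan and resolve sites for many (miRNA, transcript) pairs
#'
#' Convenience wrapper running [scan_candidate_sites()] followed by
#' [resolve_overlaps()] over a table of pairs.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param utrs named character vector of 3' UTR sequences.
#' @param pairs data.frame with columns `transcript_id`, `mirna_id`; defaults
#'   to all combinations.
#' @return combined resolved site table.
#' @export
scan_pairs <- function(mirnas, utrs, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- expand.grid(transcript_id = names(utrs), mirna_id = names(mirnas),
                         stringsAsFactors = FALSE)
  }
  missing_t <- setdiff(pairs$transcript_id, names(utrs))
  missing_m <- setdiff(pairs$mirna_id, names(mirnas))
  if (length(missing_t)) stop("unknown transcript id: ", missing_t[1L])
  if (length(missing_m)) stop("unknown miRNA id: ", missing_m[1L])
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tid <- pairs$transcript_id[i]; mid <- pairs$mirna_id[i]
    res[[i]] <- resolve_overlaps(scan_candidate_sites(
      mirnas[[mid]], utrs[[tid]], mirna_id = mid, transcript_id = tid))
  }
  out <- do.call(rbind, c(res, list(empty_sites())))
  rownames(out) <- NULL
  out
}
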