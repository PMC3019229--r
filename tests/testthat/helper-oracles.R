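## Independent oracles used to verify the package implementation.
## These are deliberately written with different machinery (character
## operations, recursion, numeric integration) than the package internals.

oracle_comp <- function(x) chartr("ACGU", "UGCA", x)

oracle_pair <- function(target, mir) {
  if (target == oracle_comp(mir)) return("WC")
  if (mir == "U" && target == "G") return("GUM")
  if (mir == "G" && target == "U") return("GUT")
  "MM"
}

## pair-class table derived from oracle_pair, for speed on long scans
ORACLE_PAIR_TAB <- local({
  b <- c("A", "C", "G", "U")
  m <- matrix("", 4, 4, dimnames = list(b, b))
  for (t in b) for (q in b) m[t, q] <- oracle_pair(t, q)
  m
})

## classify one window, string version
oracle_classify <- function(mirna, window, nextb = NULL) {
  sp <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
  m <- sp(mirna)
  w <- rev(sp(window)) # w[i] pairs miRNA position i + 1
  nw <- length(w)
  a1 <- !is.null(nextb) && identical(nextb, "A")
  if (nw == 7L) {
    cls <- ORACLE_PAIR_TAB[cbind(w, m[2:8])]
    if (all(cls == "WC")) return(if (a1) "8mer" else "7mer-m8")
    if (sum(cls != "WC") == 1L) {
      d <- which(cls != "WC")
      if (cls[d] == "GUM") return("GUM")
      if (cls[d] == "GUT") return("GUT")
      if (cls[d] == "MM" && d >= 2L && d <= 6L) return("LP") # positions 3-7
    }
    return(NA_character_)
  }
  if (nw == 6L) {
    if (all(ORACLE_PAIR_TAB[cbind(w, m[2:7])] == "WC")) {
      return(if (a1) "7mer-A1" else "6mer")
    }
    for (b in 3:7) {
      rest <- m[2:8][-(b - 1L)]
      if (all(ORACLE_PAIR_TAB[cbind(w, rest)] == "WC")) return("BM")
    }
    return(NA_character_)
  }
  if (nw == 8L) {
    for (p in 2:7) {
      ww <- w[-(9L - p)] # drop inserted base, pairing order
      if (all(ORACLE_PAIR_TAB[cbind(ww, m[2:8])] == "WC")) return("BT")
    }
    return(NA_character_)
  }
  NA_character_
}

ORACLE_TYPES <- c("8mer", "7mer-A1", "7mer-m8", "6mer",
                  "GUM", "GUT", "LP", "BM", "BT")
ORACLE_RANK <- c(0, 0, 0, 0, 1, 2, 3, 4, 5)
names(ORACLE_RANK) <- ORACLE_TYPES

## enumerate all candidate sites by looping every window
oracle_scan <- function(mirna, utr, mirna_id = "mirna",
                        transcript_id = "utr") {
  L <- nchar(utr)
  rows <- list()
  if (L >= 21L) {
    for (s in 16:(L - 5L)) {
      for (len in 6:8) {
        if (s + len - 1L > L) next
        win <- substr(utr, s, s + len - 1L)
        nb <- if (s + len <= L) substr(utr, s + len, s + len) else NULL
        ty <- oracle_classify(mirna, win, nb)
        if (is.na(ty)) next
        match_len <- len + (ty %in% c("8mer", "7mer-A1"))
        rows[[length(rows) + 1L]] <-
          data.frame(transcript_id = transcript_id, mirna_id = mirna_id,
                     seed_type = ty, seed_start = s,
                     seed_end = s + match_len - 1L,
                     precedence = unname(ORACLE_RANK[ty]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(transcript_id = character(0), mirna_id = character(0),
               seed_type = character(0), seed_start = integer(0),
               seed_end = integer(0), precedence = integer(0),
               stringsAsFactors = FALSE))))
  out <- oracle_drop_contained(out)
  out <- out[order(out$seed_start, match(out$seed_type, ORACLE_TYPES),
                   out$seed_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## containment among the rank-0 group: keep longest representative
oracle_drop_contained <- function(sites) {
  if (!nrow(sites)) return(sites)
  r0 <- sites[sites$precedence == 0, , drop = FALSE]
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (sites$precedence[i] != 0) next
    li <- sites$seed_end[i] - sites$seed_start[i]
    for (j in seq_len(nrow(r0))) {
      lj <- r0$seed_end[j] - r0$seed_start[j]
      same <- r0$seed_start[j] == sites$seed_start[i] &&
        r0$seed_end[j] == sites$seed_end[i] &&
        r0$seed_type[j] == sites$seed_type[i]
      if (same) next
      inside <- r0$seed_start[j] <= sites$seed_start[i] &&
        r0$seed_end[j] >= sites$seed_end[i]
      better <- lj > li ||
        (lj == li && match(r0$seed_type[j], ORACLE_TYPES) <
           match(sites$seed_type[i], ORACLE_TYPES))
      if (inside && better) { keep[i] <- FALSE; break }
    }
  }
  sites[keep, , drop = FALSE]
}

## independent overlap resolution: repeatedly take the best remaining site
oracle_resolve <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  sites <- oracle_drop_contained(sites)
  pool <- sites[order(sites$precedence, sites$seed_start,
                      match(sites$seed_type, ORACLE_TYPES),
                      sites$seed_end), , drop = FALSE]
  pool <- unique(pool)
  chosen <- pool[0, , drop = FALSE]
  for (i in seq_len(nrow(pool))) {
    cand <- pool[i, , drop = FALSE]
    clash <- FALSE
    if (nrow(chosen)) {
      ov <- cand$seed_start <= chosen$seed_end &
        cand$seed_end >= chosen$seed_start
      bad <- ov & !(cand$precedence == 0 & chosen$precedence == 0)
      clash <- any(bad)
    }
    if (!clash) chosen <- rbind(chosen, cand)
  }
  chosen <- chosen[order(chosen$seed_start,
                         match(chosen$seed_type, ORACLE_TYPES),
                         chosen$seed_end), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen
}

## recursive affine-gap global alignment score (memoized); pairing scores
## WC +5, GU +1, mismatch -4; gap of length k costs open + k * ext
oracle_align_score <- function(a, b, match = 5, gu = 1, mismatch = -4,
                               open = 10, ext = 0.5) {
  an <- length(a); bn <- length(b)
  memo <- new.env(hash = TRUE)
  psc <- function(x, y) {
    p <- oracle_pair(y, x) # x = miRNA side, y = target side
    if (p == "WC") match else if (p == "MM") mismatch else gu
  }
  rec <- function(i, j, st) {
    if (i == 0L && j == 0L) {
      return(if (st == "M") 0 else -Inf)
    }
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- -Inf
    if (st == "M" && i > 0L && j > 0L) {
      val <- psc(a[i], b[j]) +
        max(rec(i - 1L, j - 1L, "M"), rec(i - 1L, j - 1L, "X"),
            rec(i - 1L, j - 1L, "Y"))
    } else if (st == "X" && i > 0L) {
      val <- max(rec(i - 1L, j, "M") - open - ext,
                 rec(i - 1L, j, "X") - ext,
                 rec(i - 1L, j, "Y") - open - ext)
    } else if (st == "Y" && j > 0L) {
      val <- max(rec(i, j - 1L, "M") - open - ext,
                 rec(i, j - 1L, "Y") - ext,
                 rec(i, j - 1L, "X") - open - ext)
    }
    memo[[key]] <- val
    val
  }
  max(rec(an, bn, "M"), rec(an, bn, "X"), rec(an, bn, "Y"))
}

## AUC as the pairwise rank statistic (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## truncated ROC by numeric integration of the piecewise-linear curve.
## Tied-score blocks of positives create vertical jumps: the curve enters a
## false-positive count at the smallest true-positive count observed there
## and leaves at the largest, so both are kept (offset by epsilon in x).
oracle_roc_trunc <- function(scores, labels, cutoff, steps = 20000L) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  fp <- c(0, vapply(thr, function(t) sum(scores[!labels] >= t), 0))
  tp <- c(0, vapply(thr, function(t) sum(scores[labels] >= t), 0))
  ufp <- sort(unique(fp))
  enter <- vapply(ufp, function(x) min(tp[fp == x]), 0)
  exit <- vapply(ufp, function(x) max(tp[fp == x]), 0)
  px <- as.vector(rbind(ufp, ufp + 1e-9))
  py <- as.vector(rbind(enter, exit))
  tp_at <- stats::approxfun(px, py, rule = 2)
  xs <- seq(0, min(cutoff, n_neg), length.out = steps)
  area <- sum((tp_at(xs[-1]) + tp_at(xs[-steps])) / 2 * diff(xs))
  area / (n_pos * n_neg)
}

## random sequence helpers
rand_rna <- function(n, au = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c(au / 2, (1 - au) / 2, (1 - au) / 2, au / 2)),
        collapse = "")
}

rand_mirna <- function(len = 22L) {
  repeat {
    s <- rand_rna(len)
    part <- substr(s, 2, 8)
    if (grepl("U", part) && grepl("G", part)) return(s)
  }
}
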