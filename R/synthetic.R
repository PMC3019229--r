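## Synthetic benchmark generator.
##
## Emulates the structure of miRNA/siRNA transfection experiments: each
## transcript is assigned one transfected miRNA and a binary regulation
## label. A subset of "targeted" genes receives several functional-grade
## planted sites (stringent seed types, AU-enriched flank, and often a
## complementary 3' supplementary stretch opposite miRNA positions 13-16,
## with some site pairs spaced 17-35 nt apart); the remaining genes receive
## a few context-poor sites drawn from a background mixture that includes
## occasional stringent seed matches, mimicking the non-functional seed
## matches that pepper real UTRs. A latent repression score - the sum of
## per-site strengths (seed-type weight + AU-context and 3'-pairing terms)
## plus a cooperativity bonus for 17-35 nt site pairs and Gaussian noise -
## is thresholded to hit a configured positive fraction, and labels are
## flipped at a small noise rate. The generator therefore knows the ground
## truth for every planted site, which makes every pipeline stage testable
## without microarray data.

#' Synthetic dataset configuration
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' tests: 2000 transcripts, 5 miRNAs, log-normal UTR lengths with median
#' about 300 nt, 29% of genes carrying functional-grade sites (of which the
#' strongest quarter of the latent-score distribution is labeled
#' down-regulated, leaving a fringe of decoy genes whose single strong site
#' does not repress), and 5% label noise.
#'
#' @param n_mirnas number of miRNAs (one per simulated transfection).
#' @param n_transcripts number of transcripts.
#' @param utr_meanlog,utr_sdlog log-normal UTR length parameters (nt).
#' @param background_au background AU content (A+U fraction).
#' @param targeted_fraction fraction of genes given functional-grade sites.
#' @param targeted_sites_min,targeted_sites_pois functional site count per
#'   targeted gene: `min + Poisson(pois)`.
#' @param background_sites_pois Poisson mean of context-poor planted sites
#'   in non-targeted genes.
#' @param targeted_type_probs,background_type_probs seed-type planting
#'   mixtures (named probability vectors).
#' @param flank_au AU probability used when rewriting a functional site's
#'   upstream flank.
#' @param duplex_prob probability a functional site gets a complementary
#'   stretch opposite miRNA positions 13-16.
#' @param pair_prob probability a functional site is chained 17-35 nt from
#'   the previous one.
#' @param type_strength named per-seed-type repression weights.
#' @param w_au,w_duplex,w_synergy latent-model weights for AU context,
#'   planted 3' pairing, and each 17-35 nt site pair.
#' @param latent_sd standard deviation of the latent Gaussian noise.
#' @param pos_fraction fraction of genes labeled down-regulated (threshold
#'   on the latent score).
#' @param label_noise label flip probability, in \[0, 0.5).
#' @param seed integer random seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mirnas = 5L,
                             n_transcripts = 2000L,
                             utr_meanlog = log(300),
                             utr_sdlog = 0.7,
                             background_au = 0.5,
                             targeted_fraction = 0.29,
                             targeted_sites_min = 2L,
                             targeted_sites_pois = 2.5,
                             background_sites_pois = 1.2,
                             targeted_type_probs = c(
                               "8mer" = 0.40, "7mer-m8" = 0.27,
                               "7mer-A1" = 0.25, "6mer" = 0.08),
                             background_type_probs = c(
                               "7mer-m8" = 0.06, "6mer" = 0.22,
                               "GUM" = 0.18, "GUT" = 0.16, "LP" = 0.16,
                               "BM" = 0.12, "BT" = 0.10),
                             flank_au = 0.9,
                             duplex_prob = 0.85,
                             pair_prob = 0.5,
                             type_strength = c(
                               "8mer" = 3, "7mer-A1" = 2.5, "7mer-m8" = 2.5,
                               "6mer" = 1.2, "GUM" = 1.0, "GUT" = 0.9,
                               "LP" = 0.6, "BM" = 0.5, "BT" = 0.5),
                             w_au = 1.5,
                             w_duplex = 1.0,
                             w_synergy = 2.0,
                             latent_sd = 0.35,
                             pos_fraction = 0.25,
                             label_noise = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_mirnas >= 1L, cfg$n_transcripts >= 1L,
            cfg$label_noise >= 0, cfg$label_noise < 0.5,
            cfg$pos_fraction > 0, cfg$pos_fraction < 1,
            all(cfg$targeted_type_probs >= 0),
            all(cfg$background_type_probs >= 0),
            all(cfg$type_strength >= 0),
            cfg$targeted_sites_pois >= 0, cfg$background_sites_pois >= 0)
  stopifnot(all(names(cfg$targeted_type_probs) %in% SEED_TYPE_NAMES),
            all(names(cfg$background_type_probs) %in% SEED_TYPE_NAMES))
  class(cfg) <- "synthetic_config"
  cfg
}

sample_bases <- function(n, au = 0.5) {
  sample(RNA_BASES, n, replace = TRUE,
         prob = c(au / 2, (1 - au) / 2, (1 - au) / 2, au / 2))
}

random_mirna <- function(len = 22L) {
  repeat {
    s <- sample_bases(len, 0.5)
    seed_part <- s[2:8]
    if (any(seed_part == "U") && any(seed_part == "G")) {
      return(paste(s, collapse = ""))
    }
  }
}

## Construct the target-side window (integer codes) realizing a seed type
## for a miRNA. Returns window codes, the base to write 3' of the window
## (NA = leave the background untouched), and the seed-match length.
## Defect positions are chosen at random among the feasible ones.
construct_seed_window <- function(m, seed_type) {
  wc <- function(q) WC_PARTNER[q]
  w7 <- wc(m[8:2]) # perfect window for miRNA 2-8
  w6 <- wc(m[7:2])
  not_a <- 2L # a C never upgrades to an A1 type
  shuffle <- function(v) if (length(v) > 1L) sample(v) else v
  switch(seed_type,
    "8mer" = list(window = w7, next_base = 1L, match_len = 8L),
    "7mer-A1" = list(window = w6, next_base = 1L, match_len = 7L),
    "7mer-m8" = list(window = w7, next_base = not_a, match_len = 7L),
    "6mer" = list(window = w6, next_base = not_a, match_len = 6L),
    "GUM" = {
      qs <- shuffle(which(m[2:8] == 4L) + 1L) # miRNA U positions
      if (!length(qs)) stop("GUM impossible: no U in miRNA seed")
      w <- w7; w[9L - qs[1L]] <- 3L # target G opposite the U
      list(window = w, next_base = NA_integer_, match_len = 7L)
    },
    "GUT" = {
      qs <- shuffle(which(m[2:8] == 3L) + 1L) # miRNA G positions
      if (!length(qs)) stop("GUT impossible: no G in miRNA seed")
      w <- w7; w[9L - qs[1L]] <- 4L # target U opposite the G
      list(window = w, next_base = NA_integer_, match_len = 7L)
    },
    "LP" = {
      q <- sample(3:7, 1L)
      w <- w7
      mm <- which(PAIR_CLASS[, m[q]] == 3L)
      w[9L - q] <- mm[sample.int(length(mm), 1L)]
      list(window = w, next_base = NA_integer_, match_len = 7L)
    },
    "BM" = {
      for (q in shuffle(3:7)) {
        w <- wc(m[setdiff(8:2, q)])
        ## reject constructions that collapse to an exact 6mer
        if (!all(w == w6)) {
          return(list(window = w, next_base = NA_integer_, match_len = 6L))
        }
      }
      stop("BM impossible: every bulge collapses to a 6mer")
    },
    "BT" = {
      p <- sample(2:7, 1L)
      ins <- sample.int(4L, 1L)
      w <- append(w7, ins, after = p - 1L)
      list(window = w, next_base = NA_integer_, match_len = 8L)
    },
    stop("unknown seed type: ", seed_type))
}

#' Plant a seed-match site into a UTR
#'
#' Replaces the UTR substring at `position` with a window that
#' [classify_window()] labels exactly `seed_type` for the given miRNA (the
#' constructive inverse of the scanner's definitions). For 6mer and
#' 7mer-m8 the base immediately 3' of the window is also set to a non-A so
#' the site is not upgraded to its A1 variant; all other surrounding bases
#' are untouched.
#'
#' @param utr UTR sequence.
#' @param mirna miRNA sequence.
#' @param seed_type one of the nine seed type names.
#' @param position 1-based UTR coordinate for the seed match start
#'   (must be >= 16 and leave room for the window).
#' @return the modified UTR string, with attributes `seed_start`,
#'   `seed_end`, and `seed_type`.
#' @export
plant_site <- function(utr, mirna, seed_type, position) {
  m <- encode_rna(normalize_rna(mirna, "mirna"))
  u <- encode_rna(normalize_rna(utr, "utr"))
  L <- length(u)
  if (position < MIN_SEED_START) {
    stop("position must be >= ", MIN_SEED_START)
  }
  cons <- construct_seed_window(m, seed_type)
  need <- length(cons$window) + as.integer(!is.na(cons$next_base))
  if (position + need - 1L > L) {
    stop("window does not fit at position ", position,
         " (UTR length ", L, ")")
  }
  u[position:(position + length(cons$window) - 1L)] <- cons$window
  if (!is.na(cons$next_base)) {
    u[position + length(cons$window)] <- cons$next_base
  }
  ## confirm the construction
  w_chr <- decode_rna(u[position:(position + length(cons$window) - 1L)])
  nb_pos <- position + length(cons$window)
  nb <- if (nb_pos <= L) RNA_BASES[u[nb_pos]] else NULL
  got <- classify_window(decode_rna(m), w_chr, nb)
  if (!identical(got, seed_type)) {
    stop("could not realize seed type ", seed_type, " (got ",
         if (is.na(got)) "none" else got, ")")
  }
  out <- decode_rna(u)
  attr(out, "seed_start") <- position
  attr(out, "seed_end") <- position + cons$match_len - 1L
  attr(out, "seed_type") <- seed_type
  out
}

## Plant the given list of site types into one transcript. The intended
## type list is fixed by the caller (so verification retries cannot bias
## the realized type mixture); only background and positions are redrawn.
## For 6mer and 7mer-A1 plants a guard base mismatching miRNA position 8 is
## written immediately 5' of the window, preventing the background from
## extending the match to a longer stringent type that would displace it.
plant_transcript <- function(L, mirna_codes, is_targeted, cfg, types) {
  u <- encode_rna(paste(sample_bases(L, cfg$background_au), collapse = ""))
  occupied <- rep(FALSE, L)
  placed <- list()
  if (!length(types)) {
    return(list(u = u, manifest = NULL))
  }
  mm8 <- which(PAIR_CLASS[, mirna_codes[8L]] == 3L)[1L]
  prev_start <- NA_integer_
  for (j in seq_along(types)) {
    cons <- tryCatch(construct_seed_window(mirna_codes, types[j]),
                     error = function(e) NULL)
    if (is.null(cons)) next
    wlen <- length(cons$window) + as.integer(!is.na(cons$next_base))
    lo_margin <- if (is_targeted) 14L else 2L # reserve flank for rewriting
    pos <- NA_integer_
    for (try in 1:30) {
      cand <- if (is_targeted && !is.na(prev_start) && try <= 10 &&
                  stats::runif(1) < cfg$pair_prob) {
        prev_start + sample(17:35, 1L)
      } else if (L - wlen >= MIN_SEED_START) {
        sample(MIN_SEED_START:(L - wlen + 1L), 1L)
      } else NA_integer_
      if (is.na(cand) || cand < MIN_SEED_START || cand + wlen - 1L > L) next
      span <- max(1L, cand - lo_margin):min(L, cand + wlen)
      if (!any(occupied[span])) { pos <- cand; break }
    }
    if (is.na(pos)) next
    u[pos:(pos + length(cons$window) - 1L)] <- cons$window
    if (!is.na(cons$next_base)) u[pos + length(cons$window)] <- cons$next_base
    if (types[j] %in% c("6mer", "7mer-A1")) u[pos - 1L] <- mm8
    occupied[max(1L, pos - lo_margin):min(L, pos + wlen)] <- TRUE
    duplex_flag <- FALSE
    if (is_targeted) {
      ## AU-enrich the upstream flank, then optionally write a complementary
      ## stretch opposite miRNA positions 13-16
      fr <- flank_range(types[j], pos, length(mirna_codes))
      if (fr[2L] >= fr[1L]) {
        u[fr[1L]:fr[2L]] <- encode_rna(paste(
          sample_bases(fr[2L] - fr[1L] + 1L, cfg$flank_au), collapse = ""))
        if (types[j] %in% c("6mer", "7mer-A1")) u[pos - 1L] <- mm8
        if (stats::runif(1) < cfg$duplex_prob) {
          skip <- if (types[j] %in% c("6mer", "7mer-A1")) 1L else 0L
          for (q in 13:16) {
            coord <- pos - 1L - skip - (q - 9L)
            if (coord >= 1L) u[coord] <- WC_PARTNER[mirna_codes[q]]
          }
          duplex_flag <- TRUE
        }
      }
    }
    placed[[length(placed) + 1L]] <- data.frame(
      seed_type = types[j], seed_start = pos,
      seed_end = pos + cons$match_len - 1L,
      duplex_flag = duplex_flag, stringsAsFactors = FALSE)
    prev_start <- pos
  }
  man <- if (length(placed)) do.call(rbind, placed) else NULL
  list(u = u, manifest = man)
}

## AU fraction of up to 30 nt upstream of a seed start, on code vector u
au_upstream <- function(u, seed_start) {
  if (seed_start <= 1L) return(0.5)
  w <- u[max(1L, seed_start - 30L):(seed_start - 1L)]
  mean(w %in% c(1L, 4L))
}

#' Generate a synthetic miRNA targeting dataset
#'
#' See [synthetic_config()] for the generative mechanism. Every planted
#' site is verified against the scanner (the plant is re-drawn on the rare
#' occasions background sequence displaces a planted site through the
#' overlap-precedence rules), so the manifest is exact ground truth.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `mirsvm_dataset`: `mirnas`, `utrs` (named
#'   character vectors), `labels` (transcript_id, mirna_id, label),
#'   `manifest` (all planted sites with ground-truth strengths), `latent`
#'   (per-gene latent repression scores), `threshold`, and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  mirnas <- vapply(seq_len(cfg$n_mirnas), function(i) random_mirna(), "")
  names(mirnas) <- sprintf("mir%02d", seq_len(cfg$n_mirnas))
  mirna_codes <- lapply(mirnas, encode_rna)

  lens <- pmin(pmax(round(stats::rlnorm(n, cfg$utr_meanlog, cfg$utr_sdlog)),
                    60L), 8000L)
  tids <- sprintf("tx%04d", seq_len(n))
  assigned <- rep_len(names(mirnas), n)
  targeted <- stats::runif(n) < cfg$targeted_fraction

  utrs <- character(n)
  manifests <- vector("list", n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    mc <- mirna_codes[[assigned[i]]]
    ## the intended type list is drawn once; retries only redraw background
    if (targeted[i]) {
      n_sites <- cfg$targeted_sites_min +
        stats::rpois(1L, cfg$targeted_sites_pois)
      probs <- cfg$targeted_type_probs
    } else {
      n_sites <- stats::rpois(1L, cfg$background_sites_pois)
      probs <- cfg$background_type_probs
    }
    types <- if (n_sites > 0L) {
      sample(names(probs), n_sites, replace = TRUE, prob = probs)
    } else character(0)
    ok <- FALSE
    for (try in 1:20) {
      res <- plant_transcript(lens[i], mc, targeted[i], cfg, types)
      if (is.null(res$manifest)) { ok <- TRUE; break }
      ## verify every planted site survives scanning + overlap resolution
      resolved <- resolve_overlaps(scan_candidate_sites(
        mirnas[[assigned[i]]], decode_rna(res$u),
        mirna_id = assigned[i], transcript_id = tids[i]))
      key_res <- paste(resolved$seed_start, resolved$seed_type)
      key_plant <- paste(res$manifest$seed_start, res$manifest$seed_type)
      if (all(key_plant %in% key_res)) { ok <- TRUE; break }
    }
    if (!ok) {
      ## keep the last draw but drop the displaced sites from ground truth
      keep <- key_plant %in% key_res
      res$manifest <- res$manifest[keep, , drop = FALSE]
      if (!nrow(res$manifest)) res$manifest <- NULL
      n_skipped <- n_skipped + sum(!keep)
    }
    utrs[i] <- decode_rna(res$u)
    if (!is.null(res$manifest)) {
      m <- res$manifest
      m$transcript_id <- tids[i]
      m$mirna_id <- assigned[i]
      m$au_up <- vapply(m$seed_start, function(s) au_upstream(res$u, s), 0)
      manifests[[i]] <- m
    }
  }
  names(utrs) <- tids
  manifest <- do.call(rbind, manifests[!vapply(manifests, is.null, TRUE)])
  rownames(manifest) <- NULL

  ## latent repression: site strengths + cooperativity + noise
  strength <- cfg$type_strength[manifest$seed_type] +
    cfg$w_au * manifest$au_up + cfg$w_duplex * manifest$duplex_flag
  manifest$strength <- unname(strength)
  latent <- numeric(n)
  by_tx <- split(seq_len(nrow(manifest)), manifest$transcript_id)
  for (tid in names(by_tx)) {
    idx <- by_tx[[tid]]
    d <- if (length(idx) >= 2L) {
      as.numeric(stats::dist(matrix(manifest$seed_start[idx], ncol = 1L)))
    } else numeric(0)
    latent[match(tid, tids)] <- sum(manifest$strength[idx]) +
      cfg$w_synergy * sum(d >= 17 & d <= 35)
  }
  latent <- latent + stats::rnorm(n, 0, cfg$latent_sd)

  threshold <- stats::quantile(latent, 1 - cfg$pos_fraction, names = FALSE)
  down <- latent > threshold
  flip <- stats::runif(n) < cfg$label_noise
  down <- xor(down, flip)
  labels <- data.frame(transcript_id = tids, mirna_id = assigned,
                       label = ifelse(down, "down_regulated", "unaffected"),
                       stringsAsFactors = FALSE)
  out <- list(mirnas = mirnas, utrs = utrs, labels = labels,
              manifest = manifest, latent = latent, threshold = threshold,
              n_skipped = n_skipped, config = cfg)
  class(out) <- "mirsvm_dataset"
  out
}

#' @export
print.mirsvm_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic dataset: %d transcripts x %d miRNAs, ",
                     "%d planted sites, %d down-regulated\n"),
              length(x$utrs), length(x$mirnas), nrow(x$manifest),
              sum(x$labels$label == "down_regulated")))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `mirnas.fa`, `utrs.fa`, `labels.tsv`, and the ground-truth
#' `manifest.tsv` into a directory.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(dataset$mirnas, file.path(dir, "mirnas.fa"))
  write_fasta(dataset$utrs, file.path(dir, "utrs.fa"))
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
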