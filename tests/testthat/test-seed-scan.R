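test_that("window classification recognises all nine seed types", {
  mir <- FIX_MIRNA # seed 2-8 on the miRNA: AGCUUAU
  # perfect 2-8 complement window is AUAAGCU
  expect_identical(classify_window(mir, "AUAAGCU", "A"), "8mer")
  expect_identical(classify_window(mir, "AUAAGCU", "C"), "7mer-m8")
  expect_identical(classify_window(mir, "AUAAGCU", NULL), "7mer-m8")
  expect_identical(classify_window(mir, "UAAGCU", "A"), "7mer-A1")
  expect_identical(classify_window(mir, "UAAGCU", "G"), "6mer")
  # G opposite the miRNA U at position 5 -> wobble with U on the miRNA
  expect_identical(classify_window(mir, "AUAGGCU", NULL), "GUM")
  # U opposite the miRNA G at position 3
  expect_identical(classify_window(mir, "AUAAGUU", NULL), "GUT")
  # C opposite the miRNA U at position 5 -> internal 1x1 loop
  expect_identical(classify_window(mir, "AUACGCU", NULL), "LP")
  # miRNA position 5 bulged out (6-nt window)
  expect_identical(classify_window(mir, "AUAGCU", NULL), "BM")
  # extra target base inside the match (8-nt window)
  expect_identical(classify_window(mir, "AUACAGCU", NULL), "BT")
  # non-matching window
  expect_identical(classify_window(mir, "GGGGGGG", NULL), NA_character_)
  # too-short window is no match, not an error
  expect_identical(classify_window(mir, "AUAAG", NULL), NA_character_)
})

test_that("classification agrees with the string-based oracle on random windows", {
  set.seed(101)
  n_checked <- 0L
  for (rep in 1:40) {
    mir <- rand_mirna()
    for (len in 6:8) {
      for (i in 1:30) {
        win <- rand_rna(len)
        nb <- sample(c("A", "C", "G", "U"), 1L)
        expect_identical(classify_window(mir, win, nb),
                         oracle_classify(mir, win, nb))
        n_checked <- n_checked + 1L
      }
    }
    # windows derived from the miRNA itself hit matches far more often
    perfect <- rna_revcomp(substr(mir, 2, 8))
    for (i in 1:25) {
      w <- strsplit(perfect, "")[[1L]]
      j <- sample(seq_along(w), 1L)
      w[j] <- sample(c("A", "C", "G", "U"), 1L)
      win <- paste(w, collapse = "")
      nb <- sample(c("A", "C"), 1L)
      expect_identical(classify_window(mir, win, nb),
                       oracle_classify(mir, win, nb))
    }
  }
  expect_gte(n_checked, 3000L)
})

test_that("scanning finds a planted 8mer past the exclusion zone", {
  mir <- FIX_MIRNA
  utr <- paste0(strrep("A", 15), "AUAAGCUA")
  hits <- scan_candidate_sites(mir, utr)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$seed_type, "8mer")
  expect_equal(hits$seed_start, 16L)
  expect_equal(hits$seed_end, 23L)
})

test_that("sites inside the first 15 nt are excluded", {
  mir <- FIX_MIRNA
  utr <- paste0("AUAAGCUA", strrep("C", 20))
  expect_equal(nrow(scan_candidate_sites(mir, utr)), 0L)
  # the same match placed at position 16 is reported
  utr2 <- paste0(strrep("C", 15), "AUAAGCUA", strrep("C", 5))
  expect_equal(nrow(scan_candidate_sites(mir, utr2)), 1L)
})

test_that("UTRs shorter than 21 nt yield no sites", {
  expect_equal(nrow(scan_candidate_sites(FIX_MIRNA, strrep("A", 20))), 0L)
})

test_that("scan+resolve equals the brute-force oracle on random sequences", {
  set.seed(202)
  for (i in 1:40) {
    mir <- rand_mirna()
    utr <- rand_rna(sample(120:400, 1L), au = stats::runif(1, 0.3, 0.7))
    got <- scan_candidate_sites(mir, utr)
    want <- oracle_scan(mir, utr)
    expect_equal(got, want)
    expect_equal(resolve_overlaps(got), oracle_resolve(want))
  }
})

test_that("overlap precedence follows the stated order", {
  base <- data.frame(transcript_id = "t", mirna_id = "m",
                     stringsAsFactors = FALSE)
  mk <- function(type, start, end) {
    cbind(base, data.frame(seed_type = type, seed_start = start,
                           seed_end = end,
                           precedence = seed_types()$precedence[
                             match(type, seed_types()$name)],
                           stringsAsFactors = FALSE))
  }
  # GUM over GUT (the worked example of the precedence rule)
  got <- resolve_overlaps(rbind(mk("GUT", 20, 26), mk("GUM", 22, 28)))
  expect_identical(got$seed_type, "GUM")
  # LP over BT
  got <- resolve_overlaps(rbind(mk("BT", 30, 37), mk("LP", 33, 39)))
  expect_identical(got$seed_type, "LP")
  # partially overlapping stringent sites both survive
  got <- resolve_overlaps(rbind(mk("7mer-m8", 40, 46), mk("6mer", 44, 49)))
  expect_setequal(got$seed_type, c("7mer-m8", "6mer"))
  # stringent over any non-stringent
  got <- resolve_overlaps(rbind(mk("GUM", 50, 56), mk("6mer", 53, 58)))
  expect_identical(got$seed_type, "6mer")
  # precedence tie among non-stringents: smaller seed_start wins
  got <- resolve_overlaps(rbind(mk("GUM", 64, 70), mk("GUM", 60, 66)))
  expect_equal(got$seed_start, 60)
})

test_that("overlap resolution is idempotent and order-independent", {
  set.seed(303)
  for (i in 1:25) {
    mir <- rand_mirna()
    utr <- rand_rna(sample(150:350, 1L))
    cand <- scan_candidate_sites(mir, utr)
    if (nrow(cand) < 2L) next
    res <- resolve_overlaps(cand)
    expect_equal(resolve_overlaps(res), res)
    perm <- cand[sample(nrow(cand)), , drop = FALSE]
    expect_equal(resolve_overlaps(perm), res)
    # surviving overlaps only within the rank-0 group
    if (nrow(res) >= 2L) {
      for (a in 1:(nrow(res) - 1L)) {
        for (b in (a + 1L):nrow(res)) {
          ov <- res$seed_start[a] <= res$seed_end[b] &&
            res$seed_end[a] >= res$seed_start[b]
          if (ov) {
            expect_true(res$precedence[a] == 0L && res$precedence[b] == 0L)
          }
        }
      }
    }
    expect_true(all(res$seed_start >= 16L))
  }
})
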