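test_that("binner percentiles match quantile on the trimmed distribution", {
  set.seed(1212)
  v <- stats::rnorm(5000)
  b <- fit_binner(v)
  keep <- v >= mean(v) - 2 * stats::sd(v) & v <= mean(v) + 2 * stats::sd(v)
  expect_equal(b$cuts,
               unname(stats::quantile(v[keep], mirsvm:::BINNER_PERCENTILES,
                                      type = 7)))
  expect_true(all(diff(b$cuts) >= 0))
  expect_length(b$cuts, 14L)
  # 100th percentile cut equals the maximum of the trimmed values
  expect_equal(b$cuts[14L], max(v[keep]))
})

test_that("upper-extreme fraction on normal draws matches the normal tail", {
  set.seed(1313)
  v <- stats::rnorm(1000)
  b <- fit_binner(v)
  counts <- bin_values(b, v)
  # P(Z > mean + 2 sd) is about 0.0228; allow binomial sampling error
  expect_lt(abs(counts[16L] / 1000 - 0.0228), 0.012)
  expect_lt(abs(counts[1L] / 1000 - 0.0228), 0.012)
  expect_equal(sum(counts), 1000L)
})

test_that("constant discriminants give a degenerate but working binner", {
  b <- fit_binner(rep(1.5, 30))
  expect_equal(b$sd, 0)
  counts <- bin_values(b, rep(1.5, 7))
  expect_equal(counts[2L], 7L) # all mass in the first interior bin
  expect_equal(sum(counts), 7L)
  # unseen values off the point mass still bin without error
  expect_equal(sum(bin_values(b, c(0, 2))), 2L)
})

test_that("values exactly at a cut point go to the lower-indexed bin", {
  b <- fit_binner(seq(0, 1, length.out = 100))
  cut1 <- b$cuts[1L]
  counts <- bin_values(b, cut1)
  expect_equal(counts[2L], 1L) # first interior bin, not the second
  eps_up <- bin_values(b, cut1 + 1e-9)
  expect_equal(eps_up[3L], 1L)
})

test_that("bin counts always sum to the site count (fuzz)", {
  set.seed(1414)
  b <- fit_binner(stats::rnorm(500))
  for (i in 1:1000) {
    n <- sample(0:12, 1L)
    v <- stats::rnorm(n, sd = sample(c(0.5, 1, 5), 1L))
    expect_equal(sum(bin_values(b, v)), n)
  }
})

test_that("mRNA features encode counts, density, spacing and strength", {
  b <- fit_binner(stats::rnorm(100))
  v <- compute_mrna_features(seed_starts = c(100L, 120L),
                             discriminants = c(0.2, 1.1),
                             utr_len = 1000L, binner = b)
  expect_identical(names(v), mirsvm:::MRNA_FEATURE_NAMES)
  expect_equal(unname(v["n_sites"]), 2)
  expect_equal(unname(v["n_pairs_17_35"]), 1) # distance 20 is cooperative
  expect_equal(unname(v["log_min_pair_dist"]), log10(21))
  expect_equal(unname(v["max_discriminant"]), 1.1)
  expect_equal(unname(v["site_density"]), 0.002)
  expect_equal(unname(v["few_sites_flag"]), 1)
  expect_equal(sum(v[1:16]), 2)

  v4 <- compute_mrna_features(seq(100L, 400L, by = 100L), rep(0, 4), 1000L, b)
  expect_equal(unname(v4["site_density"]), 0.004)
  expect_equal(unname(v4["n_pairs_17_35"]), 0)

  v9 <- compute_mrna_features(seq(50L, 450L, by = 50L), rep(0, 9), 2000L, b)
  expect_equal(unname(v9["few_sites_flag"]), 0)

  expect_error(compute_mrna_features(integer(0), numeric(0), 100L, b),
               "zero sites")
})

test_that("gene feature vectors are invariant to site order", {
  set.seed(1515)
  b <- fit_binner(stats::rnorm(100))
  sites <- data.frame(transcript_id = rep(c("t1", "t2"), c(3, 2)),
                      mirna_id = "m", seed_start = c(50L, 90L, 200L, 30L, 60L),
                      discriminant = stats::rnorm(5),
                      stringsAsFactors = FALSE)
  utrs <- c(t1 = strrep("A", 500), t2 = strrep("A", 300))
  f1 <- mrna_feature_matrix(sites, utrs, b)
  f2 <- mrna_feature_matrix(sites[sample(5), ], utrs, b)
  ord1 <- order(f1$meta$transcript_id)
  ord2 <- order(f2$meta$transcript_id)
  expect_equal(f1$x[ord1, ], f2$x[ord2, ])
})

test_that("training-set assembly implements the high-site-count augmentation", {
  mk_pool <- function(n_pos, n_neg_low, n_neg_high) {
    n <- n_pos + n_neg_low + n_neg_high
    x <- matrix(stats::rnorm(n * 3), n, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    meta <- data.frame(
      transcript_id = sprintf("t%05d", seq_len(n)), mirna_id = "m",
      n_sites = c(rep(2L, n_pos), rep(3L, n_neg_low), rep(9L, n_neg_high)),
      stringsAsFactors = FALSE)
    labels <- data.frame(
      transcript_id = meta$transcript_id, mirna_id = "m",
      label = rep(c("down_regulated", "unaffected"),
                  c(n_pos, n_neg_low + n_neg_high)),
      stringsAsFactors = FALSE)
    list(gf = list(meta = meta, x = x), labels = labels)
  }
  # 5000 eligible high-site negatives: exactly 1000 are added
  p <- mk_pool(50, 500, 5000)
  ts <- assemble_training_set(p$gf, p$labels, seed = 5L,
                              negative_cap = 300L)
  n_high <- sum(ts$meta$n_sites > 7L & ts$y == "neg")
  expect_equal(n_high, 1000L)
  expect_equal(sum(ts$y == "neg"), 1300L)
  expect_equal(sum(ts$y == "pos"), 50L)
  # fewer than 1000 high-site negatives: all of them are used
  p2 <- mk_pool(50, 500, 800)
  ts2 <- assemble_training_set(p2$gf, p2$labels, seed = 5L,
                               negative_cap = 10000L)
  expect_equal(sum(ts2$meta$n_sites > 7L & ts2$y == "neg"), 800L)
  # same seed twice: identical sample
  ts3 <- assemble_training_set(p$gf, p$labels, seed = 5L,
                               negative_cap = 300L)
  expect_equal(ts$meta, ts3$meta)
  # no positives is an error
  p3 <- mk_pool(2, 50, 0)
  p3$labels$label <- "unaffected"
  expect_error(assemble_training_set(p3$gf, p3$labels, seed = 1L),
               "no positive")
})
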