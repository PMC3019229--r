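---
title: "A two-stage site- and gene-level model of miRNA targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage site- and gene-level model of miRNA targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsvm)
```

## The modelling problem

Animal miRNAs recognise targets chiefly through the seed, positions 2–7
(extendable to 8) of the miRNA 5' end, pairing antiparallel to a site in
the mRNA 3' UTR. Seed matching alone is wildly unspecific: a typical UTR
contains several matches of which few, if any, are functional. Context
determines function — local AU content, supplementary pairing of miRNA
positions 13–16, position within the UTR — and, crucially, repression is
a property of the *gene*, not of a single site: site number, strength and
17–35 nt cooperative spacing matter, and transfection experiments provide
only gene-level labels (a transcript was down-regulated or not after a
miRNA or siRNA was introduced).

`mirsvm` therefore trains two classifiers. The site stage learns what a
functional site looks like, from sites weakly labeled by their gene's
regulation call. The gene stage learns how site strengths combine,
operating on a fixed-length re-encoding of the variable number of site
scores per gene.

## Site definitions and the scanner

Nine seed-match types are recognised (`seed_types()`), in two groups:

* stringent — **8mer** (WC match to positions 2–8 plus target A opposite
  position 1), **7mer-A1**, **7mer-m8**;
* non-stringent — **6mer**, **GUM**/**GUT** (exactly one G:U wobble over
  positions 2–8, with the U on the miRNA or the target), **LP** (one
  internal 1×1 mismatch, positions 3–7), **BM**/**BT** (one unpaired base
  on the miRNA or the target, at a non-terminal position).

Design choices where the definitions were genuinely open:

* all single-defect types are defined over the 2–8 span with exactly one
  defect, which keeps the nine definitions mutually exclusive per window
  and testable by exhaustive enumeration;
* a defect may not occupy a seed-terminal position (a terminal bulge or
  loop is indistinguishable from a shorter exact match);
* a window satisfying several definitions is labeled with the
  highest-precedence one, and a rank-0 (stringent or 6mer) match whose
  seed interval is fully contained in another rank-0 match is treated as
  the same pairing reported at a shorter type and suppressed — only
  *partial* overlaps survive within that group. Every 8mer would
  otherwise also be reported as the 7mer-A1 and 6mer it contains.

Sites are excluded from the first 15 nt after the stop codon, and
overlapping sites are resolved greedily in the order 8mer = 7mer-A1 =
7mer-m8 = 6mer > GUM > GUT > LP > BM > BT, breaking ties by leftmost
start; the result is independent of input order and idempotent. The
scanner is verified against an independently written brute-force
enumerator on random sequence.

## Site features

Twenty scalars per site (`compute_site_features()`): the seed-type
one-hot (9), the duplex total score and its 13–16 restriction, AU
fraction 30 nt up- and downstream, log10 distance from the stop codon,
log10 distance to the nearest UTR end, relative position, log10 UTR
length, a UTR > 2000 nt indicator, seed AU fraction, and site GC
fraction. Distances and lengths use `log10(1 + x)` so their dynamic range
is bounded before normalization; flanking windows are truncated at UTR
boundaries and fractions computed over the available bases (an empty
window scores the uninformative midpoint 0.5).

The duplex aligner is a global Needleman–Wunsch with affine gaps over the
miRNA 3' region (positions 9 to at most 20) and the UTR flank that would
lie opposite it. Scores are defined on base-pair classes — Watson–Crick
+5, G:U +1, other mismatch −4, gap open 10 and extension 0.5 per position
(a length-k gap costs 10 + 0.5k) — which makes the score symmetric in the
two strands. Traceback prefers diagonal, then the miRNA-consuming step,
then the flank-consuming step, so alignments are deterministic. The
13–16 score sums the pairing scores of aligned columns whose miRNA base
comes from positions 13–16 and ignores gap costs. For the 6-nt-span types
(6mer, 7mer-A1) position 8 is unpaired, so one spacer base is skipped
between the seed match and the flank.

Features are normalized to [−1, 1] per feature by `v' = 2(v − min)/(max −
min) − 1` with min/max taken from the training sites only; test values
outside the training range are clamped and a constant feature maps to 0.

## The two SVM stages

The site stage uses a soft-margin SVM with the homogeneous polynomial
kernel K(x, y) = (x·y)^d, degree 5, cost C = 2 (`kernel_spec()`); linear,
gaussian and inhomogeneous-polynomial kernels with the conventional
parameter grids (C = 2^(2n−5), 0 ≤ n ≤ 11; γ = 2^(2n−13), 0 ≤ n ≤ 10;
d = 2…8) are available through `svm_grid_search()`, which breaks ties
toward simpler kernels.

Two numerical choices deserve note. First, polynomial kernels are
evaluated on L2 unit-normalized feature rows (a cosine-normalized
kernel): on raw [−1, 1] vectors a degree-5 kernel spans roughly ±20^5 and
the SMO solver fails to converge in reasonable time, while on unit rows
it is well-conditioned; the same transform is applied at training and
scoring, stored with the model. Second, the sign of libsvm's decision
values depends on label encounter order, so the model calibrates its sign
after training so that positive discriminants always mean "predicted
functional".

Site-level 10-fold cross-validation is stratified by class (the classes
are imbalanced; the fold partition is seeded and reproducible). Each
site's discriminant value is produced by the model that never saw it,
and the stored fold assignment makes that property structurally
assertable. Per-gene grouping across folds is not enforced.

The gene stage re-encodes each gene's out-of-fold discriminants as 16
counts: values below mean − 2 SD, above mean + 2 SD (mean and SD of the
pooled training discriminants), and 14 bins whose cut points are the
25.00, 43.75, 57.81, 68.36, 76.27, 82.20, 86.65, 89.99, 92.49, 94.37,
95.78, 97.19, 98.6 and 100 percentiles of the extreme-trimmed
distribution — resolution concentrated in the upper tail, where the
strong sites that matter live. Percentiles use linear interpolation
between order statistics; a value exactly at a cut point falls in the
lower-indexed bin; unseen values beyond the last cut but inside the
extreme thresholds clamp into the last interior bin, so the counts always
sum to the gene's site count; a zero-variance discriminant distribution
yields a degenerate binner that places all interior mass in the first bin
rather than failing. Seven more scalars (site count, log UTR length, site
density, a "< 7 sites" indicator, the 17–35 nt pair count, log minimum
pair distance capped at 1000 nt — single-site genes take the cap — and
the maximum discriminant) complete the 23-feature gene vector for a
linear SVM with C = 1, the library default cost, normalized with the same
min/max scheme. Genes without any candidate site are never scored; they
are reported as non-candidates.

Training genes are all down-regulated genes with at least one site plus a
random sample of unaffected genes (cap 4000 by default, a practical bound
on training-set size) *plus* up to 1000 randomly chosen unaffected genes
with more than 7 sites. The augmentation exists because true targets are
scarce among high-site-count, long-UTR genes, and plain random sampling
under a cap would under-represent exactly the negatives the classifier
most needs.

## Evaluation

`roc_curve_auc()` sweeps all thresholds; tied scores form single curve
points joined trapezoidally, so the AUC equals the probability that a
random positive outranks a random negative with ties counted one half
(verified against the pairwise statistic to 1e-12). `roc_truncated()`
integrates the same curve only up to 10·n false positives (n = number of
miRNAs) while keeping FPR measured against all negatives, so a perfect
ranking attains 10·n/#negatives — magnitudes of order 10^−2 on realistic
set sizes — rather than 1; when the cutoff covers all negatives it equals
the full AUC. `ablation_study()` removes one feature group at a time and
re-runs cross-validation on the identical fold partition, so ΔAUC
reflects the feature, not fold luck.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emulates a transfection experiment: each transcript
is assigned one miRNA and a binary regulation label. UTR lengths are
log-normal (meanlog log 300, sdlog 0.7, clamped to 60–8000 nt) — the
scale of typical mammalian 3' UTRs while keeping desk-scale runtimes —
over a uniform background composition with a configurable AU knob.
A targeted fraction (0.29) of genes receives 2 + Poisson(2.5)
functional-grade sites: stringent-heavy seed types, AU-rich rewritten
flanks (AU probability 0.9), usually (0.85) a written complementary
stretch opposite miRNA positions 13–16, and chained placements 17–35 nt
apart with probability 0.5. All other genes receive Poisson(1.2)
context-poor sites from a mixture that includes occasional stringent
matches, mimicking the non-functional seed matches that pepper real
UTRs. A latent repression score sums per-site strengths (seed-type
weight + 1.5·AU fraction + 1·pairing flag), adds 2 per 17–35 nt pair and
Gaussian noise (SD 0.35), and the top quarter of the latent distribution
is labeled down-regulated before 5% of labels are flipped.

Because the targeted fraction exceeds the positive fraction, a fringe of
genes carries one or two genuinely strong sites yet is not repressed.
These decoys are the point: they make gene-level information (count,
spacing, the discriminant distribution) genuinely necessary, so the
benchmark can detect whether the second stage adds anything over ranking
genes by their single best site. Every planted site is verified against
the scanner (backgrounds are redrawn when overlap precedence would
displace a plant, with the intended type list held fixed so retries
cannot bias the realized type mixture), making the manifest exact ground
truth.

What the generator does **not** emulate: real transcriptome sequence
composition and repeats, measurement intensity (labels are binary),
competition with endogenous miRNAs, conservation structure, and
expression heterogeneity. Passing the benchmark therefore demonstrates
that the pipeline recovers a planted mechanism of the modeled form from
sequence — not that it attains any particular accuracy on biological
data.

## Problem sizes and reproducibility

The package's own benchmark runs at 2000 transcripts × 5 miRNAs
(≈ 4000 training sites), with a 70/30 train/test split, 10-fold
site-level cross-validation, and a two-group ablation — about a minute on
one CPU. Smaller configurations (200–400 genes) back the unit tests. All
stochastic steps (generation, fold assignment, negative sampling) are
seeded; identical seeds reproduce site tables, models and metrics
byte-for-byte, which the test suite asserts. Models persist to a single
versioned archive; loading checks the version, and the mRNA stage
refuses to score discriminants produced by a site model other than the
one it was trained with (a fingerprint comparison), since the binned
distribution features are meaningless across site models.

## Known limitations

* Site-level labels inherit the gene label, so every background site in
  a down-regulated gene is a mislabeled positive; the site stage's
  measurable ceiling is well below 1 by construction.
* The duplex scoring parameters are a reasonable EMBOSS-like choice
  exposed in configuration, not values fitted to data.
* The feature inventories are not canonical: the 20 site and 23 gene
  features implemented here cover the determinants of site efficacy and
  gene-level repression established in the experimental literature (AU
  context, 13-16 supplementary pairing, positional effects, site count,
  density and 17-35 nt spacing), and the feature schema is versioned so
  extensions are explicit.
* "Default parameters" for the gene stage are taken as C = 1; accessible
  alternatives can be set via `mrna_C`.
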