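## Shared fixtures built in code.

## Two well-separated Gaussian blobs in d dimensions, for SVM sanity tests.
make_blobs <- function(n_per_class = 40L, d = 4L, sep = 6, seed = 42L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * d, +sep / 2, 1),
                    n_per_class, d),
             matrix(stats::rnorm(n_per_class * d, -sep / 2, 1),
                    n_per_class, d))
  x <- pmin(pmax(x / sep, -1), 1) # keep roughly in [-1, 1]
  colnames(x) <- paste0("f", seq_len(d))
  y <- factor(rep(c("pos", "neg"), each = n_per_class),
              levels = c("pos", "neg"))
  list(x = x, y = y)
}

## Small synthetic dataset shared by the heavier pipeline tests.
small_dataset <- function(n = 250L, seed = 11L) {
  generate_dataset(synthetic_config(n_transcripts = n, n_mirnas = 2L,
                                    seed = seed))
}

## A miRNA whose seed supports every defect type.
FIX_MIRNA <- "UAGCUUAUCAGACUGAUGUUGA"
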