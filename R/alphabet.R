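#' @keywords internal
#' @importFrom e1071 svm
"_PACKAGE"

## Internal RNA alphabet utilities. Sequences are stored as upper-case RNA
## character strings (ACGU); integer encoding A=1, C=2, G=3, U=4 is used by
## the scanner and aligner.

RNA_BASES <- c("A", "C", "G", "U")

## Watson-Crick partner by integer code: A<->U, C<->G
WC_PARTNER <- c(4L, 3L, 2L, 1L)

## Pair-class lookup: PAIR_CLASS[target, mirna]
##   0 = Watson-Crick, 1 = G:U with the U on the miRNA (target G),
##   2 = G:U with the U on the target (miRNA G), 3 = other mismatch
PAIR_CLASS <- local({
  m <- matrix(3L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (q in 1:4) m[WC_PARTNER[q], q] <- 0L
  m["G", "U"] <- 1L # target G opposite miRNA U
  m["U", "G"] <- 2L # target U opposite miRNA G
  m
})

#' Normalize a nucleotide string to upper-case RNA
#'
#' Accepts DNA or RNA in either case; `T` is mapped to `U`.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages (e.g. a record id).
#' @return character vector over the alphabet ACGU.
#' @examples
#' normalize_rna("tagcttat")
#' @export
normalize_rna <- function(x, what = "sequence") {
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in %s at position %d",
                 substr(out[i], bad[i], bad[i]),
                 if (length(what) == length(x)) what[i] else what,
                 bad[i]), call. = FALSE)
  }
  out
}

encode_rna <- function(seq) {
  codes <- c(A = 1L, C = 2L, G = 3L, U = 4L)
  v <- codes[strsplit(seq, "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop("sequence contains characters outside ACGU")
  unname(v)
}

decode_rna <- function(codes) {
  paste(RNA_BASES[codes], collapse = "")
}

#' Reverse complement of an RNA string
#'
#' @param seq RNA string (ACGU).
#' @return the reverse complement, 5' to 3'.
#' @examples
#' rna_revcomp("AAGCUU")
#' @export
rna_revcomp <- function(seq) {
  v <- encode_rna(seq)
  decode_rna(rev(WC_PARTNER[v]))
}
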