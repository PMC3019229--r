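## File interfaces: FASTA sequence input (via Biostrings), the label table,
## prediction tables, and a simple key = value config format.

#' Read miRNA or 3' UTR sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA `T` is mapped to RNA `U`; record ids are
#' taken from the FASTA headers up to the first whitespace. Characters other
#' than ACGTU (e.g. `N`) are an error naming the record and position.
#'
#' @param path FASTA file.
#' @param kind `"mirna"` (each record a mature miRNA, 5' to 3', >= 16 nt) or
#'   `"utr"` (each record one transcript's 3' UTR, 5' to 3' beginning
#'   immediately after the stop codon).
#' @return named character vector of RNA sequences (names = ids, input order
#'   preserved).
#' @export
read_sequences <- function(path, kind = c("mirna", "utr")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record ", ids[which(!nzchar(seqs))[1L]])
  }
  seqs <- normalize_rna(seqs, ids)
  if (kind == "mirna" && any(nchar(seqs) < 16L)) {
    stop("miRNA shorter than 16 nt: ", ids[which(nchar(seqs) < 16L)[1L]])
  }
  if (anyDuplicated(ids)) {
    stop("duplicated record id: ", ids[anyDuplicated(ids)])
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of RNA sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a (transcript, miRNA) regulation label table
#'
#' The table stands in for microarray-derived regulation calls: each row
#' states whether a transcript was down-regulated or unaffected after
#' transfection of a given miRNA.
#'
#' @param path tab- or comma-delimited text file with a header and columns
#'   `transcript_id`, `mirna_id`, `label`; labels must be `down_regulated`
#'   or `unaffected`.
#' @return data.frame with those three columns; duplicate
#'   (transcript, miRNA) pairs or unknown label tokens are an error.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("transcript_id", "mirna_id", "label")
  if (!all(need %in% names(d))) {
    stop("label table must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[, need]
  bad <- setdiff(unique(d$label), c("down_regulated", "unaffected"))
  if (length(bad)) {
    stop("unknown label token: ", paste(bad, collapse = ", "),
         " (expected down_regulated or unaffected)")
  }
  key <- paste(d$transcript_id, d$mirna_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicated (transcript, miRNA) pair: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  d
}

#' Write site- and gene-level prediction tables
#'
#' Two tab-delimited files are written: `<out_prefix>_sites.tsv` with columns
#' `transcript_id`, `mirna_id`, `seed_type`, `seed_start`, `seed_end`
#' (1-based inclusive UTR coordinates), `discriminant`, and
#' `<out_prefix>_genes.tsv` with `transcript_id`, `mirna_id`, `n_sites`,
#' `gene_score`. Rows are sorted by descending score; empty inputs produce
#' header-only files.
#'
#' @param sites scored site table (with a `discriminant` column).
#' @param genes scored gene table (with a `gene_score` column).
#' @param out_prefix path prefix for the two output files.
#' @return character vector of the two file paths, invisibly.
#' @export
write_predictions <- function(sites, genes, out_prefix) {
  site_cols <- c("transcript_id", "mirna_id", "seed_type",
                 "seed_start", "seed_end", "discriminant")
  gene_cols <- c("transcript_id", "mirna_id", "n_sites", "gene_score")
  s <- as.data.frame(sites)[, site_cols, drop = FALSE]
  g <- as.data.frame(genes)[, gene_cols, drop = FALSE]
  if (nrow(s)) s <- s[order(-s$discriminant, s$transcript_id, s$mirna_id,
                            s$seed_start), , drop = FALSE]
  if (nrow(g)) g <- g[order(-g$gene_score, g$transcript_id, g$mirna_id), ,
                      drop = FALSE]
  paths <- paste0(out_prefix, c("_sites.tsv", "_genes.tsv"))
  utils::write.table(s, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Values are parsed as logical (`true`/`false`) or numeric where
#' possible, otherwise kept as strings. The result can be passed to
#' [mirsvm_config()] to override defaults.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (tolower(val) %in% c("true", "false")) {
      val <- as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    out[[key]] <- val
  }
  out
}
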