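## Two-stage model: fitting, prediction, and persistence.

ARCHIVE_VERSION <- "mirsvm-archive-1"

site_labels_for <- function(sites, labels) {
  key <- paste(sites$transcript_id, sites$mirna_id, sep = "\r")
  lab_key <- paste(labels$transcript_id, labels$mirna_id, sep = "\r")
  lab <- labels$label[match(key, lab_key)]
  if (anyNA(lab)) {
    stop("sites found for ", sum(is.na(lab)),
         " (transcript, miRNA) pair(s) missing from the label table")
  }
  lab
}

#' Fit the site stage of the two-stage model
#'
#' Scans and resolves candidate sites for every labeled (transcript, miRNA)
#' pair, builds and min/max-normalizes the site feature vectors, trains the
#' site-level SVM, obtains out-of-fold discriminant values by stratified
#' k-fold cross-validation, and fits the discriminant binner on them. The
#' result feeds [fit_mrna_stage()]; [mirsvm()] runs both stages.
#'
#' @inheritParams mirsvm
#' @return object of class `mirsvm_site_stage`.
#' @export
fit_site_stage <- function(mirnas, utrs, labels,
                           site_spec = kernel_spec(), k = 10L, seed = 1L) {
  sites <- scan_pairs(mirnas, utrs, labels[, c("transcript_id", "mirna_id")])
  if (!nrow(sites)) stop("no candidate sites found in any labeled pair")
  y_site <- site_labels_for(sites, labels)

  raw <- site_feature_matrix(sites, mirnas, utrs)
  normalizer <- fit_normalizer(raw)
  xn <- apply_normalizer(normalizer, raw)

  site_cv <- crossval_discriminants(xn, y_site, site_spec, k, seed)
  site_model <- train_site_model(xn, y_site, site_spec, seed)
  site_model$normalizer <- normalizer

  binner <- fit_binner(site_cv$discriminant)
  sites$discriminant <- site_cv$discriminant
  sites$cv_fold <- site_cv$fold

  out <- list(site_model = site_model, normalizer = normalizer,
              binner = binner, site_cv = site_cv, train_sites = sites,
              seed = seed)
  class(out) <- "mirsvm_site_stage"
  out
}

#' @export
print.mirsvm_site_stage <- function(x, ...) {
  cat("site stage of a two-stage miRNA target model
  ")
  print(x$site_model$spec)
  cat(sprintf("  %d sites; 10-fold CV ROC score %.3f (se %.3f)
",
              nrow(x$train_sites), x$site_cv$mean_auc, x$site_cv$se_auc))
  invisible(x)
}

#' Fit the mRNA stage on top of a fitted site stage
#'
#' Re-encodes the site stage's out-of-fold discriminants as per-gene
#' mRNA-level features, assembles the gene training set (all down-regulated
#' genes with sites, sampled unaffected genes, plus the extra
#' high-site-count negatives), and trains the linear gene-level SVM.
#'
#' @param stage a [fit_site_stage()] result.
#' @inheritParams mirsvm
#' @return a full `mirsvm` model object.
#' @export
fit_mrna_stage <- function(stage, utrs, labels, mrna_C = 1, seed = 1L,
                           negative_cap = 4000L, n_extra_high = 1000L) {
  stopifnot(inherits(stage, "mirsvm_site_stage"))
  gene_features <- mrna_feature_matrix(stage$train_sites, utrs,
                                       stage$binner)
  train_set <- assemble_training_set(gene_features, labels, seed,
                                     negative_cap, n_extra_high)
  mrna_model <- train_mrna_model(train_set$x, train_set$y, C = mrna_C,
                                 seed = seed, binner = stage$binner,
                                 site_model = stage$site_model)
  out <- list(site_model = stage$site_model, mrna_model = mrna_model,
              normalizer = stage$normalizer, binner = stage$binner,
              site_cv = stage$site_cv, train_sites = stage$train_sites,
              train_meta = train_set$meta,
              n_train = c(pos = sum(train_set$y == "pos"),
                          neg = sum(train_set$y == "neg")),
              seed = stage$seed, archive_version = ARCHIVE_VERSION,
              call = sys.call(-1L))
  class(out) <- "mirsvm"
  out
}

#' Fit the two-stage miRNA target prediction model
#'
#' Runs the full training pipeline: scan and resolve candidate sites for
#' every labeled (transcript, miRNA) pair; build and min/max-normalize the
#' site feature vectors; train the site-level SVM and obtain out-of-fold
#' discriminant values by stratified 10-fold cross-validation; fit the
#' discriminant binner on those values; build the mRNA-level training set
#' (all down-regulated genes with sites, sampled unaffected genes, plus the
#' extra high-site-count negatives); and train the mRNA-level linear SVM.
#' Sites inherit their gene's label at the site level.
#'
#' @param mirnas named character vector of miRNA sequences (5' to 3').
#' @param utrs named character vector of 3' UTR sequences.
#' @param labels label table with columns `transcript_id`, `mirna_id`,
#'   `label` (`down_regulated` / `unaffected`); see [read_label_table()].
#' @param site_spec [kernel_spec()] for the site stage (default: degree-5
#'   homogeneous polynomial, C = 2).
#' @param mrna_C cost factor of the mRNA-level linear SVM (default 1).
#' @param k cross-validation folds (default 10).
#' @param seed integer seed for fold assignment and negative sampling.
#' @param negative_cap,n_extra_high see [assemble_training_set()].
#' @return object of class `mirsvm` bundling both stages, the site
#'   normalizer, the discriminant binner, and the cross-validation results.
#' @seealso [predict.mirsvm()], [save_mirsvm()], [generate_dataset()]
#' @export
mirsvm <- function(mirnas, utrs, labels,
                   site_spec = kernel_spec(), mrna_C = 1,
                   k = 10L, seed = 1L,
                   negative_cap = 4000L, n_extra_high = 1000L) {
  cl <- match.call()
  stage <- fit_site_stage(mirnas, utrs, labels, site_spec, k, seed)
  out <- fit_mrna_stage(stage, utrs, labels, mrna_C, seed,
                        negative_cap, n_extra_high)
  out$call <- cl
  out
}

#' @export
print.mirsvm <- function(x, ...) {
  cat("Two-stage miRNA target prediction model\n")
  cat("  site stage:  "); print(x$site_model$spec)
  cat(sprintf("  site 10-fold CV ROC score: %.3f (se %.3f)\n",
              x$site_cv$mean_auc, x$site_cv$se_auc))
  cat(sprintf("  mRNA stage:  linear kernel (C = %g)\n", x$mrna_model$C))
  cat(sprintf("  trained on %d sites; %d positive / %d negative genes\n",
              nrow(x$train_sites), x$n_train["pos"], x$n_train["neg"]))
  invisible(x)
}

#' Summarise a fitted model
#'
#' @param object a fitted `mirsvm` model.
#' @param ... unused.
#' @method summary mirsvm
#' @export
summary.mirsvm <- function(object, ...) {
  w <- mrna_weights(object$mrna_model)
  out <- list(site_spec = object$site_model$spec,
              site_cv_fold_auc = object$site_cv$fold_auc,
              site_cv_mean_auc = object$site_cv$mean_auc,
              site_cv_se_auc = object$site_cv$se_auc,
              n_sites = nrow(object$train_sites),
              n_genes = object$n_train,
              binner = object$binner,
              mrna_weights = sort(w, decreasing = TRUE))
  class(out) <- "summary.mirsvm"
  out
}

#' @export
print.summary.mirsvm <- function(x, ...) {
  cat("Two-stage miRNA target model - training summary\n\n")
  cat("Site stage: "); print(x$site_spec)
  cat(sprintf("  %d sites; per-fold CV ROC scores:\n    %s\n",
              x$n_sites,
              paste(sprintf("%.3f", x$site_cv_fold_auc), collapse = " ")))
  cat(sprintf("  mean %.3f (se %.3f)\n\n", x$site_cv_mean_auc,
              x$site_cv_se_auc))
  cat(sprintf("mRNA stage: %d positive / %d negative genes\n",
              x$n_genes["pos"], x$n_genes["neg"]))
  cat("  largest linear weights (normalized feature scale):\n")
  top <- utils::head(x$mrna_weights, 5L)
  for (i in seq_along(top)) {
    cat(sprintf("    %-18s %+.3f\n", names(top)[i], top[i]))
  }
  invisible(x)
}

#' Extract mRNA-stage linear weights
#'
#' @param object a fitted `mirsvm` model.
#' @param ... unused.
#' @return named vector of linear decision weights on the normalized mRNA
#'   feature scale (positive = pushes toward "down-regulated").
#' @method coef mirsvm
#' @export
coef.mirsvm <- function(object, ...) {
  mrna_weights(object$mrna_model)
}

#' Plot the site-stage cross-validated ROC curve
#'
#' @param x a fitted `mirsvm` model.
#' @param ... passed to [graphics::plot()].
#' @method plot mirsvm
#' @export
plot.mirsvm <- function(x, ...) {
  pts <- x$site_cv$eval$points
  graphics::plot(pts$fpr, pts$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("Site-level 10-fold CV ROC (AUC %.3f)",
                                x$site_cv$mean_auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Predict miRNA target genes with a fitted model
#'
#' Scans the given (transcript, miRNA) pairs, scores every resolved site
#' with the final site model, re-encodes each gene's discriminants with the
#' training binner, and scores genes with the mRNA model. Pairs without any
#' candidate site are not scored (a gene with no seed match is not a
#' candidate target) and are reported separately.
#'
#' @param object a fitted `mirsvm` model.
#' @param mirnas,utrs named character vectors of sequences.
#' @param pairs data.frame of `transcript_id`, `mirna_id` pairs to score;
#'   defaults to all combinations.
#' @param ... unused.
#' @return list of class `mirsvm_prediction`: `sites` (with `discriminant`),
#'   `genes` (with `gene_score`), and `no_candidates` (pairs without sites).
#' @export
predict.mirsvm <- function(object, mirnas, utrs, pairs = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- expand.grid(transcript_id = names(utrs),
                         mirna_id = names(mirnas),
                         stringsAsFactors = FALSE)
  }
  sites <- scan_pairs(mirnas, utrs, pairs)
  if (nrow(sites)) {
    raw <- site_feature_matrix(sites, mirnas, utrs)
    xn <- apply_normalizer(object$normalizer, raw)
    sites$discriminant <- score_sites(object$site_model, xn)
    gene_features <- mrna_feature_matrix(sites, utrs, object$binner)
    genes <- predict_genes(object$mrna_model, gene_features,
                           site_model = object$site_model)
  } else {
    genes <- data.frame(transcript_id = character(0),
                        mirna_id = character(0), n_sites = integer(0),
                        gene_score = numeric(0), stringsAsFactors = FALSE)
  }
  key_p <- paste(pairs$transcript_id, pairs$mirna_id, sep = "\r")
  key_g <- paste(genes$transcript_id, genes$mirna_id, sep = "\r")
  no_cand <- pairs[!(key_p %in% key_g), , drop = FALSE]
  rownames(no_cand) <- NULL
  out <- list(sites = sites, genes = genes, no_candidates = no_cand)
  class(out) <- "mirsvm_prediction"
  out
}

#' @export
print.mirsvm_prediction <- function(x, ...) {
  cat(sprintf("predictions: %d sites, %d scored genes, %d without sites\n",
              nrow(x$sites), nrow(x$genes), nrow(x$no_candidates)))
  if (nrow(x$genes)) {
    top <- x$genes[order(-x$genes$gene_score), ][
      seq_len(min(5L, nrow(x$genes))), ]
    cat("top genes:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Persist a fitted model to a single archive file
#'
#' The archive holds both SVM stages, the site-level normalizer, the
#' discriminant binner, and a format version that [load_mirsvm()] checks.
#'
#' @param object a fitted `mirsvm` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_mirsvm <- function(object, path) {
  stopifnot(inherits(object, "mirsvm"))
  saveRDS(object, path, version = 2L)
  invisible(path)
}

#' Load a model archive written by [save_mirsvm()]
#'
#' @param path archive file.
#' @return the `mirsvm` model.
#' @export
load_mirsvm <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "mirsvm") ||
      !identical(obj$archive_version, ARCHIVE_VERSION)) {
    stop("not a compatible model archive: ", path)
  }
  obj
}
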