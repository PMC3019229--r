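## mRNA-level SVM.
##
## A linear-kernel SVM with default cost (C = 1) separates down-regulated
## from unaffected genes using the mRNA-level features. The model carries
## its own min/max normalizer, the discriminant binner, and the fingerprint
## of the site model whose cross-validated discriminants it was trained on:
## scoring new genes with a different site model would make the binned
## discriminant features meaningless, so the pairing is enforced.

#' Train the mRNA-level linear SVM
#'
#' @param x raw mRNA feature matrix (rows = genes); normalized internally to
#'   \[-1, 1\] with the same affine min/max scheme as the site level.
#' @param y gene labels (pos/neg or down_regulated/unaffected).
#' @param C cost factor (default 1, the library default).
#' @param seed integer seed (stored; fitting is deterministic).
#' @param binner the [fit_binner()] object used to build `x`.
#' @param site_model the `site_model` whose discriminants built `x`.
#' @return object of class `mrna_model`.
#' @export
train_mrna_model <- function(x, y, C = 1, seed = 1L, binner = NULL,
                             site_model = NULL) {
  x <- as.matrix(x)
  yf <- as_binary_factor(y)
  if (nlevels(droplevels(yf)) < 2L) {
    stop("both classes must be present to train")
  }
  norm <- fit_normalizer(x)
  xn <- apply_normalizer(norm, x)
  set.seed(seed)
  fit <- e1071::svm(xn, yf, scale = FALSE, kernel = "linear", cost = C)
  dv <- as.numeric(attr(stats::predict(fit, xn, decision.values = TRUE),
                        "decision.values"))
  sign_cal <- if (mean(dv[yf == "pos"]) >= mean(dv[yf == "neg"])) 1 else -1
  out <- list(fit = fit, sign = sign_cal, C = C, normalizer = norm,
              binner = binner,
              site_fingerprint = if (!is.null(site_model))
                site_model$fingerprint else NA_character_,
              features = colnames(x), seed = seed,
              schema_version = MRNA_SCHEMA_VERSION)
  class(out) <- "mrna_model"
  out
}

#' @export
print.mrna_model <- function(x, ...) {
  cat(sprintf("mRNA-level linear SVM (C = %g): %d features, %d SVs\n",
              x$C, length(x$features), nrow(x$fit$SV)))
  invisible(x)
}

## Linear decision weights w = sum alpha_i y_i x_i, on the normalized scale
mrna_weights <- function(model) {
  w <- drop(crossprod(model$fit$coefs, model$fit$SV)) * model$sign
  names(w) <- model$features
  w
}

#' Score genes with a fitted mRNA model
#'
#' @param model an `mrna_model`.
#' @param gene_features result of [mrna_feature_matrix()] built with the
#'   site model bound to `model` (enforced via the stored fingerprint when
#'   `site_model` is supplied).
#' @param site_model optional `site_model` used to produce the
#'   discriminants; a fingerprint mismatch is an error.
#' @return data.frame `transcript_id`, `mirna_id`, `n_sites`, `gene_score`.
#'   Genes with zero sites never reach this function (they are not
#'   candidates and are reported separately by [predict.mirsvm()]).
#' @export
predict_genes <- function(model, gene_features, site_model = NULL) {
  if (!is.null(site_model) && !is.na(model$site_fingerprint) &&
      !identical(site_model$fingerprint, model$site_fingerprint)) {
    stop("site model does not match the one this mRNA model was trained on")
  }
  xn <- apply_normalizer(model$normalizer, gene_features$x)
  dv <- attr(stats::predict(model$fit, xn, decision.values = TRUE),
             "decision.values")
  out <- gene_features$meta
  out$gene_score <- model$sign * as.numeric(dv)
  out
}
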