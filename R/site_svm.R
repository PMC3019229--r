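## Site-level SVM.
##
## A soft-margin SVM separates sites in down-regulated genes (positive) from
## sites in unaffected genes. The default kernel is the homogeneous
## polynomial K(x, y) = (x . y)^5 with cost factor C = 2; the raw decision
## function output ("discriminant value") is used downstream as the
## predicted regulatory strength of each site. Because the underlying
## library's decision-value sign depends on label encounter order, the sign
## is calibrated after training so that positive values mean predicted
## functional sites.

#' Kernel specification
#'
#' @param kind one of `"linear"`, `"gaussian"`, `"homogeneous_poly"`,
#'   `"inhomogeneous_poly"`. A homogeneous polynomial kernel has zero
#'   constant term: K(x, y) = (x . y)^degree.
#' @param C cost factor.
#' @param gamma RBF width (gaussian kernel only).
#' @param degree polynomial degree.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("homogeneous_poly", "linear", "gaussian",
                                 "inhomogeneous_poly"),
                        C = 2, gamma = 1, degree = 5) {
  kind <- match.arg(kind)
  stopifnot(C > 0, gamma > 0, degree == round(degree), degree >= 1)
  out <- list(kind = kind, C = C, gamma = gamma, degree = as.integer(degree))
  class(out) <- "kernel_spec"
  out
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$kind,
                  linear = "",
                  gaussian = sprintf(", gamma = %g", x$gamma),
                  sprintf(", degree = %d", x$degree))
  cat(sprintf("%s kernel (C = %g%s)\n", x$kind, x$C, extra))
  invisible(x)
}

## Polynomial kernels operate on L2-unit-normalized rows (cosine-normalized
## kernel): K(x, y) = (x.y)^d on unit vectors. Without this the degree-5
## kernel's dynamic range (about 20^5 on 20 features in [-1, 1]) makes the
## SMO solver numerically ill-conditioned. Linear and gaussian kernels use
## the min/max-normalized features directly.
kernel_input <- function(spec, x) {
  if (spec$kind %in% c("homogeneous_poly", "inhomogeneous_poly")) {
    rn <- sqrt(rowSums(x^2))
    rn[rn == 0] <- 1
    x / rn
  } else {
    x
  }
}

svm_args <- function(spec) {
  switch(spec$kind,
         linear = list(kernel = "linear", cost = spec$C),
         gaussian = list(kernel = "radial", gamma = spec$gamma,
                         cost = spec$C),
         homogeneous_poly = list(kernel = "polynomial", degree = spec$degree,
                                 gamma = 1, coef0 = 0, cost = spec$C),
         inhomogeneous_poly = list(kernel = "polynomial",
                                   degree = spec$degree, gamma = 1,
                                   coef0 = 1, cost = spec$C))
}

as_binary_factor <- function(y) {
  if (is.logical(y)) y <- ifelse(y, "pos", "neg")
  if (is.factor(y)) y <- as.character(y)
  y[y %in% c("down_regulated", "TRUE", "1")] <- "pos"
  y[y %in% c("unaffected", "FALSE", "0")] <- "neg"
  if (!all(y %in% c("pos", "neg"))) {
    stop("labels must be pos/neg, down_regulated/unaffected, or logical")
  }
  factor(y, levels = c("pos", "neg"))
}

#' Train the site-level SVM
#'
#' @param x normalized feature matrix (named columns, values in \[-1, 1\]).
#' @param y site labels: logical, `"pos"`/`"neg"`, or
#'   `"down_regulated"`/`"unaffected"` (a site inherits its gene's label).
#' @param spec a [kernel_spec()]; defaults to the homogeneous polynomial
#'   kernel of degree 5 with C = 2.
#' @param seed integer seed (training is deterministic given the data; the
#'   seed is stored for provenance).
#' @return object of class `site_model`: the fitted decision function, its
#'   sign calibration, kernel spec, and the feature schema. Polynomial
#'   kernels are cosine-normalized: the kernel is evaluated on L2
#'   unit-normalized feature rows (see the methods vignette); the same
#'   transform is applied automatically when scoring.
#' @export
train_site_model <- function(x, y, spec = kernel_spec(), seed = 1L) {
  x <- as.matrix(x)
  yf <- as_binary_factor(y)
  if (nlevels(droplevels(yf)) < 2L) {
    stop("both classes must be present to train")
  }
  set.seed(seed)
  xk <- kernel_input(spec, x)
  args <- c(list(x = xk, y = yf, scale = FALSE), svm_args(spec))
  fit <- do.call(e1071::svm, args)
  dv <- as.numeric(attr(stats::predict(fit, xk, decision.values = TRUE),
                        "decision.values"))
  sign_cal <- if (mean(dv[yf == "pos"]) >= mean(dv[yf == "neg"])) 1 else -1
  out <- list(fit = fit, sign = sign_cal, spec = spec,
              features = colnames(x), seed = seed,
              schema_version = SITE_SCHEMA_VERSION)
  out$fingerprint <- model_fingerprint(out)
  class(out) <- "site_model"
  out
}

#' @export
print.site_model <- function(x, ...) {
  cat("site-level SVM: ")
  print(x$spec)
  cat(sprintf("  %d features, %d support vectors\n",
              length(x$features), nrow(x$fit$SV)))
  invisible(x)
}

## Cheap deterministic fingerprint used to bind the mRNA model to the site
## model that produced its training discriminants.
model_fingerprint <- function(obj) {
  raw <- serialize(obj, NULL, version = 2L)
  raw <- raw[-seq_len(30L)] # skip header
  v <- as.integer(raw)
  sprintf("%d-%d-%d", length(v), sum(v) %% 997L,
          sum(v * (seq_along(v) %% 31L)) %% 99991L)
}

#' Score sites with a fitted site model
#'
#' @param model a `site_model`.
#' @param x normalized feature matrix with the model's feature schema.
#' @return numeric discriminant values; positive means predicted functional.
#' @export
score_sites <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!identical(colnames(x), model$features)) {
    stop("feature schema does not match the fitted site model")
  }
  xk <- kernel_input(model$spec, x)
  dv <- attr(stats::predict(model$fit, xk, decision.values = TRUE),
             "decision.values")
  model$sign * as.numeric(dv)
}

#' Stratified k-fold assignment
#'
#' @param y labels (see [train_site_model()]).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  yf <- as_binary_factor(y)
  if (any(table(yf) < k)) stop("fewer than k records in one class")
  set.seed(seed)
  fold <- integer(length(yf))
  for (lv in levels(yf)) {
    idx <- which(yf == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated discriminant values
#'
#' Runs stratified k-fold cross-validation: each record's discriminant value
#' comes only from the model that was not trained on it. These out-of-fold
#' discriminants are what the mRNA-level feature construction uses during
#' training, so no record's own label leaks into its site score.
#'
#' @param x normalized feature matrix.
#' @param y labels.
#' @param spec a [kernel_spec()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold partition.
#' @param folds optional precomputed fold assignment (used by
#'   [ablation_study()] to keep partitions identical across runs).
#' @return list with `discriminant` (per record), `fold` (assignment),
#'   `fold_auc` (per-fold ROC score), `mean_auc`, `se_auc`, and `eval`
#'   (pooled ROC over all out-of-fold discriminants).
#' @export
crossval_discriminants <- function(x, y, spec = kernel_spec(), k = 10L,
                                   seed = 1L, folds = NULL) {
  x <- as.matrix(x)
  yf <- as_binary_factor(y)
  if (is.null(folds)) folds <- stratified_folds(yf, k, seed)
  k <- max(folds)
  dv <- numeric(nrow(x))
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    m <- train_site_model(x[!test, , drop = FALSE], yf[!test], spec, seed)
    dv[test] <- score_sites(m, x[test, , drop = FALSE])
    fold_auc[f] <- roc_curve_auc(dv[test], yf[test])$auc
  }
  list(discriminant = dv, fold = folds, fold_auc = fold_auc,
       mean_auc = mean(fold_auc),
       se_auc = stats::sd(fold_auc) / sqrt(k),
       eval = roc_curve_auc(dv, yf))
}

#' Kernel and parameter grid search
#'
#' Evaluates kernel specifications by mean cross-validated ROC score over a
#' common fold partition and returns the best. The default grid is
#' C = 2^(2n-5) for 0 <= n <= 11, gamma = 2^(2n-13) for 0 <= n <= 10, and
#' degree 2-8. Ties are broken toward simpler kernels: linear, then
#' polynomial by increasing degree (homogeneous before inhomogeneous), then
#' gaussian; then smaller C and gamma.
#'
#' @param x normalized feature matrix.
#' @param y labels.
#' @param kinds kernel kinds to search.
#' @param C,gamma,degree parameter ranges.
#' @param k folds; `seed` fixes the partition.
#' @param seed integer seed.
#' @return list with `best` (a [kernel_spec()]) and `results` (one row per
#'   candidate with its mean CV AUC).
#' @export
svm_grid_search <- function(x, y,
                            kinds = c("linear", "gaussian",
                                      "homogeneous_poly",
                                      "inhomogeneous_poly"),
                            C = 2^(2 * (0:11) - 5),
                            gamma = 2^(2 * (0:10) - 13),
                            degree = 2:8,
                            k = 10L, seed = 1L) {
  folds <- stratified_folds(y, k, seed)
  cand <- list()
  for (kind in kinds) {
    for (cc in C) {
      if (kind == "linear") {
        cand[[length(cand) + 1L]] <- kernel_spec("linear", C = cc)
      } else if (kind == "gaussian") {
        for (g in gamma) {
          cand[[length(cand) + 1L]] <- kernel_spec("gaussian", C = cc,
                                                   gamma = g)
        }
      } else {
        for (d in degree) {
          cand[[length(cand) + 1L]] <- kernel_spec(kind, C = cc, degree = d)
        }
      }
    }
  }
  complexity <- function(s) {
    switch(s$kind, linear = 0, homogeneous_poly = s$degree,
           inhomogeneous_poly = s$degree + 0.5, gaussian = 100)
  }
  res <- data.frame(kind = vapply(cand, `[[`, "", "kind"),
                    C = vapply(cand, `[[`, 0, "C"),
                    gamma = vapply(cand, `[[`, 0, "gamma"),
                    degree = vapply(cand, `[[`, 0L, "degree"),
                    mean_auc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(cand)) {
    cv <- crossval_discriminants(x, y, cand[[i]], k, seed, folds = folds)
    res$mean_auc[i] <- cv$mean_auc
  }
  cx <- vapply(cand, complexity, 0)
  ord <- order(-res$mean_auc, cx, res$C, res$gamma)
  list(best = cand[[ord[1L]]], results = res[ord, , drop = FALSE])
}
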