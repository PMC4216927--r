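# Cross-validated evaluation of held-out expression prediction, the
# nearest-neighbor baseline, the motif/protein randomization control, and
# clustering-based subtype recovery.

#' Spearman rank correlation
#'
#' Average ranks for ties. A constant vector makes the coefficient undefined;
#' `NA` is returned with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Spearman's rho.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Nearest-neighbor expression prediction baseline
#'
#' Returns the expression column of the training sample whose protein profile
#' has the smallest Euclidean distance to `p_test`; ties are broken by
#' training order.
#'
#' @param p_train Training samples x proteins matrix.
#' @param y_train Genes x training-samples expression matrix.
#' @param p_test A single protein profile (numeric vector).
#' @return The nearest training sample's expression vector.
#' @export
nearest_neighbor_predict <- function(p_train, y_train, p_test) {
  if (nrow(p_train) == 0) stop("empty training set", call. = FALSE)
  dist2 <- colSums((t(p_train) - as.numeric(p_test))^2)
  y_train[, which.min(dist2)]
}

#' Cross-validated evaluation of affinity regression
#'
#' For each fold the model is trained on the training samples alone: gene and
#' protein means are computed on the training fold, the ridge penalty is
#' selected by nested CV inside the fold (unless `lambda` is fixed), and each
#' held-out sample's expression is predicted as `D W p` and scored by
#' Spearman correlation. A 1-nearest-neighbor baseline in protein space is
#' scored on the same folds.
#'
#' @param y Genes x samples expression matrix (uncentered or centered; folds
#'   are always re-centered with training-fold means so no held-out
#'   information leaks into training).
#' @param d Genes x TFs motif-hit matrix.
#' @param p Samples x proteins matrix.
#' @param k Number of folds (default 6).
#' @param labels Optional named subtype labels; folds are then stratified so
#'   each fold balances subtypes.
#' @param lambda Fixed ridge penalty, or `NULL` to select per fold.
#' @param lambda_grid Grid for nested selection.
#' @param inner_folds Folds for nested lambda selection.
#' @param variance_fraction Passed to [reduce_protein_features()].
#' @param seed Integer seed (fold assignment and nested selection).
#' @param return_models Keep the per-fold fitted models.
#' @return An object of class `affreg_cv`: a list with `samples` (data frame
#'   of sample_id, fold, rho_model, rho_nn), `mean_rho`, `sd_rho`,
#'   `mean_rho_nn`, `fold_lambda`, and optionally `models`.
#' @export
cross_validate <- function(y, d, p, k = 6, labels = NULL, lambda = NULL,
                           lambda_grid = default_lambda_grid(),
                           inner_folds = 3, variance_fraction = 0.99,
                           seed = 1, return_models = FALSE) {
  m <- ncol(y)
  if (k > m) stop("k exceeds the number of samples", call. = FALSE)
  if (!is.null(labels)) labels <- labels[colnames(y)]
  fold <- .make_folds(m, k, labels = labels, seed = seed)
  res <- data.frame(sample_id = colnames(y), fold = fold,
                    rho_model = NA_real_, rho_nn = NA_real_,
                    stringsAsFactors = FALSE)
  fold_lambda <- numeric(k)
  models <- if (return_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    gm <- rowMeans(y[, tr, drop = FALSE])
    pm <- colMeans(p[tr, , drop = FALSE])
    ytr <- y[, tr, drop = FALSE] - gm
    ptr <- sweep(p[tr, , drop = FALSE], 2L, pm)
    attr(ytr, "centered") <- TRUE
    attr(ptr, "centered") <- TRUE
    lam <- lambda %||% as.numeric(
      select_lambda(ytr, d, ptr, lambda_grid = lambda_grid,
                    k_folds = inner_folds, seed = seed + f,
                    variance_fraction = variance_fraction))
    fold_lambda[f] <- lam
    fit <- affreg_fit(ytr, d, ptr, lambda = lam,
                      variance_fraction = variance_fraction)
    if (return_models) models[[f]] <- fit
    for (i in te) {
      pnew <- p[i, ] - pm
      yhat <- d %*% fit$W %*% pnew
      yobs <- y[, i] - gm
      res$rho_model[res$sample_id == colnames(y)[i]] <-
        suppressWarnings(spearman_cor(as.numeric(yhat), yobs))
      ynn <- nearest_neighbor_predict(ptr, ytr, pnew)
      res$rho_nn[res$sample_id == colnames(y)[i]] <-
        suppressWarnings(spearman_cor(ynn, yobs))
    }
  }
  structure(list(samples = res,
                 mean_rho = mean(res$rho_model, na.rm = TRUE),
                 sd_rho = sd(res$rho_model),
                 mean_rho_nn = mean(res$rho_nn, na.rm = TRUE),
                 fold_lambda = fold_lambda,
                 models = models),
            class = "affreg_cv")
}

#' @export
print.affreg_cv <- function(x, ...) {
  cat(sprintf("cross-validated affinity regression over %d folds, %d samples\n",
              length(x$fold_lambda), nrow(x$samples)))
  cat(sprintf("  mean Spearman rho %.3f (sd %.3f); nearest-neighbor baseline %.3f\n",
              x$mean_rho, x$sd_rho, x$mean_rho_nn))
  invisible(x)
}

#' Randomization control for cross-validated performance
#'
#' Independently permutes each gene's motif-hit row of `d` and reassigns the
#' protein profiles of `p` across samples, then runs [cross_validate()] on
#' the destroyed data. On real signal this drives the mean held-out Spearman
#' correlation to zero.
#'
#' @inheritParams cross_validate
#' @param ... Further arguments passed to [cross_validate()].
#' @return An `affreg_cv` object.
#' @export
randomization_control <- function(y, d, p, k = 6, seed = 1, ...) {
  set.seed(seed)
  d_perm <- t(apply(d, 1L, sample))
  dimnames(d_perm) <- dimnames(d)
  p_perm <- p[sample(nrow(p)), , drop = FALSE]
  rownames(p_perm) <- rownames(p)
  cross_validate(y, d_perm, p_perm, k = k, seed = seed + 1L, ...)
}

#' Hierarchical clustering of activity profiles
#'
#' Agglomerative clustering of sample columns with average linkage and
#' distance `1 - Pearson correlation`, cut to `k` clusters.
#'
#' @param a Entities x samples activity matrix.
#' @param k Number of clusters (2 <= k <= number of samples).
#' @return Integer cluster labels named by sample id.
#' @export
cluster_activities <- function(a, k) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > ncol(a)) stop("k exceeds the number of samples", call. = FALSE)
  d <- as.dist(1 - cor(unclass(a)))
  cutree(hclust(d, method = "average"), k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model; invariant to label
#' renaming and symmetric in its arguments.
#'
#' @param labels_a,labels_b Partitions of the same items.
#' @return The adjusted Rand index (1 for identical partitions).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions differ in length", call. = FALSE)
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}
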