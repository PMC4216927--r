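# Core bilinear model. The regression D W P' = Y is reduced by
# left-multiplying with Y', giving (Y'D) W P' = Y'Y, whose output is the
# sample similarity matrix. Vectorizing yields a Kronecker-structured ridge
# problem that is solved through the SVDs of the two factor matrices without
# ever materializing the Kronecker product.

#' Reduce protein features by singular value decomposition
#'
#' Computes the SVD of the centered protein matrix and retains the smallest
#' rank whose squared singular values account for at least
#' `variance_fraction` of the total. The reduced representation is the
#' left singular vectors scaled by the singular values.
#'
#' @param p Centered samples x proteins matrix.
#' @param variance_fraction Fraction of squared-singular-value mass to retain,
#'   in (0, 1]. Default 0.99: the reduction exists to drop numerically
#'   negligible directions, and retained variance bounds how much of the
#'   interaction matrix remains identifiable.
#' @return List with `u`, `d`, `v` (sign-fixed SVD of `p`), `rank` (retained
#'   rank) and `scores` (samples x rank reduced features `U_r diag(d_r)`).
#' @export
reduce_protein_features <- function(p, variance_fraction = 0.99) {
  .check_numeric_matrix(p, "p")
  if (variance_fraction <= 0 || variance_fraction > 1) {
    stop("variance_fraction must be in (0, 1]", call. = FALSE)
  }
  if (all(p == 0)) stop("protein matrix is identically zero", call. = FALSE)
  s <- .fix_svd_signs(svd(p))
  tol <- max(dim(p)) * .Machine$double.eps * s$d[1]
  nrank <- sum(s$d > tol)
  r <- which(cumsum(s$d^2) / sum(s$d^2) >= variance_fraction - 1e-12)[1]
  r <- min(r, nrank)
  list(u = s$u, d = s$d, v = s$v, rank = r,
       scores = s$u[, seq_len(r), drop = FALSE] %*% diag(s$d[seq_len(r)], r))
}

# lambda-independent factorization of the reduced system; fitting at any
# ridge value is then an elementwise rescaling (reused across a CV grid)
.ar_core <- function(y, d, p, variance_fraction) {
  sp <- reduce_protein_features(p, variance_fraction)
  r <- sp$rank
  a <- crossprod(y, d)            # M x Q, the similarity-space design Y'D
  k <- crossprod(y)               # M x M target Y'Y
  sa <- .fix_svd_signs(svd(a))
  tol <- max(dim(a)) * .Machine$double.eps * max(sa$d[1], 0)
  keep <- sa$d > tol
  sa$u <- sa$u[, keep, drop = FALSE]
  sa$v <- sa$v[, keep, drop = FALSE]
  sa$d <- sa$d[keep]
  num <- diag(sa$d, length(sa$d)) %*%
    (t(sa$u) %*% k %*% sp$u[, seq_len(r), drop = FALSE]) %*%
    diag(sp$d[seq_len(r)], r)
  list(sa = sa, sp = sp, num = num,
       den_base = outer(sa$d^2, sp$d[seq_len(r)]^2))
}

.ar_solve <- function(core, lambda) {
  w_red <- core$sa$v %*% (core$num / (core$den_base + lambda))
  r <- core$sp$rank
  list(w_reduced = w_red,
       w = w_red %*% t(core$sp$v[, seq_len(r), drop = FALSE]))
}

#' Fit the affinity regression model
#'
#' Solves `min ||(P_r (x) Y'D) vec(W_r) - vec(Y'Y)||^2 + lambda ||vec(W_r)||^2`
#' where `P_r` is the SVD-reduced protein representation, then projects the
#' solution back through the protein right singular basis so `W` is reported
#' over the original proteins.
#'
#' @param y Centered genes x samples expression matrix.
#' @param d Genes x TFs binary motif-hit matrix, rows aligned with `y`.
#' @param p Centered samples x proteins matrix, rows aligned with `y`'s
#'   columns.
#' @param lambda Ridge penalty, >= 0 (strictly positive recommended).
#' @param variance_fraction Passed to [reduce_protein_features()].
#' @return An object of class `affreg_model` with elements `W`
#'   (TFs x proteins), `W_reduced`, `lambda`, `protein_svd`, `rank_kept`,
#'   `tf_ids`, `protein_ids`, `training_sample_ids`.
#' @export
affreg_fit <- function(y, d, p, lambda = 1, variance_fraction = 0.99) {
  .check_numeric_matrix(y, "y")
  .check_numeric_matrix(d, "d")
  .check_numeric_matrix(p, "p")
  if (!identical(rownames(y), rownames(d))) {
    stop("gene rows of y and d are not aligned", call. = FALSE)
  }
  if (!identical(colnames(y), rownames(p))) {
    stop("samples of y (columns) and p (rows) are not aligned", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a single non-negative number", call. = FALSE)
  }
  if (!.is_row_centered(y)) stop("y must be mean-centered per gene", call. = FALSE)
  if (!.is_col_centered(p)) stop("p must be mean-centered per protein", call. = FALSE)
  core <- .ar_core(y, d, p, variance_fraction)
  sol <- .ar_solve(core, lambda)
  w <- sol$w
  dimnames(w) <- list(colnames(d), colnames(p))
  structure(list(W = w,
                 W_reduced = sol$w_reduced,
                 lambda = lambda,
                 variance_fraction = variance_fraction,
                 protein_svd = core$sp[c("u", "d", "v", "rank")],
                 rank_kept = core$sp$rank,
                 tf_ids = colnames(d),
                 protein_ids = colnames(p),
                 training_sample_ids = colnames(y)),
            class = "affreg_model")
}

#' @export
print.affreg_model <- function(x, ...) {
  cat(sprintf("affinity regression model: %d TFs x %d proteins\n",
              nrow(x$W), ncol(x$W)))
  cat(sprintf("  ridge lambda %.4g, protein SVD rank %d (%.0f%% variance), %d training samples\n",
              x$lambda, x$rank_kept, 100 * x$variance_fraction,
              length(x$training_sample_ids)))
  invisible(x)
}

.check_proteins <- function(model, ids) {
  unknown <- setdiff(ids, model$protein_ids)
  if (length(unknown) > 0) {
    stop(sprintf("unknown protein(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(model$protein_ids, ids)
  if (length(missing) > 0) {
    stop(sprintf("missing protein(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
}

#' Predict a relative expression profile from a protein profile
#'
#' Returns `y_hat = D W p'`. Predictions are meaningful up to an affine
#' transform (the similarity-space reduction fixes neither offset nor scale),
#' so downstream evaluation uses rank correlation.
#'
#' @param model A fitted `affreg_model`.
#' @param d Genes x TFs motif-hit matrix with columns matching the model.
#' @param p_new A named protein vector, or a samples x proteins matrix,
#'   centered with the training protein means.
#' @return Genes x samples matrix of predicted relative expression.
#' @export
predict_expression <- function(model, d, p_new) {
  if (is.vector(p_new)) p_new <- matrix(p_new, nrow = 1, dimnames = list("sample", names(p_new)))
  if (is.null(colnames(p_new))) stop("p_new must carry protein names", call. = FALSE)
  .check_proteins(model, colnames(p_new))
  if (!identical(colnames(d), model$tf_ids)) {
    stop("TF columns of d do not match the model", call. = FALSE)
  }
  d %*% model$W %*% t(p_new[, model$protein_ids, drop = FALSE])
}

.activity_matrix <- function(values, kind) {
  structure(values, kind = kind, class = c("activity_matrix", "matrix", "array"))
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("%s matrix: %d entities x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Infer per-sample TF activities from protein profiles
#'
#' Maps protein profiles through the model: `W P'`.
#'
#' @param model A fitted `affreg_model`.
#' @param p Centered samples x proteins matrix with the model's proteins.
#' @return TFs x samples activity matrix (`kind = "tf_activity"`).
#' @export
infer_tf_activities <- function(model, p) {
  .check_numeric_matrix(p, "p")
  .check_proteins(model, colnames(p))
  act <- model$W %*% t(p[, model$protein_ids, drop = FALSE])
  rownames(act) <- model$tf_ids
  .activity_matrix(act, "tf_activity")
}

#' Infer per-sample signaling-protein activities from expression profiles
#'
#' Maps expression profiles through the motif matrix and the model:
#' `Y' D W`, reported as proteins x samples.
#'
#' @param model A fitted `affreg_model`.
#' @param y Centered genes x samples expression matrix.
#' @param d Genes x TFs motif-hit matrix, rows aligned with `y`, columns
#'   matching the model.
#' @return Proteins x samples activity matrix (`kind = "protein_activity"`).
#' @export
infer_protein_activities <- function(model, y, d) {
  .check_numeric_matrix(y, "y")
  if (!identical(rownames(y), rownames(d))) {
    stop("gene rows of y and d are not aligned", call. = FALSE)
  }
  if (!identical(colnames(d), model$tf_ids)) {
    stop("TF columns of d do not match the model", call. = FALSE)
  }
  act <- t(crossprod(y, d) %*% model$W)
  rownames(act) <- model$protein_ids
  .activity_matrix(act, "protein_activity")
}

#' Default ridge penalty grid
#'
#' @param n Number of grid points.
#' @return `n` log-spaced values spanning `[1e-3, 1e3]`.
#' @export
default_lambda_grid <- function(n = 13) 10^seq(-3, 3, length.out = n)

#' Select the ridge penalty by cross-validation
#'
#' k-fold CV over a grid: each fold is centered with training-fold means,
#' fitted at every grid value (the factorization is shared across the grid),
#' and scored by the mean per-sample Spearman correlation between predicted
#' and observed held-out expression. Ties are broken toward the smallest
#' lambda.
#'
#' @param y Genes x samples expression matrix (raw or centered; folds are
#'   re-centered with training means).
#' @param d Genes x TFs motif-hit matrix.
#' @param p Samples x proteins matrix.
#' @param lambda_grid Candidate penalties.
#' @param k_folds Number of folds (>= 2, <= number of samples).
#' @param seed Integer seed controlling the fold assignment.
#' @param variance_fraction Passed to [reduce_protein_features()].
#' @return The selected lambda (a single number with a `"cv_scores"`
#'   attribute holding the mean score per grid value).
#' @export
select_lambda <- function(y, d, p, lambda_grid = default_lambda_grid(),
                          k_folds = 5, seed = 1, variance_fraction = 0.99) {
  if (length(lambda_grid) == 0) stop("lambda_grid is empty", call. = FALSE)
  m <- ncol(y)
  if (k_folds > m) stop("k_folds exceeds the number of samples", call. = FALSE)
  lambda_grid <- sort(lambda_grid)
  fold <- .make_folds(m, k_folds, seed = seed)
  scores <- matrix(NA_real_, m, length(lambda_grid))
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    gm <- rowMeans(y[, tr, drop = FALSE])
    pm <- colMeans(p[tr, , drop = FALSE])
    core <- .ar_core(y[, tr, drop = FALSE] - gm,
                     d, sweep(p[tr, , drop = FALSE], 2L, pm),
                     variance_fraction)
    for (j in seq_along(lambda_grid)) {
      w <- .ar_solve(core, lambda_grid[j])$w
      yhat <- d %*% w %*% t(sweep(p[te, , drop = FALSE], 2L, pm))
      for (i in seq_along(te)) {
        scores[te[i], j] <- suppressWarnings(
          spearman_cor(yhat[, i], y[, te[i]] - gm))
      }
    }
  }
  mean_score <- colMeans(scores, na.rm = TRUE)
  best <- max(mean_score)
  pick <- which(mean_score >= best - 1e-12)[1]
  structure(lambda_grid[pick], cv_scores = setNames(mean_score, lambda_grid))
}

#' Save / load a fitted model
#'
#' Single-file serialization that round-trips the model exactly.
#'
#' @param model An `affreg_model`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "affreg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "affreg_model")) stop("not an affreg model file", call. = FALSE)
  model
}
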