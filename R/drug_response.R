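# Relating inferred protein activities to drug sensitivity across cell
# lines: variability filter on log-GI50, protein-drug Spearman correlation
# map, two-way clustering, elastic-net stability signatures, and cross-drug
# transfer of ridge response models.

#' Filter drugs by response variability
#'
#' Keeps drugs whose log-GI50 standard deviation across cell lines is
#' strictly greater than `sd_threshold` (missing entries ignored).
#'
#' @param gi50 Cell lines x drugs matrix of log-transformed GI50, `NA`
#'   allowed.
#' @param sd_threshold Strict cutoff (default 0.5).
#' @return The matrix restricted to variable drugs.
#' @export
filter_variable_drugs <- function(gi50, sd_threshold = 0.5) {
  sds <- apply(gi50, 2L, sd, na.rm = TRUE)
  gi50[, !is.na(sds) & sds > sd_threshold, drop = FALSE]
}

#' Spearman correlation between protein activities and drug responses
#'
#' Pairwise over the cell lines shared by each protein-drug pair after
#' masking missing GI50 values; pairs with fewer than `min_shared` shared
#' lines are reported missing.
#'
#' @param a Proteins x cell-lines activity matrix.
#' @param gi50 Cell lines x drugs response matrix (`NA` allowed).
#' @param min_shared Minimum shared observations per pair (default 3).
#' @return Proteins x drugs matrix of Spearman correlations.
#' @export
protein_drug_correlation <- function(a, gi50, min_shared = 3) {
  cells <- intersect(colnames(a), rownames(gi50))
  if (length(cells) == 0) stop("no shared cell lines", call. = FALSE)
  x <- t(unclass(a)[, cells, drop = FALSE])
  g <- gi50[cells, , drop = FALSE]
  cc <- suppressWarnings(cor(x, g, method = "spearman",
                             use = "pairwise.complete.obs"))
  n_shared <- crossprod(matrix(1, length(cells), ncol(x)), !is.na(g))
  cc[n_shared < min_shared] <- NA_real_
  if (any(colSums(!is.na(cc)) == 0)) {
    warning("some drugs share too few cell lines with the activities; columns all-missing")
  }
  cc
}

#' Two-way hierarchical clustering of a correlation matrix
#'
#' Average-linkage clustering of rows and columns with distance
#' `1 - Pearson correlation` (pairwise-complete when values are missing).
#'
#' @param cmat Proteins x drugs correlation matrix.
#' @return List with `row_order`, `col_order`, `row_hclust`, `col_hclust`.
#' @export
two_way_cluster <- function(cmat) {
  if (any(rowSums(!is.na(cmat)) == 0) || any(colSums(!is.na(cmat)) == 0)) {
    stop("all-missing rows/columns must be removed before clustering", call. = FALSE)
  }
  dist_of <- function(m) as.dist(1 - cor(t(m), use = "pairwise.complete.obs"))
  hr <- hclust(dist_of(cmat), method = "average")
  hc <- hclust(dist_of(t(cmat)), method = "average")
  list(row_order = rownames(cmat)[hr$order], col_order = colnames(cmat)[hc$order],
       row_hclust = hr, col_hclust = hc)
}

#' Elastic-net stability signature of a drug
#'
#' The elastic-net mixing parameter alpha is chosen on the full data by
#' k-fold cross-validation over an even grid inside `alpha_range`. Then, for
#' each of `n_iter` iterations, the model is refit on a random subsample of
#' cell lines (penalty chosen per fit by inner CV at the one-standard-error
#' rule). The signature consists of the features with nonzero coefficients in
#' at least `min_count` iterations whose coefficient signs agree across all
#' their selections.
#'
#' @param a Proteins x cell-lines activity matrix.
#' @param response Named numeric vector of log-GI50 for one drug (`NA`
#'   allowed; missing cells are masked).
#' @param alpha_range Lower/upper bound of the alpha grid (default
#'   `c(0.001, 0.2)`).
#' @param n_alpha Number of grid values (default 20, evenly spaced).
#' @param n_iter Number of stability iterations (default 100).
#' @param subsample Fraction of cell lines per iteration (default 0.8).
#' @param min_count Minimum selections for signature membership (default 10).
#' @param folds CV folds for alpha selection (default 5).
#' @param seed Integer seed.
#' @return An object of class `drug_signature`: list with `features` (data
#'   frame of protein, selection_count, sign), `alpha`, `cv_mse`, `counts`
#'   (all proteins), and `settings`.
#' @export
fit_drug_signature <- function(a, response, alpha_range = c(0.001, 0.2),
                               n_alpha = 20, n_iter = 100, subsample = 0.8,
                               min_count = 10, folds = 5, seed = 1) {
  cells <- intersect(colnames(a), names(response))
  cells <- cells[!is.na(response[cells])]
  if (length(cells) < 10) {
    stop("fewer than 10 cell lines with observed response", call. = FALSE)
  }
  x <- t(unclass(a)[, cells, drop = FALSE])
  yv <- as.numeric(response[cells])
  n <- length(yv)
  alpha_grid <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  cvm <- vapply(alpha_grid, function(al) {
    min(glmnet::cv.glmnet(x, yv, alpha = al, foldid = foldid)$cvm)
  }, 0)
  alpha <- alpha_grid[which.min(cvm)]
  counts <- setNames(integer(ncol(x)), colnames(x))
  signs <- vector("list", ncol(x))
  names(signs) <- colnames(x)
  for (i in seq_len(n_iter)) {
    idx <- sample(n, floor(subsample * n))
    cv <- glmnet::cv.glmnet(x[idx, , drop = FALSE], yv[idx], alpha = alpha,
                            nfolds = folds)
    cf <- as.numeric(coef(cv, s = "lambda.1se"))[-1]
    nz <- which(cf != 0)
    counts[nz] <- counts[nz] + 1L
    for (j in nz) signs[[j]] <- c(signs[[j]], sign(cf[j]))
  }
  consistent <- vapply(signs, function(s) length(s) > 0 && length(unique(s)) == 1, TRUE)
  sel <- which(counts >= min_count & consistent)
  features <- data.frame(protein = names(counts)[sel],
                         selection_count = unname(counts[sel]),
                         sign = vapply(signs[sel], `[[`, 0, 1L),
                         stringsAsFactors = FALSE)
  structure(list(features = features[order(-features$selection_count), , drop = FALSE],
                 alpha = alpha, cv_mse = min(cvm), counts = counts,
                 settings = list(alpha_range = alpha_range, n_iter = n_iter,
                                 subsample = subsample, min_count = min_count,
                                 folds = folds, seed = seed, n_cells = n)),
            class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat(sprintf("elastic-net drug signature: alpha %.3f, CV MSE %.3f, %d feature(s)\n",
              x$alpha, x$cv_mse, nrow(x$features)))
  if (nrow(x$features) > 0) print(x$features, row.names = FALSE)
  invisible(x)
}

#' Cross-drug transfer of ridge response models
#'
#' For each drug a ridge model of its response from protein activities is
#' evaluated out-of-fold: every prediction for a cell line comes from a model
#' whose training folds excluded that line. Entry (i, j) is the Spearman
#' correlation between drug i's out-of-fold predictions and drug j's observed
#' responses over the cell lines shared by both.
#'
#' @param a Proteins x cell-lines activity matrix.
#' @param gi50 Cell lines x drugs response matrix (`NA` allowed).
#' @param k Folds for the out-of-fold predictions (default 5).
#' @param seed Integer seed.
#' @param min_shared Minimum shared cells to report a correlation.
#' @return Drugs x drugs matrix; rows index the trained drug, columns the
#'   evaluated drug.
#' @export
cross_drug_transfer <- function(a, gi50, k = 5, seed = 1, min_shared = 5) {
  cells <- intersect(colnames(a), rownames(gi50))
  x_all <- t(unclass(a)[, cells, drop = FALSE])
  g <- gi50[cells, , drop = FALSE]
  drugs <- colnames(g)
  preds <- matrix(NA_real_, length(cells), length(drugs),
                  dimnames = list(cells, drugs))
  set.seed(seed)
  for (dg in drugs) {
    obs <- which(!is.na(g[, dg]))
    if (length(obs) < 2 * k) next
    fold <- sample(rep_len(seq_len(k), length(obs)))
    for (f in seq_len(k)) {
      tr <- obs[fold != f]
      te <- obs[fold == f]
      cv <- glmnet::cv.glmnet(x_all[tr, , drop = FALSE], g[tr, dg], alpha = 0,
                              nfolds = min(5, length(tr)))
      preds[te, dg] <- as.numeric(predict(cv, x_all[te, , drop = FALSE],
                                          s = "lambda.min"))
    }
  }
  out <- matrix(NA_real_, length(drugs), length(drugs),
                dimnames = list(train = drugs, test = drugs))
  for (i in drugs) {
    for (j in drugs) {
      ok <- which(!is.na(preds[, i]) & !is.na(g[, j]))
      if (length(ok) >= min_shared) {
        out[i, j] <- suppressWarnings(spearman_cor(preds[ok, i], g[ok, j]))
      }
    }
  }
  out
}
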