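# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic SVD sign convention: the largest-magnitude entry of every
# left singular vector is made positive (right vectors flipped to match)
.fix_svd_signs <- function(s) {
  for (j in seq_along(s$d)) {
    i <- which.max(abs(s$u[, j]))
    if (s$u[i, j] < 0) {
      s$u[, j] <- -s$u[, j]
      s$v[, j] <- -s$v[, j]
    }
  }
  s
}

.check_numeric_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

.is_row_centered <- function(x, tol = 1e-6) {
  max(abs(rowMeans(x))) < tol * max(1, max(abs(x)))
}

.is_col_centered <- function(x, tol = 1e-6) {
  max(abs(colMeans(x))) < tol * max(1, max(abs(x)))
}

# fold assignment, optionally stratified so each fold balances label counts
.make_folds <- function(n, k, labels = NULL, seed = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the number of samples (%d)", k, n),
                  call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(labels)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(labels) == n)
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

# centered Mann-Whitney effect (U - n1*n2/2) for every row of a matrix,
# used in permutation loops where calling wilcox.test would dominate runtime
.u_effects <- function(values, ia, ib) {
  na <- length(ia)
  apply(values, 1L, function(v) {
    r <- rank(c(v[ia], v[ib]))
    sum(r[seq_len(na)]) - na * (na + 1) / 2 - na * length(ib) / 2
  })
}
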