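random_instance <- function(seed, n = 30, m = 10, q = 8, s = 6) {
  set.seed(seed)
  y <- matrix(rnorm(n * m), n, dimnames = list(paste0("g", 1:n), paste0("s", 1:m)))
  y <- y - rowMeans(y)
  d <- matrix(rbinom(n * q, 1, 0.3), n, dimnames = list(rownames(y), paste0("TF", 1:q)))
  for (j in which(colSums(d) == 0)) d[1, j] <- 1L
  p <- matrix(rnorm(m * s), m, dimnames = list(colnames(y), paste0("PR", 1:s)))
  p <- sweep(p, 2, colMeans(p))
  attr(y, "centered") <- TRUE
  attr(p, "centered") <- TRUE
  list(y = y, d = d, p = p)
}

test_that("protein SVD reduction keeps the stated variance fraction", {
  set.seed(1)
  u <- rnorm(10); v <- rnorm(6)
  p1 <- tcrossprod(u, v)                    # rank 1
  expect_identical(reduce_protein_features(p1, 0.95)$rank, 1L)
  p <- matrix(rnorm(60), 10)
  p <- sweep(p, 2, colMeans(p))
  red <- reduce_protein_features(p, 1.0)
  expect_identical(red$rank, qr(p)$rank)
  recon <- red$u %*% diag(red$d) %*% t(red$v)
  expect_lt(max(abs(recon - p)), 1e-10)
  expect_error(reduce_protein_features(matrix(0, 3, 3)), "zero")
  expect_error(reduce_protein_features(p, 0), "variance_fraction")
})

test_that("factored solver equals the explicit Kronecker ridge oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(15:40, 1); m <- sample(6:12, 1)
    q <- sample(3:10, 1); s <- sample(2:8, 1)
    inst <- random_instance(seed + 100, n, m, q, s)
    lambda <- 10^runif(1, -2, 1)
    fit <- affreg_fit(inst$y, inst$d, inst$p, lambda = lambda)
    w_oracle <- dense_affinity_ridge(inst$y, inst$d, inst$p, lambda,
                                     fit$variance_fraction)
    expect_lt(norm(unclass(fit$W) - w_oracle, "F") / norm(w_oracle, "F"), 1e-8)
  }
})

test_that("noise-free data is reproduced in similarity space at small lambda", {
  # full-rank W with S >= Q keeps the reduced system identifiable, so the
  # planted model is recovered exactly as lambda -> 0
  co <- small_cohort(seed = 5, noise_sd = 0, n_tfs = 5, n_proteins = 8,
                     rank = 5)
  cc <- centered(co)
  fit <- affreg_fit(cc$y, cc$d, cc$p, lambda = 1e-10, variance_fraction = 1)
  k <- crossprod(cc$y)
  k_hat <- crossprod(cc$y, cc$d) %*% fit$W %*% t(cc$p)
  expect_lt(norm(k_hat - k, "F") / norm(k, "F"), 1e-6)
  # held-in prediction is rank-perfect at the unpenalized least-squares limit
  # (genes sharing a motif row tie exactly; rounding keeps those ties tied)
  fit0 <- affreg_fit(cc$y, cc$d, cc$p, lambda = 0, variance_fraction = 1)
  yhat <- as.numeric(predict_expression(fit0, cc$d, cc$p[3, ]))
  expect_lt(max(abs(yhat - cc$y[, 3])), 1e-8)
  expect_equal(spearman_cor(round(yhat, 6), round(cc$y[, 3], 6)), 1.0)
})

test_that("ridge shrinkage drives W to zero as lambda grows", {
  inst <- random_instance(7)
  norms <- sapply(c(1, 1e4, 1e8, 1e12), function(l) {
    norm(affreg_fit(inst$y, inst$d, inst$p, lambda = l)$W, "F")
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-6 * norms[1])
})

test_that("prediction is linear in the protein profile", {
  inst <- random_instance(8)
  fit <- affreg_fit(inst$y, inst$d, inst$p, lambda = 0.5)
  zero <- setNames(rep(0, ncol(inst$p)), colnames(inst$p))
  expect_equal(as.numeric(predict_expression(fit, inst$d, zero)),
               rep(0, nrow(inst$y)))
  p1 <- inst$p[1, ]; p2 <- inst$p[2, ]
  expect_equal(predict_expression(fit, inst$d, p1 + p2),
               predict_expression(fit, inst$d, p1) +
                 predict_expression(fit, inst$d, p2),
               tolerance = 1e-10, ignore_attr = TRUE)
  bad <- setNames(rep(0, 2), c("PR1", "nope"))
  expect_error(predict_expression(fit, inst$d, bad), "unknown protein.*nope")
})

test_that("activity mappings are the stated linear maps", {
  inst <- random_instance(9, m = 6, s = 6)
  fit <- affreg_fit(inst$y, inst$d, inst$p, lambda = 0.5)
  # one-hot protein profiles return columns of W
  eye <- diag(ncol(inst$p))
  dimnames(eye) <- list(paste0("x", 1:6), colnames(inst$p))
  act <- infer_tf_activities(fit, eye)
  expect_equal(unclass(act), unclass(fit$W), ignore_attr = TRUE)
  expect_identical(attr(act, "kind"), "tf_activity")
  # doubling P doubles activities
  act1 <- infer_tf_activities(fit, inst$p)
  act2 <- infer_tf_activities(fit, 2 * inst$p)
  expect_equal(unclass(act2), 2 * unclass(act1), tolerance = 1e-12)

  # protein activities: zero expression gives zero activity
  y0 <- inst$y * 0
  expect_true(all(infer_protein_activities(fit, y0, inst$d) == 0))
  pa <- infer_protein_activities(fit, inst$y, inst$d)
  expect_identical(dim(unclass(pa)), c(ncol(inst$p), ncol(inst$y)))
  expect_identical(attr(pa, "kind"), "protein_activity")
  # algebraic identity: W P' equals the reduced-basis product, so the
  # training residual through the full-basis W matches the fit residual
  r <- fit$rank_kept
  b <- fit$protein_svd$u[, 1:r, drop = FALSE] %*% diag(fit$protein_svd$d[1:r], r)
  expect_equal(unclass(fit$W) %*% t(inst$p), fit$W_reduced %*% t(b),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mapping duality: D (W P') stacks the per-sample predictions", {
  inst <- random_instance(10)
  fit <- affreg_fit(inst$y, inst$d, inst$p, lambda = 2)
  via_act <- inst$d %*% unclass(infer_tf_activities(fit, inst$p))
  via_pred <- predict_expression(fit, inst$d, inst$p)
  expect_equal(via_act, via_pred, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scaling Y by c scales W by c at lambda = 0", {
  inst <- random_instance(11, n = 40, m = 12, q = 6, s = 4)
  f1 <- affreg_fit(inst$y, inst$d, inst$p, lambda = 0)
  f3 <- affreg_fit(3 * inst$y, inst$d, inst$p, lambda = 0)
  expect_lt(norm(unclass(f3$W) - 3 * unclass(f1$W), "F") / norm(f1$W, "F"), 1e-6)
})

test_that("lambda selection is deterministic and breaks flat ties small", {
  inst <- random_instance(12)
  expect_equal(as.numeric(select_lambda(inst$y, inst$d, inst$p,
                                        lambda_grid = 0.7, k_folds = 3)), 0.7)
  co <- small_cohort(seed = 13, noise_sd = 0)
  # noise-free: the CV curve is flat at rho = 1 over negligible penalties
  lam <- select_lambda(co$Y, co$D, co$P, lambda_grid = c(1e-8, 1e-6, 1e-4),
                       k_folds = 3, seed = 2)
  expect_equal(as.numeric(lam), 1e-8)
  l1 <- select_lambda(inst$y, inst$d, inst$p, k_folds = 3, seed = 4)
  l2 <- select_lambda(inst$y, inst$d, inst$p, k_folds = 3, seed = 4)
  expect_identical(l1, l2)
  expect_error(select_lambda(inst$y, inst$d, inst$p, k_folds = 99), "exceeds")
})

test_that("model serialization round-trips exactly", {
  inst <- random_instance(14)
  fit <- affreg_fit(inst$y, inst$d, inst$p, lambda = 1)
  f <- tempfile(fileext = ".rds")
  save_model(fit, f)
  expect_identical(load_model(f), fit)
})

test_that("fit validates alignment, centering, and penalty", {
  inst <- random_instance(15)
  expect_error(affreg_fit(inst$y, inst$d[, 1:3], inst$p, lambda = -1), "lambda")
  expect_error(affreg_fit(inst$y[1:10, ], inst$d, inst$p, 1), "not aligned")
  y_raw <- inst$y + 5
  expect_error(affreg_fit(y_raw, inst$d, inst$p, 1), "centered")
})

test_that("planted interaction matrix is recovered from a clean cohort", {
  co <- small_cohort(seed = 16, n_genes = 250, n_samples = 40, noise_sd = 0.05)
  cc <- centered(co)
  fit <- affreg_fit(cc$y, cc$d, cc$p, lambda = 0.1)
  expect_gt(cor(as.vector(co$truth$W_true), as.vector(unclass(fit$W))), 0.9)
  # inferred TF activities track the planted ones
  act <- unclass(infer_tf_activities(fit, cc$p))
  rho <- sapply(rownames(act), function(tf) {
    cor(act[tf, ], co$truth$tf_activity_true[tf, ])
  })
  expect_gt(median(rho), 0.9)
})
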