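# Independent oracles: these deliberately avoid the package's factored code
# paths and solve the same problems by brute force on small instances.

# explicit Kronecker ridge for min ||A W B' - K||_F^2 + lambda ||W||_F^2:
# materializes the full (M*M) x (ncol(A)*ncol(B)) design and solves the
# normal equations
dense_kron_ridge <- function(a, b, k, lambda) {
  x <- kronecker(b, a)
  w <- solve(crossprod(x) + lambda * diag(ncol(x)), crossprod(x, as.vector(k)))
  matrix(w, nrow = ncol(a))
}

# the reduced-system problem affreg_fit solves, set up independently from
# raw (y, d, p): reduce p by SVD at the same retained-variance rule, then
# call the dense solver and project back to the protein basis
dense_affinity_ridge <- function(y, d, p, lambda, variance_fraction = 0.99) {
  s <- svd(p)
  r <- which(cumsum(s$d^2) / sum(s$d^2) >= variance_fraction - 1e-12)[1]
  b <- s$u[, seq_len(r), drop = FALSE] %*% diag(s$d[seq_len(r)], r)
  w_red <- dense_kron_ridge(crossprod(y, d), b, crossprod(y), lambda)
  w_red %*% t(s$v[, seq_len(r), drop = FALSE])
}

# exact Cox partial log-likelihood (Breslow form; instances are generated
# with continuous times so there are no ties and Breslow = Efron), maximized
# numerically
cox_brute_force <- function(time, event, x) {
  x <- as.matrix(x)
  nll <- function(beta) {
    lp <- as.numeric(x %*% beta)
    s <- 0
    for (i in which(event == 1)) {
      s <- s - lp[i] + log(sum(exp(lp[time >= time[i]])))
    }
    s
  }
  optim(rep(0, ncol(x)), nll, method = "BFGS",
        control = list(reltol = 1e-14, maxit = 500))$par
}
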