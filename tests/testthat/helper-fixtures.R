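# Shared in-code fixtures for the test suite.

# a small but structured simulated study: two diet types, genetic and
# metagenomic signal, desk-scale dimensions
small_study <- function(seed = 11, n = 120, h2 = 0.3, m2 = 0.2, i2 = 0,
                        n_snps = 300, n_orfs = 200) {
  simulate_study(sim_config(
    n_animals = n, n_snps = n_snps, n_orfs = n_orfs,
    target_h2 = h2, target_m2 = m2, target_i2 = i2,
    library_size_mean = 5e4, seed = seed))
}

# the worked 3-animal toy matrices used throughout the kernel tests
toy_dosages <- function() matrix(c(0, 1, 2), 3, 1,
                                 dimnames = list(c("a", "b", "c"), "snp1"))
toy_S <- function() matrix(c(0, 1, 2, 0, 2, 4), 3, 2,
                           dimnames = list(c("a", "b", "c"), c("o1", "o2")))

# strip a rel_matrix (or any matrix) down to its bare numeric values
kmat <- function(x) {
  m <- unclass(x)
  matrix(as.numeric(m), nrow(m))
}

# independent REML oracle: evaluate the restricted likelihood directly from
# its definition (dense determinants, explicit projection matrix)
reml_logl_direct <- function(y, X, Ks, sigma2) {
  n <- length(y)
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(Ks)) V <- V + sigma2[k] * unclass(Ks[[k]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(y) %*% P %*% y))
}

# grid + direct-optimiser maximiser of the restricted likelihood over
# variance ratios, with the total variance profiled out analytically;
# independent of the AI-REML iteration
reml_grid_optimum <- function(y, X, Ks, n_grid = 41) {
  n <- length(y)
  p <- qr(X)$rank
  K <- length(Ks)
  # profiled restricted likelihood at kernel ratio vector r (residual is
  # 1 - sum(r)); the optimal total variance is yP0y / (n - p)
  prof <- function(r) {
    re <- 1 - sum(r)
    if (any(r < 0) || re <= 1e-8) return(list(logl = -Inf))
    V0 <- diag(re, n)
    for (k in seq_len(K)) V0 <- V0 + r[k] * unclass(Ks[[k]])
    ch <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(ch)) return(list(logl = -Inf))
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(list(logl = -Inf))
    P0 <- Vi - Vi %*% X %*% chol2inv(chX) %*% crossprod(X, Vi)
    yPy <- drop(t(y) %*% P0 %*% y)
    if (yPy <= 0) return(list(logl = -Inf))
    s_hat <- yPy / (n - p)
    logl <- -0.5 * ((n - p) * log(s_hat) + (n - p) +
                      2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))))
    list(logl = logl, s_hat = s_hat)
  }
  eval_r <- function(r) prof(r)$logl
  grid <- seq(0, 0.995, length.out = n_grid)
  best <- NULL; best_val <- -Inf
  combos <- if (K == 1L) lapply(grid, identity) else
    apply(expand.grid(grid, grid), 1, c, simplify = FALSE)
  for (r in combos) {
    if (sum(r) > 0.995) next
    v <- eval_r(r)
    if (v > best_val) { best_val <- v; best <- r }
  }
  # refine from the grid optimum
  if (K == 1L) {
    opt1 <- stats::optimize(function(r) -eval_r(r), c(0, 0.9995), tol = 1e-10)
    refined <- opt1$minimum
  } else {
    obj <- function(z) -eval_r(stats::plogis(z))
    z0 <- stats::qlogis(pmin(pmax(best, 1e-5), 1 - 1e-5))
    opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    refined <- stats::plogis(opt$par)
  }
  # boundary candidates: drop each kernel component to exactly zero, and
  # push the residual to its boundary (tuned kernels keep V PD there)
  cand <- list(refined)
  for (k in seq_len(K)) {
    r0 <- refined; r0[k] <- 0
    cand <- c(cand, list(r0))
  }
  if (sum(refined) > 0)
    cand <- c(cand, list(refined / sum(refined) * (1 - 1e-7)))
  vals <- vapply(cand, eval_r, 0)
  r <- cand[[which.max(vals)]]
  pr <- prof(r)
  list(logl = pr$logl, ratios = c(r, 1 - sum(r)),
       sigma2 = c(r, 1 - sum(r)) * pr$s_hat)
}
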