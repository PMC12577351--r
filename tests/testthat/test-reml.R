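test_that("the restricted likelihood matches a direct dense-algebra oracle", {
  set.seed(41)
  # identity kernel, known components: compare against the definition
  y <- rnorm(5, 3)
  X <- cbind(1, rnorm(5))
  Ks <- list(diag(5))
  for (s in list(c(1, 1), c(0.3, 2), c(2.5, 0.4))) {
    expect_equal(restricted_log_likelihood(y, X, Ks, s),
                 reml_logl_direct(y, X, Ks, s), tolerance = 1e-10)
  }
  # and with a structured kernel
  Q <- simulate_genotypes(12, 30, seed = 6)
  G <- tune(build_grm(Q))
  y2 <- rnorm(12)
  X2 <- matrix(1, 12, 1)
  expect_equal(restricted_log_likelihood(y2, X2, list(G), c(0.7, 0.5)),
               reml_logl_direct(y2, X2, list(G), c(0.7, 0.5)),
               tolerance = 1e-10)
  expect_error(restricted_log_likelihood(y, cbind(X, X[, 1]), Ks, c(1, 1)),
               "rank")
})

test_that("the restricted likelihood is scale-equivariant", {
  set.seed(42)
  n <- 15
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  G <- tune(build_grm(simulate_genotypes(n, 40, seed = 2)))
  l1 <- restricted_log_likelihood(y, X, list(G), c(0.5, 0.5))
  for (cc in c(2, 10)) {
    l2 <- restricted_log_likelihood(cc * y, X, list(G), cc^2 * c(0.5, 0.5))
    expect_equal(l2 - l1, -(n - 2) * log(cc), tolerance = 1e-8)
  }
})

test_that("AI-REML recovers a single-kernel heritability and hits the oracle optimum", {
  set.seed(43)
  n <- 300
  Q <- simulate_genotypes(n, 500, seed = 8)
  G <- tune(build_grm(Q))
  u <- drop(crossprod(chol(unclass(G)), rnorm(n)))
  u <- u * sqrt(0.5 / var(u))
  y <- 4 + u + rnorm(n, sd = sqrt(0.5))
  X <- matrix(1, n, 1)
  fit <- fit_mixed_model(y, X, list(genomic = G))
  expect_true(fit$converged)
  h2 <- fit$ratios$estimate[fit$ratios$ratio == "h2"]
  expect_lt(abs(h2 - 0.5), 0.15)
  # the AI-REML optimum matches the grid/direct optimiser
  sub <- 1:25
  Gs <- rel_matrix(unclass(G)[sub, sub], kind = "G", tuned = TRUE)
  fit_s <- fit_mixed_model(y[sub], X[sub, , drop = FALSE], list(genomic = Gs))
  oracle <- reml_grid_optimum(y[sub], X[sub, , drop = FALSE], list(Gs))
  expect_lt(abs(fit_s$logl - oracle$logl), 1e-4)
  expect_lt(abs(fit_s$sigma2[1] / sum(fit_s$sigma2) - oracle$ratios[1]), 0.02)
})

test_that("degenerate inputs are flagged: constant phenotype and identity kernel", {
  n <- 40
  G <- tune(build_grm(simulate_genotypes(n, 60, seed = 5)))
  X <- matrix(1, n, 1)
  # constant y: the kernel component is driven to the zero boundary
  fit <- suppressWarnings(
    fit_mixed_model(rep(2, n) + rnorm(n, sd = 1e-4), X, list(genomic = G)))
  expect_true(fit$boundary[["genomic"]])
  # identity kernel: only the total variance is identifiable
  expect_warning(
    fit_i <- fit_mixed_model(rnorm(n), X,
                             list(genomic = rel_matrix(diag(n), kind = "G",
                                                       tuned = TRUE))),
    "identity")
  expect_true(fit_i$degenerate)
})

test_that("variance ratios follow their definitions with delta-method SEs", {
  r <- variance_ratios(c(genomic = 3, metagenomic = 1, residual = 6))
  expect_equal(r$estimate[match(c("h2", "m2", "i_a2"), r$ratio)],
               c(0.3, 0.1, 0.4))
  # genomic-only: no metagenomic ratios
  r1 <- variance_ratios(c(genomic = 3, residual = 7))
  expect_identical(r1$ratio, "h2")
  # zero interaction component: i_i2 collapses onto i_a2
  r2 <- variance_ratios(c(genomic = 2, metagenomic = 1, interaction = 0,
                          residual = 7))
  expect_equal(r2$estimate[r2$ratio == "i_i2"],
               r2$estimate[r2$ratio == "i_a2"])
  expect_error(variance_ratios(c(genomic = 0, residual = 0)), "undefined")
  # ratios recompute exactly from a fitted model's components
  set.seed(44)
  n <- 60
  G <- tune(build_grm(simulate_genotypes(n, 80, seed = 3)))
  fit <- fit_mixed_model(rnorm(n) + 2, matrix(1, n, 1), list(genomic = G))
  expect_equal(fit$ratios$estimate[1], fit$sigma2[[1]] / sum(fit$sigma2))
})

test_that("masked animals receive conditional-expectation BLUPs", {
  set.seed(45)
  sim <- small_study(seed = 29, n = 60, n_snps = 120, n_orfs = 80)
  ds <- sim$dataset
  S <- log_relative_abundance(ds$counts)
  G <- tune(build_grm(ds$genotypes))
  M <- tune(build_mrm(S, 1))
  y <- ds$phenotypes$trait
  names(y) <- ds$phenotypes$animal_id
  X <- build_fixed_design(ds$phenotypes)
  test <- 1:10
  y_mask <- y
  y_mask[test] <- NA
  fit <- fit_mixed_model(y_mask, X, list(genomic = G, metagenomic = M))
  obs <- setdiff(seq_len(60), test)
  V <- fit$sigma2[1] * unclass(G)[obs, obs] +
    fit$sigma2[2] * unclass(M)[obs, obs] + fit$sigma2[3] * diag(50)
  r <- y[obs] - X[obs, fit$X_names] %*% fit$beta
  for (k in 1:2) {
    Kf <- if (k == 1) unclass(G) else unclass(M)
    expected <- fit$sigma2[k] * Kf[test, obs] %*% solve(V, r)
    expect_equal(unname(fit$blup[test, k]), unname(drop(expected)),
                 tolerance = 1e-8)
  }
})

test_that("AIC responds to phenotype scaling by a model-independent constant", {
  set.seed(46)
  sim <- small_study(seed = 37, n = 80, n_snps = 120, n_orfs = 80)
  ds <- sim$dataset
  S <- log_relative_abundance(ds$counts)
  G <- tune(build_grm(ds$genotypes))
  M <- tune(build_mrm(S, 1))
  y <- ds$phenotypes$trait
  names(y) <- ds$phenotypes$animal_id
  X <- build_fixed_design(ds$phenotypes)
  aics <- sapply(list(list(genomic = G), list(metagenomic = M),
                      list(genomic = G, metagenomic = M)), function(k) {
    c(fit_mixed_model(y, X, k)$aic, fit_mixed_model(3 * y, X, k)$aic)
  })
  shifts <- aics[2, ] - aics[1, ]
  expect_lt(max(shifts) - min(shifts), 0.02)  # same constant for every model
})

test_that("per-ORF heritability estimates recover nulls, signal and boundaries", {
  set.seed(47)
  n <- 300
  Q <- simulate_genotypes(n, 400, seed = 10)
  G <- tune(build_grm(Q))
  X <- matrix(1, n, 1)
  L <- t(chol(unclass(G)))
  n_orf <- 12
  h2_true <- rep(c(0, 0.6), each = n_orf / 2)
  S <- sapply(h2_true, function(h) {
    drop(L %*% rnorm(n)) * sqrt(h) + rnorm(n, sd = sqrt(1 - h))
  })
  est <- estimate_orf_heritabilities(S, G, X)
  expect_true(all(est >= 0 & est < 1))
  expect_lt(median(est[h2_true == 0]), 0.08)
  expect_lt(abs(median(est[h2_true == 0.6]) - 0.6), 0.12)
  # constant column pinned at zero with a warning
  expect_warning(est0 <- estimate_orf_heritabilities(cbind(S, 1), G, X),
                 "constant")
  expect_equal(unname(est0[n_orf + 1]), 0)
})

test_that("the model grid enumerates the study design", {
  expect_equal(nrow(model_grid("addmi")), 19)
  expect_equal(nrow(model_grid(c("addmi", "adg"))), 38)
  expect_equal(nrow(model_grid("addmi", adjustments = "naive")), 7)
  g <- model_grid("t")
  expect_equal(sum(g$complexity == "genomic-only"), 1)
  expect_equal(sum(g$complexity == "interaction"), 6)
  expect_false(anyDuplicated(g$model_id) > 0)
})
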