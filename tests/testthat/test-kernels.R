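test_that("the GRM matches the hand-computed toy and is row-centred", {
  G <- build_grm(toy_dosages())
  expect_equal(kmat((G)),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3), tolerance = 1e-12)
  # centring identity on a larger random input
  Q <- simulate_genotypes(40, 100, seed = 2)
  G2 <- build_grm(Q)
  expect_lt(max(abs(rowSums(G2))), 1e-10)
  # duplicated animals give identical rows and diagonal entries
  Qd <- rbind(Q, Q[1, , drop = FALSE])
  G3 <- unclass(build_grm(Qd))
  expect_equal(G3[41, ], G3[1, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(G3[41, 41], G3[1, 1])
  expect_error(build_grm(matrix(2, 5, 3)), "monomorphic")
  expect_error(build_grm(matrix(c(NA, 1, 0, 2), 2)), "missing")
})

test_that("log relative abundance normalises with a unit pseudocount", {
  expect_equal(unclass(log_relative_abundance(matrix(0, 1, 10))),
               matrix(-1, 1, 10), ignore_attr = TRUE)
  S <- log_relative_abundance(matrix(c(9, 0, 0), 1, 3))
  expect_equal(drop(unclass(S)), log10(c(10, 1, 1) / 12), tolerance = 1e-12,
               ignore_attr = TRUE)
  R <- matrix(rpois(60, 30), 6, 10)
  S2 <- log_relative_abundance(R)
  expect_true(all(S2 <= 0))
  expect_equal(rowSums(10^unclass(S2)), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(log_relative_abundance(matrix(-1, 2, 2)), "non-negative")
})

test_that("both MRM constructions reproduce the worked toy and its identities", {
  S <- toy_S()
  expected <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3)
  M1 <- build_mrm(S, 1)
  M2 <- build_mrm(S, 2)
  expect_equal(kmat((M1)), expected, tolerance = 1e-12)
  expect_equal(kmat((M2)), expected, tolerance = 1e-12)
  expect_equal(sum(diag(M2)), 2)  # n - 1 under the sample-variance convention

  set.seed(4)
  Sb <- log_relative_abundance(matrix(rpois(50 * 30, 40), 50, 30))
  for (meth in 1:2) {
    M <- kmat(build_mrm(Sb, meth))
    expect_equal(sum(diag(M)), 49, tolerance = 1e-8)
    expect_equal(M, t(M), tolerance = 1e-12)
  }
  expect_lt(max(abs(rowSums(kmat(build_mrm(Sb, 1))))), 1e-10)

  # weights of 1 change nothing; weights enter as the diagonal D
  w <- rep(1, 30)
  expect_equal(kmat(build_mrm(Sb, 1, weights = w)),
               kmat(build_mrm(Sb, 1)), tolerance = 1e-12)
  w2 <- runif(30)
  Sc <- sweep(unclass(Sb), 2, colMeans(Sb))
  M1w_direct <- Sc %*% diag(w2) %*% t(Sc) / sum(apply(Sb, 2, var))
  expect_equal(kmat(build_mrm(Sb, 1, weights = w2)), M1w_direct,
               tolerance = 1e-10, ignore_attr = TRUE)

  # equal column variances make the two methods coincide exactly
  Se <- matrix(rnorm(40 * 6), 40, 6)
  Se <- sweep(sweep(Se, 2, colMeans(Se)), 2, apply(Se, 2, sd), "/")  # var 1
  expect_equal(kmat(build_mrm(Se, 1)), kmat(build_mrm(Se, 2)),
               tolerance = 1e-10)

  # zero-variance column: method 2 refuses, method 1 tolerates
  Sz <- cbind(Se, const = 0)
  expect_error(build_mrm(Sz, 2), "zero-variance")
  expect_silent(build_mrm(Sz, 1))
})

test_that("kernel construction is permutation-equivariant", {
  sim <- small_study(seed = 17, n = 30, n_snps = 60, n_orfs = 40)
  S <- log_relative_abundance(sim$dataset$counts)
  perm <- sample(30)
  for (builder in list(function(x) build_grm(sim$dataset$genotypes[x, ]),
                       function(x) build_mrm(S[x, ], 1),
                       function(x) build_mrm(S[x, ], 2))) {
    K_full <- kmat(builder(seq_len(30)))
    K_perm <- kmat(builder(perm))
    expect_equal(K_perm, K_full[perm, perm], tolerance = 1e-10)
  }
})

test_that("data-driven clustering separates diet types and degenerates sanely", {
  cfg <- sim_config(n_animals = 20, n_snps = 50, n_orfs = 60,
                    diet_shift_sd = 10, library_size_mean = 2e4, seed = 7)
  sim <- simulate_study(cfg)
  S <- log_relative_abundance(sim$dataset$counts)
  dt <- sim$dataset$phenotypes$diet_type
  lab <- assign_clusters(S, n_components = 4, k = 2, seed = 3)
  agree <- max(mean((lab == 1) == (dt == 1)), mean((lab == 2) == (dt == 1)))
  expect_equal(agree, 1)
  expect_identical(assign_clusters(S, 4, 2, seed = 3), lab)
  expect_identical(unname(assign_clusters(S, 4, 1, seed = 3)), rep(1L, 20))
  expect_error(assign_clusters(S, 4, 50, seed = 1), "exceed")
})

test_that("the multi-population MRM reduces, block-scales, and preserves order", {
  sim <- small_study(seed = 19, n = 40, n_snps = 60, n_orfs = 50)
  S <- log_relative_abundance(sim$dataset$counts)
  # single cluster: identical to the single-population build
  for (meth in 1:2)
    expect_equal(kmat(build_mrm_multipop(S, meth, rep(1L, 40))),
                 kmat(build_mrm(S, meth)), tolerance = 1e-10)
  # two clusters, method 2: each diagonal block has trace n_c - 1
  lab <- rep(1:2, each = 20)
  Mp <- kmat(build_mrm_multipop(S, 2, lab))
  expect_equal(sum(diag(Mp[1:20, 1:20])), 19, tolerance = 1e-8)
  expect_equal(sum(diag(Mp[21:40, 21:40])), 19, tolerance = 1e-8)
  # animal order preserved under label interleaving
  lab_i <- rep(1:2, 20)
  Mi <- kmat(build_mrm_multipop(S, 1, lab_i))
  ord <- order(lab_i)
  Mo <- kmat(build_mrm_multipop(S[ord, ], 1, lab_i[ord]))
  expect_equal(Mi[ord, ord], Mo, tolerance = 1e-10)
  expect_error(build_mrm_multipop(S, 1, c(1L, rep(2L, 39))), "at least 2")

  # two clusters with identical distributions: cross blocks close to the
  # single-population values at moderate n
  set.seed(31)
  Sh <- matrix(rnorm(200 * 40), 200, 40)
  labh <- rep(1:2, each = 100)
  M1p <- kmat(build_mrm_multipop(Sh, 1, labh))
  M1s <- kmat(build_mrm(Sh, 1))
  cross_p <- M1p[1:100, 101:200]
  cross_s <- M1s[1:100, 101:200]
  expect_lt(mean(abs(cross_p - cross_s)), 0.05 * sd(diag(M1s)) + 0.02)
})

test_that("Hadamard interaction kernels are elementwise products and stay PSD", {
  G <- build_grm(toy_dosages())
  M <- build_mrm(toy_S(), 1)
  J <- hadamard_interaction(G, M)
  expect_equal(kmat((J)),
               matrix(c(2, 0, 2, 0, 0, 0, 2, 0, 2), 3), tolerance = 1e-12)
  # identity M masks G to its diagonal
  Mi <- rel_matrix(diag(3), kind = "M")
  Ji <- unclass(hadamard_interaction(G, Mi))
  expect_equal(Ji, diag(diag(unclass(G))), ignore_attr = TRUE)
  # random PSD pairs stay PSD (Schur product theorem)
  set.seed(12)
  for (i in 1:5) {
    A <- tcrossprod(matrix(rnorm(100), 10))
    B <- tcrossprod(matrix(rnorm(100), 10))
    ev <- min(eigen(A * B, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(ev, -1e-8 * sum(diag(A * B)) / 10)
  }
  expect_error(hadamard_interaction(tune(G), M), "untuned")
})

test_that("tuning adds exactly the ridge once and makes kernels invertible", {
  I2 <- rel_matrix(diag(2), kind = "G")
  T2 <- tune(I2, 0.001)
  expect_equal(diag(unclass(T2)), rep(1.001, 2), ignore_attr = TRUE)
  expect_true(is_tuned(T2))
  expect_error(tune(T2), "already tuned")
  expect_error(tune(I2, epsilon = 0), "positive")
  # singular toy M1 becomes positive definite
  M1 <- build_mrm(toy_S(), 1)
  expect_lt(abs(det(unclass(M1))), 1e-12)
  expect_gt(det(unclass(tune(M1))), 0)
})

test_that("the kernel-set builder emits the six MRMs and six interactions", {
  sim <- small_study(seed = 23, n = 50, n_snps = 80, n_orfs = 60)
  X <- build_fixed_design(sim$dataset$phenotypes)
  kset <- build_kernel_set(sim$dataset$genotypes, sim$dataset$counts, X = X,
                           seed = 1)
  expect_length(kset$M, 6)
  expect_length(kset$J, 6)
  expect_setequal(names(kset$M),
                  c("m1_naive", "m2_naive", "m1_weighted", "m2_weighted",
                    "m1_data_driven", "m2_data_driven"))
  expect_identical(names(kset$J), names(kset$M))
  expect_true(all(vapply(c(kset$M, kset$J, list(kset$G)), is_tuned, TRUE)))
  expect_true(all(kset$orf_h2 >= 0 & kset$orf_h2 < 1))
})
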