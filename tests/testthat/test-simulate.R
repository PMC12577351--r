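test_that("simulated genotypes follow their drawn allele frequencies", {
  # degenerate frequency pins the expected dosage at 1
  Q <- simulate_genotypes(500, 1, maf_range = c(0.5, 0.5), seed = 3)
  expect_true(all(Q %in% 0:2))
  expect_lt(abs(mean(Q) - 1), 3 * sqrt(0.5 / 1000))

  # per-column observed frequency within 3 binomial SDs of its drawn p
  Q <- simulate_genotypes(1000, 200, maf_range = c(0.05, 0.5), seed = 1)
  p <- attr(Q, "allele_freq")
  obs <- colMeans(Q) / 2
  sds <- sqrt(p * (1 - p) / (2 * 1000))
  expect_true(all(abs(obs - p) <= 3.5 * sds))

  expect_identical(simulate_genotypes(50, 20, seed = 9),
                   simulate_genotypes(50, 20, seed = 9))
  expect_error(simulate_genotypes(10, 5, maf_range = c(0, 0.6)), "maf_range")
})

test_that("microbiome counts are valid multinomial draws with the injected structure", {
  cfg <- sim_config(n_animals = 80, n_snps = 100, n_orfs = 150,
                    library_size_mean = 2e4, seed = 21)
  geno <- simulate_genotypes(80, 100, seed = 1)
  scores <- simulate_genetic_scores(geno, 10, seed = 2)
  diet_type <- rep(1:2, each = 40)
  mb <- simulate_microbiome(scores, diet_type, cfg)
  expect_true(all(mb$counts >= 0))
  expect_identical(unname(rowSums(mb$counts)),
                   as.numeric(mb$truth$library_sizes))
  mb2 <- simulate_microbiome(scores, diet_type, cfg)
  expect_identical(mb$counts, mb2$counts)

  # no injected structure: ORF columns exchangeable across diet types
  cfg0 <- sim_config(n_animals = 80, n_snps = 100, n_orfs = 200,
                     diet_shift_sd = 0, orf_h2_mean = 1e-4,
                     library_size_mean = 2e4, seed = 22)
  mb0 <- simulate_microbiome(scores, diet_type, cfg0)
  S0 <- log_relative_abundance(mb0$counts)
  pvals <- apply(S0, 2, function(x)
    stats::t.test(x[diet_type == 1], x[diet_type == 2])$p.value)
  expect_lt(mean(pvals < 0.05), 0.12)  # nominal rate, with slack

  # large shift on half the ORFs: k-means on PCs recovers the diet types
  cfg10 <- sim_config(n_animals = 80, n_snps = 100, n_orfs = 150,
                      diet_shift_sd = 10, diet_shift_prop = 0.5,
                      library_size_mean = 2e4, seed = 23)
  mb10 <- simulate_microbiome(scores, diet_type, cfg10)
  lab <- assign_clusters(log_relative_abundance(mb10$counts), 4, 2, seed = 5)
  agree <- max(mean((lab == 1) == (diet_type == 1)),
               mean((lab == 2) == (diet_type == 1)))
  expect_gte(agree, 0.95)
})

test_that("phenotype components realise their target variance fractions", {
  # single-component limit: y - X beta is essentially the genetic effect
  cfg <- sim_config(n_animals = 200, n_snps = 300, n_orfs = 100,
                    target_h2 = 0.98, target_m2 = 0, target_i2 = 0,
                    library_size_mean = 2e4, seed = 31)
  sim <- simulate_study(cfg)
  tr <- sim$truth$traits$trait
  y_rand <- tr$u + tr$m + tr$o + tr$e
  expect_gt(cor(y_rand, tr$u), 0.95)

  # null case: the random part is pure residual
  cfg0 <- sim_config(n_animals = 200, n_snps = 300, n_orfs = 100,
                     target_h2 = 0, target_m2 = 0, target_i2 = 0,
                     library_size_mean = 2e4, seed = 32)
  tr0 <- simulate_study(cfg0)$truth$traits$trait
  expect_identical(unname(tr0$realized_fractions[c("u", "m", "o")]),
                   c(0, 0, 0))

  # realised fractions track the targets. The genomic fraction converges as
  # n grows; the metagenomic fraction is unbiased but keeps an O(1)
  # fluctuation from the random contrast's loading on the diet axis of the
  # abundance matrix (see the methods vignette), so it is checked for
  # unbiasedness rather than convergence.
  frac_at <- function(n, seeds) {
    t(sapply(seeds, function(s) {
      sim <- simulate_study(sim_config(
        n_animals = n, n_snps = 250, n_orfs = 120, target_h2 = 0.30,
        target_m2 = 0.20, library_size_mean = 2e4, seed = s))
      sim$truth$traits$trait$realized_fractions[c("u", "m")]
    }))
  }
  f200 <- frac_at(200, 1:10)
  f800 <- frac_at(800, 1:10)
  expect_lt(median(abs(f800[, "u"] - 0.30)), 0.05)
  expect_lt(median(abs(f800[, "u"] - 0.30)),
            median(abs(f200[, "u"] - 0.30)) + 0.01)
  # m fraction unbiased: mean within 3 standard errors of the target
  se_m <- sd(f800[, "m"]) / sqrt(nrow(f800))
  expect_lt(abs(mean(f800[, "m"]) - 0.20), 3 * se_m + 0.02)
})

test_that("the full generator is deterministic and invalid configs are rejected", {
  s1 <- small_study(seed = 5, n = 60, n_snps = 80, n_orfs = 60)
  s2 <- small_study(seed = 5, n = 60, n_snps = 80, n_orfs = 60)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$dataset$phenotypes$trait, s2$dataset$phenotypes$trait)

  expect_error(sim_config(target_h2 = 0.6, target_m2 = 0.5), "sum below 1")
  expect_error(sim_config(n_diets = 5, n_diet_types = 2, n_management_groups = 20),
               "divisible")
  expect_error(sim_config(maf_range = c(0.2, 0.1)), "maf_range")
})

test_that("write_study round-trips through the TSV readers", {
  sim <- small_study(seed = 8, n = 40, n_snps = 50, n_orfs = 40)
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  cfg <- study_config(sim = NULL,
                      paths = list(genotypes = file.path(dir, "genotypes.tsv"),
                                   counts = file.path(dir, "orf_counts.tsv"),
                                   phenotypes = file.path(dir, "phenotypes.tsv")),
                      traits = "trait")
  tabs <- metablup:::read_study_tables(cfg$paths)
  expect_equal(unname(tabs$genotypes), unname(sim$dataset$genotypes))
  expect_equal(unname(tabs$counts), unname(sim$dataset$counts))
  expect_equal(tabs$phenotypes$trait, sim$dataset$phenotypes$trait)
})
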