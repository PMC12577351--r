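#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic-data generator. The
#' defaults emulate the structure of the multi-diet beef cattle feed
#' efficiency design the package targets: roughly 700 animals in 16
#' management groups nested within 4 diets of 2 diet types (sex is a proxy
#' for diet type), SNP genotypes in Hardy-Weinberg proportions with MAF of
#' at least 0.05, ORF log relative abundances with a weak host-genetic
#' component (per-ORF heritabilities Beta-distributed with mean 0.07 and
#' median 0.04) and a strong diet-type compositional shift, and phenotypes
#' composed of fixed effects plus genomic, metagenomic, optional interaction,
#' and residual components with configurable variance fractions. SNP and ORF
#' counts default to desk-scale values so a full study runs in minutes.
#'
#' @param n_animals,n_snps,n_orfs dataset dimensions.
#' @param n_diets,n_diet_types,n_management_groups design structure;
#'   `n_diets` must be divisible by `n_diet_types` and
#'   `n_management_groups` by `n_diets`.
#' @param maf_range allele-frequency range for simulated SNPs, within
#'   (0, 0.5].
#' @param target_h2,target_m2,target_i2 target phenotypic variance fractions
#'   of the genomic, metagenomic and interaction components; their sum must
#'   be below 1 (the remainder is residual).
#' @param orf_h2_mean mean of the Beta-distributed per-ORF heritabilities.
#' @param diet_shift_sd magnitude (log10-abundance units) of the diet-type
#'   shift applied to affected ORFs.
#' @param diet_shift_prop fraction of ORFs affected by the diet-type shift.
#' @param orf_noise_sd total within-diet-type SD of latent log10 abundances.
#' @param library_size_mean mean sequencing depth (reads per sample);
#'   realised depths are log-normal around it.
#' @param n_breeds number of breed-fraction covariates.
#' @param n_genetic_factors rank of the latent genetic factor basis used to
#'   give ORFs a heritable component.
#' @param seed integer seed; every downstream stream is derived from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 717, n_snps = 5000, n_orfs = 2000,
                       n_diets = 4, n_diet_types = 2,
                       n_management_groups = 16,
                       maf_range = c(0.05, 0.5),
                       target_h2 = 0.30, target_m2 = 0.20, target_i2 = 0,
                       orf_h2_mean = 0.07, diet_shift_sd = 1.0,
                       diet_shift_prop = 0.5, orf_noise_sd = 0.5,
                       library_size_mean = 2e7,
                       n_breeds = 18, n_genetic_factors = 20, seed = 1) {
  cfg <- list(n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
              n_orfs = as.integer(n_orfs), n_diets = as.integer(n_diets),
              n_diet_types = as.integer(n_diet_types),
              n_management_groups = as.integer(n_management_groups),
              maf_range = as.numeric(maf_range),
              target_h2 = target_h2, target_m2 = target_m2,
              target_i2 = target_i2, orf_h2_mean = orf_h2_mean,
              diet_shift_sd = diet_shift_sd,
              diet_shift_prop = diet_shift_prop,
              orf_noise_sd = orf_noise_sd,
              library_size_mean = library_size_mean,
              n_breeds = as.integer(n_breeds),
              n_genetic_factors = as.integer(n_genetic_factors),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_animals, n_snps, n_orfs, n_diets, n_diet_types,
              n_management_groups) < 1))
      stop("counts must be positive")
    if (n_diets %% n_diet_types != 0)
      stop("'n_diets' must be divisible by 'n_diet_types'")
    if (n_management_groups %% n_diets != 0)
      stop("'n_management_groups' must be divisible by 'n_diets'")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("'maf_range' must lie within (0, 0.5] with lower <= upper")
    if (min(target_h2, target_m2, target_i2) < 0 ||
        target_h2 + target_m2 + target_i2 >= 1)
      stop("variance-fraction targets must be non-negative and sum below 1")
    if (orf_h2_mean <= 0 || orf_h2_mean >= 1)
      stop("'orf_h2_mean' must be in (0, 1)")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate SNP dosages under Hardy-Weinberg equilibrium
#'
#' Each locus draws an alternate-allele frequency uniformly from `maf_range`
#' and then per-animal dosages from Binomial(2, p).
#'
#' @param n number of animals.
#' @param s number of SNPs.
#' @param maf_range allele-frequency range within (0, 0.5].
#' @param seed integer seed.
#' @return integer dosage matrix (n x s) with animal/SNP dimnames and an
#'   attribute `allele_freq` holding the drawn frequencies.
#' @export
simulate_genotypes <- function(n, s, maf_range = c(0.05, 0.5), seed = 1) {
  if (n < 1 || s < 1) stop("'n' and 's' must be at least 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must lie within (0, 0.5]")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  p <- stats::runif(s, maf_range[1], maf_range[2])
  Q <- matrix(stats::rbinom(n * s, 2L, rep(p, each = n)), n, s)
  dimnames(Q) <- list(sprintf("A%04d", seq_len(n)), sprintf("snp%05d", seq_len(s)))
  attr(Q, "allele_freq") <- p
  Q
}

#' Simulate the fixed-effect design
#'
#' Allocates animals to diet types (with sex as a proxy: concentrate diets go
#' to steers, forage diets to heifers), diets within type, and management
#' groups within diet, and draws breed fractions (Dirichlet) plus an expected
#' heterozygosity covariate.
#'
#' @param config a [sim_config()].
#' @return data frame with `animal_id`, `sex`, `diet_type`, `diet`,
#'   `management_group`, breed-fraction columns `breed_1..breed_K`, and
#'   `heterozygosity`.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, "design"))
  n <- config$n_animals
  ids <- sprintf("A%04d", seq_len(n))
  diet <- sort(rep_len(seq_len(config$n_diets), n))
  diets_per_type <- config$n_diets / config$n_diet_types
  diet_type <- (diet - 1L) %/% diets_per_type + 1L
  groups_per_diet <- config$n_management_groups / config$n_diets
  mg <- integer(n)
  for (d in seq_len(config$n_diets)) {
    rows <- which(diet == d)
    mg[rows] <- (d - 1L) * groups_per_diet +
      rep_len(seq_len(groups_per_diet), length(rows))
  }
  bf <- matrix(stats::rgamma(n * config$n_breeds, shape = 0.8), n)
  bf <- bf / rowSums(bf)
  colnames(bf) <- sprintf("breed_%d", seq_len(config$n_breeds))
  het <- stats::rbeta(n, 20, 40)  # bounded covariate centred near 1/3
  out <- data.frame(animal_id = ids,
                    sex = ifelse(diet_type == 1L, "steer", "heifer"),
                    diet_type = diet_type,
                    diet = factor(diet),
                    management_group = factor(mg),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(bf), heterozygosity = het)
}

#' Latent genetic scores for the microbiome generator
#'
#' Projects centred dosages onto random SNP-weight vectors and standardises
#' the columns, yielding a low-rank basis of per-animal genetic scores whose
#' covariance across animals follows the genomic relationships. ORF genetic
#' components are random combinations of these factors.
#'
#' @param genotypes dosage matrix.
#' @param n_factors number of latent factors.
#' @param seed integer seed.
#' @return n x `n_factors` matrix of unit-variance genetic scores.
#' @export
simulate_genetic_scores <- function(genotypes, n_factors = 20, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  Q <- as.matrix(genotypes)
  Z <- sweep(Q, 2L, colMeans(Q))
  W <- matrix(stats::rnorm(ncol(Q) * n_factors), ncol(Q), n_factors)
  F_ <- Z %*% W
  sds <- apply(F_, 2L, stats::sd)
  sds[sds == 0] <- 1
  out <- sweep(F_, 2L, sds, `/`)
  rownames(out) <- rownames(Q)
  out
}

# Beta parameters reproducing the target per-ORF heritability profile:
# mean orf_h2_mean with a heavy mass near zero (median ~ 0.04 at mean 0.07)
orf_h2_beta_shape <- function(mean_h2) {
  a <- 0.605 * mean_h2 / 0.07  # calibrated at the default mean
  c(a = a, b = a * (1 - mean_h2) / mean_h2)
}

#' Simulate an ORF read-count table
#'
#' Generates latent log10 relative abundances as the sum of an ORF baseline,
#' a diet-type shift for a random subset of ORFs, a host-genetic component
#' scaled so each ORF attains its drawn heritability, and Gaussian noise;
#' converts rows to multinomial probabilities and draws counts at log-normal
#' library sizes. ORFs are conditionally independent given diet and genetics.
#'
#' @param genetic_scores matrix of per-animal genetic factor scores, e.g.
#'   from [simulate_genetic_scores()].
#' @param diet_type integer vector of diet-type labels per animal.
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, rows summing to the drawn
#'   library sizes), `latent` (the latent log10 abundance matrix), and
#'   `truth` (`orf_h2`, `shifted`, `library_sizes`).
#' @export
simulate_microbiome <- function(genetic_scores, diet_type, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genetic_scores)
  if (length(diet_type) != n) stop("'diet_type' must have one label per animal")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, "microbiome"))
  m <- config$n_orfs
  sh <- orf_h2_beta_shape(config$orf_h2_mean)
  orf_h2 <- stats::rbeta(m, sh["a"], sh["b"])
  if (any(orf_h2 < 0 | orf_h2 >= 1)) stop("per-ORF heritability outside [0, 1)")

  baseline <- stats::rnorm(m, -log10(m), 1)
  shifted <- stats::runif(m) < config$diet_shift_prop
  shift_dir <- sample(c(-1, 1), m, replace = TRUE)
  tau <- config$orf_noise_sd
  nf <- ncol(genetic_scores)
  Wg <- matrix(stats::rnorm(nf * m), nf, m) / sqrt(nf)
  Gc <- genetic_scores %*% Wg                       # ~ unit variance columns
  Gc <- sweep(Gc, 2L, sqrt(orf_h2) * tau, `*`)
  E <- matrix(stats::rnorm(n * m), n, m)
  E <- sweep(E, 2L, sqrt(1 - orf_h2) * tau, `*`)
  shift_mat <- outer(ifelse(diet_type == 1L, -0.5, 0.5),
                     shift_dir * shifted * config$diet_shift_sd)
  latent <- sweep(Gc + E + shift_mat, 2L, baseline, `+`)

  lib <- stats::rlnorm(n, meanlog = log(config$library_size_mean) - 0.3^2 / 2,
                       sdlog = 0.3)
  lib <- pmax(round(lib), m)  # at least one read per ORF slot on average
  counts <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    pr <- 10^(latent[i, ] - max(latent[i, ]))
    counts[i, ] <- stats::rmultinom(1L, size = lib[i], prob = pr / sum(pr))
  }
  dimnames(counts) <- list(rownames(genetic_scores),
                           sprintf("orf%05d", seq_len(m)))
  dimnames(latent) <- dimnames(counts)
  list(counts = counts, latent = latent,
       truth = list(orf_h2 = orf_h2, shifted = shifted, library_sizes = lib))
}

#' Simulate phenotypes with known variance partition
#'
#' Composes `y = X beta + u + m + o + e` where `u ~ N(0, G sigma2_u)` with
#' `G` built from the supplied genotypes, `m` is a random weighted sum of
#' centred log-abundance columns (so its covariance is proportional to the
#' method-1 MRM), `o ~ N(0, (G o M) sigma2_o)` captures the
#' genome-by-microbiome interaction, and `e` is iid. Variance scales are set
#' so the expected phenotypic fractions equal the configured targets; the
#' realised components are returned as ground truth.
#'
#' @param genotypes dosage matrix.
#' @param S log relative abundance matrix over the same animals.
#' @param design data frame from [simulate_design()].
#' @param config a [sim_config()].
#' @return list with `y` (named phenotype vector), `X` (the fixed-effect
#'   design matrix used), `beta`, and `truth` (component vectors `u`, `m`,
#'   `o`, `e` and their realised variance fractions).
#' @export
simulate_phenotypes <- function(genotypes, S, design, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  if (nrow(S) != n || nrow(design) != n)
    stop("genotypes, abundances and design must cover the same animals")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, "phenotypes"))

  X <- build_fixed_design(design)

  G <- unclass(build_grm(genotypes))
  u <- drop(crossprod(chol(G + 1e-6 * diag(n)), stats::rnorm(n)))
  u <- u * sqrt(config$target_h2 / mean(diag(G)))

  Sc <- sweep(unclass(S), 2L, colMeans(S))
  # model-consistent metagenomic effect: with iid standard-normal ORF
  # weights, cov(m) = k^2 Sc Sc' which is proportional to the method-1 MRM,
  # and the trace-based scale k makes the coefficient on the MRM equal the
  # target, so REML recovers it without bias. The REALISED variance of one
  # draw keeps an O(1) fluctuation from the contrast's random loading on the
  # dominant (diet) axis of the MRM; see the methods vignette.
  alpha <- stats::rnorm(ncol(Sc))
  m_eff <- drop(Sc %*% alpha)
  scale2 <- mean(rowSums(Sc^2))
  m_eff <- if (scale2 > 0 && config$target_m2 > 0)
    m_eff * sqrt(config$target_m2 / scale2) else numeric(n)

  if (config$target_i2 > 0) {
    M1 <- unclass(build_mrm(S, method = 1))
    J <- G * M1
    o <- drop(crossprod(chol(J + 1e-6 * diag(n)), stats::rnorm(n)))
    o <- o * sqrt(config$target_i2 / mean(diag(J)))
  } else o <- numeric(n)

  sigma2_e <- 1 - config$target_h2 - config$target_m2 - config$target_i2
  e <- stats::rnorm(n, sd = sqrt(sigma2_e))

  beta <- c(stats::rnorm(1, 10, 1),                         # intercept
            stats::rnorm(ncol(X) - 1L, 0, 0.5))
  names(beta) <- colnames(X)
  # management-group effects drawn wider so beta estimation is non-trivial
  mg_cols <- grep("^management_group", colnames(X))
  beta[mg_cols] <- stats::rnorm(length(mg_cols), 0, 2)

  y <- drop(X %*% beta) + u + m_eff + o + e
  names(y) <- design$animal_id
  comp <- cbind(u = u, m = m_eff, o = o, e = e)
  total <- sum(apply(comp, 2L, stats::var))
  list(y = y, X = X, beta = beta,
       truth = list(u = u, m = m_eff, o = o, e = e,
                    realized_fractions = apply(comp, 2L, stats::var) / total))
}

#' Fixed-effect design matrix
#'
#' Builds the model matrix used throughout: intercept, management group
#' (reference level dropped), all but one breed fraction (the last is dropped
#' to break the sum-to-one collinearity), and expected heterozygosity.
#'
#' @param design data frame with `management_group`, breed-fraction columns
#'   and `heterozygosity`.
#' @return numeric model matrix with `n` rows.
#' @export
build_fixed_design <- function(design) {
  bf_cols <- grep("^breed_", names(design), value = TRUE)
  if (length(bf_cols) > 1) bf_cols <- bf_cols[-length(bf_cols)]
  fml <- stats::as.formula(paste(
    "~ management_group +", paste(c(bf_cols, "heterozygosity"), collapse = " + ")))
  X <- stats::model.matrix(fml, droplevels(design))
  rownames(X) <- design$animal_id
  X
}

#' Simulate a complete study dataset
#'
#' Runs the whole generator: design, genotypes, microbiome, and one phenotype
#' per requested trait, returning an aligned dataset plus the full ground
#' truth. All randomness derives from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param traits named list of target variance-fraction triples
#'   `c(h2, m2, i2)`; defaults to a single trait at the config targets.
#' @return list of class `mg_simulation` with `dataset` (an `mg_dataset`),
#'   `latent`, and `truth` (per-trait component records, per-ORF
#'   heritabilities, shifted-ORF flags).
#' @export
simulate_study <- function(config = sim_config(), traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(traits))
    traits <- list(trait = c(config$target_h2, config$target_m2,
                             config$target_i2))
  design <- simulate_design(config)
  geno <- simulate_genotypes(config$n_animals, config$n_snps,
                             config$maf_range,
                             seed = derive_seed(config$seed, "genotypes"))
  scores <- simulate_genetic_scores(geno, config$n_genetic_factors,
                                    seed = derive_seed(config$seed, "scores"))
  mb <- simulate_microbiome(scores, design$diet_type, config)
  S <- log_relative_abundance(mb$counts)
  ph <- design
  truth <- list(orf_h2 = mb$truth$orf_h2, shifted = mb$truth$shifted,
                library_sizes = mb$truth$library_sizes, traits = list())
  for (tn in names(traits)) {
    tcfg <- config
    tg <- traits[[tn]]
    tcfg$target_h2 <- tg[1]; tcfg$target_m2 <- tg[2]
    tcfg$target_i2 <- if (length(tg) > 2) tg[3] else 0
    tcfg$seed <- derive_seed(config$seed, paste0("trait-", tn))
    sim <- simulate_phenotypes(geno, S, design, tcfg)
    ph[[tn]] <- as.numeric(sim$y)
    truth$traits[[tn]] <- sim$truth
  }
  dataset <- align_dataset(geno, mb$counts, ph)
  structure(list(dataset = dataset, latent = mb$latent, truth = truth,
                 config = config),
            class = "mg_simulation")
}

#' Write a simulated study to disk
#'
#' Emits the three study input tables (genotype TSV, ORF-count TSV,
#' phenotype/covariate TSV) plus a ground-truth TSV of per-animal components,
#' each with a `# seed:` header line.
#'
#' @param sim an `mg_simulation` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "mg_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# seed: %d", sim$config$seed)
  paths <- file.path(dir, c("genotypes.tsv", "orf_counts.tsv",
                            "phenotypes.tsv", "truth.tsv"))
  write_mat <- function(M, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    df <- data.frame(animal_id = rownames(M), M, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(sim$dataset$genotypes, paths[1])
  write_mat(sim$dataset$counts, paths[2])
  con <- file(paths[3], "w")
  writeLines(hdr, con)
  utils::write.table(sim$dataset$phenotypes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  tr <- sim$truth$traits[[1]]
  truth_df <- data.frame(animal_id = sim$dataset$animal_ids,
                         u = tr$u, m = tr$m, o = tr$o, e = tr$e)
  con <- file(paths[4], "w")
  writeLines(hdr, con)
  utils::write.table(truth_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}
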