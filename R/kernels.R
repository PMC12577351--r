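#' Genomic relationship matrix (VanRaden method 1)
#'
#' Builds the GRM from an animals-by-SNP dosage matrix `Q` (counts of the
#' alternate allele, 0/1/2):
#' \deqn{G = (Q - P)(Q - P)' / (2 \sum_i p_i (1 - p_i))}
#' where \eqn{p_i} is the observed alternate-allele frequency at locus
#' \eqn{i} and the columns of `P` equal \eqn{2 p_i}. Because the frequencies
#' are computed from the data themselves, the columns of `Q - P` are centred
#' and every row of `G` sums to zero.
#'
#' @param genotypes numeric matrix of dosages in \{0, 1, 2\}, animals in rows;
#'   no missing values (see [impute_missing_genotypes()]).
#' @return a `rel_matrix` of kind `"G"`, untuned.
#' @seealso [tune()], [hadamard_interaction()]
#' @export
build_grm <- function(genotypes) {
  Q <- as.matrix(genotypes)
  if (anyNA(Q))
    stop("genotype matrix contains missing values; impute first")
  p <- colMeans(Q) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNP columns are monomorphic; GRM denominator is zero")
  Z <- sweep(Q, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(Q), rownames(Q))
  rel_matrix((G + t(G)) / 2, kind = "G")
}

#' Log relative abundance transform of an ORF count table
#'
#' Converts raw read counts `R` (animals x ORFs) into log10 relative
#' abundances with a unit pseudocount:
#' \deqn{S_{ij} = \log_{10}\left((R_{ij} + 1) / \sum_j (R_{ij} + 1)\right)}
#' The pseudocount keeps zero counts finite and the row-wise normalisation
#' absorbs uneven sequencing depth; within each row, \eqn{\sum_j 10^{S_{ij}} = 1}.
#'
#' @param counts non-negative integer matrix of ORF read counts, animals in
#'   rows.
#' @return numeric matrix of the same shape (all entries `<= 0`), with the
#'   class attribute `log_abundance`.
#' @export
log_relative_abundance <- function(counts) {
  R <- as.matrix(counts)
  if (anyNA(R) || any(R < 0))
    stop("counts must be non-negative and complete")
  Rp <- R + 1
  S <- log10(Rp / rowSums(Rp))
  dimnames(S) <- dimnames(R)
  class(S) <- c("log_abundance", class(S))
  S
}

#' Metagenome relationship matrix (single population)
#'
#' Builds an MRM from the log relative abundance matrix `S` by one of two
#' constructions:
#' * **method 1** (GRM-analogous): \eqn{M_1 = (S - N) D (S - N)' / \sum_j var(s_j)},
#'   where `N` holds the per-ORF column means and the denominator is the sum
#'   of per-ORF sample variances;
#' * **method 2** (per-ORF standardisation): columns are centred and scaled
#'   individually to give `C`, then \eqn{M_2 = C D C' / m}.
#'
#' `D` is a diagonal matrix of optional per-ORF weights (identity when
#' `weights` is `NULL`); the weighted adjustment uses `1 - h2_ORF` to
#' down-weight ORFs under strong host-genetic control. Sample (n-1)
#' variances are used throughout, which makes `trace(M1) = trace(M2) = n - 1`
#' for unweighted kernels.
#'
#' @param S log relative abundance matrix (animals x ORFs), from
#'   [log_relative_abundance()].
#' @param method `1` or `2`.
#' @param weights optional per-ORF weights in `[0, 1]`, e.g.
#'   `1 - estimate_orf_heritabilities(...)`.
#' @return a `rel_matrix` of kind `"M"`, untuned.
#' @export
build_mrm <- function(S, method = 1, weights = NULL) {
  S <- unclass(as.matrix(S))
  method <- as.integer(method)
  if (!method %in% c(1L, 2L)) stop("'method' must be 1 or 2")
  m <- ncol(S)
  adjustment <- "naive"
  if (!is.null(weights)) {
    if (length(weights) != m) stop("'weights' must have one entry per ORF")
    if (any(weights < 0 | weights > 1)) stop("'weights' must lie in [0, 1]")
    adjustment <- "weighted"
  }
  v <- apply(S, 2L, stats::var)
  Sc <- sweep(S, 2L, colMeans(S))
  if (method == 1L) {
    denom <- sum(v)
    if (denom <= 0) stop("all ORF columns have zero variance")
    if (!is.null(weights)) Sc <- sweep(Sc, 2L, sqrt(weights), `*`)
    M <- tcrossprod(Sc) / denom
  } else {
    if (any(v <= 0))
      stop("zero-variance ORF column(s); method 2 cannot standardise them")
    C <- sweep(Sc, 2L, sqrt(v), `/`)
    if (!is.null(weights)) C <- sweep(C, 2L, sqrt(weights), `*`)
    M <- tcrossprod(C) / m
  }
  dimnames(M) <- list(rownames(S), rownames(S))
  rel_matrix((M + t(M)) / 2, kind = "M", method = method,
             adjustment = adjustment, weights = weights)
}

#' Cluster animals on principal components of the ORF matrix
#'
#' The data-driven MRM adjustment groups animals by their metagenome
#' composition rather than by an imposed label such as diet: a PCA of the
#' log abundance matrix is followed by k-means (Euclidean, multiple random
#' restarts) on the first few principal component scores.
#'
#' @param S log relative abundance matrix (animals x ORFs).
#' @param n_components number of leading PCs fed to k-means (default 4).
#' @param k number of clusters (default 2).
#' @param seed integer seed controlling the k-means restarts.
#' @param nstart number of k-means restarts; the best within-cluster
#'   sum-of-squares solution is kept.
#' @return integer vector of labels in `1..k`, one per animal.
#' @export
assign_clusters <- function(S, n_components = 4, k = 2, seed = 1, nstart = 25) {
  S <- unclass(as.matrix(S))
  n <- nrow(S)
  if (k > n) stop("'k' cannot exceed the number of animals")
  if (k == 1L) return(rep(1L, n))
  n_components <- min(n_components, n - 1L, ncol(S))
  pcs <- stats::prcomp(S, center = TRUE, scale. = FALSE, rank. = n_components)$x
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  km <- stats::kmeans(pcs, centers = k, nstart = nstart, iter.max = 100L)
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(S)
  labels
}

#' Multi-population metagenome relationship matrix (data-driven adjustment)
#'
#' Builds an MRM in which centring and scaling are performed within animal
#' clusters (normally the output of [assign_clusters()]), so that large
#' compositional shifts between groups (e.g. forage vs concentrate diets) do
#' not dominate the kernel. Block structure over clusters a, b:
#' * **method 1**: diagonal blocks as the single-population method-1 MRM using
#'   that cluster's means/variances; cross blocks
#'   \eqn{(S_a - N_a)(S_b - N_b)' / \sqrt{\sum_j var(s_{aj})} \sqrt{\sum_j var(s_{bj})}}
#'   (geometric mean of the two variance sums);
#' * **method 2**: per-cluster standardised matrices `C_c`, blocks
#'   \eqn{C_a C_b' / m}.
#'
#' The input animal order is preserved in the output.
#'
#' @param S log relative abundance matrix (animals x ORFs).
#' @param method `1` or `2`.
#' @param labels per-animal cluster labels; every cluster needs at least two
#'   animals.
#' @return a `rel_matrix` of kind `"M"` with `adjustment = "data-driven"`.
#' @export
build_mrm_multipop <- function(S, method = 1, labels) {
  S <- unclass(as.matrix(S))
  method <- as.integer(method)
  if (!method %in% c(1L, 2L)) stop("'method' must be 1 or 2")
  n <- nrow(S)
  if (length(labels) != n) stop("'labels' must have one entry per animal")
  labels <- as.integer(factor(labels))
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("every cluster must contain at least 2 animals (variance undefined)")
  clusters <- sort(unique(labels))
  m <- ncol(S)

  # per-cluster centred (method 1) or standardised (method 2) sub-matrices,
  # plus the per-cluster variance sums used for method-1 scaling
  centred <- vector("list", length(clusters))
  vsum <- numeric(length(clusters))
  for (ci in seq_along(clusters)) {
    rows <- which(labels == clusters[ci])
    Sc <- S[rows, , drop = FALSE]
    v <- apply(Sc, 2L, stats::var)
    Cc <- sweep(Sc, 2L, colMeans(Sc))
    if (method == 2L) {
      if (any(v <= 0))
        stop("zero-variance ORF column within a cluster; method 2 cannot standardise")
      Cc <- sweep(Cc, 2L, sqrt(v), `/`)
    }
    centred[[ci]] <- Cc
    vsum[ci] <- sum(v)
  }
  if (method == 1L && any(vsum <= 0))
    stop("a cluster has zero total ORF variance")

  M <- matrix(0, n, n)
  for (a in seq_along(clusters)) {
    ra <- which(labels == clusters[a])
    for (b in seq_len(a)) {
      rb <- which(labels == clusters[b])
      cross <- tcrossprod(centred[[a]], centred[[b]])
      block <- if (method == 1L) cross / sqrt(vsum[a] * vsum[b]) else cross / m
      M[ra, rb] <- block
      if (a != b) M[rb, ra] <- t(block)
    }
  }
  dimnames(M) <- list(rownames(S), rownames(S))
  rel_matrix((M + t(M)) / 2, kind = "M", method = method,
             adjustment = "data-driven", cluster_labels = labels)
}

#' Hadamard genome-by-microbiome interaction kernel
#'
#' The covariance of a genotype-by-microbiome interaction effect is modelled
#' as the elementwise (Hadamard) product of the genomic and metagenomic
#' kernels, \eqn{J = G \circ M}. Both inputs must be untuned: the ridge is
#' applied to `J` itself afterwards, not inherited from its factors. The
#' Schur product theorem guarantees `J` is positive semidefinite whenever
#' both factors are.
#'
#' @param G untuned genomic `rel_matrix`.
#' @param M untuned metagenomic `rel_matrix` over the same animals, in the
#'   same order.
#' @return a `rel_matrix` of kind `"J"`, untuned, inheriting the MRM's
#'   method/adjustment tags.
#' @export
hadamard_interaction <- function(G, M) {
  stopifnot(inherits(G, "rel_matrix"), inherits(M, "rel_matrix"))
  if (is_tuned(G) || is_tuned(M))
    stop("interaction kernels are formed from untuned G and M; got a tuned input")
  if (!all(dim(G) == dim(M)))
    stop("G and M must have the same dimension")
  if (!is.null(rownames(G)) && !is.null(rownames(M)) &&
      !identical(rownames(G), rownames(M)))
    stop("G and M must be indexed by the same animals in the same order")
  J <- unclass(G) * unclass(M)
  rel_matrix(J, kind = "J", method = attr(M, "method"),
             adjustment = attr(M, "adjustment"))
}

#' Build the full kernel set of the study design
#'
#' One call that produces the genomic relationship matrix, the six metagenome
#' relationship matrices (methods 1 and 2, each with naive, weighted, and
#' data-driven adjustments) and the six corresponding Hadamard interaction
#' kernels, all tuned with the same diagonal ridge. The weighted adjustment
#' needs per-ORF heritabilities; pass them via `orf_h2` or let the function
#' estimate them with [estimate_orf_heritabilities()] (requires `X`).
#'
#' @param genotypes dosage matrix (no missing values).
#' @param counts ORF count table over the same animals.
#' @param orf_h2 optional per-ORF heritability vector for the weighted
#'   adjustment; estimated from the data when `NULL`.
#' @param X fixed-effect design matrix, used only when `orf_h2` is `NULL`.
#' @param n_components,k,seed data-driven clustering settings, see
#'   [assign_clusters()].
#' @param epsilon tuning ridge (default 0.001).
#' @return a list with elements `G` (tuned GRM), `M` (named list of six tuned
#'   MRMs), `J` (named list of six tuned interaction kernels),
#'   `cluster_labels`, `orf_h2`, and the untuned `G_raw`.
#' @export
build_kernel_set <- function(genotypes, counts, orf_h2 = NULL, X = NULL,
                             n_components = 4, k = 2, seed = 1,
                             epsilon = 0.001) {
  S <- log_relative_abundance(counts)
  G_raw <- build_grm(genotypes)
  if (is.null(orf_h2)) {
    if (is.null(X)) X <- matrix(1, nrow(S), 1)
    orf_h2 <- estimate_orf_heritabilities(S, tune(G_raw, epsilon), X)
  }
  w <- pmin(pmax(1 - orf_h2, 0), 1)
  labels <- assign_clusters(S, n_components = n_components, k = k, seed = seed)

  M_raw <- list(
    m1_naive       = build_mrm(S, 1),
    m2_naive       = build_mrm(S, 2),
    m1_weighted    = build_mrm(S, 1, weights = w),
    m2_weighted    = build_mrm(S, 2, weights = w),
    m1_data_driven = build_mrm_multipop(S, 1, labels),
    m2_data_driven = build_mrm_multipop(S, 2, labels)
  )
  J_raw <- lapply(M_raw, function(M) hadamard_interaction(G_raw, M))
  list(
    G = tune(G_raw, epsilon),
    M = lapply(M_raw, tune, epsilon = epsilon),
    J = lapply(J_raw, tune, epsilon = epsilon),
    cluster_labels = labels,
    orf_h2 = orf_h2,
    G_raw = G_raw
  )
}
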