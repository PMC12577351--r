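#' Minor allele frequency filter
#'
#' Drops SNP columns whose minor allele frequency, computed from non-missing
#' dosages, is not strictly greater than `threshold`. Column order is
#' preserved.
#'
#' @param genotypes dosage matrix in \{0, 1, 2\}, `NA` allowed.
#' @param threshold MAF cutoff; default 0.05.
#' @return the filtered dosage matrix, with an attribute `n_removed`.
#' @export
filter_maf <- function(genotypes, threshold = 0.05) {
  Q <- as.matrix(genotypes)
  p <- colMeans(Q, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep))
    stop(sprintf("MAF filter removed all %d SNP columns", ncol(Q)))
  out <- Q[, keep, drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing call with twice the observed alternate-allele
#' frequency of its locus (the column mean dosage), the standard fill-in for
#' GRM construction when upstream imputation is unavailable.
#'
#' @param genotypes dosage matrix with `NA` for missing calls.
#' @return complete dosage matrix.
#' @export
impute_missing_genotypes <- function(genotypes) {
  Q <- as.matrix(genotypes)
  if (!anyNA(Q)) return(Q)
  full_missing <- colSums(!is.na(Q)) == 0
  if (any(full_missing)) {
    bad <- colnames(Q)[full_missing] %||% which(full_missing)
    stop("column(s) fully missing: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  mu <- colMeans(Q, na.rm = TRUE)
  idx <- which(is.na(Q), arr.ind = TRUE)
  Q[idx] <- mu[idx[, 2L]]
  Q
}

#' Prevalence/abundance filter for ORF count tables
#'
#' An ORF is removed only when it is BOTH rare across samples and never
#' abundant within any single sample: prevalence (fraction of samples with a
#' non-zero count) below `min_prevalence` AND maximum within-sample relative
#' abundance below `min_abundance`. Meeting either criterion keeps the ORF.
#' Setting `logic = "or"` removes an ORF failing either criterion instead.
#'
#' @param counts non-negative integer matrix, animals in rows.
#' @param min_prevalence prevalence threshold, default 0.10.
#' @param min_abundance within-sample relative-abundance threshold, default
#'   1e-4 (0.01 percent).
#' @param logic `"and"` (default; removal requires both deficiencies) or
#'   `"or"`.
#' @return filtered count matrix with attribute `n_removed`.
#' @export
filter_orfs <- function(counts, min_prevalence = 0.10, min_abundance = 1e-4,
                        logic = c("and", "or")) {
  logic <- match.arg(logic)
  R <- as.matrix(counts)
  if (any(R < 0)) stop("counts must be non-negative")
  totals <- rowSums(R)
  if (any(totals == 0)) {
    bad <- rownames(R)[totals == 0] %||% which(totals == 0)
    stop("sample(s) with zero total reads: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  prevalence <- colMeans(R > 0)
  rel <- R / totals
  max_abund <- apply(rel, 2L, max)
  low_prev <- prevalence < min_prevalence
  low_abund <- max_abund < min_abundance
  remove <- if (logic == "and") low_prev & low_abund else low_prev | low_abund
  out <- R[, !remove, drop = FALSE]
  attr(out, "n_removed") <- sum(remove)
  out
}

#' Within-group phenotype outlier removal
#'
#' Removes animals whose value for ANY listed trait lies further than
#' `z` standard deviations from that trait's mean within the animal's group
#' (by default, diet). Group means and SDs are computed once on the original
#' data (single pass, no iteration). Groups with zero trait SD remove nobody.
#'
#' @param phenotypes data frame with an `animal_id` column, the trait columns
#'   and the grouping column.
#' @param traits character vector of trait column names.
#' @param group_key grouping column name; default `"diet"`.
#' @param z SD multiplier; default 3.
#' @return list with `data` (the filtered data frame) and `removed`
#'   (character vector of removed animal ids).
#' @export
filter_phenotype_outliers <- function(phenotypes, traits, group_key = "diet",
                                      z = 3) {
  stopifnot(is.data.frame(phenotypes), all(traits %in% names(phenotypes)),
            group_key %in% names(phenotypes))
  grp <- phenotypes[[group_key]]
  out_flag <- rep(FALSE, nrow(phenotypes))
  for (tr in traits) {
    x <- phenotypes[[tr]]
    mu <- stats::ave(x, grp, FUN = function(v) mean(v, na.rm = TRUE))
    sd_g <- stats::ave(x, grp, FUN = function(v) stats::sd(v, na.rm = TRUE))
    dev <- abs(x - mu)
    flag <- !is.na(sd_g) & sd_g > 0 & dev > z * sd_g
    out_flag <- out_flag | (flag & !is.na(flag))
  }
  removed <- as.character(phenotypes$animal_id[out_flag])
  list(data = phenotypes[!out_flag, , drop = FALSE], removed = removed)
}

#' Align genotype, count and phenotype tables on a common animal set
#'
#' Intersects the animal ids of the three inputs and returns them subset and
#' reordered identically, the invariant every kernel and model fit relies on.
#'
#' @param genotypes dosage matrix with animal rownames.
#' @param counts ORF count matrix with animal rownames.
#' @param phenotypes data frame with an `animal_id` column.
#' @return list of class `mg_dataset` with elements `genotypes`, `counts`,
#'   `phenotypes`, `animal_ids`.
#' @export
align_dataset <- function(genotypes, counts, phenotypes) {
  ids <- Reduce(intersect, list(rownames(genotypes), rownames(counts),
                                as.character(phenotypes$animal_id)))
  if (length(ids) == 0) stop("no animals shared across the three inputs")
  if (anyDuplicated(ids)) stop("duplicated animal ids")
  ph <- phenotypes[match(ids, as.character(phenotypes$animal_id)), , drop = FALSE]
  rownames(ph) <- NULL
  structure(list(genotypes = genotypes[ids, , drop = FALSE],
                 counts = counts[ids, , drop = FALSE],
                 phenotypes = ph,
                 animal_ids = ids),
            class = "mg_dataset")
}

#' Apply the full record/feature filter chain to a dataset
#'
#' Convenience wrapper running, in order: within-group trait outlier removal,
#' genotype MAF filtering and mean-dosage imputation, and the ORF
#' prevalence/abundance filter, re-aligning animals afterwards. A manifest of
#' removal counts is attached.
#'
#' @param dataset an `mg_dataset` from [align_dataset()].
#' @param traits trait columns used for outlier removal.
#' @param maf,min_prevalence,min_abundance,outlier_z,orf_logic filter
#'   settings; see the individual filter functions.
#' @return filtered `mg_dataset` with attribute `filter_manifest`.
#' @export
apply_filters <- function(dataset, traits, maf = 0.05, min_prevalence = 0.10,
                          min_abundance = 1e-4, outlier_z = 3,
                          orf_logic = "and") {
  stopifnot(inherits(dataset, "mg_dataset"))
  ph <- filter_phenotype_outliers(dataset$phenotypes, traits, z = outlier_z)
  geno <- filter_maf(dataset$genotypes, threshold = maf)
  n_snps_removed <- attr(geno, "n_removed")
  geno <- impute_missing_genotypes(geno)
  orfs <- filter_orfs(dataset$counts, min_prevalence, min_abundance,
                      logic = orf_logic)
  n_orfs_removed <- attr(orfs, "n_removed")
  out <- align_dataset(geno, orfs, ph$data)
  attr(out, "filter_manifest") <- list(
    animals_removed = length(ph$removed),
    removed_ids = ph$removed,
    snps_removed = n_snps_removed,
    orfs_removed = n_orfs_removed
  )
  out
}
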