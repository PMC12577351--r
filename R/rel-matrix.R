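#' Relationship-matrix objects
#'
#' A `rel_matrix` is a dense symmetric animal-by-animal (co)variance kernel
#' with metadata recording how it was built: its `kind` (`"G"` for the genomic
#' relationship matrix, `"M"` for a metagenome relationship matrix, `"J"` for
#' a Hadamard genome-by-microbiome interaction kernel), the MRM construction
#' `method` (1 or 2) and `adjustment` (`"naive"`, `"weighted"`,
#' `"data-driven"`) where applicable, whether it has been tuned (ridge added
#' for invertibility), and optional per-animal cluster labels or per-ORF
#' weights used during construction.
#'
#' @param values symmetric numeric matrix (animals x animals); dimnames are
#'   used as animal ids when present.
#' @param kind one of `"G"`, `"M"`, `"J"`.
#' @param method MRM construction method, `1L`, `2L`, or `NA`.
#' @param adjustment MRM adjustment, or `NA` for non-MRM kernels.
#' @param tuned logical; has the diagonal ridge been applied?
#' @param cluster_labels optional per-animal cluster assignment (data-driven
#'   kernels).
#' @param weights optional per-ORF weight vector (weighted kernels).
#'
#' @return an object of class `rel_matrix` (a numeric matrix with attributes).
#' @export
rel_matrix <- function(values, kind = c("G", "M", "J"), method = NA_integer_,
                       adjustment = NA_character_, tuned = FALSE,
                       cluster_labels = NULL, weights = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("relationship matrix must be symmetric")
  structure(
    values,
    kind = kind,
    method = method,
    adjustment = adjustment,
    tuned = isTRUE(tuned),
    cluster_labels = cluster_labels,
    weights = weights,
    class = c("rel_matrix", "matrix", "array")
  )
}

#' @export
print.rel_matrix <- function(x, ...) {
  adj <- attr(x, "adjustment")
  lbl <- attr(x, "kind")
  if (!is.na(attr(x, "method"))) lbl <- paste0(lbl, attr(x, "method"))
  if (!is.na(adj) && length(adj)) lbl <- paste(lbl, adj)
  cat(sprintf("<rel_matrix %s, %d animals, %s>\n", lbl, nrow(x),
              if (is_tuned(x)) "tuned" else "untuned"))
  invisible(x)
}

#' Test whether a kernel has been tuned
#' @param x a `rel_matrix`.
#' @return logical scalar.
#' @export
is_tuned <- function(x) isTRUE(attr(x, "tuned"))

#' Tune a relationship matrix for inversion
#'
#' Adds a small ridge `epsilon` to the diagonal (`A + epsilon * I`) so that
#' singular Gram-type kernels become positive definite and hence invertible
#' in the mixed-model equations. Tuning the same kernel twice is refused:
#' the ridge is part of the model definition, not a numerical fix to iterate.
#'
#' @param A a `rel_matrix` (untuned).
#' @param epsilon positive diagonal increment; default 0.001.
#' @return the tuned `rel_matrix`.
#' @export
tune <- function(A, epsilon = 0.001) {
  stopifnot(inherits(A, "rel_matrix"))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("'epsilon' must be a single positive number")
  if (is_tuned(A))
    stop("kernel is already tuned; tuning twice is not allowed")
  out <- unclass(A)
  diag(out) <- diag(out) + epsilon
  rel_matrix(out,
             kind = attr(A, "kind"), method = attr(A, "method"),
             adjustment = attr(A, "adjustment"), tuned = TRUE,
             cluster_labels = attr(A, "cluster_labels"),
             weights = attr(A, "weights"))
}

# relative PSD check used by kernel constructors: smallest eigenvalue no more
# negative than 1e-8 * trace/n (floating-point slack for Gram matrices)
check_psd <- function(values, tol_scale = 1e-8) {
  ev <- min(eigen(values, symmetric = TRUE, only.values = TRUE)$values)
  ev >= -tol_scale * max(sum(diag(values)) / nrow(values), 1)
}
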