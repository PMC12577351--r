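#' Stratified fourfold cross-validation plans
#'
#' Randomly allocates animals to folds within each sex stratum (sex being a
#' proxy for diet type), so the folds are balanced for diet type; the whole
#' allocation is repeated `n_replicates` times. Each replicate partitions the
#' animals: every animal is tested exactly once per replicate. With 4 folds
#' and 5 replicates a model accumulates 20 evaluation results.
#'
#' @param animals character vector of animal ids.
#' @param sex per-animal stratum labels.
#' @param n_folds number of folds (default 4).
#' @param n_replicates number of replicates (default 5); replicate `r` uses
#'   seed `seed + r`.
#' @param seed integer base seed.
#' @return list of fold plans; each is a list with `scheme`, `replicate`,
#'   `fold`, `train`, `test` (ids).
#' @export
make_fourfold_plan <- function(animals, sex, n_folds = 4, n_replicates = 5,
                               seed = 1) {
  animals <- as.character(animals)
  stopifnot(length(sex) == length(animals))
  strata <- split(animals, sex)
  if (any(lengths(strata) < n_folds))
    stop("every sex stratum needs at least 'n_folds' animals")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  plans <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(as.integer(seed) + r)
    fold_of <- integer(length(animals))
    names(fold_of) <- animals
    for (st in strata) {
      shuffled <- sample(st)
      fold_of[shuffled] <- rep_len(seq_len(n_folds), length(shuffled))
    }
    for (f in seq_len(n_folds)) {
      test <- animals[fold_of[animals] == f]
      plans[[length(plans) + 1L]] <- list(scheme = "fourfold", replicate = r,
                                          fold = f,
                                          train = setdiff(animals, test),
                                          test = test)
    }
  }
  plans
}

#' Leave-one-diet-out cross-validation plans
#'
#' One plan per diet: that diet's animals are the test set and all remaining
#' diets form the training set.
#'
#' @param animals character vector of animal ids.
#' @param diet per-animal diet labels.
#' @return list of fold plans in diet order.
#' @export
make_lodo_plan <- function(animals, diet) {
  animals <- as.character(animals)
  stopifnot(length(diet) == length(animals))
  diets <- unique(diet)
  if (length(diets) < 2) stop("need at least 2 diets")
  lapply(seq_along(diets), function(i) {
    test <- animals[diet == diets[i]]
    if (!length(test)) stop("diet ", diets[i], " has no animals")
    list(scheme = "lodo", replicate = 1L, fold = i,
         diet = as.character(diets[i]),
         train = animals[diet != diets[i]], test = test)
  })
}

#' Evaluate one cross-validation fold
#'
#' Masks the test animals' phenotypes, re-estimates variance components on
#' the training records with [fit_mixed_model()] (the kernels, built once on
#' all animals, are shared across folds), obtains BLUP solutions for the
#' test animals through their kernel relationships, and scores prediction of
#' the adjusted phenotype `y_adj = y - X beta_hat`:
#' * accuracy: Pearson correlation of `y_adj` with the total animal merit
#'   (TAM, the per-animal sum of random-effect solutions) and with each
#'   individual solution (EBV for the genomic, EMV for the metagenomic, EIV
#'   for the interaction effect);
#' * RMSE of TAM against `y_adj`;
#' * dispersion: the slope of the OLS regression (with intercept) of `y_adj`
#'   on TAM, 1 indicating unbiased calibration.
#'
#' When a variance component is pinned at the zero boundary its solutions
#' are identically zero; such a degenerate predictor is scored with accuracy
#' 0 (it carries no ranking information) and `NA` dispersion.
#'
#' `beta_hat` defaults to the training-fit GLS solutions; pass the fixed
#' effects of a full-data fit instead when test levels (e.g. a left-out
#' diet's management groups) are unestimable from training data.
#'
#' @param y phenotype vector over all animals (named by animal id).
#' @param X fixed-effect design matrix over all animals (rownames = ids).
#' @param kernels named list of tuned kernels over all animals.
#' @param plan a single fold plan.
#' @param beta_hat optional fixed-effect vector (named by design column)
#'   supplying `y_adj`; `NULL` uses the training fit's estimates.
#' @param ... passed to [fit_mixed_model()].
#' @return one-row data frame of class `prediction_metrics`: scheme,
#'   replicate, fold, accuracies, rmse, dispersion, converged.
#' @export
evaluate_fold <- function(y, X, kernels, plan, beta_hat = NULL, ...) {
  ids <- rownames(as.matrix(kernels[[1]]))
  if (is.null(ids)) ids <- names(y)
  stopifnot(!is.null(ids), all(plan$test %in% ids), all(plan$train %in% ids))
  y_mask <- y[ids]
  y_mask[ids %in% plan$test] <- NA

  if (is.null(beta_hat)) {
    # training-only beta requires every design level to appear in training
    Xtr <- X[ids %in% plan$train, , drop = FALSE]
    keep <- qr(Xtr)$rank
    if (keep < ncol(Xtr))
      stop("fixed-effect levels present only in the test set; ",
           "supply 'beta_hat' from a full-data fit")
  }

  fit <- fit_mixed_model(y_mask, X, kernels, ...)
  bh <- if (is.null(beta_hat)) fit$beta else beta_hat[fit$X_names]
  y_adj <- drop(y[ids] - X[, fit$X_names, drop = FALSE] %*% bh)
  names(y_adj) <- ids

  test <- plan$test
  tam <- rowSums(fit$blup)[test]
  ya <- y_adj[test]
  # a degenerate predictor (all solutions zero, e.g. the component pinned at
  # the zero boundary) has no predictive ability: accuracy 0, dispersion NA
  acc <- function(pred, obs) {
    if (stats::sd(obs) == 0) return(NA_real_)
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, obs)
  }
  comp_acc <- c(accuracy_EBV = NA_real_, accuracy_EMV = NA_real_,
                accuracy_EIV = NA_real_)
  map <- c(genomic = "accuracy_EBV", metagenomic = "accuracy_EMV",
           interaction = "accuracy_EIV")
  for (k in colnames(fit$blup))
    if (k %in% names(map)) comp_acc[map[[k]]] <- acc(fit$blup[test, k], ya)
  disp <- if (stats::sd(tam) > 0)
    unname(stats::coef(stats::lm(ya ~ tam))[2]) else NA_real_
  out <- data.frame(scheme = plan$scheme, replicate = plan$replicate,
                    fold = plan$fold,
                    accuracy_TAM = acc(tam, ya),
                    accuracy_EBV = comp_acc[["accuracy_EBV"]],
                    accuracy_EMV = comp_acc[["accuracy_EMV"]],
                    accuracy_EIV = comp_acc[["accuracy_EIV"]],
                    rmse = sqrt(mean((ya - tam)^2)),
                    dispersion = disp,
                    converged = fit$converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_metrics", class(out))
  out
}

#' Summarise per-fold prediction metrics
#'
#' Medians and standard deviations of each metric across folds, computed over
#' converged folds only; non-converged folds are counted and reported, not
#' summarised.
#'
#' @param metrics data frame of stacked [evaluate_fold()] rows, optionally
#'   with extra grouping columns.
#' @param group_by character vector of grouping column names (e.g. `trait`,
#'   `model_id`, `scheme`); `NULL` summarises everything together.
#' @return data frame with one row per group: `median_*` and `sd_*` per
#'   metric, `n_folds`, `n_omitted`.
#' @export
summarize_metrics <- function(metrics, group_by = NULL) {
  stopifnot(is.data.frame(metrics))
  vars <- intersect(c("accuracy_TAM", "accuracy_EBV", "accuracy_EMV",
                      "accuracy_EIV", "rmse", "dispersion"), names(metrics))
  grp <- if (is.null(group_by)) rep("all", nrow(metrics)) else
    interaction(metrics[group_by], drop = TRUE, sep = " | ")
  out <- lapply(split(metrics, grp), function(d) {
    ok <- d$converged %in% TRUE
    n_omit <- sum(!ok)
    d <- d[ok, , drop = FALSE]
    if (!nrow(d)) {
      warning("a group has no converged folds; omitted from the summary")
      return(NULL)
    }
    row <- d[1, group_by, drop = FALSE]
    for (v in vars) {
      row[[paste0("median_", v)]] <- stats::median(d[[v]], na.rm = TRUE)
      row[[paste0("sd_", v)]] <- stats::sd(d[[v]], na.rm = TRUE)
    }
    row$n_folds <- nrow(d)
    row$n_omitted <- n_omit
    row
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
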