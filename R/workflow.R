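#' Study configuration
#'
#' Assembles (and validates) the configuration driving [run_study()]: either
#' paths to the three input tables or a [sim_config()] for synthetic data,
#' filter thresholds, kernel settings, the model-grid selection, validation
#' settings, the output directory and a single global seed from which every
#' random stream is derived.
#'
#' @param sim a [sim_config()], or `NULL` when `paths` are given.
#' @param paths named list with `genotypes`, `counts`, `phenotypes` TSV paths
#'   (as written by [write_study()]); ignored when `sim` is given.
#' @param traits named list of trait target triples for simulation, or
#'   character vector of phenotype columns when loading from paths.
#' @param filters list of filter settings (`maf`, `min_prevalence`,
#'   `min_abundance`, `outlier_z`, `orf_logic`).
#' @param kernels list of kernel settings (`epsilon`, `k`, `n_pcs`).
#' @param models list restricting the model grid (`complexities`, `methods`,
#'   `adjustments`).
#' @param validation list of validation settings (`schemes`, `n_folds`,
#'   `n_replicates`, `beta_source` one of `"full"`/`"train"`).
#' @param out_dir output directory, or `NULL` for no file output.
#' @param seed global seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(sim = sim_config(), paths = NULL, traits = NULL,
                         filters = list(), kernels = list(), models = list(),
                         validation = list(), out_dir = NULL, seed = 1) {
  filters <- utils::modifyList(list(maf = 0.05, min_prevalence = 0.10,
                                    min_abundance = 1e-4, outlier_z = 3,
                                    orf_logic = "and"), filters)
  kernels <- utils::modifyList(list(epsilon = 0.001, k = 2L, n_pcs = 4L),
                               kernels)
  models <- utils::modifyList(list(
    complexities = c("genomic-only", "metagenomic-only", "joint",
                     "interaction"),
    methods = c(1L, 2L),
    adjustments = c("naive", "weighted", "data-driven")), models)
  validation <- utils::modifyList(list(schemes = c("fourfold", "lodo"),
                                       n_folds = 4L, n_replicates = 5L,
                                       beta_source = "full"), validation)
  if (is.null(sim) && is.null(paths))
    stop("either 'sim' or 'paths' must be provided")
  if (!is.null(paths)) {
    missing_p <- setdiff(c("genotypes", "counts", "phenotypes"), names(paths))
    if (length(missing_p)) stop("paths missing: ", paste(missing_p, collapse = ", "))
    for (p in unlist(paths)) if (!file.exists(p)) stop("path does not exist: ", p)
  }
  structure(list(sim = sim, paths = paths, traits = traits, filters = filters,
                 kernels = kernels, models = models, validation = validation,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Keys mirror the arguments of [study_config()]; `sim` holds [sim_config()]
#' fields. Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else
    if (is.null(raw$paths)) sim_config() else NULL
  paths <- raw$paths
  if (!is.null(paths))
    paths <- lapply(paths, function(p)
      if (file.exists(p)) p else file.path(dirname(path), p))
  study_config(sim = sim, paths = paths, traits = raw$traits,
               filters = raw$filters %||% list(),
               kernels = raw$kernels %||% list(),
               models = raw$models %||% list(),
               validation = raw$validation %||% list(),
               out_dir = raw$out_dir, seed = raw$seed %||% 1)
}

read_study_tables <- function(paths) {
  read_tsv <- function(p) utils::read.delim(p, comment.char = "#",
                                            check.names = FALSE)
  gt <- read_tsv(paths$genotypes)
  geno <- as.matrix(gt[, -1, drop = FALSE])
  rownames(geno) <- as.character(gt[[1]])
  ct <- read_tsv(paths$counts)
  counts <- as.matrix(ct[, -1, drop = FALSE])
  rownames(counts) <- as.character(ct[[1]])
  ph <- read_tsv(paths$phenotypes)
  names(ph)[1] <- "animal_id"
  for (cl in intersect(c("diet", "management_group"), names(ph)))
    ph[[cl]] <- factor(ph[[cl]])
  list(genotypes = geno, counts = counts, phenotypes = ph)
}

#' Run the full study workflow
#'
#' Orchestrates, from one configuration: data simulation (or loading),
#' record/feature filtering, construction of the GRM, six MRMs and six
#' interaction kernels, REML fitting of the model grid per trait (variance
#' ratios, SEs, AIC, convergence), and both cross-validation schemes with
#' per-fold and summarised prediction metrics. Partial failures (a model
#' that errors) are recorded in the manifest and do not abort the bundle.
#'
#' @param config a [study_config()] (or a YAML path readable by
#'   [read_study_config()]).
#' @param verbose print progress to stderr.
#' @return list of class `study_report`: `parameters` (per-model variance
#'   ratios and AIC), `cv_folds` (per-fold metrics), `cv_summary`,
#'   `manifest`, `dataset`, `kernel_set`, and `truth` when simulated. When
#'   `config$out_dir` is set, the tables are also written as TSV plus a JSON
#'   manifest.
#' @export
run_study <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)
  manifest <- list(seed = config$seed, timestamp = format(Sys.time()),
                   package_version = as.character(utils::packageVersion("metablup")))

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulating dataset")
    cfg <- config$sim
    cfg$seed <- derive_seed(config$seed, "simulate")
    sim <- simulate_study(cfg, traits = config$traits)
    dataset <- sim$dataset
    truth <- sim$truth
    trait_names <- names(truth$traits)
    manifest$sim <- unclass(cfg)[c("n_animals", "n_snps", "n_orfs", "n_diets",
                                   "n_management_groups", "seed")]
  } else {
    say("loading dataset from paths")
    tabs <- read_study_tables(config$paths)
    dataset <- align_dataset(tabs$genotypes, tabs$counts, tabs$phenotypes)
    trait_names <- config$traits %||%
      stop("'traits' must name the phenotype columns when loading from paths")
  }

  say("filtering")
  dataset <- apply_filters(dataset, traits = trait_names,
                           maf = config$filters$maf,
                           min_prevalence = config$filters$min_prevalence,
                           min_abundance = config$filters$min_abundance,
                           outlier_z = config$filters$outlier_z,
                           orf_logic = config$filters$orf_logic)
  manifest$filters <- attr(dataset, "filter_manifest")
  ph <- dataset$phenotypes
  X <- build_fixed_design(ph)

  # --- kernels ------------------------------------------------------------
  say("building kernels")
  kset <- build_kernel_set(dataset$genotypes, dataset$counts, X = X,
                           n_components = config$kernels$n_pcs,
                           k = config$kernels$k,
                           seed = derive_seed(config$seed, "clusters"),
                           epsilon = config$kernels$epsilon)
  manifest$kernels <- list(n_mrm = length(kset$M), n_interaction = length(kset$J),
                           epsilon = config$kernels$epsilon,
                           k = config$kernels$k)

  grid <- model_grid(trait_names, complexities = config$models$complexities,
                     methods = config$models$methods,
                     adjustments = config$models$adjustments)
  manifest$n_models <- nrow(grid)

  # --- full-data fits: parameter table ------------------------------------
  param_rows <- list()
  full_fits <- list()
  failures <- list()
  for (i in seq_len(nrow(grid))) {
    spec <- grid[i, ]
    say("fitting ", spec$model_id)
    res <- tryCatch({
      klist <- kernels_for_spec(spec, kset)
      y <- ph[[spec$trait]]
      names(y) <- ph$animal_id
      fit_mixed_model(y, X, klist)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[spec$model_id]] <- conditionMessage(res)
      next
    }
    full_fits[[spec$model_id]] <- res
    r <- res$ratios
    row <- data.frame(spec, row.names = NULL)
    for (nm in c("h2", "m2", "i_a2", "i_i2")) {
      hit <- match(nm, r$ratio)
      row[[nm]] <- if (is.na(hit)) NA_real_ else r$estimate[hit]
      row[[paste0(nm, "_se")]] <- if (is.na(hit)) NA_real_ else r$se[hit]
    }
    row$logl <- res$logl
    row$aic <- res$aic
    row$converged <- res$converged
    param_rows[[length(param_rows) + 1L]] <- row
  }
  parameters <- do.call(rbind, param_rows)
  manifest$failed_models <- failures

  # --- cross-validation ---------------------------------------------------
  fold_rows <- list()
  schemes <- config$validation$schemes
  plans <- list()
  if ("fourfold" %in% schemes)
    plans <- c(plans, make_fourfold_plan(ph$animal_id, ph$sex,
                                         n_folds = config$validation$n_folds,
                                         n_replicates = config$validation$n_replicates,
                                         seed = derive_seed(config$seed, "folds")))
  if ("lodo" %in% schemes)
    plans <- c(plans, make_lodo_plan(ph$animal_id, as.character(ph$diet)))
  manifest$n_plans <- length(plans)

  for (i in seq_len(nrow(grid))) {
    spec <- grid[i, ]
    if (is.null(full_fits[[spec$model_id]])) next
    klist <- kernels_for_spec(spec, kset)
    y <- ph[[spec$trait]]
    names(y) <- ph$animal_id
    bh <- if (identical(config$validation$beta_source, "full")) {
      b <- full_fits[[spec$model_id]]$beta
      b
    } else NULL
    for (pl in plans) {
      say("  ", spec$model_id, " ", pl$scheme, " rep ", pl$replicate,
          " fold ", pl$fold)
      mrow <- tryCatch(
        evaluate_fold(y, X, klist, pl, beta_hat = bh),
        error = function(e) e)
      if (inherits(mrow, "error")) {
        failures[[paste(spec$model_id, pl$scheme, pl$replicate, pl$fold,
                        sep = ".")]] <- conditionMessage(mrow)
        next
      }
      mrow <- cbind(data.frame(trait = spec$trait, model_id = spec$model_id,
                               stringsAsFactors = FALSE), mrow)
      fold_rows[[length(fold_rows) + 1L]] <- mrow
    }
  }
  cv_folds <- do.call(rbind, fold_rows)
  cv_summary <- if (!is.null(cv_folds) && nrow(cv_folds))
    summarize_metrics(cv_folds, group_by = c("trait", "model_id", "scheme"))
  else NULL
  manifest$failed_models <- failures

  report <- structure(list(parameters = parameters, cv_folds = cv_folds,
                           cv_summary = cv_summary, manifest = manifest,
                           dataset = dataset, kernel_set = kset,
                           truth = truth),
                      class = "study_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) if (!is.null(d))
      utils::write.table(d, file.path(config$out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(parameters, "parameters.tsv")
    wt(cv_folds, "cv_folds.tsv")
    wt(cv_summary, "cv_summary.tsv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         force = TRUE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  models fitted:", if (is.null(x$parameters)) 0 else nrow(x$parameters), "\n")
  cat("  cv folds evaluated:",
      if (is.null(x$cv_folds)) 0 else nrow(x$cv_folds), "\n")
  invisible(x)
}
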