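#' Restricted log-likelihood of a multi-kernel animal model
#'
#' Evaluates the REML log-likelihood of `y = X beta + sum_k u_k + e` with
#' `u_k ~ N(0, K_k sigma2_k)` and `e ~ N(0, I sigma2_e)`:
#' \deqn{\ell_R = -\tfrac12 [\log|V| + \log|X'V^{-1}X| + y'Py]}
#' (up to the usual constant), where `V = sum_k sigma2_k K_k + sigma2_e I`
#' and `P` is the REML projection matrix.
#'
#' @param y phenotype vector (no missing values here; see
#'   [fit_mixed_model()] for masked records).
#' @param X fixed-effect design matrix, full column rank.
#' @param kernels list of relationship matrices over the same animals.
#' @param sigma2 numeric vector of variance components, one per kernel plus
#'   the residual last.
#' @return the restricted log-likelihood (scalar).
#' @export
restricted_log_likelihood <- function(y, X, kernels, sigma2) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y disagree in length")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  K <- length(kernels)
  if (length(sigma2) != K + 1L)
    stop("'sigma2' needs one entry per kernel plus the residual")
  V <- diag(sigma2[K + 1L], n)
  for (k in seq_len(K)) V <- V + sigma2[k] * unclass(kernels[[k]])
  ch <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite at sigma2 = (",
         paste(signif(sigma2, 4), collapse = ", "), ")"))
  ldV <- 2 * sum(log(diag(ch)))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vinv_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vinv_X)
  chX <- chol(XtViX)
  ldX <- 2 * sum(log(diag(chX)))
  beta <- backsolve(chX, forwardsolve(t(chX), crossprod(X, Vinv_y)))
  yPy <- sum(y * Vinv_y) - sum(crossprod(X, Vinv_y) * beta)
  -0.5 * (ldV + ldX + yPy)
}

#' Fit a multi-kernel animal model by AI-REML
#'
#' Estimates variance components for up to three correlated random effects
#' (genomic, metagenomic, interaction) plus a residual by average-information
#' REML with EM fallback steps whenever an AI update would leave the
#' parameter space, solves the mixed-model equations for BLUP of every
#' random effect, and reports variance ratios with delta-method standard
#' errors and AIC.
#'
#' Animals with `NA` phenotypes are excluded from estimation but still
#' receive BLUP solutions through their kernel relationships with phenotyped
#' animals, which is how cross-validation predictions are obtained.
#' Components that converge to the zero boundary are pinned there and
#' flagged; they remain in the AIC parameter count.
#'
#' @param y phenotype vector over all kernel animals, `NA` for masked
#'   records.
#' @param X fixed-effect design matrix over all kernel animals.
#' @param kernels named list of 1-3 tuned `rel_matrix` objects; recognised
#'   names `genomic`, `metagenomic`, `interaction` drive ratio reporting.
#' @param max_iter,tol_logl,tol_par convergence controls.
#' @param verbose print the iteration trace.
#' @return an object of class `mm_fit`: `sigma2` (named, residual last),
#'   `se_sigma2`, `vcov_sigma2`, `beta`, `blup` (animals x kernels), `logl`,
#'   `aic`, `ratios` (see [variance_ratios()]), `converged`, `boundary`,
#'   `iterations`, `n_obs`.
#' @export
fit_mixed_model <- function(y, X, kernels, max_iter = 200, tol_logl = 1e-8,
                            tol_par = 1e-6, verbose = FALSE) {
  X <- as.matrix(X)
  if (!is.list(kernels)) kernels <- list(genomic = kernels)
  K <- length(kernels)
  if (K < 1L || K > 3L) stop("1 to 3 kernels are supported")
  if (is.null(names(kernels)) || any(!nzchar(names(kernels))))
    names(kernels) <- c("genomic", "metagenomic", "interaction")[seq_len(K)]
  N <- nrow(as.matrix(kernels[[1]]))
  if (length(y) != N || nrow(X) != N)
    stop("y, X and the kernels must cover the same animals")
  obs <- which(!is.na(y))
  n <- length(obs)
  if (n < ncol(X) + 2L) stop("too few phenotyped records")
  yo <- as.numeric(y[obs])
  Xo <- X[obs, , drop = FALSE]
  Xo <- Xo[, qr(Xo)$pivot[seq_len(qr(Xo)$rank)], drop = FALSE]
  if (qr(Xo)$rank < ncol(Xo)) stop("fixed-effect design is rank deficient")
  Ko <- lapply(kernels, function(k) unclass(k)[obs, obs, drop = FALSE])

  # ridge-degenerate guard: a single kernel that is (numerically) a scaled
  # identity cannot be separated from the residual
  degenerate <- FALSE
  if (K == 1L) {
    A <- Ko[[1]]
    off <- A; diag(off) <- 0
    if (max(abs(off)) < 1e-10 * max(mean(diag(A)), 1)) {
      degenerate <- TRUE
      warning("kernel is numerically proportional to the identity; ",
              "only the total variance is identifiable")
    }
  }

  vary <- stats::var(yo)
  lb <- 1e-8 * vary

  eval_parts <- function(s2) {
    V <- diag(s2[K + 1L], n)
    for (k in seq_len(K)) V <- V + s2[k] * Ko[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    ViX <- Vinv %*% Xo
    XtViX <- crossprod(Xo, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    Pm <- Vinv - ViX %*% chol2inv(chX) %*% t(ViX)
    Py <- drop(Pm %*% yo)
    logl <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) +
                      sum(yo * Py))
    list(Vinv = Vinv, P = Pm, Py = Py, logl = logl, chX = chX, ViX = ViX)
  }

  Klist <- c(Ko, list(diag(1, n)))

  grad_ai <- function(parts) {
    Py <- parts$Py
    Tk <- lapply(Klist, function(Kk) drop(Kk %*% Py))
    score <- vapply(seq_len(K + 1L), function(k)
      -0.5 * (sum(parts$P * Klist[[k]]) - sum(Py * Tk[[k]])), 0)
    PT <- lapply(Tk, function(t) drop(parts$P %*% t))
    AI <- matrix(0, K + 1L, K + 1L)
    for (a in seq_len(K + 1L))
      for (b in seq_len(a))
        AI[a, b] <- AI[b, a] <- 0.5 * sum(Tk[[a]] * PT[[b]])
    list(score = score, AI = AI)
  }

  # one AI-REML run from a given starting point
  run_reml <- function(sigma2) {
  names(sigma2) <- c(names(kernels), "residual")
  parts <- eval_parts(sigma2)
  if (is.null(parts)) return(NULL)
  logl <- parts$logl
  converged <- FALSE
  iter <- 0L
  active <- rep(TRUE, K + 1L)  # components may be pinned at the boundary

  while (iter < max_iter) {
    iter <- iter + 1L
    ga <- grad_ai(parts)
    score <- ga$score
    AI <- ga$AI

    # KKT handling at the boundary: pin components whose gradient points
    # outward (kernel components at 0, the residual at its tiny positive
    # floor - the tuned kernels keep V positive definite there), release
    # those whose gradient points inward with a non-trivial expected gain
    for (k in seq_len(K + 1L)) {
      gain <- if (AI[k, k] > 0) 0.5 * score[k]^2 / AI[k, k] else abs(score[k])
      if (sigma2[k] <= 1.0001 * lb && score[k] <= 0) active[k] <- FALSE
      if (!active[k] && score[k] > 0 && gain > 1e-9) active[k] <- TRUE
    }
    if (!any(active)) break  # everything at a boundary optimum
    act <- which(active)

    base_prop <- sigma2
    base_prop[seq_len(K)][!active[seq_len(K)]] <- 0
    if (!active[K + 1L]) base_prop[K + 1L] <- lb
    delta_ai <- tryCatch(
      solve(AI[act, act, drop = FALSE] + diag(1e-12, length(act)),
            score[act]),
      error = function(e) NULL)
    # EM direction on the active set: always an ascent direction and it
    # respects the parameter space, used when the (clamped) AI step fails
    Py <- parts$Py
    delta_em <- sigma2[act]^2 *
      vapply(act, function(k)
        sum(Py * drop(Klist[[k]] %*% Py)) - sum(parts$P * Klist[[k]]),
        0) / n
    proposals <- list()
    if (!is.null(delta_ai)) {
      p1 <- base_prop
      p1[act] <- pmax(sigma2[act] + delta_ai, 0)
      p1[K + 1L] <- max(p1[K + 1L], lb)
      proposals <- c(proposals, list(p1))
    }
    p2 <- base_prop
    p2[act] <- pmax(sigma2[act] + delta_em, 0)
    p2[K + 1L] <- max(p2[K + 1L], lb)
    proposals <- c(proposals, list(p2))

    # step halving until the likelihood is computable and not decreasing;
    # the AI step is tried first, then the EM step
    step_ok <- FALSE
    np <- NULL
    for (prop in proposals) {
      for (h in 0:12) {
        cand <- sigma2 + (prop - sigma2) / 2^h
        cand[cand < lb & prop <= 0] <- 0  # let components land exactly on 0
        cand[K + 1L] <- max(cand[K + 1L], lb)
        np <- eval_parts(cand)
        if (!is.null(np) && np$logl > logl + 1e-12) {
          step_ok <- TRUE
          break
        }
      }
      if (step_ok) break
    }
    if (!step_ok) {
      converged <- TRUE  # no direction improves: at the (possibly boundary) optimum
      break
    }
    delta_l <- np$logl - logl
    delta_p <- max(abs(cand - sigma2)) / max(vary, 1e-12)
    sigma2 <- cand
    names(sigma2) <- c(names(kernels), "residual")
    parts <- np
    logl <- np$logl
    if (delta_l < tol_logl * (1 + abs(logl)) && delta_p < tol_par) {
      # accept only if no pinned component wants back in AND the expected
      # Newton gain on the active set is negligible (guards against the
      # slow-crawl false convergence of EM steps near a boundary)
      ga2 <- grad_ai(parts)
      gains <- vapply(seq_len(K + 1L), function(k)
        if (ga2$AI[k, k] > 0) 0.5 * ga2$score[k]^2 / ga2$AI[k, k]
        else abs(ga2$score[k]), 0)
      pinned_in <- any(!active & ga2$score > 0 & gains > 1e-9)
      act2 <- which(active)
      newton_gain <- tryCatch({
        d2 <- solve(ga2$AI[act2, act2, drop = FALSE] +
                      diag(1e-12, length(act2)), ga2$score[act2])
        # ignore blocked descent directions out of the parameter space
        blocked <- sigma2[act2] <= lb & d2 < 0
        0.5 * sum((ga2$score[act2] * d2)[!blocked])
      }, error = function(e) 0)
      if (!pinned_in && abs(newton_gain) < 1e-7) {
        converged <- TRUE
        break
      }
    }
  }
  list(sigma2 = sigma2, parts = parts, logl = logl, converged = converged,
       iterations = iter)
  }

  # the restricted likelihood can be multimodal (especially with several
  # competing kernels on few records), so the iteration is started from an
  # equal split plus starts skewed towards each component, keeping the best
  starts <- list(rep(vary / (K + 1), K + 1L))
  for (k in seq_len(K + 1L)) {
    s <- rep(0.3 * vary / K, K + 1L)
    s[k] <- 0.7 * vary
    starts <- c(starts, list(s))
  }
  best <- NULL
  for (s0 in starts) {
    r <- run_reml(s0)
    if (is.null(r)) next
    if (is.null(best) || r$logl > best$logl + 1e-10) best <- r
  }
  if (is.null(best)) stop("V not positive definite at any starting point")
  sigma2 <- best$sigma2
  parts <- best$parts
  logl <- best$logl
  converged <- best$converged

  boundary <- sigma2[seq_len(K)] <= max(lb, 1e-6 * vary)

  # SEs from the inverse AI matrix at the optimum
  Py <- parts$Py
  Tk <- lapply(Klist, function(Kk) drop(Kk %*% Py))
  PT <- lapply(Tk, function(t) drop(parts$P %*% t))
  AI <- matrix(0, K + 1L, K + 1L)
  for (a in seq_len(K + 1L))
    for (b in seq_len(a)) AI[a, b] <- AI[b, a] <- 0.5 * sum(Tk[[a]] * PT[[b]])
  vcov_s <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, K + 1L, K + 1L))
  se <- sqrt(pmax(diag(vcov_s), 0))
  names(se) <- names(sigma2)

  # GLS fixed effects and BLUP for ALL kernel animals from phenotyped records
  ViX <- parts$ViX
  XtViX <- crossprod(Xo, ViX)
  beta <- drop(solve(XtViX, crossprod(ViX, yo)))
  names(beta) <- colnames(Xo)
  resid_adj <- drop(parts$Vinv %*% (yo - Xo %*% beta))  # equals Py
  blup <- matrix(0, N, K, dimnames = list(rownames(as.matrix(kernels[[1]])),
                                          names(kernels)))
  for (k in seq_len(K))
    blup[, k] <- sigma2[k] * drop(unclass(kernels[[k]])[, obs] %*% resid_adj)

  aic <- -2 * logl + 2 * (K + 1L)
  fit <- structure(list(sigma2 = sigma2, se_sigma2 = se, vcov_sigma2 = vcov_s,
                        beta = beta, blup = blup, logl = logl, aic = aic,
                        converged = converged, boundary = boundary,
                        degenerate = degenerate, iterations = best$iterations,
                        n_obs = n, kernel_names = names(kernels),
                        X_names = colnames(Xo)),
                   class = "mm_fit")
  fit$ratios <- variance_ratios(fit)
  fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit: %d kernels, n = %d, logL = %.3f, AIC = %.1f, %s>\n",
              length(x$kernel_names), x$n_obs, x$logl, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  print(round(rbind(estimate = x$sigma2, se = x$se_sigma2), 4))
  if (!is.null(x$ratios) && nrow(x$ratios))
    print(x$ratios, digits = 3)
  invisible(x)
}

#' Variance ratios of a fitted model
#'
#' Computes the reported variance-fraction parameters, each as a ratio over
#' the sum of ALL variance components in the model (including the residual):
#' heritability `h2 = s2_u / total`, microbiability `m2 = s2_m / total`,
#' `i_a2 = (s2_u + s2_m) / total`, and `i_i2 = (s2_u + s2_m + s2_o) / total`.
#' Ratios are only defined for the effects present in the model. Standard
#' errors use the first-order delta method on the variance-component
#' covariance matrix.
#'
#' @param fit an `mm_fit`, or a named numeric vector of variance components
#'   (residual named `"residual"`).
#' @param vcov optional covariance matrix of the components when `fit` is a
#'   plain vector.
#' @return data frame with columns `ratio`, `estimate`, `se`.
#' @export
variance_ratios <- function(fit, vcov = NULL) {
  if (inherits(fit, "mm_fit")) {
    sigma2 <- fit$sigma2
    vcov <- fit$vcov_sigma2
  } else sigma2 <- fit
  if (all(sigma2 == 0)) stop("all variance components are zero; ratios undefined")
  total <- sum(sigma2)
  roles <- names(sigma2)
  numerators <- list()
  if ("genomic" %in% roles) numerators$h2 <- "genomic"
  if ("metagenomic" %in% roles) numerators$m2 <- "metagenomic"
  if (all(c("genomic", "metagenomic") %in% roles))
    numerators$i_a2 <- c("genomic", "metagenomic")
  if (all(c("genomic", "metagenomic", "interaction") %in% roles))
    numerators$i_i2 <- c("genomic", "metagenomic", "interaction")
  if (!length(numerators)) {
    numerators <- as.list(setdiff(roles, "residual"))
    names(numerators) <- paste0("frac_", unlist(numerators))
  }
  est <- se <- numeric(length(numerators))
  for (i in seq_along(numerators)) {
    idx <- match(numerators[[i]], roles)
    est[i] <- sum(sigma2[idx]) / total
    if (!is.null(vcov) && all(is.finite(vcov))) {
      # gradient of (sum_idx s) / (sum_all s)
      g <- rep(-sum(sigma2[idx]) / total^2, length(sigma2))
      g[idx] <- g[idx] + 1 / total
      se[i] <- sqrt(max(drop(t(g) %*% vcov %*% g), 0))
    } else se[i] <- NA_real_
  }
  data.frame(ratio = names(numerators), estimate = est, se = se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-ORF heritability estimates
#'
#' Fits a univariate animal model to each column of the log relative
#' abundance matrix (that column as the phenotype, the tuned GRM as the
#' single kernel) and returns the REML heritability estimates, boundary
#' constrained to [0, 1). The weighted MRM adjustment uses `1 - h2_ORF` as
#' per-ORF weights. A single eigendecomposition of the GRM is reused across
#' ORFs, with the total variance profiled out, so the sweep costs one 1-D
#' optimisation per ORF.
#'
#' @param S log relative abundance matrix (animals x ORFs).
#' @param G_T tuned genomic `rel_matrix`.
#' @param X fixed-effect design matrix.
#' @return numeric vector of per-ORF heritabilities; constant columns (or
#'   failed fits) yield 0 with a warning/message.
#' @export
estimate_orf_heritabilities <- function(S, G_T, X) {
  S <- unclass(as.matrix(S))
  X <- as.matrix(X)
  n <- nrow(S)
  stopifnot(nrow(as.matrix(G_T)) == n, nrow(X) == n)
  eg <- eigen(unclass(G_T), symmetric = TRUE)
  U <- eg$vectors
  lam <- eg$values
  Xt <- crossprod(U, X)
  Xt <- Xt[, qr(Xt)$pivot[seq_len(qr(Xt)$rank)], drop = FALSE]
  p <- ncol(Xt)

  neg_profile <- function(h2, yt) {
    d <- h2 * lam + (1 - h2)
    w <- 1 / d
    Xw <- Xt * w
    XtWX <- crossprod(Xt, Xw)
    chX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(chX)) return(1e10)
    XtWy <- crossprod(Xw, yt)
    b <- backsolve(chX, forwardsolve(t(chX), XtWy))
    yPy <- sum(yt^2 * w) - sum(XtWy * b)
    if (yPy <= 0) return(1e10)
    0.5 * ((n - p) * log(yPy) + sum(log(d)) + 2 * sum(log(diag(chX))))
  }

  h2 <- numeric(ncol(S))
  n_failed <- 0L
  for (j in seq_len(ncol(S))) {
    yj <- S[, j]
    if (stats::var(yj) <= 0) {
      h2[j] <- 0
      n_failed <- n_failed + 1L
      next
    }
    yt <- drop(crossprod(U, yj))
    opt <- tryCatch(
      stats::optimize(neg_profile, c(0, 0.999), yt = yt, tol = 1e-6),
      error = function(e) NULL)
    if (is.null(opt)) {
      h2[j] <- 0
      n_failed <- n_failed + 1L
      next
    }
    # prefer the boundary when it is at least as good (optimize avoids ends)
    cand <- c(opt$minimum, 0)
    vals <- c(opt$objective, neg_profile(0, yt))
    h2[j] <- cand[which.min(vals)]
  }
  if (n_failed > 0)
    warning(sprintf("%d ORF column(s) constant or unfittable; h2 set to 0",
                    n_failed))
  names(h2) <- colnames(S)
  h2
}

#' Enumerate the model grid of the study
#'
#' Per trait: one genomic-only model, plus one model per MRM
#' method-adjustment combination at each of the metagenomic-only, joint, and
#' interaction complexities (interaction models always carry both the
#' genomic and metagenomic effects). With both methods and all three
#' adjustments this yields 19 specifications per trait.
#'
#' @param traits character vector of trait names.
#' @param complexities subset of
#'   `c("genomic-only", "metagenomic-only", "joint", "interaction")`.
#' @param methods MRM construction methods to include.
#' @param adjustments MRM adjustments to include.
#' @return data frame of model specifications with columns `trait`,
#'   `complexity`, `mrm_method`, `adjustment`, `model_id`.
#' @export
model_grid <- function(traits,
                       complexities = c("genomic-only", "metagenomic-only",
                                        "joint", "interaction"),
                       methods = c(1L, 2L),
                       adjustments = c("naive", "weighted", "data-driven")) {
  complexities <- match.arg(complexities, several.ok = TRUE)
  rows <- list()
  for (tr in traits) {
    if ("genomic-only" %in% complexities)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, complexity = "genomic-only",
        mrm_method = NA_integer_, adjustment = NA_character_)
    for (cx in setdiff(complexities, "genomic-only"))
      for (mth in methods)
        for (adj in adjustments)
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, complexity = cx,
            mrm_method = as.integer(mth), adjustment = adj)
  }
  out <- do.call(rbind, rows)
  out$model_id <- ifelse(
    is.na(out$mrm_method),
    paste(out$trait, out$complexity, sep = "."),
    paste(out$trait, out$complexity,
          paste0("m", out$mrm_method), gsub("-", "_", out$adjustment),
          sep = "."))
  rownames(out) <- NULL
  out
}

# Select the kernel list for one model spec from a build_kernel_set() result
kernels_for_spec <- function(spec, kset) {
  if (spec$complexity == "genomic-only")
    return(list(genomic = kset$G))
  key <- paste0("m", spec$mrm_method, "_", gsub("-", "_", spec$adjustment))
  M <- kset$M[[key]]
  if (is.null(M)) stop("no MRM named ", key, " in the kernel set")
  switch(spec$complexity,
         "metagenomic-only" = list(metagenomic = M),
         "joint" = list(genomic = kset$G, metagenomic = M),
         "interaction" = list(genomic = kset$G, metagenomic = M,
                              interaction = kset$J[[key]]),
         stop("unknown complexity ", spec$complexity))
}
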