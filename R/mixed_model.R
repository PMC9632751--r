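# Public animal-model interface: Henderson's mixed-model equations, REML
# variance-component estimation, and BLUP breeding values.

# build the pond fixed-effect design (reference-level coding); drops empty
# levels with a warning and checks full rank
pond_design <- function(pond) {
  pond <- as.character(pond)
  tab <- table(pond)
  if (any(tab == 0)) warning("dropping pond level(s) with no records", call. = FALSE)
  f <- factor(pond)
  if (nlevels(f) < 2L) {
    X <- matrix(1, length(pond), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  X <- model.matrix(~ f)
  colnames(X) <- c("(Intercept)", paste0("pond", levels(f)[-1]))
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient", call. = FALSE)
  X
}

#' Henderson's mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side of the animal-model MME
#' for given variance components:
#' `[X'X, X'Z; Z'X, Z'Z + lambda * Ainv] [b; a] = [X'y; Z'y]`
#' with `lambda = sigmaE2 / sigmaA2`. With `random = FALSE` the system reduces
#' to the ordinary (GLS/OLS) normal equations for the fixed effects. If A is
#' numerically singular a 1e-8 ridge is added to its diagonal (with a message).
#'
#' @param data Data.frame with `animal_id`, `pond` and the trait column.
#' @param trait Trait column name.
#' @param A Relationship matrix; must contain all phenotyped animals.
#' @param sigmaA2,sigmaE2 Variance components fixing the ratio `lambda`.
#' @param random Include the animal random effect (default TRUE).
#' @return List with `C` (coefficient matrix), `rhs`, `solution` (named), and
#'   the index bookkeeping (`fixed`, `animals`).
#' @export
build_mme <- function(data, trait, A, sigmaA2 = 1, sigmaE2 = 1, random = TRUE) {
  stopifnot(trait %in% names(data))
  keep <- !is.na(data[[trait]]) & !is.na(data$pond)
  data <- data[keep, ]
  y <- data[[trait]]
  X <- pond_design(data$pond)
  if (!random) {
    C <- crossprod(X); rhs <- crossprod(X, y)
    sol <- drop(solve(C, rhs))
    names(sol) <- colnames(X)
    return(list(C = C, rhs = drop(rhs), solution = sol,
                fixed = colnames(X), animals = character(0)))
  }
  ids <- as.character(data$animal_id)
  if (!all(ids %in% rownames(A))) {
    stop("animal(s) missing from relationship matrix: ",
         paste(utils::head(setdiff(ids, rownames(A)), 5), collapse = ", "), call. = FALSE)
  }
  all_ids <- rownames(A)
  Z <- matrix(0, nrow(data), length(all_ids), dimnames = list(NULL, all_ids))
  Z[cbind(seq_len(nrow(data)), match(ids, all_ids))] <- 1
  Ainv <- tryCatch(solve(A), error = function(e) {
    message("A is numerically singular; adding 1e-8 ridge to its diagonal")
    solve(A + diag(1e-8, nrow(A)))
  })
  lambda <- sigmaE2 / sigmaA2
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ainv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- drop(solve(C, rhs))
  names(sol) <- c(colnames(X), all_ids)
  list(C = C, rhs = rhs, solution = sol, fixed = colnames(X), animals = all_ids)
}

#' Univariate animal-model REML fit
#'
#' Estimates the additive-genetic and residual variance of one trait under the
#' animal model `y = Xb + Za + e` with pond as the fixed effect and
#' `cov(a) = sigmaA2 * A`. The likelihood is maximised by average-information
#' (AI) updates with step-halving and an exact EM fallback (`algorithm =
#' "em"` forces pure EM, whose REML log-likelihood is non-decreasing by
#' construction). Standard errors come from the inverse AI matrix at
#' convergence; the heritability SE uses the delta method.
#'
#' @param data Data.frame with columns `animal_id`, `pond` and the trait.
#' @param trait Trait column name.
#' @param A Relationship matrix covering all phenotyped animals.
#' @param algorithm `"ai"` (default) or `"em"`.
#' @param tol Relative parameter-change convergence tolerance (1e-8); the
#'   log-likelihood change must also fall below 1e-6.
#' @param max_iter Iteration cap (200 for AI, 5000 for EM); hitting it returns
#'   `converged = FALSE` rather than an error.
#' @param sp Optional precomputed [spectral_prep()] of `A` over the phenotyped
#'   animals, reused across traits/replicates sharing one design.
#' @param fixed_formula Optional one-sided formula evaluated in `data` to
#'   replace the default `~ pond` design.
#' @param keep_trace Keep the per-iteration log-likelihood trace.
#' @return Object of class `uni_fit`: variance components with SEs, `h2` with
#'   delta-method SE, log-likelihood, convergence state, and the projections
#'   needed by [blup_ebv()].
#' @export
reml_fit <- function(data, trait, A, algorithm = c("ai", "em"), tol = 1e-8,
                     max_iter = NULL, sp = NULL, fixed_formula = NULL,
                     keep_trace = FALSE) {
  algorithm <- match.arg(algorithm)
  stopifnot(trait %in% names(data))
  keep <- !is.na(data[[trait]]) & !is.na(data$pond)
  data <- data[keep, ]
  ids <- as.character(data$animal_id)
  if (!all(ids %in% rownames(A))) {
    stop("animal(s) missing from relationship matrix", call. = FALSE)
  }
  y <- data[[trait]]
  X <- if (is.null(fixed_formula)) pond_design(data$pond)
       else model.matrix(fixed_formula, data)
  if (length(y) <= ncol(X) + 1) {
    stop("need more records than fixed-effect levels + 1", call. = FALSE)
  }
  if (is.null(sp)) sp <- spectral_prep(A, ids)
  if (!identical(sp$ids, ids)) {
    o <- match(sp$ids, ids)
    if (anyNA(o)) stop("`sp` does not match the phenotyped animals", call. = FALSE)
    y <- y[o]; X <- X[o, , drop = FALSE]; ids <- ids[o]
  }
  res <- reml_spectral_uni(y, X, sp, algorithm = algorithm, tol = tol,
                           max_iter = max_iter, keep_trace = keep_trace)
  h <- if (res$theta[1] + res$theta[2] > 0) {
    heritability(res$theta[1], res$theta[2],
                 cov = if (all(is.finite(res$cov_theta))) res$cov_theta else NULL)
  } else list(h2 = NA_real_, se = NA_real_)
  structure(list(
    trait = trait, sigmaA2 = unname(res$theta[1]), sigmaE2 = unname(res$theta[2]),
    se = sqrt(pmax(diag(res$cov_theta), 0)),
    cov_theta = res$cov_theta, h2 = h$h2, h2_se = h$se,
    loglik = res$loglik, converged = res$converged, n_iter = res$n_iter,
    boundary = isTRUE(res$boundary), algorithm = algorithm,
    beta = res$beta, ids = ids, Py_orig = res$Py_orig, sp = sp, proj = res$proj,
    used_em_fallback = isTRUE(res$used_em_fallback),
    loglik_trace = res$loglik_trace
  ), class = "uni_fit")
}

#' @export
print.uni_fit <- function(x, ...) {
  cat("Animal-model REML fit (", x$algorithm, "), trait ", x$trait, "\n", sep = "")
  cat(sprintf("  sigmaA2 = %.6g (SE %.3g)\n", x$sigmaA2, x$se[1]))
  cat(sprintf("  sigmaE2 = %.6g (SE %.3g)\n", x$sigmaE2, x$se[2]))
  cat(sprintf("  h2 = %.4f (SE %.3g)\n", x$h2, x$h2_se))
  cat(sprintf("  logLik = %.4f, %s in %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Bivariate animal-model REML fit
#'
#' Two modes:
#' \describe{
#'   \item{trait pair}{`traits` names two columns measured on the same
#'     animals; the 2x2 genetic (G) and residual (R) covariance matrices are
#'     estimated, giving genetic, phenotypic and environmental correlations.}
#'   \item{cross-environment}{`traits` names one column and `cross_env` two
#'     pond labels; the same trait in the two ponds is treated as two traits.
#'     No animal is measured in both ponds, so the residual covariance is a
#'     structural zero, and the genetic correlation `G[1,2] /
#'     sqrt(G[1,1] * G[2,2])` measures genotype-by-environment interaction.}
#' }
#' If an iterate leaves the parameter space, G (and R) are projected onto the
#' nearest positive semi-definite matrix (eigenvalue floor), and the fit is
#' flagged `clipped`.
#'
#' @param data Data.frame with `animal_id`, `pond` and trait column(s).
#' @param traits One or two trait column names (see above).
#' @param A Relationship matrix.
#' @param cross_env Optional character vector of two pond labels.
#' @param sp Optional shared [spectral_prep()] (trait-pair mode only).
#' @param tol,max_iter Convergence controls as in [reml_fit()].
#' @param start Optional starting vector of (co)variance parameters.
#' @return Object of class `biv_fit` with `G`, `R`, `cov_theta`, `cov_G`
#'   (sampling covariance of `(sigmaA12, sigmaA1^2, sigmaA2^2)`), convergence
#'   state, and `correlations` (rg/rp/re with delta-method SEs; rp/re only in
#'   trait-pair mode).
#' @export
reml_bivariate <- function(data, traits, A, cross_env = NULL, sp = NULL,
                           tol = 1e-8, max_iter = 200L, start = NULL) {
  if (!is.null(cross_env)) {
    stopifnot(length(traits) == 1L, length(cross_env) == 2L)
    tr <- traits
    d1 <- data[data$pond == cross_env[1] & !is.na(data[[tr]]), ]
    d2 <- data[data$pond == cross_env[2] & !is.na(data[[tr]]), ]
    if (nrow(d1) < 3 || nrow(d2) < 3) stop("too few records in a pond", call. = FALSE)
    ids1 <- as.character(d1$animal_id); ids2 <- as.character(d2$animal_id)
    if (length(intersect(ids1, ids2))) {
      stop("cross-environment fit requires disjoint animal sets", call. = FALSE)
    }
    res <- reml_dense_crossenv(d1[[tr]], d2[[tr]],
                               M11 = A[ids1, ids1], M22 = A[ids2, ids2],
                               M12 = A[ids1, ids2, drop = FALSE],
                               tol = tol, max_iter = max_iter, start = start)
    covt <- res$cov_theta
    cov_G <- covt[c(2, 1, 3), c(2, 1, 3)]
    rg <- genetic_correlation(res$G[1, 2], res$G[1, 1], res$G[2, 2],
                              cov = if (all(is.finite(cov_G))) cov_G else NULL)
    out <- c(res, list(mode = "cross_env", traits = tr, ponds = cross_env,
                       cov_G = cov_G, correlations = list(rg = rg)))
    class(out) <- "biv_fit"
    return(out)
  }
  stopifnot(length(traits) == 2L)
  keep <- !is.na(data[[traits[1]]]) & !is.na(data[[traits[2]]]) & !is.na(data$pond)
  data <- data[keep, ]
  ids <- as.character(data$animal_id)
  if (!all(ids %in% rownames(A))) stop("animal(s) missing from A", call. = FALSE)
  Y <- as.matrix(data[, traits])
  X <- pond_design(data$pond)
  if (is.null(sp)) sp <- spectral_prep(A, ids)
  if (!identical(sp$ids, ids)) {
    o <- match(sp$ids, ids)
    if (anyNA(o)) stop("`sp` does not match the phenotyped animals", call. = FALSE)
    Y <- Y[o, , drop = FALSE]; X <- X[o, , drop = FALSE]
  }
  res <- reml_spectral_biv(Y, X, sp, tol = tol, max_iter = max_iter, start = start)
  covt <- res$cov_theta
  cov_G <- covt[c(2, 1, 3), c(2, 1, 3)]
  rg <- genetic_correlation(res$G[1, 2], res$G[1, 1], res$G[2, 2],
                            cov = if (all(is.finite(cov_G))) cov_G else NULL)
  # phenotypic: (co)variances are sums of genetic + residual parameters
  Tp <- rbind(c(0, 1, 0, 0, 1, 0), c(1, 0, 0, 1, 0, 0), c(0, 0, 1, 0, 0, 1))
  cov_P <- if (all(is.finite(covt))) Tp %*% covt %*% t(Tp) else NULL
  rp <- genetic_correlation(res$G[1, 2] + res$R[1, 2],
                            res$G[1, 1] + res$R[1, 1],
                            res$G[2, 2] + res$R[2, 2], cov = cov_P)
  cov_E <- if (all(is.finite(covt))) covt[c(5, 4, 6), c(5, 4, 6)] else NULL
  re <- genetic_correlation(res$R[1, 2], res$R[1, 1], res$R[2, 2], cov = cov_E)
  out <- c(res, list(mode = "trait_pair", traits = traits, cov_G = cov_G,
                     correlations = list(rg = rg, rp = rp, re = re)))
  class(out) <- "biv_fit"
  out
}

#' @export
print.biv_fit <- function(x, ...) {
  cat("Bivariate animal-model REML fit (", x$mode, ")\n", sep = "")
  cat("  G:\n"); print(signif(x$G, 5))
  cat("  R:\n"); print(signif(x$R, 5))
  co <- x$correlations
  cat(sprintf("  rg = %.3f (SE %.3g)\n", co$rg$r, co$rg$se))
  if (!is.null(co$rp)) cat(sprintf("  rp = %.3f, re = %.3f\n", co$rp$r, co$re$r))
  cat(sprintf("  logLik = %.4f, %s in %d iterations%s\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (isTRUE(x$clipped)) " (parameter space boundary hit)" else ""))
  invisible(x)
}

#' BLUP estimated breeding values
#'
#' Computes EBVs for any set of animals in the relationship matrix from a
#' converged univariate fit: `a_hat = sigmaA2 * A[ids, obs] %*% P y`, the BLUP
#' at the REML estimates. Prediction-error variances
#' `PEV_i = sigmaA2 * A_ii - sigmaA2^2 * a_i' P a_i` and reliabilities
#' `1 - PEV / (sigmaA2 * A_ii)` are returned for the requested animals.
#' Animals without phenotypes (e.g. parents) receive pedigree-propagated EBVs;
#' a non-phenotyped offspring of two parents gets the parental average.
#'
#' @param fit A converged `uni_fit` from [reml_fit()].
#' @param A The same relationship matrix used in the fit.
#' @param ids Animals to report (default: all rows of `A`).
#' @param pev Compute prediction-error variance/reliability (default TRUE).
#' @return Data.frame `animal_id, ebv, pev, reliability`.
#' @export
blup_ebv <- function(fit, A, ids = rownames(A), pev = TRUE) {
  stopifnot(inherits(fit, "uni_fit"))
  if (!fit$converged) warning("fit did not converge; EBVs are provisional", call. = FALSE)
  if (!all(ids %in% rownames(A))) {
    stop("animal(s) absent from relationship matrix: ",
         paste(utils::head(setdiff(ids, rownames(A)), 5), collapse = ", "), call. = FALSE)
  }
  sA <- fit$sigmaA2
  Cm <- A[fit$ids, ids, drop = FALSE]            # obs x requested
  ebv <- drop(sA * crossprod(Cm, fit$Py_orig))
  out <- data.frame(animal_id = ids, ebv = ebv, stringsAsFactors = FALSE)
  if (pev) {
    # quadratic form a_i' P a_i in the rotated space:
    # P = W - W X (X'WX)^-1 X'W, using the projections stored at fit time
    Ct <- crossprod(fit$sp$U, Cm)                # rotated columns, n_obs x k
    corr <- crossprod(fit$proj$WX, Ct)           # p x k
    quad <- colSums(Ct * (fit$proj$W * Ct)) -
      colSums(corr * (fit$proj$XtWXinv %*% corr))
    pev_v <- sA * diag(A)[match(ids, rownames(A))] - sA^2 * quad
    pev_v <- pmax(pev_v, 0)
    out$pev <- pev_v
    denom <- sA * diag(A)[match(ids, rownames(A))]
    out$reliability <- ifelse(denom > 0, 1 - pev_v / denom, NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Per-pond parent EBVs
#'
#' Refits the univariate animal model within each pond (pond fixed effect
#' collapsing to an intercept) and extracts the EBVs of a set of parents,
#' mirroring per-environment genetic evaluation.
#'
#' @param data Phenotype data.frame (`animal_id`, `pond`, trait).
#' @param trait Trait name.
#' @param A Relationship matrix.
#' @param parents Parent ids to report.
#' @param ... Passed to [reml_fit()].
#' @return Data.frame `pond, animal_id, ebv, pev, reliability`.
#' @export
ebv_by_pond <- function(data, trait, A, parents, ...) {
  ponds <- sort(unique(as.character(data$pond)))
  out <- lapply(ponds, function(p) {
    sub <- data[data$pond == p, ]
    fit <- tryCatch(reml_fit(sub, trait, A, ...), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    e <- blup_ebv(fit, A, ids = parents)
    cbind(pond = p, e, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
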