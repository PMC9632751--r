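# Genetic parameters derived from variance components: heritability, genetic/
# phenotypic/environmental correlations, correlated selection response and the
# relative efficiency of indirect selection, plus descriptive statistics and
# the cross-pond GxE correlation table.

#' Heritability from variance components
#'
#' `h2 = sigmaA2 / (sigmaA2 + sigmaE2)`, with a delta-method standard error
#' when the sampling covariance of the two components is supplied.
#'
#' @param sigmaA2,sigmaE2 Additive-genetic and residual variances (>= 0, not
#'   both zero).
#' @param cov Optional 2 x 2 sampling covariance matrix of
#'   `(sigmaA2, sigmaE2)` (e.g. the inverse average-information matrix).
#' @return List with `h2` and `se` (NA when `cov` is missing).
#' @export
heritability <- function(sigmaA2, sigmaE2, cov = NULL) {
  if (sigmaA2 < 0 || sigmaE2 < 0) stop("variance components must be >= 0", call. = FALSE)
  tot <- sigmaA2 + sigmaE2
  if (tot == 0) stop("both variance components are zero; h2 undefined", call. = FALSE)
  h2 <- sigmaA2 / tot
  se <- NA_real_
  if (!is.null(cov)) {
    g <- c(sigmaE2, -sigmaA2) / tot^2
    se <- sqrt(max(0, drop(t(g) %*% cov %*% g)))
  }
  list(h2 = h2, se = se)
}

#' Genetic (or phenotypic/environmental) correlation
#'
#' `r = sigma12 / sqrt(sigma1^2 * sigma2^2)`: the covariance between the two
#' (co)variance components over the geometric mean of the variances. Used for
#' between-trait genetic correlations and, with the same trait in two ponds,
#' as the measure of genotype-by-environment interaction. A non-positive
#' variance makes the correlation non-estimable.
#'
#' @param sigma12 Covariance component.
#' @param sigma1_2,sigma2_2 The two variance components.
#' @param cov Optional 3 x 3 sampling covariance of
#'   `(sigma12, sigma1_2, sigma2_2)` for a delta-method SE.
#' @return List with `r`, `se`, `estimable` and `clipped` (TRUE when the raw
#'   estimate exceeded 1 in magnitude and was clipped to the boundary).
#' @export
genetic_correlation <- function(sigma12, sigma1_2, sigma2_2, cov = NULL) {
  if (!is.finite(sigma1_2) || !is.finite(sigma2_2) ||
      sigma1_2 <= 0 || sigma2_2 <= 0) {
    return(list(r = NA_real_, se = NA_real_, estimable = FALSE, clipped = FALSE))
  }
  r <- sigma12 / sqrt(sigma1_2 * sigma2_2)
  clipped <- abs(r) > 1
  se <- NA_real_
  if (!is.null(cov)) {
    g <- c(1 / sqrt(sigma1_2 * sigma2_2), -r / (2 * sigma1_2), -r / (2 * sigma2_2))
    se <- sqrt(max(0, drop(t(g) %*% cov %*% g)))
  }
  list(r = max(-1, min(1, r)), se = se, estimable = TRUE, clipped = clipped)
}

#' Correlated response to selection
#'
#' Expected response in trait y to a one-phenotypic-SD selection differential
#' applied to trait x: `CR_y = rg * h_x * h_y * SD_y`, with `h = sqrt(h2)`.
#' The default reports the standardised response (`sd_y = 1`, i.e. in
#' phenotypic-SD units of y); pass `sd_y` to convert to trait units.
#'
#' @param rg Genetic correlation between x and y (|rg| <= 1).
#' @param h2x,h2y Heritabilities of the selected and the correlated trait,
#'   each in [0, 1].
#' @param sd_y Phenotypic SD of y; 1 (standardised) by default.
#' @return Correlated response.
#' @export
correlated_response <- function(rg, h2x, h2y, sd_y = 1) {
  if (any(abs(rg) > 1)) stop("|rg| > 1", call. = FALSE)
  if (any(h2x < 0 | h2x > 1 | h2y < 0 | h2y > 1)) {
    stop("heritabilities must lie in [0, 1]", call. = FALSE)
  }
  rg * sqrt(h2x) * sqrt(h2y) * sd_y
}

#' Relative efficiency of indirect selection
#'
#' The correlated response in y under selection on x, as a percentage of the
#' response achievable by direct selection on y:
#' `%IS = 100 * rg * h_x / h_y` with `h = sqrt(h2)`. Equals `100 * rg` when
#' the two heritabilities are equal.
#'
#' @inheritParams correlated_response
#' @return Percentage (can exceed 100 when x is the more heritable trait).
#' @export
relative_efficiency <- function(rg, h2x, h2y) {
  if (any(abs(rg) > 1)) stop("|rg| > 1", call. = FALSE)
  if (any(h2y <= 0)) {
    stop("h2y must be > 0 for indirect-selection efficiency", call. = FALSE)
  }
  100 * rg * sqrt(h2x) / sqrt(h2y)
}

#' Descriptive statistics per trait
#'
#' Sample mean, SD (n-1 denominator) and coefficient of variation
#' `CV = 100 * SD / mean` for each numeric trait column.
#'
#' @param traits Data.frame of trait records (or a numeric matrix); non-numeric
#'   columns are ignored.
#' @return Data.frame with columns `trait, n, mean, sd, cv`.
#' @export
descriptives <- function(traits) {
  num <- traits[vapply(traits, is.numeric, logical(1))]
  if (ncol(num) == 0) stop("no numeric trait columns", call. = FALSE)
  out <- do.call(rbind, lapply(names(num), function(nm) {
    x <- num[[nm]][!is.na(num[[nm]])]
    if (length(x) < 2) stop("need n >= 2 for trait ", nm, call. = FALSE)
    m <- mean(x); s <- sd(x)
    data.frame(trait = nm, n = length(x), mean = m, sd = s,
               cv = if (m == 0) NA_real_ else 100 * s / m,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-pond genetic correlation (GxE) table
#'
#' For one trait, fits a bivariate cross-environment animal model to every
#' pond pair (the same trait in two ponds treated as two traits with a
#' structural zero residual covariance, since no animal is measured in both)
#' and reports the genetic correlation per pair. Pairs connected by fewer
#' than `min_link_sires` sires with offspring in both ponds are non-estimable
#' and reported as missing; estimates with SE above `se_flag` carry a caveat
#' flag (little family overlap makes such estimates uninformative).
#'
#' @param data Data.frame with `animal_id`, `pond` and the trait column.
#' @param trait Trait column name.
#' @param A Relationship matrix covering all phenotyped animals and, via its
#'   dimnames, their ancestors.
#' @param ped The `pedigree` (used to count linking sires).
#' @param min_link_sires Minimum shared sires for a pair to be estimable (2).
#' @param se_flag SE threshold for the interpretation caveat (0.3).
#' @param tol Convergence tolerance for the pair fits (1e-6; component changes
#'   far below any cross-pond SE).
#' @param ... Passed to [reml_bivariate()].
#' @return List with `table` (long-format data.frame: pond1, pond2, rg, se,
#'   estimable, high_se) and `matrix` (lower-triangular rg matrix, NA where
#'   non-estimable).
#' @export
gxe_matrix <- function(data, trait, A, ped, min_link_sires = 2, se_flag = 0.3,
                       tol = 1e-6, ...) {
  ponds <- sort(unique(as.character(data$pond)))
  if (length(ponds) < 2) stop("need at least two ponds for GxE", call. = FALSE)
  sire_of <- setNames(ped$sire, ped$animal)
  # per-pond univariate components as starting values for the pair fits
  pond_start <- lapply(setNames(ponds, ponds), function(p) {
    f <- tryCatch(reml_fit(data[data$pond == p, ], trait, A, tol = 1e-6),
                  error = function(e) NULL)
    if (is.null(f)) NULL else c(f$sigmaA2, f$sigmaE2)
  })
  rows <- list()
  M <- matrix(NA_real_, length(ponds), length(ponds), dimnames = list(ponds, ponds))
  for (i in seq_along(ponds)[-1]) for (j in seq_len(i - 1)) {
    p1 <- ponds[j]; p2 <- ponds[i]
    s1 <- unique(sire_of[data$animal_id[data$pond == p1]])
    s2 <- unique(sire_of[data$animal_id[data$pond == p2]])
    n_link <- length(intersect(s1[!is.na(s1)], s2[!is.na(s2)]))
    rg <- NA_real_; se <- NA_real_; ok <- FALSE
    if (n_link >= min_link_sires) {
      st <- if (!is.null(pond_start[[p1]]) && !is.null(pond_start[[p2]])) {
        c(pond_start[[p1]][1], 0, pond_start[[p2]][1],
          pond_start[[p1]][2], pond_start[[p2]][2])
      } else NULL
      fit <- tryCatch(
        reml_bivariate(data, traits = trait, A = A, cross_env = c(p1, p2),
                       tol = tol, start = st, ...),
        error = function(e) NULL)
      if (!is.null(fit)) {
        gc <- genetic_correlation(fit$G[1, 2], fit$G[1, 1], fit$G[2, 2],
                                  cov = fit$cov_G)
        if (gc$estimable) { rg <- gc$r; se <- gc$se; ok <- TRUE }
      }
    }
    if (ok) M[i, j] <- rg
    rows[[length(rows) + 1L]] <- data.frame(
      trait = trait, pond1 = p1, pond2 = p2, rg = rg, se = se,
      n_link_sires = n_link, estimable = ok,
      high_se = isTRUE(ok && is.finite(se) && se > se_flag),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), matrix = M)
}
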