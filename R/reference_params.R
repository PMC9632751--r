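# Published genetic-parameter estimates for image-derived morphometric traits
# of farmed Penaeus monodon (5,308 offspring of 64 sires and 54 dams across
# eight grow-out ponds). These serve two purposes: worked-example inputs for
# the selection-response calculators, and the default genetic architecture of
# the dataset simulator.

#' Published trait summary (means, components, heritabilities)
#'
#' Per-trait mean, SD, CV, additive-genetic and residual variance components
#' (with SEs) and heritability from a genetic evaluation of image-derived
#' morphometric traits in farmed black tiger shrimp. Units: BW g; BL, TT cm;
#' BS, HS, AS cm^2; AP %; FBR, CF, CFL dimensionless.
#'
#' @return Data.frame, one row per trait.
#' @export
reference_trait_summary <- function() {
  out <- read.csv(text = "
trait,mean,sd,cv,sigmaA2,sigmaA2_se,sigmaE2,sigmaE2_se,h2,h2_se
BW,14.52,3.92,27.0,4.56,0.92,9.38,0.52,0.32,0.05
BL,10.82,1.01,9.3,0.35,0.07,0.61,0.03,0.36,0.06
BS,13.39,2.61,19.5,2.08,0.42,4.27,0.23,0.32,0.05
HS,4.83,0.92,19.2,0.25,0.05,0.56,0.02,0.31,0.05
AS,8.56,1.71,20.0,0.87,0.17,1.80,0.10,0.32,0.05
AP,63.87,1.48,2.3,0.15,0.03,1.48,0.03,0.09,0.02
TT,1.17,0.13,11.9,0.004,0.001,0.01,0.0005,0.28,0.05
FBR,0.84,0.06,7.2,0.0001,0.00005,0.002,0.00005,0.08,0.02
CF,1.11,0.07,6.6,0.0003,0.0001,0.005,0.0001,0.06,0.02
CFL,11.30,0.52,4.6,0.0008,0.001,0.25,0.005,0.003,0.004
", stringsAsFactors = FALSE)
  out
}

#' Published between-trait correlations and selection responses
#'
#' Genetic (rg), phenotypic (rp) and environmental (re) correlations between
#' trait pairs, with the published standardised correlated response (CR, in
#' phenotypic-SD units of trait y per one-SD selection differential on trait
#' x) and relative efficiency of indirect selection (%IS). Pairs the original
#' bivariate models could not fit are absent.
#'
#' @return Data.frame, one row per (trait_x, trait_y) pair.
#' @export
reference_trait_correlations <- function() {
  read.csv(text = "
trait_x,trait_y,rg,rg_se,rp,rp_se,re,re_se,CR,pctIS
BW,BL,0.99,0.002,0.95,0.001,0.94,0.003,0.34,105
BW,BS,0.99,0.001,0.95,0.001,0.93,0.003,0.32,99
BW,HS,0.99,0.002,0.93,0.002,0.90,0.005,0.31,101
BW,AS,0.99,0.002,0.93,0.001,0.95,0.003,0.32,99
BW,AP,0.36,0.14,0.17,0.01,0.13,0.02,0.06,19
BW,TT,0.96,0.01,0.86,0.005,0.82,0.009,0.29,103
BW,FBR,-0.48,0.13,-0.19,0.01,-0.15,0.02,-0.08,-96
BW,CF,-0.63,0.13,0.05,0.01,0.16,0.02,-0.09,-145
BL,BS,0.99,0.0006,0.96,0.001,0.95,0.002,0.34,105
BL,HS,0.99,0.001,0.94,0.002,0.92,0.004,0.33,107
BL,AS,0.99,0.001,0.96,0.001,0.95,0.002,0.34,105
BL,AP,0.36,0.14,0.15,0.02,0.18,0.01,0.06,72
BL,TT,0.97,0.008,0.89,0.004,0.85,0.007,0.31,110
BL,FBR,-0.49,0.13,-0.21,0.01,-0.16,0.02,-0.08,-102
BL,CF,-0.69,0.12,-0.17,0.01,0.11,0.02,-0.1,-169
BS,HS,0.99,0.001,0.98,0.0007,0.97,0.001,0.32,99
BS,AS,0.99,0.0003,0.99,0.0002,0.99,0.0004,0.32,99
BS,AP,0.40,0.14,0.15,0.01,0.10,0.02,0.07,75
BS,TT,0.97,0.007,0.92,0.002,0.90,0.004,0.29,104
BS,FBR,-0.53,0.12,-0.17,0.01,-0.11,0.02,-0.08,-106
BS,CF,-0.67,0.12,-0.11,0.01,-0.03,0.02,-0.09,-155
HS,AS,0.99,0.003,0.95,0.001,0.94,0.003,0.31,97
HS,TT,0.97,0.009,0.89,0.004,0.85,0.007,0.29,102
HS,FBR,-0.45,0.14,-0.02,0.01,0.06,0.02,-0.07,-89
HS,CF,-0.69,0.12,-0.11,0.01,-0.03,0.02,-0.09,-157
AS,TT,0.97,0.007,0.93,0.002,0.91,0.004,0.29,104
AS,FBR,-0.56,0.12,-0.26,0.01,-0.21,0.02,-0.09,-112
AS,CF,-0.65,0.12,-0.11,0.01,0.03,0.02,-0.09,-150
AP,FBR,-0.96,0.01,-0.88,0.003,-0.87,0.003,-0.16,-51
AP,CF,-0.08,0.20,0.001,0.01,0.008,0.01,-0.01,-10
TT,FBR,-0.57,0.12,-0.30,0.01,-0.26,0.02,-0.09,-30
TT,CF,-0.67,0.12,-0.12,0.01,-0.04,0.02,-0.09,-31
TT,CFL,0.81,0.31,0.40,0.01,0.45,0.01,0.02,8
FBR,CF,0.20,0.20,0.003,0.01,-0.01,0.01,0.01,23
FBR,CFL,-0.96,0.29,0.04,0.01,0.08,0.01,-0.01,-19
CF,CFL,0.28,0.42,0.29,0.03,0.29,0.04,0.00,125
", stringsAsFactors = FALSE)
}

# nearest-PSD projection for a covariance matrix assembled from published
# correlations: eigenvalue clipping with the original diagonal restored,
# alternated a few times (a light-weight Higham-style correction)
nearest_psd_cov <- function(S, floor_frac = 1e-8, iters = 10) {
  dn <- dimnames(S)
  dg <- diag(S)
  for (it in seq_len(iters)) {
    e <- eigen(S, symmetric = TRUE)
    fl <- floor_frac * max(e$values)
    if (all(e$values >= fl)) break
    S <- e$vectors %*% diag(pmax(e$values, fl)) %*% t(e$vectors)
    S <- (S + t(S)) / 2
    sc <- sqrt(dg / diag(S))
    S <- S * tcrossprod(sc)
  }
  dimnames(S) <- dn
  S
}

#' Default genetic architecture for the simulator
#'
#' Assembles the 10-trait additive-genetic covariance matrix G (from the
#' published variance components and genetic correlations) and the residual
#' covariance matrix R (from residual variances and environmental
#' correlations). Pairs without a published estimate are set to zero
#' covariance, and each matrix is projected to the nearest positive
#' semi-definite matrix with its diagonal restored.
#'
#' @return List with `G`, `R` (10 x 10, dimnames = trait names) and `traits`.
#' @export
reference_covariances <- function() {
  ts <- reference_trait_summary()
  tc <- reference_trait_correlations()
  traits <- ts$trait
  k <- length(traits)
  G <- diag(ts$sigmaA2); R <- diag(ts$sigmaE2)
  dimnames(G) <- dimnames(R) <- list(traits, traits)
  for (i in seq_len(nrow(tc))) {
    a <- tc$trait_x[i]; b <- tc$trait_y[i]
    G[a, b] <- G[b, a] <- tc$rg[i] * sqrt(G[a, a] * G[b, b])
    R[a, b] <- R[b, a] <- tc$re[i] * sqrt(R[a, a] * R[b, b])
  }
  list(G = nearest_psd_cov(G), R = nearest_psd_cov(R), traits = traits)
}
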