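# REML engines for the animal model y = Xb + Za + e with cov(a) = sigmaA2 * A.
#
# Univariate and paired-bivariate fits use a spectral ("eigendecomposition")
# formulation: with M = A restricted to the phenotyped animals and
# M = U diag(d) U', the rotated model y~ = U'y has a diagonal (univariate) or
# 2x2-block (bivariate) covariance, so every REML iteration after the single
# O(n^3) eigendecomposition costs O(n p^2). Average-information (AI) updates
# are the default, with an exact EM step as fallback; the EM step is monotone
# in the REML log-likelihood. Cross-environment bivariate fits (the same trait
# in two ponds, disjoint animals, structural zero residual covariance) use a
# dense-V engine, since the two genetic blocks cannot be diagonalised jointly.

#' Spectral decomposition of a relationship matrix block
#'
#' One-off eigendecomposition reused across REML fits that share the same set
#' of phenotyped animals (e.g. all traits of one dataset, or simulation
#' replicates over a fixed design).
#'
#' @param A Relationship matrix (with dimnames).
#' @param ids Animal ids selecting the block to decompose (default: all).
#' @return List with `U`, `d` (eigenvalues clamped at 0) and `ids`.
#' @export
spectral_prep <- function(A, ids = rownames(A)) {
  M <- A[ids, ids]
  e <- eigen(M, symmetric = TRUE)
  list(U = e$vectors, d = pmax(e$values, 0), ids = ids)
}

# core univariate spectral REML; y, X already restricted/ordered to sp$ids
reml_spectral_uni <- function(y, X, sp, algorithm = c("ai", "em"),
                              tol = 1e-8, max_iter = NULL, start = NULL,
                              keep_trace = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(max_iter)) max_iter <- if (algorithm == "ai") 200L else 5000L
  n <- length(y); p <- ncol(X)
  U <- sp$U; d <- sp$d
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vp <- var(qr.resid(qr(X), y)) * (n - 1) / max(1, n - p)
  if (!is.finite(vp) || vp < 1e-30) {
    return(list(theta = c(sigmaA2 = 0, sigmaE2 = 0), loglik = NA_real_,
                converged = TRUE, n_iter = 0L, boundary = TRUE,
                cov_theta = matrix(NA_real_, 2, 2), beta = rep(NA_real_, p),
                message = "response has no residual variance"))
  }
  floor_v <- 1e-10 * vp
  theta <- if (is.null(start)) c(vp / 2, vp / 2) else start
  theta <- pmax(theta, floor_v)

  eval_at <- function(theta) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 0)) return(NULL)
    W <- 1 / v
    WX <- Xt * W
    XtWX <- crossprod(Xt, WX)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- drop(chol2inv(ch) %*% crossprod(WX, yt))
    r <- yt - drop(Xt %*% beta)
    Py <- W * r
    yPy <- sum(r * Py)
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(ch))) + yPy) -
      0.5 * (n - p) * log(2 * pi)
    XtWXinv <- chol2inv(ch)
    B <- WX %*% XtWXinv            # n x p
    Pdiag <- W - rowSums(B * WX)
    list(v = v, W = W, WX = WX, XtWXinv = XtWXinv, beta = beta, r = r,
         Py = Py, ll = ll, B = B, Pdiag = Pdiag)
  }
  Pu <- function(st, u) st$W * u - st$B %*% crossprod(st$WX, u)

  ai_score <- function(st) {
    trPA <- sum(d * st$Pdiag); trPE <- sum(st$Pdiag)
    uA <- d * st$Py; uE <- st$Py
    yPAPy <- sum(st$Py * uA); yPEPy <- sum(st$Py * uE)
    score <- -0.5 * c(trPA - yPAPy, trPE - yPEPy)
    PuA <- Pu(st, uA); PuE <- Pu(st, uE)
    AI <- 0.5 * matrix(c(sum(uA * PuA), sum(uA * PuE),
                         sum(uA * PuE), sum(uE * PuE)), 2, 2)
    list(score = score, AI = AI)
  }
  em_update <- function(st, theta) {
    sA <- theta[1]; sE <- theta[2]
    pos <- d > 1e-12 * max(d, 1)
    m <- sum(pos)
    # E[c_i^2]/d_i for the genetic pseudo-components c_i ~ N(0, sA * d_i)
    ga <- sA^2 * d * st$Py^2 + sA - sA^2 * d * st$Pdiag
    sA_new <- if (m > 0) sum(ga[pos]) / m else 0
    sE_new <- mean(sE^2 * st$Py^2 + sE - sE^2 * st$Pdiag)
    pmax(c(sA_new, sE_new), floor_v)
  }

  st <- eval_at(theta)
  if (is.null(st)) stop("REML could not be initialised (singular system)", call. = FALSE)
  ll_trace <- st$ll
  converged <- FALSE; iter <- 0L; used_em_fallback <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (algorithm == "em") {
      theta_new <- em_update(st, theta)
    } else {
      sc <- ai_score(st)
      delta <- tryCatch(solve(sc$AI, sc$score), error = function(e) NULL)
      ok <- FALSE
      if (!is.null(delta) && all(is.finite(delta))) {
        step <- 1
        for (h in 1:15) {
          cand <- pmax(theta + step * delta, floor_v)
          st_c <- eval_at(cand)
          if (!is.null(st_c) && st_c$ll >= st$ll - 1e-10) {
            theta_new <- cand; st_new <- st_c; ok <- TRUE; break
          }
          step <- step / 2
        }
      }
      if (!ok) {   # non-PD or unproductive AI step: one exact EM step
        used_em_fallback <- TRUE
        theta_new <- em_update(st, theta)
      }
    }
    st_new <- eval_at(theta_new)
    if (is.null(st_new)) { theta_new <- pmax(theta_new, floor_v); st_new <- eval_at(theta_new) }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    dll <- st_new$ll - st$ll
    theta <- theta_new; st <- st_new
    if (keep_trace) ll_trace <- c(ll_trace, st$ll)
    if (rel < tol && abs(dll) < 1e-6) { converged <- TRUE; break }
  }
  sc <- ai_score(st)
  cov_theta <- tryCatch(solve(sc$AI), error = function(e) matrix(NA_real_, 2, 2))
  list(theta = c(sigmaA2 = theta[1], sigmaE2 = theta[2]),
       loglik = st$ll, converged = converged, n_iter = iter,
       boundary = any(theta <= floor_v * (1 + 1e-8)),
       cov_theta = cov_theta, beta = st$beta,
       Py_orig = drop(U %*% st$Py),
       proj = list(W = st$W, WX = st$WX, XtWXinv = st$XtWXinv),
       used_em_fallback = used_em_fallback,
       loglik_trace = if (keep_trace) ll_trace else NULL)
}

# project a symmetric 2x2 matrix to PSD with an eigenvalue floor
psd_project <- function(S, floor = 0) {
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= floor)) return(list(S = S, clipped = FALSE))
  v <- pmax(e$values, floor)
  list(S = e$vectors %*% diag(v, nrow = 2) %*% t(e$vectors), clipped = TRUE)
}

# paired bivariate spectral REML: two traits on the same animals, shared X.
# Y: n x 2 responses (original space), X: n x p, sp: spectral_prep() block.
reml_spectral_biv <- function(Y, X, sp, tol = 1e-8, max_iter = 200L,
                              start = NULL) {
  n <- nrow(Y); p <- ncol(X)
  U <- sp$U; d <- sp$d
  Yt <- crossprod(U, Y)
  Xt <- crossprod(U, X)
  y1 <- Yt[, 1]; y2 <- Yt[, 2]
  vps <- apply(Y, 2, function(y) var(qr.resid(qr(X), y)))
  if (any(vps < 1e-30)) stop("a response trait is constant", call. = FALSE)
  floor_e <- 1e-10 * vps
  # theta = (g11, g12, g22, e11, e12, e22)
  theta <- if (is.null(start)) c(vps[1] / 2, 0, vps[2] / 2, vps[1] / 2, 0, vps[2] / 2)
           else start
  clipped_any <- FALSE

  sanitize <- function(th) {
    G <- matrix(th[c(1, 2, 2, 3)], 2); R <- matrix(th[c(4, 5, 5, 6)], 2)
    pg <- psd_project(G, 1e-10 * mean(vps))
    pr <- psd_project(R, 1e-8 * mean(vps))
    if (pg$clipped || pr$clipped) clipped_any <<- TRUE
    G <- pg$S; R <- pr$S
    R[1, 1] <- max(R[1, 1], floor_e[1]); R[2, 2] <- max(R[2, 2], floor_e[2])
    c(G[1, 1], G[1, 2], G[2, 2], R[1, 1], R[1, 2], R[2, 2])
  }
  theta <- sanitize(theta)

  eval_at <- function(th) {
    va <- th[1] * d + th[4]; vb <- th[2] * d + th[5]; vc <- th[3] * d + th[6]
    det <- va * vc - vb^2
    if (any(det <= 0) || any(va <= 0) || any(vc <= 0)) return(NULL)
    w11 <- vc / det; w12 <- -vb / det; w22 <- va / det
    B11 <- crossprod(Xt, Xt * w11); B12 <- crossprod(Xt, Xt * w12)
    B22 <- crossprod(Xt, Xt * w22)
    C <- rbind(cbind(B11, B12), cbind(B12, B22))
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Cinv <- chol2inv(ch)
    rhs <- c(crossprod(Xt, w11 * y1 + w12 * y2), crossprod(Xt, w12 * y1 + w22 * y2))
    beta <- drop(Cinv %*% rhs)
    b1 <- beta[seq_len(p)]; b2 <- beta[p + seq_len(p)]
    r1 <- y1 - drop(Xt %*% b1); r2 <- y2 - drop(Xt %*% b2)
    Py1 <- w11 * r1 + w12 * r2; Py2 <- w12 * r1 + w22 * r2
    yPy <- sum(r1 * Py1) + sum(r2 * Py2)
    ll <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(ch))) + yPy) -
      0.5 * (2 * n - 2 * p) * log(2 * pi)
    list(w11 = w11, w12 = w12, w22 = w22, Cinv = Cinv, beta = beta,
         Py1 = Py1, Py2 = Py2, ll = ll)
  }

  # apply P to a 2n "stacked" vector given as two n-vectors
  Papply <- function(st, u1, u2) {
    v1 <- st$w11 * u1 + st$w12 * u2
    v2 <- st$w12 * u1 + st$w22 * u2
    xv <- c(crossprod(Xt, v1), crossprod(Xt, v2))
    z <- drop(st$Cinv %*% xv)
    z1 <- drop(Xt %*% z[seq_len(p)]); z2 <- drop(Xt %*% z[p + seq_len(p)])
    list(v1 - (st$w11 * z1 + st$w12 * z2),
         v2 - (st$w12 * z1 + st$w22 * z2))
  }

  Ek_u <- function(st, k) {
    # u_k = V_k P y, V_k = coef * E_k with coef = d (genetic) or 1 (residual)
    cf <- if (k <= 3) d else 1
    switch(((k - 1) %% 3) + 1,
           list(cf * st$Py1, 0 * st$Py1),                 # E11
           list(cf * st$Py2, cf * st$Py1),                # E12
           list(0 * st$Py1, cf * st$Py2))                 # E22
  }

  ai_score <- function(st) {
    w11 <- st$w11; w12 <- st$w12; w22 <- st$w22
    # tr(V^-1 V_k) and correction tr(Cinv * H_k)
    trs <- numeric(6); quad <- numeric(6)
    us <- lapply(1:6, function(k) Ek_u(st, k))
    Pus <- lapply(us, function(u) Papply(st, u[[1]], u[[2]]))
    Hblocks <- function(wts) {
      # wts: list of three n-vectors (block weights 11, 12, 22)
      H11 <- crossprod(Xt, Xt * wts[[1]]); H12 <- crossprod(Xt, Xt * wts[[2]])
      H22 <- crossprod(Xt, Xt * wts[[3]])
      rbind(cbind(H11, H12), cbind(H12, H22))
    }
    for (k in 1:6) {
      cf <- if (k <= 3) d else 1
      ek <- ((k - 1) %% 3) + 1
      trVinvVk <- switch(ek, sum(cf * w11), 2 * sum(cf * w12), sum(cf * w22))
      wts <- switch(ek,
        list(cf * w11^2, cf * w11 * w12, cf * w12^2),
        list(cf * 2 * w11 * w12, cf * (w11 * w22 + w12^2), cf * 2 * w12 * w22),
        list(cf * w12^2, cf * w12 * w22, cf * w22^2))
      Hk <- Hblocks(wts)
      trs[k] <- trVinvVk - sum(st$Cinv * Hk)
      quad[k] <- sum(st$Py1 * us[[k]][[1]]) + sum(st$Py2 * us[[k]][[2]])
    }
    score <- -0.5 * (trs - quad)
    AI <- matrix(0, 6, 6)
    for (k in 1:6) for (l in k:6) {
      AI[k, l] <- AI[l, k] <-
        0.5 * (sum(us[[k]][[1]] * Pus[[l]][[1]]) + sum(us[[k]][[2]] * Pus[[l]][[2]]))
    }
    list(score = score, AI = AI)
  }

  em_update <- function(st, th) {
    G <- matrix(th[c(1, 2, 2, 3)], 2); R <- matrix(th[c(4, 5, 5, 6)], 2)
    # per-observation diagonal 2x2 blocks of P
    K11 <- st$Cinv[seq_len(p), seq_len(p)]
    K12 <- st$Cinv[seq_len(p), p + seq_len(p)]
    K22 <- st$Cinv[p + seq_len(p), p + seq_len(p)]
    k11 <- rowSums((Xt %*% K11) * Xt)
    k12 <- rowSums((Xt %*% K12) * Xt)
    k22 <- rowSums((Xt %*% K22) * Xt)
    w11 <- st$w11; w12 <- st$w12; w22 <- st$w22
    # [Vi^-1 Xi Cinv Xi' Vi^-1]_{ts} = sum_uv w_tu w_sv k_uv
    q11 <- w11^2 * k11 + 2 * w11 * w12 * k12 + w12^2 * k22
    q12 <- w11 * w12 * k11 + (w11 * w22 + w12^2) * k12 + w12 * w22 * k22
    q22 <- w12^2 * k11 + 2 * w12 * w22 * k12 + w22^2 * k22
    P11 <- w11 - q11; P12 <- w12 - q12; P22 <- w22 - q22
    pos <- d > 1e-12 * max(d, 1); m <- sum(pos)
    # genetic latent c_i ~ N(0, d_i G)
    c1 <- d * (G[1, 1] * st$Py1 + G[1, 2] * st$Py2)
    c2 <- d * (G[1, 2] * st$Py1 + G[2, 2] * st$Py2)
    Sc <- matrix(0, 2, 2)
    Sc[1, 1] <- sum((c1^2 / d)[pos]); Sc[2, 2] <- sum((c2^2 / d)[pos])
    Sc[1, 2] <- Sc[2, 1] <- sum((c1 * c2 / d)[pos])
    SP <- matrix(0, 2, 2)   # sum_i d_i * Pblock_i over pos
    SP[1, 1] <- sum((d * P11)[pos]); SP[2, 2] <- sum((d * P22)[pos])
    SP[1, 2] <- SP[2, 1] <- sum((d * P12)[pos])
    G_new <- (Sc + m * G - G %*% SP %*% G) / m
    e1 <- R[1, 1] * st$Py1 + R[1, 2] * st$Py2
    e2 <- R[1, 2] * st$Py1 + R[2, 2] * st$Py2
    Se <- matrix(c(sum(e1^2), sum(e1 * e2), sum(e1 * e2), sum(e2^2)), 2)
    SPe <- matrix(c(sum(P11), sum(P12), sum(P12), sum(P22)), 2)
    R_new <- (Se + n * R - R %*% SPe %*% R) / n
    c(G_new[1, 1], G_new[1, 2], G_new[2, 2], R_new[1, 1], R_new[1, 2], R_new[2, 2])
  }

  st <- eval_at(theta)
  if (is.null(st)) stop("bivariate REML could not be initialised", call. = FALSE)
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sc <- ai_score(st)
    delta <- tryCatch(solve(sc$AI, sc$score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:12) {
        cand <- sanitize(theta + step * delta)
        if (max(abs(cand - theta)) < 1e-12 * mean(vps)) break  # stagnant
        st_c <- eval_at(cand)
        if (!is.null(st_c) && st_c$ll >= st$ll - 1e-10) {
          theta_new <- cand; st_new <- st_c; accepted <- TRUE; break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      theta_new <- sanitize(em_update(st, theta))
      st_new <- eval_at(theta_new)
      if (is.null(st_new) || st_new$ll < st$ll - 1e-8) {
        # no ascent direction improves the likelihood: constrained optimum
        # on the parameter-space boundary
        converged <- TRUE
        break
      }
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-10 * mean(vps)))
    dll <- st_new$ll - st$ll
    theta <- theta_new; st <- st_new
    if (rel < tol && abs(dll) < 1e-6) { converged <- TRUE; break }
  }
  sc <- ai_score(st)
  cov_theta <- tryCatch(solve(sc$AI), error = function(e) matrix(NA_real_, 6, 6))
  G <- matrix(theta[c(1, 2, 2, 3)], 2); R <- matrix(theta[c(4, 5, 5, 6)], 2)
  list(G = G, R = R, theta = theta, cov_theta = cov_theta,
       loglik = st$ll, converged = converged, n_iter = iter,
       clipped = clipped_any, beta = st$beta)
}

# cross-environment bivariate REML: one trait in two ponds, disjoint animal
# sets, residual covariance structurally zero. Dense-V engine.
# y1, y2: responses; M11, M22, M12: relationship blocks among/between the two
# sets; X1, X2: fixed-effect designs (usually intercepts).
reml_dense_crossenv <- function(y1, y2, M11, M22, M12, X1 = NULL, X2 = NULL,
                                tol = 1e-8, max_iter = 100L, start = NULL) {
  n1 <- length(y1); n2 <- length(y2)
  if (is.null(X1)) X1 <- matrix(1, n1, 1)
  if (is.null(X2)) X2 <- matrix(1, n2, 1)
  p1 <- ncol(X1); p2 <- ncol(X2); p <- p1 + p2
  N <- n1 + n2
  y <- c(y1, y2)
  X <- rbind(cbind(X1, matrix(0, n1, p2)), cbind(matrix(0, n2, p1), X2))
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  vps <- c(var(qr.resid(qr(X1), y1)), var(qr.resid(qr(X2), y2)))
  if (any(!is.finite(vps) | vps < 1e-30)) stop("a response is constant", call. = FALSE)
  floor_e <- 1e-10 * vps
  # theta = (g11, g12, g22, e1, e2)
  theta <- if (is.null(start)) c(vps[1] / 2, 0, vps[2] / 2, vps[1] / 2, vps[2] / 2)
           else start
  clipped_any <- FALSE
  sanitize <- function(th) {
    G <- matrix(th[c(1, 2, 2, 3)], 2)
    pg <- psd_project(G, 1e-10 * mean(vps))
    if (pg$clipped) clipped_any <<- TRUE
    c(pg$S[1, 1], pg$S[1, 2], pg$S[2, 2], max(th[4], floor_e[1]), max(th[5], floor_e[2]))
  }
  theta <- sanitize(theta)

  eval_at <- function(th) {
    V <- matrix(0, N, N)
    V[i1, i1] <- th[1] * M11
    V[i2, i2] <- th[3] * M22
    V[i1, i2] <- th[2] * M12; V[i2, i1] <- t(th[2] * M12)
    V[cbind(i1, i1)] <- V[cbind(i1, i1)] + th[4]
    V[cbind(i2, i2)] <- V[cbind(i2, i2)] + th[5]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    C <- crossprod(X, VinvX)
    chC <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(chC)) return(NULL)
    Cinv <- chol2inv(chC)
    beta <- drop(Cinv %*% crossprod(VinvX, y))
    r <- y - drop(X %*% beta)
    Py <- drop(Vinv %*% r)
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chC))) + sum(r * Py)) -
      0.5 * (N - p) * log(2 * pi)
    P <- Vinv - VinvX %*% tcrossprod(Cinv, VinvX)
    list(P = P, Py = Py, beta = beta, ll = ll)
  }

  u_of <- function(st, k) {
    Py1 <- st$Py[i1]; Py2 <- st$Py[i2]
    switch(k,
           c(drop(M11 %*% Py1), numeric(n2)),
           c(drop(M12 %*% Py2), drop(crossprod(M12, Py1))),
           c(numeric(n1), drop(M22 %*% Py2)),
           c(Py1, numeric(n2)),
           c(numeric(n1), Py2))
  }
  ai_score <- function(st) {
    trs <- c(sum(st$P[i1, i1] * M11),
             2 * sum(st$P[i1, i2] * M12),
             sum(st$P[i2, i2] * M22),
             sum(diag(st$P)[i1]),
             sum(diag(st$P)[i2]))
    us <- lapply(1:5, function(k) u_of(st, k))
    quad <- vapply(us, function(u) sum(st$Py * u), numeric(1))
    score <- -0.5 * (trs - quad)
    Pus <- lapply(us, function(u) drop(st$P %*% u))
    AI <- matrix(0, 5, 5)
    for (k in 1:5) for (l in k:5) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(us[[k]] * Pus[[l]])
    }
    list(score = score, AI = AI)
  }

  st <- eval_at(theta)
  if (is.null(st)) stop("cross-environment REML could not be initialised", call. = FALSE)
  converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sc <- ai_score(st)
    delta <- tryCatch(solve(sc$AI, sc$score), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(delta) && all(is.finite(delta))) {
      step <- 1
      for (h in 1:12) {
        cand <- sanitize(theta + step * delta)
        if (max(abs(cand - theta)) < 1e-12 * mean(vps)) break  # stagnant
        st_c <- eval_at(cand)
        if (!is.null(st_c) && st_c$ll >= st$ll - 1e-10) {
          theta_new <- cand; st_new <- st_c; accepted <- TRUE; break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      # damped diagonal-scaled ascent step as fallback
      dAI <- pmax(diag(sc$AI), 1e-12)
      step <- 0.5; ok <- FALSE
      for (h in 1:10) {
        cand <- sanitize(theta + step * sc$score / dAI)
        if (max(abs(cand - theta)) < 1e-12 * mean(vps)) break  # stagnant
        st_c <- eval_at(cand)
        if (!is.null(st_c) && st_c$ll >= st$ll - 1e-10) {
          theta_new <- cand; st_new <- st_c; ok <- TRUE; break
        }
        step <- step / 2
      }
      if (!ok) {
        # neither the AI step nor damped ascent improves the likelihood:
        # constrained optimum (typically on the PSD boundary)
        converged <- TRUE
        break
      }
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-10 * mean(vps)))
    dll <- st_new$ll - st$ll
    theta <- theta_new; st <- st_new
    if (rel < tol && abs(dll) < 1e-6) { converged <- TRUE; break }
  }
  sc <- ai_score(st)
  cov_theta <- tryCatch(solve(sc$AI), error = function(e) matrix(NA_real_, 5, 5))
  G <- matrix(theta[c(1, 2, 2, 3)], 2)
  R <- diag(theta[4:5])
  list(G = G, R = R, theta = theta, cov_theta = cov_theta,
       loglik = st$ll, converged = converged, n_iter = iter,
       clipped = clipped_any, beta = st$beta)
}
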