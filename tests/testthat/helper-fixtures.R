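# Shared fixtures and independent oracles.

# independent shoelace polygon area (oracle; kept separate from the package's
# internal helper on purpose)
oracle_shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# random convex shrimp-like outline: the template pushed through a random
# affine map (affine maps preserve convexity and the anterior/posterior
# labelling semantics), with an optional tiny accepted-only jitter
random_convex_landmarks <- function(id = "r", jitter = 0) {
  repeat {
    th <- runif(1, -pi / 6, pi / 6)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    S <- diag(runif(2, 0.6, 1.8))
    K <- matrix(c(1, 0, runif(1, -0.25, 0.25), 1), 2)
    pts <- shrimp_template()$points %*% t(Rm %*% S %*% K)
    pts <- pts + matrix(runif(2, -3, 3), 12, 2, byrow = TRUE)
    if (jitter > 0) pts <- pts + matrix(rnorm(24, sd = jitter), 12, 2)
    rownames(pts) <- rownames(shrimp_template()$points)
    ok <- tryCatch({
      lm <- landmark_set(id, pts)
      p <- pts[c("A1", "D1", "D2", "D3", "D4", "PT", "PB",
                 "V5", "V4", "V3", "V2", "V1"), ]
      n <- nrow(p)
      cr <- vapply(seq_len(n), function(i) {
        a <- p[i, ]; b <- p[i %% n + 1, ]; c <- p[(i + 1) %% n + 1, ]
        (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      }, numeric(1))
      if (all(cr > 0) || all(cr < 0)) lm else NULL
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
}

# outline polygon coordinates in cyclic order for a landmark set
outline_coords <- function(lm) {
  lm$points[c("A1", "D1", "D2", "D3", "D4", "PT", "PB",
              "V5", "V4", "V3", "V2", "V1"), ]
}

# random acyclic pedigree of n animals, first n_founder founders
random_pedigree <- function(n, n_founder = 10, seed = 1) {
  set.seed(seed)
  an <- sprintf("A%03d", seq_len(n))
  s <- d <- rep(NA_character_, n)
  for (i in (n_founder + 1):n) {
    s[i] <- an[sample.int(i - 1, 1)]
    d[i] <- an[sample.int(i - 1, 1)]
    if (identical(s[i], d[i])) d[i] <- NA
  }
  as_pedigree(data.frame(animal = an, sire = s, dam = d))
}

# balanced paternal half-sib design: ns sires, k offspring each, unknown dams
halfsib_pedigree <- function(ns, k) {
  sires <- sprintf("S%03d", seq_len(ns))
  off <- sprintf("O%05d", seq_len(ns * k))
  as_pedigree(data.frame(animal = c(sires, off),
                         sire = c(rep(NA, ns), rep(sires, each = k)),
                         dam = NA))
}
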