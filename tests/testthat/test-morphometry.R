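test_that("pairwise distances follow the canonical 66-pair contract", {
  set.seed(11)
  lm <- random_convex_landmarks()
  d <- pairwise_distances(lm)
  expect_length(d, 66)
  expect_identical(names(d)[1:3], c("A1-D1", "A1-D2", "A1-D3"))
  expect_true(all(d >= 0))

  # degenerate configuration: all points coincident -> all distances zero
  z <- matrix(0, 12, 2, dimnames = list(landmark_labels(), c("x", "y")))
  expect_equal(unname(pairwise_distances(z)), rep(0, 66))

  # schema errors
  bad <- shrimp_template()$points
  rownames(bad)[1] <- "D1"
  expect_error(landmark_set("x", bad), "duplicate")
  expect_error(landmark_set("x", bad[-1, ]), "labels")
})

test_that("pairwise distances match a brute-force double loop", {
  set.seed(21)
  labs <- landmark_labels()
  for (rep in 1:1000) {
    pts <- matrix(rnorm(24, sd = 3), 12, 2, dimnames = list(labs, NULL))
    d <- pairwise_distances(pts)
    k <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      k <- k + 1
      expected <- sqrt(sum((pts[labs[i], ] - pts[labs[j], ])^2))
      if (abs(d[k] - expected) > 1e-12) {
        fail(sprintf("mismatch at pair %s-%s", labs[i], labs[j]))
      }
    }
  }
  succeed()
})

test_that("Heron's formula handles classic, degenerate and random triangles", {
  expect_equal(heron_area(3, 4, 5), 6)
  expect_equal(heron_area(1, 2, 3), 0)           # collinear
  expect_error(heron_area(1, 1, 5), "triangle inequality")
  expect_error(heron_area(-1, 2, 2), "non-negative")

  set.seed(31)
  for (i in 1:200) {
    tri <- matrix(rnorm(6, sd = 4), 3, 2)
    a <- sqrt(sum((tri[1, ] - tri[2, ])^2))
    b <- sqrt(sum((tri[2, ] - tri[3, ])^2))
    c <- sqrt(sum((tri[1, ] - tri[3, ])^2))
    expect_equal(heron_area(a, b, c), oracle_shoelace(tri), tolerance = 1e-9)
  }
})

test_that("segment areas sum to the outline's shoelace area on convex outlines", {
  set.seed(41)
  for (i in 1:100) {
    lm <- random_convex_landmarks()
    S <- segment_areas(lm)
    expect_true(all(S > 0))
    total <- sum(S)
    expect_equal(total, oracle_shoelace(outline_coords(lm)),
                 tolerance = 1e-9)
  }
})

test_that("a unit-square segment has area one and areas scale quadratically", {
  pts <- shrimp_template()$points
  # rebuild S1 = (D1, D2, V3, V2) as the unit square
  pts["D1", ] <- c(0, 1); pts["D2", ] <- c(1, 1)
  pts["V2", ] <- c(0, 0); pts["V3", ] <- c(1, 0)
  pts["A1", ] <- c(-2, 0.5); pts["V1", ] <- c(-1, -0.2)
  suppressWarnings({
    S <- segment_areas(landmark_set("sq", pts))
  })
  expect_equal(unname(S["S1"]), 1)

  lm <- random_convex_landmarks()
  S1 <- segment_areas(lm)
  lm2 <- landmark_set("scaled", lm$points * 2)
  expect_equal(unname(segment_areas(lm2)), unname(S1 * 4), tolerance = 1e-12)
})

test_that("derived traits reproduce their defining arithmetic", {
  tpl <- shrimp_template()
  tr <- derive_traits(tpl, bw = 14.52, pond = "P1")
  expect_equal(tr$BL, 10.82, tolerance = 1e-6)
  expect_equal(tr$CF, 100 * 14.52 / 10.82^3, tolerance = 1e-9)
  expect_equal(round(tr$CF, 2), 1.15)
  expect_equal(tr$BS, tr$HS + tr$AS, tolerance = 1e-12)
  expect_equal(tr$AP, 100 * tr$AS / tr$BS, tolerance = 1e-12)
  expect_gt(tr$AP, 0); expect_lt(tr$AP, 100)
  expect_equal(tr$CFL, 100 * tr$BS / tr$BL^2, tolerance = 1e-12)
  expect_error(derive_traits(tpl, bw = -1, pond = "P1"), "positive")

  # AP follows directly from the head/abdominal split
  S <- segment_areas(tpl)
  hs <- S[["S0"]]; as_ <- sum(S) - hs
  expect_equal(tr$AP, 100 * as_ / (hs + as_))
})

test_that("ratio traits are invariant under rigid motion and scaling", {
  set.seed(51)
  lm <- random_convex_landmarks()
  tr <- derive_traits(lm, bw = 10, pond = "P")
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (s in c(0.5, 2, 3.7)) {
    pts2 <- (lm$points %*% t(Rm)) * s
    pts2 <- pts2 + matrix(c(5, -2), 12, 2, byrow = TRUE)
    rownames(pts2) <- rownames(lm$points)
    tr2 <- derive_traits(landmark_set("m", pts2), bw = 10, pond = "P")
    expect_equal(tr2$AP, tr$AP, tolerance = 1e-9)
    expect_equal(tr2$FBR, tr$FBR, tolerance = 1e-9)
    expect_equal(tr2$CFL, tr$CFL, tolerance = 1e-9)   # area/length^2
    expect_equal(tr2$BL, s * tr$BL, tolerance = 1e-9)
    expect_equal(tr2$TT, s * tr$TT, tolerance = 1e-9)
    expect_equal(tr2$BS, s^2 * tr$BS, tolerance = 1e-9)
  }
})

test_that("PCA isolates a single varying column and fixes component signs", {
  set.seed(61)
  D <- matrix(5, 20, 66)
  colnames(D) <- paste0("d", 1:66)
  D[, 7] <- rnorm(20)
  p <- run_pca(D)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(p$loadings[7, 1]), 1, tolerance = 1e-12)
  expect_gt(p$loadings[7, 1], 0)  # sign fixed positive
  expect_error(run_pca(D, scale. = TRUE), "d1")
})

test_that("PCA reconstructs the data and matches an SVD oracle", {
  set.seed(62)
  D <- matrix(rnorm(30 * 8), 30, 8)
  p <- run_pca(D)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(crossprod(p$loadings), diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)
  recon <- p$scores %*% t(p$loadings)
  centred <- scale(D, center = TRUE, scale = FALSE)
  expect_equal(recon, unname(centred), tolerance = 1e-9, ignore_attr = TRUE)
  sv <- svd(centred)
  expect_equal(p$sdev^2, sv$d^2 / (nrow(D) - 1), tolerance = 1e-9)
})
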