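#' @importFrom stats dist prcomp rnorm runif setNames var sd cor rgamma rmultinom
#' @importFrom stats model.matrix aggregate
#' @importFrom utils read.csv write.csv
NULL

#' Canonical landmark labels
#'
#' The twelve body landmarks used throughout: one anterior point (`A1`), four
#' dorsal points (`D1`-`D4`, anterior to posterior), five ventral points
#' (`V1`-`V5`, anterior to posterior) and the two posterior tail points
#' (`PT` dorsal, `PB` ventral). The canonical (lexicographic) ordering used
#' for distance vectors is `A1, D1..D4, PB, PT, V1..V5`.
#'
#' @return Character vector of the 12 labels in canonical order.
#' @export
landmark_labels <- function() {
  sort(c("A1", paste0("D", 1:4), paste0("V", 1:5), "PT", "PB"))
}

#' Construct a landmark set
#'
#' A landmark set holds one animal's twelve 2-D landmark coordinates, in cm
#' (any pixel-to-cm scaling is applied on input).
#'
#' @param animal_id Identifier for the animal.
#' @param points A 12 x 2 numeric matrix of coordinates with rownames equal to
#'   [landmark_labels()] (any row order; rows are reordered canonically).
#' @param scale_cm_per_px Positive scale already applied upstream; stored for
#'   provenance only. Default 1.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(animal_id, points, scale_cm_per_px = 1) {
  labs <- landmark_labels()
  points <- as.matrix(points)
  if (is.null(rownames(points))) {
    stop("`points` must have rownames giving the landmark labels", call. = FALSE)
  }
  if (anyDuplicated(rownames(points))) {
    stop("duplicate landmark label(s): ",
         paste(unique(rownames(points)[duplicated(rownames(points))]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(labs, rownames(points))
  extra <- setdiff(rownames(points), labs)
  if (length(missing) || length(extra)) {
    stop("landmark labels must be exactly {", paste(labs, collapse = ", "), "}; ",
         if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "), "; "),
         if (length(extra)) paste0("unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  points <- points[labs, , drop = FALSE]
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || !all(is.finite(points))) {
    stop("`points` must be a 12 x 2 matrix of finite coordinates", call. = FALSE)
  }
  if (!is.numeric(scale_cm_per_px) || scale_cm_per_px <= 0) {
    stop("`scale_cm_per_px` must be a positive number", call. = FALSE)
  }
  # no two chain-adjacent landmarks may coincide
  chain <- outline_order()
  p <- points[chain, ]
  seg <- sqrt(rowSums((p - p[c(2:nrow(p), 1L), ])^2))
  if (any(seg == 0)) {
    bad <- which(seg == 0)[1L]
    stop("chain-adjacent landmarks coincide: ", chain[bad], " and ",
         chain[bad %% length(chain) + 1L], call. = FALSE)
  }
  structure(list(animal_id = animal_id, points = points,
                 scale_cm_per_px = scale_cm_per_px),
            class = "landmark_set")
}

# cyclic order of landmarks around the body outline polygon
outline_order <- function() {
  c("A1", "D1", "D2", "D3", "D4", "PT", "PB", "V5", "V4", "V3", "V2", "V1")
}

#' All pairwise landmark distances
#'
#' Computes the 66 = choose(12, 2) Euclidean distances between landmark pairs,
#' ordered by the canonical lexicographic label ordering (the same ordering for
#' every animal, so distance vectors are directly comparable and round-trip
#' through files).
#'
#' @param lm A [landmark_set()], or a labelled 12 x 2 coordinate matrix
#'   (degenerate configurations such as coincident points are permitted in
#'   matrix form, since distances are defined for them even where a validated
#'   landmark set is not).
#' @return Named numeric vector of length 66; names are `"L1-L2"` label pairs.
#' @export
pairwise_distances <- function(lm) {
  labs <- landmark_labels()
  if (is.matrix(lm)) {
    stopifnot(setequal(rownames(lm), labs))
    lm <- list(points = lm[labs, , drop = FALSE])
  } else {
    stopifnot(inherits(lm, "landmark_set"))
  }
  d <- as.vector(dist(lm$points[labs, ]))
  nm <- outer(labs, labs, function(a, b) paste0(a, "-", b))
  names(d) <- t(nm)[lower.tri(nm)]  # dist() order: (1,2),(1,3),...,(2,3),...
  d
}

#' Triangle area by Heron's formula
#'
#' @param a,b,c Side lengths (cm), each >= 0. Vectorised.
#' @return Area(s) in cm^2. Tiny negative radicands from floating-point
#'   cancellation (|radicand| < 1e-12 * s^4) are clamped to zero; a genuine
#'   triangle-inequality violation is an error.
#' @examples
#' heron_area(3, 4, 5)  # 6
#' @export
heron_area <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("side lengths must be non-negative", call. = FALSE)
  s <- (a + b + c) / 2
  rad <- s * (s - a) * (s - b) * (s - c)
  tol <- 1e-12 * pmax(s, 1)^4
  bad <- rad < -tol
  if (any(bad)) {
    stop("triangle inequality violated for sides (",
         paste(signif(c(a[bad][1], b[bad][1], c[bad][1]), 6), collapse = ", "), ")",
         call. = FALSE)
  }
  sqrt(pmax(rad, 0))
}

# signed shoelace area of a polygon given as an m x 2 coordinate matrix
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# do segments p1-p2 and p3-p4 properly intersect?
segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o(p1, p2, p3) * o(p1, p2, p4) < 0 && o(p3, p4, p1) * o(p3, p4, p2) < 0
}

# area of the quadrilateral v1..v4 (cyclic) as the sum of the two Heron
# triangles cut by the diagonal from v1 (the anterior-dorsal vertex)
quad_area <- function(p, v, warn_label = NULL) {
  q <- p[v, ]
  if (segments_cross(q[1, ], q[2, ], q[3, ], q[4, ]) ||
      segments_cross(q[2, ], q[3, ], q[4, ], q[1, ])) {
    warning("self-intersecting quadrilateral ", warn_label,
            "; area computed from its two triangles as-is", call. = FALSE)
  }
  len <- function(i, j) sqrt(sum((q[i, ] - q[j, ])^2))
  heron_area(len(1, 2), len(2, 3), len(1, 3)) +
    heron_area(len(1, 3), len(3, 4), len(1, 4))
}

#' Body segment areas
#'
#' Partitions the body outline into five quadrilaterals and returns their
#' areas: `S0` the head (A1, D1, V2, V1) and `S1`-`S4` the four abdominal
#' segments bounded by successive dorsal/ventral landmark pairs, ending in the
#' tail segment (D4, PT, PB, V5). The ventral chain carries one extra anterior
#' landmark, so dorsal point `Di` pairs with ventral point `V(i+1)`. Each
#' quadrilateral is split along the diagonal from its anterior-dorsal vertex
#' into two triangles whose Heron areas are summed; for convex outlines the sum
#' of the five areas equals the shoelace area of the whole outline polygon.
#'
#' @param lm A [landmark_set()].
#' @return Named numeric vector `c(S0, S1, S2, S3, S4)` in cm^2.
#' @export
segment_areas <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  p <- lm$points
  quads <- list(
    S0 = c("A1", "D1", "V2", "V1"),
    S1 = c("D1", "D2", "V3", "V2"),
    S2 = c("D2", "D3", "V4", "V3"),
    S3 = c("D3", "D4", "V5", "V4"),
    S4 = c("D4", "PT", "PB", "V5")
  )
  vapply(names(quads), function(nm) quad_area(p, quads[[nm]], nm), numeric(1))
}

#' Derive morphometric traits from landmarks
#'
#' Computes the image-derived size and shape traits used for genetic
#' evaluation:
#' \describe{
#'   \item{BL}{body length (cm): distance from the anterior point `A1` to the
#'     posterior tail point, taken as the midpoint of `PT` and `PB` (set
#'     `bl_endpoint = "max"` to use the farther of the two instead).}
#'   \item{TT}{tail tip (cm): the dorso-ventral distance `|PT - PB|`.}
#'   \item{HS, AS, BS}{head, abdominal and total body segment areas (cm^2):
#'     `HS = S0`, `AS = S1 + S2 + S3 + S4`, `BS = HS + AS`.}
#'   \item{AP}{abdominal percentage: `100 * AS / BS`.}
#'   \item{FBR}{front-back ratio: `(S0 + S1) / (S2 + S3 + S4)`.}
#'   \item{CF}{condition factor: `100 * BW / BL^3`.}
#'   \item{CFL}{condition factor by length: `100 * BS / BL^2`.}
#' }
#'
#' @param lm A [landmark_set()].
#' @param bw Body weight in g (> 0).
#' @param pond Pond (environment) label.
#' @param bl_endpoint `"midpoint"` (default) or `"max"`: how the posterior
#'   body-length endpoint is formed from `PT` and `PB`.
#' @return One-row data.frame with columns
#'   `animal_id, pond, BW, BL, BS, HS, AS, AP, TT, FBR, CF, CFL`.
#' @export
derive_traits <- function(lm, bw, pond, bl_endpoint = c("midpoint", "max")) {
  stopifnot(inherits(lm, "landmark_set"))
  bl_endpoint <- match.arg(bl_endpoint)
  if (!is.numeric(bw) || length(bw) != 1L || !is.finite(bw) || bw <= 0) {
    stop("`bw` (body weight, g) must be a single positive number", call. = FALSE)
  }
  p <- lm$points
  tt <- sqrt(sum((p["PT", ] - p["PB", ])^2))
  if (bl_endpoint == "midpoint") {
    tail_pt <- (p["PT", ] + p["PB", ]) / 2
    bl <- sqrt(sum((p["A1", ] - tail_pt)^2))
  } else {
    bl <- max(sqrt(sum((p["A1", ] - p["PT", ])^2)),
              sqrt(sum((p["A1", ] - p["PB", ])^2)))
  }
  if (bl == 0) stop("body length is zero; cannot form condition factors", call. = FALSE)
  S <- segment_areas(lm)
  if (any(S == 0) && any(S > 0)) {
    warning("zero segment area(s): ", paste(names(S)[S == 0], collapse = ", "),
            "; traits computed anyway", call. = FALSE)
  }
  hs <- S[["S0"]]
  as_ <- S[["S1"]] + S[["S2"]] + S[["S3"]] + S[["S4"]]
  bs <- hs + as_
  back <- S[["S2"]] + S[["S3"]] + S[["S4"]]
  data.frame(
    animal_id = lm$animal_id, pond = as.character(pond),
    BW = bw, BL = bl, BS = bs, HS = hs, AS = as_,
    AP = 100 * as_ / bs, TT = tt,
    FBR = (S[["S0"]] + S[["S1"]]) / back,
    CF = 100 * bw / bl^3, CFL = 100 * bs / bl^2,
    stringsAsFactors = FALSE
  )
}

#' PCA of a morphometric distance matrix
#'
#' Principal component analysis of an n x 66 matrix of pairwise landmark
#' distances (or any numeric trait matrix), used to describe the pattern of
#' shape variation. Columns are centred; standardisation is optional. The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making results reproducible across platforms.
#'
#' @param D Numeric matrix, animals in rows (n >= 2), no missing values.
#' @param center,scale. Passed to the underlying decomposition; defaults
#'   centre but do not standardise.
#' @return List with `loadings` (p x k), `scores` (n x k),
#'   `variance_explained` (length-k proportions, non-increasing) and `sdev`.
#' @export
run_pca <- function(D, center = TRUE, scale. = FALSE) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 rows for PCA", call. = FALSE)
  if (anyNA(D)) stop("missing values in distance matrix", call. = FALSE)
  if (isTRUE(scale.)) {
    s <- apply(D, 2, sd)
    if (any(s == 0)) {
      stop("constant column(s) cannot be standardised: ",
           paste(colnames(D)[s == 0], collapse = ", "), call. = FALSE)
    }
  }
  pc <- prcomp(D, center = center, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  sco <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = rot, scores = sco, variance_explained = ve, sdev = pc$sdev)
}
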