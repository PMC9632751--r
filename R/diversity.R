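# Family-distribution diagnostics: how evenly full/half-sib families are
# represented within ponds (Shannon-Wiener) and how similar the family
# composition of two ponds is (Morisita-Horn).

#' Shannon-Wiener diversity index
#'
#' Natural-log entropy of family proportions within a pond,
#' `H = -sum(p_i * log(p_i))` over families present (zero counts contribute
#' nothing). Maximum diversity `H_max = log(k)` occurs when the k families
#' present are represented equally.
#'
#' @param counts Non-negative counts (or proportions) per family.
#' @return List with `H`, `H_max` and `n_families` (families present).
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("all counts are zero", call. = FALSE)
  p <- counts[counts > 0] / tot
  list(H = -sum(p * log(p)), H_max = log(length(p)), n_families = length(p))
}

#' Morisita-Horn overlap index
#'
#' Abundance-based similarity of two family distributions:
#' `MH = 2 * sum(p1 * p2) / (sum(p1^2) + sum(p2^2))`, ranging from 0 (no
#' shared families) to 1 (identical family representation). Counts are aligned
#' on the union of family names (absent = 0) and the index is invariant to
#' rescaling either pond's counts by a positive constant.
#'
#' @param counts1,counts2 Named non-negative count vectors for the two ponds.
#' @return Scalar in [0, 1].
#' @export
morisita_horn <- function(counts1, counts2) {
  if (sum(counts1) <= 0 || sum(counts2) <= 0) stop("empty pond", call. = FALSE)
  if (is.null(names(counts1)) || is.null(names(counts2))) {
    if (length(counts1) != length(counts2)) {
      stop("unnamed count vectors must have equal length", call. = FALSE)
    }
    keys <- seq_along(counts1)
    p1 <- counts1; p2 <- counts2
  } else {
    keys <- union(names(counts1), names(counts2))
    p1 <- setNames(numeric(length(keys)), keys)
    p2 <- p1
    p1[names(counts1)] <- counts1
    p2[names(counts2)] <- counts2
  }
  p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
  2 * sum(p1 * p2) / (sum(p1^2) + sum(p2^2))
}

#' Family-by-pond offspring counts
#'
#' Tabulates offspring per family within each pond, separately for
#' sire-families and dam-families.
#'
#' @param offspring Data.frame with columns `animal_id` (or `animal`), `sire`,
#'   `dam`, `pond`.
#' @return List of two pond x family count matrices: `sire` and `dam`.
#' @export
family_distribution <- function(offspring) {
  if (!"animal_id" %in% names(offspring) && "animal" %in% names(offspring)) {
    offspring$animal_id <- offspring$animal
  }
  stopifnot(all(c("animal_id", "sire", "dam", "pond") %in% names(offspring)))
  tab <- function(parent) {
    t <- table(offspring$pond, offspring[[parent]])
    m <- matrix(as.integer(t), nrow = nrow(t), dimnames = dimnames(t))
    names(dimnames(m)) <- c("pond", "family")
    m
  }
  list(sire = tab("sire"), dam = tab("dam"))
}

#' Family diversity report
#'
#' Per-pond Shannon-Wiener indices (sire- and dam-families tabulated
#' independently) and the symmetric pairwise Morisita-Horn overlap matrices.
#'
#' @param dist A [family_distribution()] result (or an offspring data.frame,
#'   which is tabulated first).
#' @return List with `shannon` (data.frame pond x {sire_H, dam_H, ...}) and
#'   `mh` (list of two symmetric pond x pond matrices with unit diagonal).
#' @export
diversity_report <- function(dist) {
  if (is.data.frame(dist)) dist <- family_distribution(dist)
  stopifnot(all(c("sire", "dam") %in% names(dist)))
  ponds <- rownames(dist$sire)
  sh <- data.frame(
    pond = ponds,
    sire_H = apply(dist$sire, 1, function(x) shannon(x)$H),
    dam_H = apply(dist$dam, 1, function(x) shannon(x)$H),
    sire_n_families = apply(dist$sire, 1, function(x) sum(x > 0)),
    dam_n_families = apply(dist$dam, 1, function(x) sum(x > 0)),
    stringsAsFactors = FALSE
  )
  mh_one <- function(m) {
    k <- nrow(m)
    out <- diag(1, k)
    dimnames(out) <- list(rownames(m), rownames(m))
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        out[i, j] <- out[j, i] <- morisita_horn(m[i, ], m[j, ])
      }
    }
    out
  }
  list(shannon = sh, mh = list(sire = mh_one(dist$sire), dam = mh_one(dist$dam)))
}
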