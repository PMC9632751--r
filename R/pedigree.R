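# Pedigree handling and the additive (numerator) relationship matrix.

#' Construct and validate a pedigree
#'
#' A pedigree is a data.frame with columns `animal`, `sire`, `dam` (character;
#' `NA` = unknown parent). Parents that appear only in the sire/dam columns are
#' added as founder records. Records are returned in topological order
#' (every parent precedes its offspring); a cycle (including a self-parent) is
#' an error that names the animals involved.
#'
#' @param df Data.frame with columns `animal`, `sire`, `dam`; `0`, `""` and
#'   `NA` all encode an unknown parent.
#' @return Data.frame of class `pedigree`, topologically sorted, with a
#'   `founder` logical column.
#' @export
as_pedigree <- function(df) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "")] <- NA_character_
    x
  }
  animal <- clean(df$animal); sire <- clean(df$sire); dam <- clean(df$dam)
  if (anyNA(animal)) stop("missing animal id", call. = FALSE)
  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "), call. = FALSE)
  }
  implicit <- setdiff(c(sire, dam), c(animal, NA))
  if (length(implicit)) {
    animal <- c(implicit, animal)
    sire <- c(rep(NA_character_, length(implicit)), sire)
    dam <- c(rep(NA_character_, length(implicit)), dam)
  }
  n <- length(animal)
  idx <- function(x) match(x, animal)  # NA-safe
  si <- idx(sire); di <- idx(dam)

  # Kahn topological sort over parent -> offspring edges
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving: ",
         paste(animal[cyc], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(animal = animal[order], sire = sire[order], dam = dam[order],
                    stringsAsFactors = FALSE)
  out$founder <- is.na(out$sire) & is.na(out$dam)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree file
#'
#' Three-column delimited file `animal,sire,dam`; `0` or an empty field
#' encodes an unknown parent. See [as_pedigree()] for validation rules.
#'
#' @param path CSV/TSV path.
#' @return A sorted `pedigree` data.frame.
#' @export
read_pedigree <- function(path) {
  df <- read_delim_auto(path)
  names(df)[1:3] <- c("animal", "sire", "dam")
  as_pedigree(df)
}

#' Write a pedigree file
#'
#' @param ped A `pedigree` data.frame.
#' @param path Output CSV path; unknown parents written as `0`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("animal", "sire", "dam")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Additive (numerator) relationship matrix
#'
#' Builds the pedigree relationship matrix A by the recursive tabular method:
#' processing animals parents-first, `A[i,j] = (A[j,s(i)] + A[j,d(i)]) / 2` for
#' previously processed `j`, and `A[i,i] = 1 + A[s(i),d(i)] / 2`; an unknown
#' parent contributes 0. A is symmetric positive semi-definite with diagonal
#' `1 + F` (F the inbreeding coefficient). Dense storage; intended scale is up
#' to roughly 10,000 animals (a sparse-inverse construction is a possible
#' future optimisation).
#'
#' @param ped A `pedigree` from [as_pedigree()] / [read_pedigree()].
#' @return n x n matrix with dimnames equal to the animal ids.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[j, s]
      if (!is.na(d)) row <- row + A[j, d]
      row <- row / 2
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' `F_i = A[i,i] - 1` from the tabular relationship matrix.
#'
#' @param ped A sorted `pedigree`.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  diag(build_A(ped)) - 1
}

#' Monte-Carlo relationship matrix by gene dropping
#'
#' Independent check on [build_A()]: founders receive two unique alleles each,
#' alleles are dropped through the pedigree by Mendelian sampling, and the
#' additive relationship between i and j is estimated as twice the observed
#' probability that a random allele drawn from each is identical by descent.
#' Used for validation; the tabular method is the production path.
#'
#' @param ped A sorted `pedigree`.
#' @param n_rep Number of gene-dropping replicates (e.g. 50000).
#' @param seed Integer seed.
#' @param batch Replicates per sparse accumulation batch.
#' @return n x n estimated relationship matrix.
#' @export
gene_drop_A <- function(ped, n_rep = 50000, seed = 1, batch = 500) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  # pre-assign unique founder-allele ids, incl. for unknown parent slots
  a1 <- integer(n); a2 <- integer(n)
  nxt <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) { a1[i] <- nxt; nxt <- nxt + 1L }
    if (is.na(di[i])) { a2[i] <- nxt; nxt <- nxt + 1L }
  }
  K <- nxt - 1L + 2L * n  # allele id space upper bound
  acc <- matrix(0, n, n)
  done <- 0L
  while (done < n_rep) {
    B <- min(batch, n_rep - done)
    A1 <- matrix(0L, n, B); A2 <- matrix(0L, n, B)
    for (i in seq_len(n)) {
      if (is.na(si[i])) A1[i, ] <- a1[i] else {
        pick <- runif(B) < 0.5
        A1[i, ] <- ifelse(pick, A1[si[i], ], A2[si[i], ])
      }
      if (is.na(di[i])) A2[i, ] <- a2[i] else {
        pick <- runif(B) < 0.5
        A2[i, ] <- ifelse(pick, A1[di[i], ], A2[di[i], ])
      }
    }
    # sparse indicator: rows = animals, cols = (replicate, allele id)
    col <- (rep(seq_len(B), each = n) - 1L) * K
    S <- Matrix::sparseMatrix(
      i = rep.int(seq_len(n), 2L * B),
      j = c(col + as.vector(A1), col + as.vector(A2)),
      x = 1, dims = c(n, as.double(B) * K)
    )
    acc <- acc + as.matrix(Matrix::tcrossprod(S))
    done <- done + B
  }
  est <- acc / (2 * n_rep)  # 2 * coancestry
  dimnames(est) <- list(ped$animal, ped$animal)
  est
}
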