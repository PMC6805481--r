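## Relationship matrices: pedigree A and its sparse inverse, genomic G
## (VanRaden method 1), the adjusted Ga, the blended Gw, and the
## single-step H inverse kept as parts.

#' Normalise and topologically sort a pedigree
#'
#' Accepts a data frame with at least `id`, `sire`, `dam` columns (0 or `NA`
#' denote an unknown parent) and returns the same rows ordered so that every
#' parent precedes its offspring, with ids coerced to character.
#'
#' @param ped data frame with columns `id`, `sire`, `dam` (extra columns kept).
#' @return the sorted data frame with an integer `sire_idx`/`dam_idx`
#'   attribute-free encoding in columns `.si`, `.di` (0 = unknown).
#' @keywords internal
normalize_pedigree <- function(ped) {
  .check(is.data.frame(ped) && all(c("id", "sire", "dam") %in% names(ped)),
         "pedigree must be a data frame with columns id, sire, dam")
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$sire[is.na(ped$sire) | ped$sire == "0" | ped$sire == ""] <- NA
  ped$dam[is.na(ped$dam) | ped$dam == "0" | ped$dam == ""] <- NA
  .check(!anyDuplicated(ped$id), "duplicated animal ids in pedigree")
  unknown <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA))
  .check(length(unknown) == 0,
         paste0("parents absent from the pedigree: ",
                paste(utils::head(unknown, 5), collapse = ", ")))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  ## Kahn topological sort over parent -> offspring edges
  indeg <- (si > 0) + (di > 0)
  children <- vector("list", n)
  for (i in idx) {
    if (si[i] > 0) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  ## stable Kahn sort: always emit the smallest input index next, so a
  ## pedigree already in parents-first order keeps its row order
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue)) {
    queue <- sort(queue)
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  .check(length(order) == n,
         "pedigree contains a loop: an animal is its own ancestor")
  ped <- ped[order, , drop = FALSE]
  idx2 <- seq_len(n)
  names(idx2) <- ped$id
  ped$.si <- ifelse(is.na(ped$sire), 0L, unname(idx2[ped$sire]))
  ped$.di <- ifelse(is.na(ped$dam), 0L, unname(idx2[ped$dam]))
  rownames(ped) <- NULL
  ped
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix A, including inbreeding, by the
#' tabular recursion: for animal `i` with parents `s`, `d`,
#' `a(i, j) = (a(s, j) + a(d, j)) / 2` for older `j` and
#' `a(i, i) = 1 + a(s, d) / 2`.
#'
#' @param ped pedigree data frame (`id`, `sire`, `dam`; 0/NA = unknown).
#' @return symmetric numeric matrix with animal ids as dimnames and class
#'   `relmat` (attribute `kind = "A"`).
#' @export
#' @examples
#' ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
#' a_matrix(ped)["1", "3"]   # parent-offspring: 0.5
a_matrix <- function(ped) {
  ped <- normalize_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- ped$.si; di <- ped$.di
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0) row <- row + A[s, j]
      if (d > 0) row <- row + A[d, j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  structure(A, class = c("relmat", "matrix"), kind = "A")
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: the Mendelian-sampling variance of
#' animal `i` is `d_i = 0.5 - 0.25 (F_s + F_d)` (with the usual adjustments
#' for unknown parents), and `A^-1 = sum_i (1/d_i) w_i w_i'` where `w_i` has
#' 1 at `i` and -1/2 at each known parent. Inbreeding coefficients are taken
#' from the tabular A, so the result agrees with `solve(a_matrix(ped))` to
#' numerical precision.
#'
#' @inheritParams a_matrix
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with id dimnames.
#' @export
a_inverse <- function(ped) {
  ped <- normalize_pedigree(ped)
  n <- nrow(ped)
  Fcoef <- diag(a_matrix(ped)) - 1
  si <- ped$.si; di <- ped$.di
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    Fs <- if (s > 0) Fcoef[s] else -1   # unknown parent contributes F = -1
    Fd <- if (d > 0) Fcoef[d] else -1   # (i.e. drops the 0.25 term wholly)
    dvar <- 0.5 - 0.25 * (Fs + Fd)
    w_idx <- c(i, if (s > 0) s, if (d > 0) d)
    w_val <- c(1, if (s > 0) -0.5, if (d > 0) -0.5)
    for (a in seq_along(w_idx)) for (b in seq_along(w_idx)) {
      ii <- c(ii, w_idx[a]); jj <- c(jj, w_idx[b])
      xx <- c(xx, w_val[a] * w_val[b] / dvar)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p (1 - p))` with `Z = M - 2p`, where `M` is the
#' individuals-by-markers dosage matrix (0/1/2) and `p` the allele
#' frequencies. Monomorphic markers carry no information and are dropped
#' with a message.
#'
#' @param panel a `genotype_panel` or a plain dosage matrix with individual
#'   ids as rownames.
#' @param p optional allele-frequency vector (one per marker); defaults to
#'   frequencies observed in the genotyped set.
#' @return symmetric `relmat` (kind `"G"`).
#' @export
g_matrix <- function(panel, p = NULL) {
  M <- dosage_matrix(panel)
  .check(!anyNA(M), "dosage matrix contains missing values; run QC first")
  if (is.null(p)) p <- colMeans(M) / 2
  .check(length(p) == ncol(M), "p must have one frequency per marker")
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    .check(any(poly), "all markers are monomorphic; G is undefined")
    message(sum(!poly), " monomorphic marker(s) dropped before G")
    M <- M[, poly, drop = FALSE]
    p <- p[poly]
  }
  Z <- sweep(M, 2, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- .symmetrize(tcrossprod(Z) / denom)
  structure(G, class = c("relmat", "matrix"), kind = "G",
            scale_denom = denom)
}

#' Rescale G to the scale and location of A22
#'
#' Solves the two matching equations
#' `avg.diag(G) * beta + alpha = avg.diag(A22)` and
#' `avg.offdiag(G) * beta + alpha = avg.offdiag(A22)` and returns
#' `Ga = G * beta + alpha` (alpha added to every element), so that the
#' average diagonal and off-diagonal of Ga equal those of A22 exactly.
#'
#' @param G genomic relationship matrix (same id order as `A22`).
#' @param A22 pedigree-relationship sub-block for the genotyped animals.
#' @return list with `Ga` (relmat, kind `"Ga"`), `alpha`, `beta`.
#' @export
adjust_g <- function(G, A22) {
  .check(is.matrix(G) && is.matrix(A22) && all(dim(G) == dim(A22)),
         "G and A22 must be matrices of identical dimension")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)))
    .check(identical(rownames(G), rownames(A22)),
           "G and A22 must share the same id order")
  n <- nrow(G)
  .check(n >= 2, "need at least two animals to match off-diagonals")
  off <- row(G) != col(G)
  dG <- mean(diag(G)); oG <- mean(G[off])
  dA <- mean(diag(A22)); oA <- mean(A22[off])
  .check(abs(dG - oG) > 1e-12,
         "avg.diag(G) equals avg.offdiag(G): matching system is singular")
  beta <- (dA - oA) / (dG - oG)
  alpha <- dA - dG * beta
  Ga <- G * beta + alpha
  list(Ga = structure(.symmetrize(Ga), class = c("relmat", "matrix"),
                      kind = "Ga"),
       alpha = alpha, beta = beta)
}

#' Blend the adjusted genomic matrix with A22
#'
#' `Gw = w * Ga + (1 - w) * A22`; the default `w = 0.95` keeps 5% pedigree
#' relationship in the matrix to avoid singularity.
#'
#' @param Ga adjusted genomic matrix.
#' @param A22 pedigree sub-block, same id order.
#' @param w blending weight in `[0, 1]`.
#' @return `relmat` of kind `"Gw"`.
#' @export
blend_g <- function(Ga, A22, w = 0.95) {
  .check(.is_scalar(w) && w >= 0 && w <= 1, "w must lie in [0, 1]")
  .check(all(dim(Ga) == dim(A22)), "Ga and A22 must match in dimension")
  structure(.symmetrize(w * Ga + (1 - w) * A22),
            class = c("relmat", "matrix"), kind = "Gw")
}

#' Single-step H inverse, stored as parts
#'
#' `H^-1 = A^-1 + [[Gw^-1 - A22^-1, 0], [0, 0]]` with the correction block on
#' the genotyped animals. The sparse pedigree part and the dense genotyped
#' correction are kept separate; use [assemble_h_inverse()] for the dense
#' matrix.
#'
#' @param ped pedigree data frame covering all animals.
#' @param Gw blended genomic matrix for the genotyped animals (id dimnames).
#' @param genotyped_ids character ids of genotyped animals (defaults to
#'   `rownames(Gw)`); must be a subset of the pedigree ids.
#' @return object of class `h_inverse_parts` with elements `A_inv`,
#'   `correction` (dense, `Gw^-1 - A22^-1`), `genotyped_ids`, `ids`.
#' @export
h_inverse <- function(ped, Gw, genotyped_ids = rownames(Gw)) {
  ped <- normalize_pedigree(ped)
  Ainv <- a_inverse(ped)
  ids <- ped$id
  .check(all(genotyped_ids %in% ids),
         "genotyped_ids must all appear in the pedigree")
  if (length(genotyped_ids) == 0) {
    parts <- list(A_inv = Ainv, correction = NULL,
                  genotyped_ids = character(0), ids = ids)
    class(parts) <- "h_inverse_parts"
    return(parts)
  }
  .check(is.matrix(Gw) && identical(rownames(Gw), genotyped_ids),
         "Gw rownames must equal genotyped_ids (same order)")
  A <- a_matrix(ped)
  A22 <- A[genotyped_ids, genotyped_ids, drop = FALSE]
  Gw_inv <- tryCatch(chol2inv(chol(Gw)),
                     error = function(e) stop("Gw is singular: ",
                                              conditionMessage(e), call. = FALSE))
  A22_inv <- chol2inv(chol(A22))
  corr <- .symmetrize(Gw_inv - A22_inv)
  dimnames(corr) <- list(genotyped_ids, genotyped_ids)
  parts <- list(A_inv = Ainv, correction = corr,
                genotyped_ids = genotyped_ids, ids = ids)
  class(parts) <- "h_inverse_parts"
  parts
}

#' Assemble the dense single-step H inverse
#'
#' @param parts an `h_inverse_parts` object from [h_inverse()].
#' @return dense symmetric matrix over all pedigree ids.
#' @export
assemble_h_inverse <- function(parts) {
  .check(inherits(parts, "h_inverse_parts"), "parts must come from h_inverse()")
  H <- as.matrix(parts$A_inv)
  if (length(parts$genotyped_ids)) {
    g <- match(parts$genotyped_ids, parts$ids)
    H[g, g] <- H[g, g] + parts$correction
  }
  dimnames(H) <- list(parts$ids, parts$ids)
  .symmetrize(H)
}

#' Dense single-step H matrix (for tests and small problems)
#'
#' @inheritParams assemble_h_inverse
#' @return dense H, the inverse of the assembled H inverse.
#' @export
h_matrix <- function(parts) {
  Hinv <- assemble_h_inverse(parts)
  H <- chol2inv(chol(Hinv))
  dimnames(H) <- dimnames(Hinv)
  .symmetrize(H)
}
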