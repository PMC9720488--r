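# Relationship matrices: pedigree-based additive relationships (tabular
# method) and the VanRaden (2008, method 1) genomic relationship matrix.

#' Pedigree-based additive relationship matrix (A)
#'
#' Tabular method on a topologically ordered pedigree: for animal i with
#' parents s and d, a_ii = 1 + a_sd / 2 and a_ij = (a_js + a_jd) / 2 for
#' every earlier animal j; an unknown parent contributes 0.  The pedigree
#' is validated (and reordered parents-first) internally; a cycle is an
#' error.
#'
#' @param ped pedigree data.frame (`animal`, `sire`, `dam`).
#' @return symmetric numeric matrix with dimnames = animal ids, carrying
#'   attribute `kind = "pedigree_A"`.
#' @export
additive_relationship_matrix <- function(ped) {
  ped <- validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (is.na(s)) 0 else A[s, j]
      row_d <- if (is.na(d)) 0 else A[d, j]
      aij <- (row_s + row_d) / 2
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else A[s, d] / 2
  }
  attr(A, "kind") <- "pedigree_A"
  A
}

#' VanRaden genomic relationship matrix (G)
#'
#' Method 1 of VanRaden (2008): G = W W' / (2 * sum_j p_j (1 - p_j)),
#' where W = M - 2p with M the 0/1/2 call matrix and p_j the allele
#' frequency observed in the sample.  Missing calls are mean-imputed
#' (W entry 0, zero contribution); monomorphic SNPs contribute to
#' neither numerator nor denominator.
#'
#' @param panel a [geno_panel()] (QC'd; at least 2 polymorphic SNPs
#'   recommended, at least 1 required).
#' @return symmetric numeric matrix over the panel's individuals with
#'   attribute `kind = "genomic_G"`.
#' @export
vanraden_grm <- function(panel) {
  stopifnot(inherits(panel, "geno_panel"))
  M <- panel$calls
  storage.mode(M) <- "double"
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("all SNPs are monomorphic; G is undefined", call. = FALSE)
  M <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(M, 2L, 2 * p)
  W[is.na(W)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(panel$calls), rownames(panel$calls))
  attr(G, "kind") <- "genomic_G"
  G
}

#' Blend a relationship matrix with the identity
#'
#' G* = (1 - w) G + w I.  A small blend weight bounds the smallest
#' eigenvalue away from zero so mixed-model equations using G* are
#' well-conditioned.
#'
#' @param G square symmetric relationship matrix.
#' @param blend_weight w in \[0, 1).
#' @return the blended matrix (dimnames and `kind` preserved).
#' @export
stabilize_grm <- function(G, blend_weight = 0.01) {
  if (blend_weight < 0 || blend_weight >= 1)
    stop("blend_weight must be in [0, 1)", call. = FALSE)
  if (!is.matrix(G) || nrow(G) != ncol(G))
    stop("G must be a square matrix", call. = FALSE)
  if (max(abs(G - t(G))) > 1e-8)
    stop("G must be symmetric", call. = FALSE)
  out <- (1 - blend_weight) * G + blend_weight * diag(nrow(G))
  dimnames(out) <- dimnames(G)
  attr(out, "kind") <- attr(G, "kind")
  out
}

#' Eigendecomposition of a relationship matrix over chosen individuals
#'
#' One-off spectral decomposition reused across REML fits and GWAS runs
#' on the same kinship.  Eigenvalues are clipped at zero to guard against
#' numerically tiny negatives.
#'
#' @param K relationship matrix with id dimnames.
#' @param ids individuals to keep, in order; default all.
#' @return list `ids`, `values`, `vectors` (class `kinship_eigen`).
#' @export
kinship_eigen <- function(K, ids = rownames(K)) {
  if (is.null(rownames(K)))
    stop("K must carry individual ids as dimnames", call. = FALSE)
  j <- match(ids, rownames(K))
  if (anyNA(j))
    stop("individual(s) absent from K: ",
         paste(utils::head(ids[is.na(j)], 5L), collapse = ", "),
         call. = FALSE)
  e <- eigen(K[j, j, drop = FALSE], symmetric = TRUE)
  structure(list(ids = ids, values = pmax(e$values, 0),
                 vectors = e$vectors),
            class = "kinship_eigen")
}
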