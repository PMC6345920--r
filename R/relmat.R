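# Pedigree numerator (A), gametic (2n x 2n) and genomic relationship
# matrices. All are returned as dense base matrices with individual (or
# gamete) ids as dimnames; they are symmetric and suited to the desk-scale
# pedigrees the mixed models operate on.

# Sort a pedigree parents-before-offspring; error on cycles.
.sortPedigree <- function(ped) {
  n <- nrow(ped)
  pos <- match(ped$sire, ped$id)
  pom <- match(ped$dam, ped$id)
  if (any(ped$sire == ped$id) || any(ped$dam == ped$id))
    stop("individual listed as its own parent")
  ord <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- !placed &
      (ped$sire == 0L | is.na(pos) | placed[ifelse(is.na(pos), 1L, pos)]) &
      (ped$dam == 0L | is.na(pom) | placed[ifelse(is.na(pom), 1L, pom)])
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) {
      if (all(placed)) break
      stop("pedigree contains a cycle (individual is its own ancestor)")
    }
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
    if (all(placed)) break
  }
  ped[ord, , drop = FALSE]
}

.checkPed <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree needs columns 'id', 'sire', 'dam'")
  ped$sire[is.na(ped$sire)] <- 0L
  ped$dam[is.na(ped$dam)] <- 0L
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  miss <- setdiff(c(ped$sire, ped$dam), c(0L, ped$id))
  if (length(miss))
    stop("parents absent from pedigree: ", paste(miss, collapse = ", "))
  ped
}

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular-method additive relationship matrix, including inbreeding (e.g.
#' from selfing: a selfed offspring of a non-inbred parent has diagonal 1.5
#' and relationship 1 to its parent). The pedigree is sorted internally so
#' parents precede offspring; unknown parents are coded 0 or `NA`.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`.
#' @return symmetric matrix with ids as dimnames, diagonal `1 + F`.
#' @export
numeratorA <- function(pedigree) {
  ped <- .sortPedigree(.checkPed(pedigree))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  ps <- match(ped$sire, ped$id)
  pd <- match(ped$dam, ped$id)
  for (k in seq_len(n)) {
    s <- ps[k]; d <- pd[k]
    if (k > 1L) {
      j <- seq_len(k - 1L)
      row <- 0.5 * ((if (!is.na(s)) A[s, j] else 0) +
                    (if (!is.na(d)) A[d, j] else 0))
      A[k, j] <- row
      A[j, k] <- row
    }
    A[k, k] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  # return in the caller's id order
  ord <- match(.checkPed(pedigree)$id, ped$id)
  A[ord, ord, drop = FALSE]
}

#' Gametic relationship matrix (2n x 2n)
#'
#' Identity-by-descent relationships among the paternal and maternal gametes
#' of all individuals. Founder gametes are unrelated with diagonal 1; the
#' paternal gamete of a non-founder relates to any other gamete g as
#' `0.5 * (rel(sire paternal, g) + rel(sire maternal, g))`, and likewise for
#' the maternal gamete through the dam. The numerator matrix is recovered by
#' averaging the four gamete-pair relationships of two individuals:
#' `a_ij = 0.5 * sum(G[gametes_i, gametes_j])`.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`.
#' @return symmetric 2n x 2n matrix; rows named `<id>.p` / `<id>.m`.
#' @export
gameticRel <- function(pedigree) {
  ped <- .sortPedigree(.checkPed(pedigree))
  n <- nrow(ped)
  G <- matrix(0, 2L * n, 2L * n)
  ps <- match(ped$sire, ped$id)
  pd <- match(ped$dam, ped$id)
  gi <- function(k) c(2L * k - 1L, 2L * k)
  for (k in seq_len(n)) {
    rp <- 2L * k - 1L; rm <- 2L * k
    prev <- seq_len(rp - 1L)
    if (!is.na(ps[k])) {
      g <- gi(ps[k])
      G[rp, prev] <- 0.5 * (G[g[1L], prev] + G[g[2L], prev])
      G[prev, rp] <- G[rp, prev]
    }
    G[rp, rp] <- 1
    prev <- seq_len(rm - 1L)
    if (!is.na(pd[k])) {
      g <- gi(pd[k])
      G[rm, prev] <- 0.5 * (G[g[1L], prev] + G[g[2L], prev])
      G[prev, rm] <- G[rm, prev]
    }
    G[rm, rm] <- 1
  }
  nm <- as.vector(rbind(paste0(ped$id, ".p"), paste0(ped$id, ".m")))
  dimnames(G) <- list(nm, nm)
  ord <- match(.checkPed(pedigree)$id, ped$id)
  keep <- as.vector(rbind(2L * ord - 1L, 2L * ord))
  G[keep, keep, drop = FALSE]
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum(p_k q_k))` with `Z = M - 2p`, where `M` are gene
#' counts and `p` the allele frequencies (estimated from the data when not
#' supplied). With frequencies from the same data the off-diagonal mean is
#' approximately zero.
#'
#' @param geneCounts individuals x markers matrix of 0/1/2 gene counts.
#' @param freqs optional allele frequencies per marker.
#' @return symmetric matrix with individual ids as dimnames.
#' @export
genomicRel <- function(geneCounts, freqs = NULL) {
  M <- as.matrix(geneCounts)
  if (anyNA(M)) stop("gene counts must be complete (impute upstream)")
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("all markers monomorphic: genomic relationship undefined")
  Z <- sweep(M, 2L, 2 * freqs)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' Blend a genomic with a pedigree relationship matrix
#'
#' Elementwise convex combination `(1 - weight) * G + weight * A`, used to
#' restore full rank when the genomic matrix is rank deficient (more
#' individuals than effective markers). Positive definiteness of the result
#' is verified by Cholesky factorization.
#'
#' @param G genomic relationship matrix.
#' @param A numerator relationship matrix on the same individuals, in the
#'   same order.
#' @param weight weight on `A` (default 0.05, i.e. 5% blending).
#' @return blended symmetric positive definite matrix.
#' @export
blendRel <- function(G, A, weight = 0.05) {
  if (!identical(dim(G), dim(A)))
    stop("'G' and 'A' must have identical dimensions")
  if (!is.null(dimnames(G)) && !is.null(dimnames(A)) &&
      !identical(rownames(G), rownames(A)))
    stop("'G' and 'A' must be indexed by the same individuals in the same order")
  B <- (1 - weight) * G + weight * A
  ok <- tryCatch({ chol(B); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("blended matrix is not positive definite; increase 'weight' ",
         "(minimum eigenvalue ", format(min(eigen(B, symmetric = TRUE,
                                                  only.values = TRUE)$values),
                                        digits = 3), ")")
  B
}
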