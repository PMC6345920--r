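# Shared fixtures: small simulated populations, random pedigrees and
# brute-force oracles used across the test files.

# Small two-generation population (defaults scaled down from the study
# design; study-scale runs live in the acceptance tests).
tinyTwoGen <- function(nParents = 20, off = 2, seed = 1, ...) {
  cfg <- simConfig("two_gen", nParents = nParents,
                   offspringPerFamily = off, ...)
  simulatePopulation(cfg, seed = seed)
}

# Random pedigree: founders followed by individuals whose parents are drawn
# from all earlier individuals (selfing possible when allowSelf).
randomPedigree <- function(nFounders, nTotal, seed, allowSelf = TRUE) {
  set.seed(seed)
  id <- seq_len(nTotal)
  sire <- dam <- integer(nTotal)
  for (k in (nFounders + 1L):nTotal) {
    sire[k] <- sample.int(k - 1L, 1L)
    dam[k] <- if (allowSelf) sample.int(k - 1L, 1L) else
      sample(setdiff(seq_len(k - 1L), sire[k]), 1L)
  }
  data.frame(id = id, sire = sire, dam = dam)
}

# Drop a biallelic locus through a pedigree; returns gene counts.
dropLocus <- function(ped, p = 0.5) {
  n <- nrow(ped)
  a1 <- a2 <- integer(n)
  for (k in seq_len(n)) {
    a1[k] <- if (ped$sire[k] == 0L) rbinom(1, 1, p) else
      if (runif(1) < 0.5) a1[ped$sire[k]] else a2[ped$sire[k]]
    a2[k] <- if (ped$dam[k] == 0L) rbinom(1, 1, p) else
      if (runif(1) < 0.5) a1[ped$dam[k]] else a2[ped$dam[k]]
  }
  a1 + a2
}

# Brute-force BH step-up: flags the smallest k p-values where
# p_(k) <= q * k / m, k maximal.
bhBrute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- ps <= q * seq_len(m) / m
  flag <- logical(m)
  if (any(ok)) flag[o[seq_len(max(which(ok)))]] <- TRUE
  flag
}

# Dense-marginal GLS/BLUP oracle for the absorbed parent model: builds the
# full covariance V = Z G0 Z' + R explicitly and computes REML quantities
# with generic matrix algebra, independent of the MME route.
parentModelOracle <- function(y, sireIdx, damIdx, A, vs, vd, cv, ve,
                              X = NULL) {
  q <- nrow(A)
  n <- length(y)
  if (is.null(X)) X <- cbind(rep(1, n))
  Z <- matrix(0, n, 2 * q)
  Z[cbind(seq_len(n), sireIdx)] <- 1
  Z[cbind(seq_len(n), q + damIdx)] <- 1
  G0 <- rbind(cbind(vs * A, cv * A), cbind(cv * A, vd * A))
  Fp <- diag(A) - 1
  R <- diag(ve + (1 - Fp[sireIdx]) * vs + (1 - Fp[damIdx]) * vd)
  V <- Z %*% G0 %*% t(Z) + R
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  u <- G0 %*% t(Z) %*% Vi %*% r
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  m2ll <- (n - ncol(X)) * log(2 * pi) +
    determinant(V, logarithm = TRUE)$modulus +
    determinant(XtVX, logarithm = TRUE)$modulus +
    t(y) %*% P %*% y
  list(fixef = as.numeric(b), taSire = u[seq_len(q)],
       taDam = u[q + seq_len(q)], logLik = -0.5 * as.numeric(m2ll))
}
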