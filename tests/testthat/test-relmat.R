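# Relationship matrices: tabular A, gametic matrix, genomic matrix and
# blending.

test_that("numerator A reproduces textbook relationships", {
  founders <- data.frame(id = 1:3, sire = 0L, dam = 0L)
  expect_equal(numeratorA(founders), diag(3),
               ignore_attr = TRUE)
  ped <- rbind(founders, data.frame(id = 4, sire = 1, dam = 2),
               data.frame(id = 5, sire = 1, dam = 2))
  A <- numeratorA(ped)
  expect_equal(A["4", "1"], 0.5)          # parent-offspring
  expect_equal(A["4", "5"], 0.5)          # full sibs of unrelated parents
  expect_equal(A["4", "4"], 1)            # unrelated parents: not inbred
  # selfing: diagonal 1.5, relationship 1 to the single parent
  peds <- rbind(founders, data.frame(id = 4, sire = 1, dam = 1))
  As <- numeratorA(peds)
  expect_equal(As["4", "4"], 1.5)
  expect_equal(As["4", "1"], 1)
  # order-insensitive: shuffled pedigree gives the same matrix
  sh <- peds[c(4, 2, 1, 3), ]
  expect_equal(numeratorA(sh)[rownames(As), colnames(As)], As)
  # an individual cannot be its own ancestor
  bad <- data.frame(id = 1:2, sire = c(2, 1), dam = 0L)
  expect_error(numeratorA(bad), "cycle|parent")
})

test_that("gametic matrix: founder identity and parent-gamete transmission", {
  ped <- data.frame(id = 1:2, sire = 0L, dam = 0L)
  expect_equal(gameticRel(ped), diag(4), ignore_attr = TRUE)
  ped <- rbind(ped, data.frame(id = 3, sire = 1, dam = 2))
  G <- gameticRel(ped)
  expect_equal(G["3.p", "1.p"], 0.5)
  expect_equal(G["3.p", "1.m"], 0.5)
  expect_equal(G["3.p", "2.p"], 0)
  expect_equal(diag(G), rep(1, 6), ignore_attr = TRUE)
})

test_that("gametic matrix collapses to tabular A on random pedigrees", {
  for (seed in 1:4) {
    ped <- randomPedigree(5, 50, seed = seed)
    A <- numeratorA(ped)
    G <- gameticRel(ped)
    n <- nrow(ped)
    collapse <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gi <- c(2 * i - 1, 2 * i); gj <- c(2 * j - 1, 2 * j)
      collapse[i, j] <- 0.5 * sum(G[gi, gj])
    }
    expect_equal(collapse, unname(A), tolerance = 1e-12)
    expect_equal(A, t(A))
    expect_equal(G, t(G))
  }
})

test_that("genomic relationship matrix follows VanRaden method 1", {
  set.seed(2)
  M <- matrix(rbinom(20 * 50, 2, 0.4), 20, 50,
              dimnames = list(1:20, NULL))
  M[2, ] <- M[1, ]                        # identical genotypes
  G <- genomicRel(M)
  expect_equal(G[1, ], G[2, ], ignore_attr = TRUE)
  expect_equal(G[1, 2], G[1, 1])
  expect_equal(G, t(G))
  # centering with observed frequencies: columns of Z sum to zero, so all
  # entries of G sum to zero exactly and the off-diagonal mean is the small
  # negative -trace/(n-1) counterweight
  expect_equal(sum(G), 0, tolerance = 1e-10)
  off <- G[upper.tri(G)]
  expect_equal(mean(off), -sum(diag(G)) / (nrow(G) * (nrow(G) - 1)))
  # all-heterozygous individual at p = 0.5 has Z = 0, so diagonal 0
  M2 <- rbind(het = rep(1, 10), a = rep(0, 10), b = rep(2, 10))
  G2 <- genomicRel(M2, freqs = rep(0.5, 10))
  expect_equal(G2["het", "het"], 0)
  expect_error(genomicRel(matrix(2, 4, 3)), "monomorphic")
})

test_that("blending restores positive definiteness and is convex", {
  set.seed(5)
  M <- matrix(rbinom(30 * 8, 2, 0.5), 30, 8,
              dimnames = list(1:30, NULL))   # more individuals than markers
  G <- genomicRel(M)
  expect_error(chol(G))                      # rank deficient
  ped <- data.frame(id = 1:30, sire = 0L, dam = 0L)
  A <- numeratorA(ped)
  dimnames(A) <- dimnames(G)
  B <- blendRel(G, A, weight = 0.05)
  expect_silent(chol(B))
  expect_equal(B, 0.95 * G + 0.05 * A)
  expect_equal(blendRel(G, A, weight = 1), A)
  expect_error(blendRel(G[1:5, 1:5], A), "dimensions")
})
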