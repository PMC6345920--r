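# Population simulator: QTL calibration, founder LD, recombination,
# design layouts and true genetic values.

test_that("QTL effects are calibrated from the variance shares", {
  e <- calibrateQtlEffects("paternal_full", 0.5, 0.05, 0.25)
  expect_equal(unname(e["alpha"]), sqrt(0.05 * 1.35 / 0.5), tolerance = 1e-10)
  expect_equal(unname(e["alpha"]), unname(e["i"]))   # maternal copy silent
  lp <- locusParams(0.5, a = e["alpha"], i = e["i"])
  expect_equal(unname(substitutionEffects(lp)["alphaM"]), 0)
  e <- calibrateQtlEffects("mendelian", 0.4, 0.30, 0)
  expect_equal(unname(e["alpha"]), sqrt(0.405 / 0.48), tolerance = 1e-10)
  expect_equal(unname(e["i"]), 0)
  e <- calibrateQtlEffects("maternal_partial", 0.5, 0.30, 0.25)
  expect_equal(unname(e["alpha"]), 0.9, tolerance = 1e-10)
  expect_equal(unname(e["i"]), -sqrt(0.25 * 0.27 / 0.5), tolerance = 1e-10)
  expect_error(calibrateQtlEffects("mendelian", 0, 0.3, 0), "maf")
})

test_that("founder haplotypes carry the configured marker-QTL LD", {
  cfg <- simConfig("two_gen")
  loci <- poescan:::.buildLoci(cfg)
  set.seed(11)
  fo <- sampleFounders(4e4, loci, D = 0.1)
  m <- fo$hap1[, 5]; qa <- fo$hap1[, 17]    # marker 5 and its QTL
  Dhat <- mean(m * qa) - mean(m) * mean(qa)
  expect_equal(Dhat, 0.1, tolerance = 0.05)
  expect_equal(mean(m[qa == 1]), 0.7, tolerance = 0.02)
  expect_equal(cor(m, qa)^2, 0.16, tolerance = 0.05)
  # D = 0: marker and QTL independent
  fo0 <- sampleFounders(4e4, loci, D = 0)
  D0 <- mean(fo0$hap1[, 5] * fo0$hap1[, 17]) -
    mean(fo0$hap1[, 5]) * mean(fo0$hap1[, 17])
  expect_lt(abs(D0), 0.01)
  # infeasible D errors
  expect_error(sampleFounders(10, loci, D = 0.3), "incompatible")
})

test_that("recombination follows the Haldane map function", {
  cfg <- simConfig("two_gen")
  loci <- poescan:::.buildLoci(cfg)
  hapP <- matrix(1L, 1, nrow(loci))
  hapM <- matrix(0L, 1, nrow(loci))
  set.seed(4)
  g <- poescan:::.gamete(hapP, hapM, rep(1L, 1e5), loci)
  cHald <- 0.5 * (1 - exp(-0.2))
  expect_equal(mean(g[, 5] != g[, 17]), cHald, tolerance = 0.05)
  expect_equal(mean(g[, 1] == g[, 3]), 0.5, tolerance = 0.02)
  # zero map distance: complete co-segregation
  cfg0 <- simConfig("two_gen", qtls = within(defaultQtls(), mapDistCM <- 0))
  loci0 <- poescan:::.buildLoci(cfg0)
  g0 <- poescan:::.gamete(hapP, hapM, rep(1L, 5e3), loci0)
  expect_true(all(g0[, 5] == g0[, 17]))
})

test_that("two-generation design produces the cross-classified layout", {
  pop <- tinyTwoGen(nParents = 10, off = 2, seed = 3)
  ped <- pedigree(pop)
  expect_equal(sum(ped$generation == 2), 10 * 10 * 2)
  expect_true(all(is.na(phenotypes(pop)[ped$generation == 1])))
  expect_true(all(!is.na(phenotypes(pop)[ped$generation == 2])))
  # each ordered parent pair appears with the configured family size
  fam <- table(paste(ped$sire[ped$generation == 2],
                     ped$dam[ped$generation == 2]))
  expect_true(all(fam == 2))
  # the study-scale design yields 30,000 offspring records
  popFull <- simulatePopulation(simConfig("two_gen"), seed = 2)
  expect_equal(sum(!is.na(phenotypes(popFull))), 30000)
  v <- var(phenotypes(popFull), na.rm = TRUE)
  expect_equal(v, 1.35 + 0.27 + 2, tolerance = 0.08)
})

test_that("phenotypic variance collapses to the residual without QTL effects", {
  qtls <- defaultQtls()
  qtls$shareVa <- 0; qtls$shareVi <- 0
  pop <- simulatePopulation(simConfig("two_gen", nParents = 40,
                                      offspringPerFamily = 2, qtls = qtls),
                            seed = 8)
  expect_equal(var(phenotypes(pop), na.rm = TRUE), 2, tolerance = 0.1)
  expect_equal(truePOE(pop), rep(0, nrow(pedigree(pop))))
})

test_that("true POEs follow the ordered-genotype table", {
  pop <- tinyTwoGen(nParents = 50, off = 1, seed = 5)
  loci <- pop@loci
  qrows <- which(loci$type == "qtl")
  # hand evaluation: dam-minus-sire sum of -i * (gc - 2p) across QTL
  gcq <- geneCounts(pop, type = "qtl")
  hand <- -as.vector(gcq %*% loci$i[qrows]) +
    sum(2 * loci$p[qrows] * loci$i[qrows])
  expect_equal(truePOE(pop), hand)
  # population mean near zero at scale
  popFull <- simulatePopulation(simConfig("two_gen"), seed = 9)
  expect_lt(abs(mean(truePOE(popFull))), 0.05)
  # regression of true POE on a QTL's own gene count recovers -i
  # (dam-minus-sire convention), per the closed-form oracle; noise is
  # driven by the between-QTL sampling covariance among the founders
  popBig <- simulatePopulation(simConfig("two_gen", nParents = 500,
                                         offspringPerFamily = 1), seed = 10)
  gcq <- geneCounts(popBig, type = "qtl", ids = 1:500)
  i2 <- loci$i[qrows[2]]
  b <- coef(lm(truePOE(popBig, 1:500) ~ gcq[, 2]))[2]
  expect_equal(unname(b), -i2, tolerance = 0.15)
})

test_that("three-generation design: sizes, retention and phenotype placement", {
  cfg <- simConfig("three_gen")
  st <- popStructure(cfg, seed = 21)
  expect_equal(sum(st$gpFamilies$n), st$nParents)
  expect_gt(st$nParents, 400); expect_lt(st$nParents, 600)
  expect_equal(st$nRetained / st$nPossible, 0.03, tolerance = 0.15)
  pop <- simulatePopulation(cfg, seed = 22, structure = st)
  ped <- pedigree(pop)
  expect_true(all(is.na(phenotypes(pop)[ped$generation < 3])))
  expect_true(all(!is.na(phenotypes(pop)[ped$generation == 3])))
})

test_that("replicates share the pedigree but redraw genotypes", {
  cfg <- simConfig("three_gen", nGrandparents = 6, nGpFamilies = 20,
                   familySizeMean = 3, retention = 0.05)
  st <- popStructure(cfg, seed = 31)
  p1 <- simulatePopulation(cfg, seed = 32, structure = st)
  p2 <- simulatePopulation(cfg, seed = 33, structure = st)
  expect_identical(pedigree(p1), pedigree(p2))
  expect_false(identical(p1@hapPat, p2@hapPat))
  # determinism under a fixed seed
  p3 <- simulatePopulation(cfg, seed = 32, structure = st)
  expect_identical(p1@hapPat, p3@hapPat)
  expect_identical(phenotypes(p1), phenotypes(p3))
})
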