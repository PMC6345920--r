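# Mixed-model engines: REML correctness against closed forms and dense
# oracles, equivalence of the absorbed and full gametic models, and the
# behaviour of the single-marker fit.

test_that("kinship REML matches the one-way ANOVA closed form and lme4", {
  set.seed(10)
  a <- 25; m <- 6                        # balanced one-way layout
  vu <- 2; ve <- 3
  g <- rep(rnorm(a, 0, sqrt(vu)), each = m)
  y <- 5 + g + rnorm(a * m, 0, sqrt(ve))
  grp <- rep(seq_len(a), each = m)
  K <- outer(grp, grp, "==") * 1
  X <- cbind(rep(1, a * m))
  ft <- poescan:::.kinshipReml(y, X, K, rep(1, a * m))
  # closed-form REML for the balanced one-way random-effects model
  ybar <- tapply(y, grp, mean)
  msa <- m * sum((ybar - mean(y))^2) / (a - 1)
  mse <- sum((y - ybar[grp])^2) / (a * (m - 1))
  expect_equal(unname(ft$varcomp["sigma2e"]), mse, tolerance = 1e-6)
  expect_equal(unname(ft$varcomp["sigma2u"]), (msa - mse) / m,
               tolerance = 1e-5)
  skip_if_not_installed("lme4")
  lf <- lme4::lmer(y ~ 1 + (1 | grp), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(ft$varcomp["sigma2u"]), vc$vcov[1], tolerance = 1e-4)
  expect_equal(unname(ft$varcomp["sigma2e"]), vc$vcov[2], tolerance = 1e-4)
  expect_equal(ft$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-4)
})

test_that("parent-model likelihood and BLUPs match the dense marginal oracle", {
  set.seed(20)
  ped <- randomPedigree(6, 12, seed = 7)
  A <- numeratorA(ped)
  q <- nrow(A)
  nrec <- 40
  sireIdx <- sample.int(q, nrec, replace = TRUE)
  damIdx <- sample.int(q, nrec, replace = TRUE)
  y <- rnorm(nrec, 3, 1.5)
  vs <- 0.5; vd <- 0.4; cv <- 0.25; ve <- 1.2
  eng <- poescan:::.remlParentModel(
    y, sireIdx, damIdx, A, model = "imprinting", fixed = TRUE,
    start = c(sigma2s = vs, sigma2d = vd, sigmasd = cv, sigma2e = ve))
  ora <- parentModelOracle(y, sireIdx, damIdx, A, vs, vd, cv, ve)
  expect_equal(eng$logLik, ora$logLik, tolerance = 1e-8)
  expect_equal(unname(eng$fixef), ora$fixef, tolerance = 1e-8)
  expect_equal(eng$taSire, ora$taSire, tolerance = 1e-8)
  expect_equal(eng$taDam, ora$taDam, tolerance = 1e-8)
})

test_that("absorbed fit equals the full gametic mixed model (incl. selfing)", {
  set.seed(9)
  nf <- 6
  ped <- data.frame(id = 1:nf, sire = 0L, dam = 0L)
  mat <- data.frame(sire = c(1, 1, 2, 3, 4, 5, 6, 2, 3),
                    dam  = c(2, 3, 4, 5, 6, 6, 6, 2, 1))  # includes selfing
  off <- do.call(rbind, lapply(seq_len(nrow(mat)), function(k)
    data.frame(sire = mat$sire[k], dam = mat$dam[k])[rep(1, 2), ]))
  off$id <- nf + seq_len(nrow(off))
  ped <- rbind(ped, off[, c("id", "sire", "dam")])
  y <- rnorm(nrow(off), 2, 1.5)
  Sig <- matrix(c(0.8, 0.5, 0.5, 0.7), 2)   # gametic scale
  ve <- 1.3
  full <- gameticBlup(y, off$id, ped, Sig, ve)
  A <- numeratorA(ped[1:nf, ])
  eng <- poescan:::.remlParentModel(
    y, match(off$sire, 1:nf), match(off$dam, 1:nf), A,
    model = "imprinting", fixed = TRUE,
    start = c(sigma2s = Sig[1, 1] / 2, sigma2d = Sig[2, 2] / 2,
              sigmasd = Sig[1, 2] / 2, sigma2e = ve))
  expect_equal(eng$logLik, full$logLik, tolerance = 1e-8)
  expect_equal(unname(eng$fixef), unname(full$fixef), tolerance = 1e-8)
  expect_equal(eng$taSire, unname(full$taSire[1:nf]), tolerance = 1e-8)
  expect_equal(eng$taDam, unname(full$taDam[1:nf]), tolerance = 1e-8)
})

test_that("imprinting model: no-imprinting data yield near-zero ePOE variance
           and ePOEs track true POEs otherwise", {
  qtls <- defaultQtls()
  qtls$shareVi <- 0
  qtls$pattern <- "mendelian"
  popNull <- simulatePopulation(
    simConfig("two_gen", nParents = 30, offspringPerFamily = 3, qtls = qtls),
    seed = 14)
  fitNull <- fitImprintingModel(popNull)
  vc <- varComponents(fitNull)
  vimp <- unname(vc["sigma2s"] + vc["sigma2d"] - 2 * vc["sigmasd"])
  expect_lt(vimp, 0.08)                      # true value 0
  # imprinted data: ePOEs correlate with true POEs, more offspring help
  pop1 <- tinyTwoGen(nParents = 25, off = 1, seed = 15)
  pop4 <- tinyTwoGen(nParents = 25, off = 4, seed = 15)
  c1 <- cor(resultTable(fitImprintingModel(pop1))$epoe, truePOE(pop1)[1:25])
  c4 <- cor(resultTable(fitImprintingModel(pop4))$epoe, truePOE(pop4)[1:25])
  expect_gt(c1, 0)
  expect_gt(c4, c1)
})

test_that("reliabilities are zero without information and lie in [0, 1]", {
  set.seed(33)
  # direct API with an unconnected founder in the pedigree
  ped <- data.frame(id = 1:5, sire = 0L, dam = 0L)
  y <- rnorm(30, 0, 1)
  fit <- fitImprintingModel(y = y, sire = rep(1:2, 15), dam = rep(3:4, 15),
                            pedigree = ped)
  est <- resultTable(fit)
  expect_equal(est$relEpoe[est$id == 5], 0)
  expect_equal(est$relSire[est$id == 5], 0)
  expect_true(all(est$relSire >= 0 & est$relSire <= 1))
  expect_true(all(est$relEpoe >= 0 & est$relEpoe <= 1))
  # reliabilities do not depend on the overall mean
  fit2 <- fitImprintingModel(y = y + 100, sire = rep(1:2, 15),
                             dam = rep(3:4, 15), pedigree = ped)
  expect_equal(resultTable(fit2)$relEpoe, est$relEpoe, tolerance = 1e-4)
})

test_that("reduced animal model halves breeding values into TAs", {
  pop <- tinyTwoGen(nParents = 30, off = 3, seed = 40)
  fitA <- fitAnimalModel(pop)
  fitI <- fitImprintingModel(pop)
  estA <- resultTable(fitA); estI <- resultTable(fitI)
  # the single TA tracks the average of the two sex-specific TAs
  expect_gt(cor(estA$taSire, (estI$taSire + estI$taDam) / 2), 0.95)
  # a TA equals half the (additive) breeding value, up to BLUP shrinkage:
  # regressing the estimated TA on the parents' true additive BV gives a
  # slope near 0.5
  loci <- pop@loci
  qrows <- which(loci$type == "qtl")
  gcq <- geneCounts(pop, type = "qtl", ids = 1:30)
  alphaQ <- loci$alpha[qrows]
  bvAdd <- as.vector(sweep(gcq, 2, 2 * loci$p[qrows]) %*% alphaQ)
  expect_equal(unname(coef(lm(estA$taSire ~ bvAdd))[2]), 0.5,
               tolerance = 0.25)
})

test_that("marker model reduces to OLS and recovers exact relations", {
  set.seed(50)
  n <- 80
  x <- rbinom(n, 2, 0.4)
  y <- 1 + 0.5 * x + rnorm(n)
  ft <- fitMarkerModel(y, x)
  lf <- summary(lm(y ~ x))
  expect_equal(ft$effect, unname(coef(lf)[2, 1]))
  expect_equal(ft$se, unname(coef(lf)[2, 2]))
  expect_equal(ft$F, unname(coef(lf)[2, 3])^2)   # F = squared t
  expect_equal(ft$p, unname(coef(lf)[2, 4]))
  # exact linear signal
  fte <- fitMarkerModel(2 * x, x)
  expect_equal(fte$effect, 2, tolerance = 1e-10)
  expect_lt(fte$p, 1e-12)
  # weighted fit equals weighted least squares
  w <- runif(n, 0.5, 2)
  ftw <- fitMarkerModel(y, x, weights = w)
  lw <- summary(lm(y ~ x, weights = w))
  expect_equal(ftw$effect, unname(coef(lw)[2, 1]))
  expect_equal(ftw$se, unname(coef(lw)[2, 2]))
  # constant marker is skipped, not an error
  expect_true(fitMarkerModel(y, rep(1, n))$skipped)
  # collinear design errors
  expect_error(fitMarkerModel(y, x, covariates = cbind(x)), "singular")
})

test_that("null p-values are uniform for the kinship marker model", {
  set.seed(60)
  ped <- randomPedigree(60, 500, seed = 61, allowSelf = FALSE)
  A <- numeratorA(ped)
  n <- nrow(A)
  L <- t(chol(A))
  vu <- 1; ve <- 2
  eig <- NULL
  pvals <- replicate(1000, {
    u <- as.vector(L %*% rnorm(n, 0, sqrt(vu)))
    y <- u + rnorm(n, 0, sqrt(ve))
    x <- dropLocus(ped, p = 0.5)          # family-structured genotypes
    ft <- fitMarkerModel(y, x, K = A, eig = eig)
    eig <<- ft$eig
    ft$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # no inflation: roughly nominal rejection rate at 5%
  expect_lt(mean(pvals < 0.05), 0.08)
})

test_that("measured genotype model: symmetry, recovery and null behaviour", {
  pop <- tinyTwoGen(nParents = 25, off = 3, seed = 70)
  m5 <- fitMeasuredGenotypeModel(pop, 5)
  # swapping parental labels flips the imprinting effect, F unchanged
  popSwap <- pop
  popSwap@hapPat <- pop@hapMat
  popSwap@hapMat <- pop@hapPat
  m5s <- fitMeasuredGenotypeModel(popSwap, 5)
  expect_equal(m5s$bP, -m5$bP, tolerance = 1e-5)
  expect_equal(m5s$FImp, m5$FImp, tolerance = 1e-4)
  expect_equal(m5s$FAdd, m5$FAdd, tolerance = 1e-4)
  # parameter recovery: phenotype built from a known imprinting contrast
  set.seed(71)
  mcol <- which(pop@loci$type == "marker")[5]
  ph <- !is.na(pop@phenotype)
  xp <- (pop@hapPat[, mcol] - pop@hapMat[, mcol])[ph]
  popR <- pop
  popR@phenotype[ph] <- 0.4 * xp + rnorm(sum(ph), 0, 1)
  mr <- fitMeasuredGenotypeModel(popR, 5)
  expect_lt(abs(mr$bP - 0.4), 2 * mr$seP)
  # dropping the imprinting term leaves the additive test intact
  m2a <- fitMeasuredGenotypeModel(pop, 2)
  m2b <- fitMeasuredGenotypeModel(pop, 2, imprintingTerm = FALSE)
  expect_equal(m2b$FAdd, m2a$FAdd, tolerance = 0.05)
})
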