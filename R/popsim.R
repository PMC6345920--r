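# Population simulator: pedigreed populations with imprinted QTL in linkage
# disequilibrium with biallelic markers, recombination by the Haldane map
# function, and phenotypes for the final generation only.

#' Default QTL configuration of the simulation study
#'
#' Five QTL, each linked to one of markers 2, 5, 8, 11 and 14 at 10 cM:
#' a purely Mendelian QTL (30% of the total additive variance), a purely
#' paternally and a purely maternally expressed QTL (5% of the additive and
#' 25% of the imprinting variance each) and two partially imprinted QTL with
#' opposite POEs (30% of the additive and 25% of the imprinting variance
#' each).
#'
#' @return data.frame with columns `marker`, `maf`, `pattern`, `shareVa`,
#'   `shareVi`, `mapDistCM`.
#' @export
defaultQtls <- function() {
  data.frame(
    marker  = c(2L, 5L, 8L, 11L, 14L),
    maf     = c(0.4, 0.5, 0.5, 0.5, 0.5),
    pattern = c("mendelian", "paternal_full", "maternal_full",
                "paternal_partial", "maternal_partial"),
    shareVa = c(0.30, 0.05, 0.05, 0.30, 0.30),
    shareVi = c(0.00, 0.25, 0.25, 0.25, 0.25),
    mapDistCM = 10,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Collects all settings of the population simulator. Defaults reproduce the
#' study conditions: a two-generation design with 100 parents inter-mated in
#' all 100 x 100 ordered combinations (selfing included) at three full sibs
#' per family, or a three-generation design in which 10 grandparents produce
#' 100 full-sib families of Poisson(5) size, the resulting parents are again
#' inter-mated cross-classified with Poisson(5) family sizes and 3% of the
#' progeny are retained with phenotypes. The total additive genetic variance
#' is 1.35, the total imprinting variance 0.27 and the residual variance 2.
#' 15 mutually unlinked markers are simulated; linked markers sit 10 cM from
#' their QTL and founder linkage disequilibrium is `initialLD = 0.1`,
#' interpreted as the haplotype-frequency covariance D entering the
#' conditional founder draw. Unlinked markers segregate at frequency 0.5.
#'
#' @param design `"two_gen"` or `"three_gen"`.
#' @param nParents two-generation design: number of founder parents.
#' @param offspringPerFamily two-generation design: full-sib family size.
#' @param nGrandparents,nGpFamilies,familySizeMean,retention three-generation
#'   design: grandparent count, number of grandparent full-sib families, mean
#'   Poisson family size, fraction of final progeny retained with records.
#' @param totalVa,totalVi,varResidual variance targets for QTL calibration
#'   and the residual draw.
#' @param nMarkers number of markers.
#' @param initialLD founder marker-QTL LD coefficient D.
#' @param markerMaf allele frequency at markers not linked to any QTL.
#' @param qtls QTL table as in [defaultQtls()].
#' @return list of class `"SimConfig"`.
#' @export
simConfig <- function(design = c("two_gen", "three_gen"),
                      nParents = 100L, offspringPerFamily = 3L,
                      nGrandparents = 10L, nGpFamilies = 100L,
                      familySizeMean = 5.0, retention = 0.03,
                      totalVa = 1.35, totalVi = 0.27, varResidual = 2.0,
                      nMarkers = 15L, initialLD = 0.1, markerMaf = 0.5,
                      qtls = defaultQtls()) {
  design <- match.arg(design)
  stopifnot(nParents >= 1, offspringPerFamily >= 1, nGrandparents >= 1,
            nGpFamilies >= 1, familySizeMean > 0,
            retention > 0, retention <= 1,
            totalVa >= 0, totalVi >= 0, varResidual > 0, nMarkers >= 1)
  if (any(qtls$marker > nMarkers))
    stop("QTL linked to a marker index beyond 'nMarkers'")
  cfg <- list(design = design, nParents = as.integer(nParents),
              offspringPerFamily = as.integer(offspringPerFamily),
              nGrandparents = as.integer(nGrandparents),
              nGpFamilies = as.integer(nGpFamilies),
              familySizeMean = familySizeMean, retention = retention,
              totalVa = totalVa, totalVi = totalVi,
              varResidual = varResidual, nMarkers = as.integer(nMarkers),
              initialLD = initialLD, markerMaf = markerMaf, qtls = qtls)
  class(cfg) <- "SimConfig"
  cfg
}

#' Calibrate QTL effects from variance shares
#'
#' Solves the single-locus variance identities for the substitution and
#' imprinting effects: `2pq alpha^2 = shareVa * totalVa` and
#' `2pq i^2 = shareVi * totalVi`. The imprinting effect is positive for
#' paternal expression patterns and negative for maternal ones, so the two
#' partially imprinted QTL of the default configuration have opposite POEs;
#' for a fully imprinted QTL the calibration implies `|i| = alpha`, i.e. one
#' parental copy is completely silenced. Dominance is zero throughout.
#'
#' @param pattern one of `"mendelian"`, `"paternal_full"`, `"maternal_full"`,
#'   `"paternal_partial"`, `"maternal_partial"`.
#' @param maf minor allele frequency in (0, 0.5].
#' @param shareVa,shareVi shares of `totalVa` / `totalVi` explained.
#' @param totalVa,totalVi total additive and imprinting variances.
#' @return named numeric vector `c(alpha, i)`.
#' @export
calibrateQtlEffects <- function(pattern, maf, shareVa, shareVi,
                                totalVa = 1.35, totalVi = 0.27) {
  pattern <- match.arg(pattern, c("mendelian", "paternal_full",
                                  "maternal_full", "paternal_partial",
                                  "maternal_partial"))
  if (maf <= 0 || maf > 0.5)
    stop("monomorphic or invalid 'maf'; need 0 < maf <= 0.5")
  twopq <- 2 * maf * (1 - maf)
  alpha <- sqrt(shareVa * totalVa / twopq)
  i <- if (pattern == "mendelian") 0 else sqrt(shareVi * totalVi / twopq)
  if (grepl("^maternal", pattern)) i <- -i
  c(alpha = alpha, i = i)
}

# Haldane map function: map distance in centiMorgans -> recombination fraction
.haldane <- function(cM) 0.5 * (1 - exp(-2 * cM / 100))

# Locus table: markers first (columns 1..nMarkers), then the QTL columns.
.buildLoci <- function(cfg) {
  q <- cfg$qtls
  nm <- cfg$nMarkers
  loci <- data.frame(
    name = c(sprintf("M%d", seq_len(nm)), sprintf("Q%d", seq_len(nrow(q)))),
    type = c(rep("marker", nm), rep("qtl", nrow(q))),
    marker = c(seq_len(nm), q$marker),
    p = c(ifelse(seq_len(nm) %in% q$marker,
                 q$maf[match(seq_len(nm), q$marker)], cfg$markerMaf),
          q$maf),
    alpha = 0, i = 0, recomb = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(q))) {
    eff <- calibrateQtlEffects(q$pattern[k], q$maf[k], q$shareVa[k],
                               q$shareVi[k], cfg$totalVa, cfg$totalVi)
    loci$alpha[nm + k] <- eff["alpha"]
    loci$i[nm + k] <- eff["i"]
    loci$recomb[nm + k] <- .haldane(q$mapDistCM[k])
  }
  loci
}

#' Sample founder haplotypes with marker-QTL linkage disequilibrium
#'
#' For each founder haplotype the QTL allele is drawn Bernoulli at its allele
#' frequency and the linked marker allele from the conditional distribution
#' implied by the LD coefficient D: `P(m = B | q = B) = p_m + D / p_q` and
#' `P(m = B | q = b) = p_m - D / q_q`. Markers without a linked QTL are drawn
#' independently at their own frequencies. The two haplotypes of a founder
#' are independent (random mating).
#'
#' @param n number of founders.
#' @param loci locus table as built by the simulator (see [simConfig()]);
#'   internal format.
#' @param D LD coefficient between each linked marker and its QTL.
#' @return list with integer matrices `hap1`, `hap2` (n x loci).
#' @keywords internal
sampleFounders <- function(n, loci, D) {
  L <- nrow(loci)
  draw <- function() {
    h <- matrix(0L, n, L)
    qrows <- which(loci$type == "qtl")
    linked <- loci$marker[qrows]
    for (k in seq_along(qrows)) {
      qr <- qrows[k]; mr <- linked[k]
      pq <- loci$p[qr]; pm <- loci$p[mr]
      pBB <- pm + D / pq
      pBb <- pm - D / (1 - pq)
      if (pBB < 0 || pBB > 1 || pBb < 0 || pBb > 1)
        stop(sprintf("LD D = %g incompatible with allele frequencies %g/%g",
                     D, pm, pq))
      qa <- as.integer(runif(n) < pq)
      ma <- as.integer(runif(n) < ifelse(qa == 1L, pBB, pBb))
      h[, qr] <- qa
      h[, mr] <- ma
    }
    for (j in setdiff(which(loci$type == "marker"), linked))
      h[, j] <- as.integer(runif(n) < loci$p[j])
    h
  }
  list(hap1 = draw(), hap2 = draw())
}

# Vectorized meiosis for a vector of parent row-indices. Each linked
# marker-QTL pair recombines with its Haldane fraction; all other loci
# segregate independently.
.gamete <- function(hapP, hapM, par, loci) {
  m <- length(par)
  L <- nrow(loci)
  out <- matrix(0L, m, L)
  qrows <- which(loci$type == "qtl")
  linked <- loci$marker[qrows]
  pick <- function(j, usePat) {
    ifelse(usePat, hapP[cbind(par, j)], hapM[cbind(par, j)])
  }
  for (k in seq_along(qrows)) {
    qr <- qrows[k]; mr <- linked[k]
    chooseM <- runif(m) < 0.5
    rec <- runif(m) < loci$recomb[qr]
    out[, mr] <- pick(mr, chooseM)
    out[, qr] <- pick(qr, xor(chooseM, rec))
  }
  for (j in setdiff(which(loci$type == "marker"), linked))
    out[, j] <- pick(j, runif(m) < 0.5)
  out
}

#' Transmit gametes from parents of a population
#'
#' Draws one gamete per requested parent using the population's locus map
#' (linked marker-QTL pairs recombine at their Haldane fraction, everything
#' else segregates independently). Uses the current RNG state.
#'
#' @param pop an [ImprintPop-class].
#' @param parents vector of parent ids.
#' @return integer matrix (length(parents) x loci) of allele indicators.
#' @export
transmitGametes <- function(pop, parents) {
  idx <- match(parents, pop@pedigree$id)
  if (anyNA(idx)) stop("unknown parent id")
  .gamete(pop@hapPat, pop@hapMat, idx, pop@loci)
}

# Genotypic value from ordered QTL genotypes: BB = a, Bb = d + i, bB = d - i,
# bb = -a (first allele paternal); here a = alpha and d = 0.
.geneticValue <- function(hapP, hapM, loci) {
  qrows <- which(loci$type == "qtl")
  val <- numeric(nrow(hapP))
  for (qr in qrows) {
    pat <- hapP[, qr]; mat <- hapM[, qr]
    a <- loci$alpha[qr]; i <- loci$i[qr]
    val <- val + ifelse(pat == mat, (2 * pat - 1) * a, (pat - mat) * i)
  }
  val
}

#' Fixed mating structure of a simulated design
#'
#' Draws (once) the pedigree skeleton: which parents are mated, family sizes
#' and - for the three-generation design - which final progeny are retained
#' with records. Replicated simulations redraw genotypes and residuals on a
#' fixed structure.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer seed used for the structural draws.
#' @return list describing the matings per generation.
#' @export
popStructure <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (cfg$design == "two_gen") {
    m <- expand.grid(sire = seq_len(cfg$nParents),
                     dam = seq_len(cfg$nParents))
    return(list(design = "two_gen",
                matings = data.frame(sire = m$sire, dam = m$dam,
                                     n = cfg$offspringPerFamily)))
  }
  set.seed(seed)
  gp <- data.frame(
    sire = sample.int(cfg$nGrandparents, cfg$nGpFamilies, replace = TRUE),
    dam  = sample.int(cfg$nGrandparents, cfg$nGpFamilies, replace = TRUE),
    n    = rpois(cfg$nGpFamilies, cfg$familySizeMean))
  n2 <- sum(gp$n)
  if (n2 < 2L) stop("degenerate structure: fewer than two parents")
  # cross-classified ordered matings among the n2 parents; i.i.d. Bernoulli
  # thinning of the Poisson-sized families down to the retained records
  tot <- rpois(n2 * n2, cfg$familySizeMean)
  kept <- rbinom(length(tot), tot, cfg$retention)
  idx <- which(kept > 0L)
  g3 <- data.frame(sire = (idx - 1L) %% n2 + 1L,
                   dam = (idx - 1L) %/% n2 + 1L,
                   n = kept[idx])
  list(design = "three_gen", gpFamilies = gp, nParents = n2, matings = g3,
       nPossible = sum(tot), nRetained = sum(kept))
}

#' Simulate a pedigreed population with imprinted QTL
#'
#' Draws founder haplotypes with the configured marker-QTL LD, transmits
#' gametes down the pedigree with recombination, and generates phenotypes for
#' the final generation as the sum of ordered-genotype QTL values and a
#' normal residual. Family structure is taken from `structure` (or drawn via
#' [popStructure()] when omitted) so replicates can redraw genotypes and
#' residuals on an identical pedigree.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer seed for the genotype and residual draws.
#' @param structure optional result of [popStructure()].
#' @return An [ImprintPop-class].
#' @export
simulatePopulation <- function(cfg, seed = 1L, structure = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (is.null(structure)) structure <- popStructure(cfg, seed)
  if (structure$design != cfg$design)
    stop("'structure' was drawn for a different design")
  loci <- .buildLoci(cfg)
  set.seed(seed)
  if (cfg$design == "two_gen") {
    n0 <- cfg$nParents
    fo <- sampleFounders(n0, loci, cfg$initialLD)
    mat <- structure$matings
    sire <- rep(mat$sire, mat$n)
    dam <- rep(mat$dam, mat$n)
    noff <- length(sire)
    hapPat <- rbind(fo$hap1, .gamete(fo$hap1, fo$hap2, sire, loci))
    hapMat <- rbind(fo$hap2, .gamete(fo$hap1, fo$hap2, dam, loci))
    ped <- data.frame(id = seq_len(n0 + noff),
                      sire = c(rep(0L, n0), sire),
                      dam = c(rep(0L, n0), dam),
                      generation = rep(1:2, c(n0, noff)))
    pheno <- c(rep(NA_real_, n0),
               .geneticValue(hapPat[n0 + seq_len(noff), , drop = FALSE],
                             hapMat[n0 + seq_len(noff), , drop = FALSE],
                             loci) +
                 rnorm(noff, 0, sqrt(cfg$varResidual)))
  } else {
    n0 <- cfg$nGrandparents
    fo <- sampleFounders(n0, loci, cfg$initialLD)
    gp <- structure$gpFamilies
    sire2 <- rep(gp$sire, gp$n)
    dam2 <- rep(gp$dam, gp$n)
    n2 <- length(sire2)
    hp2 <- .gamete(fo$hap1, fo$hap2, sire2, loci)
    hm2 <- .gamete(fo$hap1, fo$hap2, dam2, loci)
    m3 <- structure$matings
    sire3 <- rep(m3$sire, m3$n)           # indices within generation 2
    dam3 <- rep(m3$dam, m3$n)
    n3 <- length(sire3)
    hp3 <- .gamete(hp2, hm2, sire3, loci)
    hm3 <- .gamete(hp2, hm2, dam3, loci)
    hapPat <- rbind(fo$hap1, hp2, hp3)
    hapMat <- rbind(fo$hap2, hm2, hm3)
    ped <- data.frame(id = seq_len(n0 + n2 + n3),
                      sire = c(rep(0L, n0), sire2, sire3 + n0),
                      dam = c(rep(0L, n0), dam2, dam3 + n0),
                      generation = rep(1:3, c(n0, n2, n3)))
    pheno <- c(rep(NA_real_, n0 + n2),
               .geneticValue(hp3, hm3, loci) +
                 rnorm(n3, 0, sqrt(cfg$varResidual)))
  }
  new("ImprintPop", pedigree = ped, hapPat = hapPat, hapMat = hapMat,
      loci = loci, phenotype = pheno, config = unclass(cfg))
}

setMethod("show", "ImprintPop", function(object) {
  gen <- table(object@pedigree$generation)
  cat(sprintf("ImprintPop: %d individuals (%s), %d markers, %d QTL\n",
              nrow(object@pedigree),
              paste(sprintf("gen %s: %d", names(gen), gen), collapse = ", "),
              sum(object@loci$type == "marker"),
              sum(object@loci$type == "qtl")))
  cat(sprintf("  %d phenotyped individuals\n", sum(!is.na(object@phenotype))))
})

#' @describeIn geneCounts marker (or QTL) gene counts of an
#'   [ImprintPop-class].
#' @export
setMethod("geneCounts", "ImprintPop", function(x, type = "marker", ids = NULL) {
  cols <- which(x@loci$type == type)
  idx <- if (is.null(ids)) seq_len(nrow(x@pedigree)) else
    match(ids, x@pedigree$id)
  gc <- x@hapPat[idx, cols, drop = FALSE] + x@hapMat[idx, cols, drop = FALSE]
  dimnames(gc) <- list(x@pedigree$id[idx], x@loci$name[cols])
  gc
})

#' True parent-of-origin effects of simulated individuals
#'
#' Sums the single-locus POE over all QTL for each individual, in the
#' dam-minus-sire convention used by [fitImprintingModel()] (the negative of
#' the classical father-minus-mother column of [genotypeTable()]). Depends
#' only on the gene count at each QTL, so it is well defined for ordered and
#' un-ordered carriers alike.
#'
#' @param pop an [ImprintPop-class].
#' @param ids individuals to evaluate (default: all).
#' @return numeric vector of true POEs.
#' @export
truePOE <- function(pop, ids = NULL) {
  idx <- if (is.null(ids)) seq_len(nrow(pop@pedigree)) else
    match(ids, pop@pedigree$id)
  qrows <- which(pop@loci$type == "qtl")
  val <- numeric(length(idx))
  for (qr in qrows) {
    gc <- pop@hapPat[idx, qr] + pop@hapMat[idx, qr]
    val <- val - pop@loci$i[qr] * (gc - 2 * pop@loci$p[qr])
  }
  val
}

#' True summed genotypic values at the QTL
#'
#' @param pop an [ImprintPop-class].
#' @param ids individuals to evaluate (default: all).
#' @return numeric vector of genotypic values (no residual).
#' @export
trueGeneticValue <- function(pop, ids = NULL) {
  idx <- if (is.null(ids)) seq_len(nrow(pop@pedigree)) else
    match(ids, pop@pedigree$id)
  .geneticValue(pop@hapPat[idx, , drop = FALSE],
                pop@hapMat[idx, , drop = FALSE], pop@loci)
}

#' Export a simulated population as plain-text tables
#'
#' Writes `pedigree.csv` (id, sire, dam, generation; 0 = unknown parent),
#' `genotypes.tsv` (individuals x markers gene counts), `haplotypes.tsv`
#' (ordered allele indicators for all loci) and `phenotypes.csv` (phenotyped
#' individuals only).
#'
#' @param pop an [ImprintPop-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writePopulation <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(pop@pedigree, file.path(dir, "pedigree.csv"),
                   row.names = FALSE)
  gc <- geneCounts(pop)
  utils::write.table(data.frame(id = pop@pedigree$id, gc),
                     file.path(dir, "genotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  hap <- data.frame(id = pop@pedigree$id,
                    setNames(as.data.frame(pop@hapPat),
                             paste0(pop@loci$name, "_pat")),
                    setNames(as.data.frame(pop@hapMat),
                             paste0(pop@loci$name, "_mat")))
  utils::write.table(hap, file.path(dir, "haplotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ph <- !is.na(pop@phenotype)
  utils::write.csv(data.frame(id = pop@pedigree$id[ph],
                              phenotype = pop@phenotype[ph]),
                   file.path(dir, "phenotypes.csv"), row.names = FALSE)
  invisible(dir)
}
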