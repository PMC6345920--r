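#' @import methods
#' @importFrom stats rnorm runif rbinom rpois pf optim optimize pchisq
#'   p.adjust var sd setNames complete.cases lm.wfit coef aggregate
#' @importFrom Matrix sparseMatrix Matrix crossprod t Diagonal
#' @importFrom utils write.csv write.table
NULL

#' Single-locus genetic parameters for an imprinted biallelic locus
#'
#' Holds the allele frequency and the genotypic-effect parameterization of a
#' single biallelic locus with genomic imprinting: the additive effect `a`
#' (half the difference between the homozygote means), the dominance effect
#' `d` (deviation of the mean heterozygote from the homozygote midpoint) and
#' the imprinting effect `i` (half the difference between the two reciprocal
#' heterozygotes, paternal-B minus maternal-B). All effects are in trait
#' units; `p` is the frequency of the B allele, `q = 1 - p` that of b.
#'
#' @slot p frequency of allele B, in \[0, 1\].
#' @slot a additive effect.
#' @slot d dominance effect.
#' @slot i imprinting effect.
#' @seealso [locusParams()], [substitutionEffects()], [genotypeTable()],
#'   [poeMoments()]
#' @export
setClass("LocusParams",
  representation(p = "numeric", a = "numeric", d = "numeric", i = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@p) != 1L || is.na(object@p) ||
        object@p < 0 || object@p > 1)
      msg <- c(msg, "'p' must be a single value in [0, 1]")
    for (s in c("a", "d", "i")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v))
        msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Simulated pedigreed population with ordered haplotypes
#'
#' Container for a simulated population: a pedigree, phased (ordered)
#' haplotypes at markers and QTL, phenotypes of the final generation, and the
#' simulation configuration (including the calibrated QTL effects). Haplotype
#' matrices code the B allele as 1 and b as 0; `hapPat` carries the paternally
#' inherited allele, `hapMat` the maternally inherited one, so the ordered
#' genotype of any individual at any locus is directly available.
#'
#' @slot pedigree data.frame with columns `id`, `sire`, `dam` (0 = unknown)
#'   and `generation` (founders are generation 1).
#' @slot hapPat,hapMat integer matrices (individuals x loci) of paternal and
#'   maternal allele indicators.
#' @slot loci data.frame describing the columns of the haplotype matrices
#'   (type `"marker"` or `"qtl"`, allele frequency, linked marker, calibrated
#'   `alpha` and `i`, recombination fraction to the linked marker).
#' @slot phenotype numeric vector, `NA` for individuals without records.
#' @slot config list of simulation settings (see [simConfig()]).
#' @export
setClass("ImprintPop",
  representation(pedigree = "data.frame", hapPat = "matrix",
                 hapMat = "matrix", loci = "data.frame",
                 phenotype = "numeric", config = "list"),
  validity = function(object) {
    n <- nrow(object@pedigree)
    msg <- character()
    if (nrow(object@hapPat) != n || nrow(object@hapMat) != n)
      msg <- c(msg, "haplotype matrices must have one row per individual")
    if (length(object@phenotype) != n)
      msg <- c(msg, "'phenotype' must have one entry per individual")
    ped <- object@pedigree
    known <- ped$sire > 0L
    if (any(known & match(ped$sire, ped$id) >= seq_len(n), na.rm = TRUE))
      msg <- c(msg, "every sire must precede its offspring")
    known <- ped$dam > 0L
    if (any(known & match(ped$dam, ped$id) >= seq_len(n), na.rm = TRUE))
      msg <- c(msg, "every dam must precede its offspring")
    if (length(msg)) msg else TRUE
  }
)

#' Parental transmitting abilities, ePOEs and reliabilities
#'
#' Result container for the reduced imprinting model (and, with a single
#' transmitting-ability column, for the reduced animal model). For each parent
#' it stores the transmitting ability as sire, as dam, the estimated
#' parent-of-origin effect `epoe = taDam - taSire`, and the corresponding
#' reliabilities from the inverse of the mixed-model coefficient matrix.
#'
#' @slot estimates data.frame with one row per parent (`id`, `taSire`,
#'   `taDam`, `epoe`, `relSire`, `relDam`, `relEpoe`; the reduced animal model
#'   fills `taSire`/`taDam` with the single TA and `epoe` with 0).
#' @slot varcomp named numeric vector of REML variance components.
#' @slot model character, `"imprinting"` or `"additive"`.
#' @slot logLik REML log-likelihood at convergence.
#' @slot details list (optimizer trace, fixed effects, ...).
#' @export
setClass("ImprintEstimates",
  representation(estimates = "data.frame", varcomp = "numeric",
                 model = "character", logLik = "numeric", details = "list"),
  validity = function(object) {
    need <- c("id", "taSire", "taDam", "epoe", "relSire", "relDam", "relEpoe")
    if (!all(need %in% names(object@estimates)))
      return(paste("estimates must contain columns:",
                   paste(need, collapse = ", ")))
    rel <- unlist(object@estimates[c("relSire", "relDam", "relEpoe")])
    rel <- rel[!is.na(rel)]
    if (length(rel) && (min(rel) < -1e-8 || max(rel) > 1 + 1e-8))
      return("reliabilities must lie in [0, 1]")
    TRUE
  }
)

#' Per-marker association scan results
#'
#' One row per tested marker: estimated marker effect, its standard error,
#' the conditional Wald F statistic, p-value and FDR decisions at the genome
#' and chromosome level. Markers skipped by QC or monomorphic in the scanned
#' sample carry `NA` statistics.
#'
#' @slot table data.frame with columns `marker`, `chrom`, `effect`, `se`,
#'   `F`, `p`, `fdrGenome`, `fdrChrom` (plus model-specific extras such as
#'   `effectAdd`/`effectImp` for the measured genotype model, or `cBest`
#'   for weighted scans).
#' @slot model character label of the analysis (e.g. `"1A"`, `"2A"`, `"3B"`).
#' @slot details list of scan settings.
#' @export
setClass("MarkerScan",
  representation(table = "data.frame", model = "character", details = "list"),
  validity = function(object) {
    need <- c("marker", "effect", "se", "F", "p")
    if (!all(need %in% names(object@table)))
      return(paste("scan table must contain columns:",
                   paste(need, collapse = ", ")))
    p <- object@table$p
    p <- p[!is.na(p)]
    if (length(p) && (min(p) <= 0 || max(p) > 1))
      return("p-values must lie in (0, 1]")
    TRUE
  }
)
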