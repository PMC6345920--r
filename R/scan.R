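# Genotype quality control, exact Hardy-Weinberg test, per-marker
# association scans and genome-/chromosome-wide FDR control.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, enumerates all
#' possible heterozygote counts of matching parity, computes their
#' probabilities under Hardy-Weinberg equilibrium and sums those no more
#' probable than the observed configuration (two-sided, by probability
#' ordering).
#'
#' @param nAA,nAB,nBB genotype counts.
#' @return exact p-value.
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2L * nAA + nAB
  nB <- 2L * nBB + nAB
  rare <- min(nA, nB)
  het <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(nAB = h | allele counts) up to a common constant
  lp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((nB - het) / 2) + het * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, het)]
  min(1, sum(pr[pr <= obs + 1e-12]))
}

#' Genotype quality control
#'
#' Removes markers with minor allele frequency below `mafMin` or an exact
#' Hardy-Weinberg test p-value at or below `hweAlpha`. Gene counts must be
#' complete (impute upstream).
#'
#' @param geneCounts individuals x markers matrix of 0/1/2 gene counts.
#' @param mafMin minimum minor allele frequency (markers with MAF strictly
#'   below are removed; default 0.05).
#' @param hweAlpha HWE exclusion threshold (markers with p <= `hweAlpha`
#'   are removed; default 1e-5).
#' @return list with `keep` (logical per marker) and `log` (data.frame of
#'   per-marker MAF, HWE p and decision).
#' @export
genotypeQC <- function(geneCounts, mafMin = 0.05, hweAlpha = 1e-5) {
  M <- as.matrix(geneCounts)
  if (anyNA(M)) stop("gene counts must be complete (impute upstream)")
  p <- colMeans(M) / 2
  maf <- pmin(p, 1 - p)
  hwe <- vapply(seq_len(ncol(M)), function(j) {
    hweExactTest(sum(M[, j] == 0L), sum(M[, j] == 1L), sum(M[, j] == 2L))
  }, numeric(1))
  keep <- maf >= mafMin & hwe > hweAlpha
  log <- data.frame(marker = colnames(M) %||% seq_len(ncol(M)),
                    maf = maf, hweP = hwe, retained = keep,
                    reason = ifelse(keep, "",
                                    ifelse(maf < mafMin, "MAF", "HWE")))
  if (!any(keep)) stop("all markers removed by QC")
  list(keep = keep, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR flags at genome and chromosome level
#'
#' Applies the BH step-up procedure at level `q` once across all markers
#' (genome-wide) and once within each chromosome. The chromosome-wide flags
#' contain the genome-wide ones for small p-values whenever the chromosome
#' carries fewer tests than the genome.
#'
#' @param pvalues per-marker p-values (`NA` allowed, never flagged).
#' @param chrom chromosome labels (single chromosome when `NULL`).
#' @param q FDR level (default 0.05).
#' @return data.frame with logical columns `fdrGenome`, `fdrChrom`.
#' @export
fdrControl <- function(pvalues, chrom = NULL, q = 0.05) {
  if (is.null(chrom)) chrom <- rep(1L, length(pvalues))
  genome <- rep(FALSE, length(pvalues))
  ok <- !is.na(pvalues)
  genome[ok] <- p.adjust(pvalues[ok], method = "BH") <= q
  chromFlag <- rep(FALSE, length(pvalues))
  for (ch in unique(chrom)) {
    sel <- chrom == ch & ok
    if (any(sel))
      chromFlag[sel] <- p.adjust(pvalues[sel], method = "BH") <= q
  }
  data.frame(fdrGenome = genome, fdrChrom = chromFlag)
}

#' Per-marker association scan
#'
#' Runs [fitMarkerModel()] for each marker column of `geno` against the
#' dependent variable `values` (ePOEs, TAs, deregressed proofs, ...), with an
#' optional polygenic kinship and residual weights, then applies genome- and
#' chromosome-wide BH FDR control. Markers failing QC (when `qc = TRUE`) or
#' monomorphic in the scanned sample are reported with `NA` statistics
#' rather than dropped.
#'
#' @param values dependent variable, one entry per scanned individual.
#' @param geno individuals x markers gene-count matrix.
#' @param K optional kinship among the scanned individuals.
#' @param weights optional residual weights.
#' @param chrom optional chromosome label per marker.
#' @param q FDR level.
#' @param qc apply [genotypeQC()] first.
#' @param model label stored with the result.
#' @return A [MarkerScan-class].
#' @export
runScan <- function(values, geno, K = NULL, weights = NULL, chrom = NULL,
                    q = 0.05, qc = FALSE, model = "scan") {
  geno <- as.matrix(geno)
  nm <- ncol(geno)
  keep <- rep(TRUE, nm)
  qclog <- NULL
  if (qc) {
    res <- genotypeQC(geno)
    keep <- res$keep
    qclog <- res$log
  }
  rows <- vector("list", nm)
  for (j in seq_len(nm)) {
    if (!keep[j]) {
      rows[[j]] <- data.frame(effect = NA_real_, se = NA_real_, F = NA_real_,
                              p = NA_real_)
      next
    }
    ft <- tryCatch(
      fitMarkerModel(values, geno[, j], K = K, weights = weights),
      error = function(e) {
        warning("marker ", j, " flagged: ", conditionMessage(e))
        list(effect = NA_real_, se = NA_real_, F = NA_real_, p = NA_real_)
      })
    rows[[j]] <- data.frame(effect = ft$effect, se = ft$se, F = ft$F,
                            p = ft$p)
  }
  tab <- do.call(rbind, rows)
  tab <- cbind(marker = colnames(geno) %||% seq_len(nm),
               chrom = chrom %||% rep(1L, nm), tab)
  tab <- cbind(tab, fdrControl(tab$p, tab$chrom, q))
  new("MarkerScan", table = tab, model = model,
      details = list(q = q, qc = qclog, n = length(values),
                     weighted = !is.null(weights), kinship = !is.null(K)))
}

setMethod("show", "MarkerScan", function(object) {
  tab <- object@table
  cat(sprintf("MarkerScan (%s): %d markers, n = %d\n", object@model,
              nrow(tab), object@details$n))
  sig <- sum(tab$fdrGenome, na.rm = TRUE)
  cat(sprintf("  %d marker(s) significant at genome-wide FDR %.0f%%\n",
              sig, 100 * object@details$q))
  top <- tab[order(tab$p), ][seq_len(min(5L, nrow(tab))), ]
  print(top, row.names = FALSE, digits = 4)
})

#' Run one of the study analyses on a simulated population
#'
#' Orchestrates the two-step procedure for the analysis layouts of the
#' simulation study:
#' \describe{
#'   \item{1A / 1B}{ePOEs (imprinting fit) or TAs (additive fit) of the
#'     founder parents regressed on their own gene counts by ordinary least
#'     squares (founders are unrelated, so no polygenic term).}
#'   \item{2A / 2B}{phenotypes of the ordered-genotyped offspring under the
#'     measured genotype model with (2A) or without (2B) the imprinting
#'     covariate.}
#'   \item{3A / 3B / 3C}{ePOEs of the parents of the phenotyped generation,
#'     untreated (3A), deregressed and PA-corrected (3B), or additionally
#'     weighted with a per-marker grid search over c (3C); polygenic term
#'     with the pedigree A among the scanned parents.}
#' }
#'
#' @param pop an [ImprintPop-class].
#' @param analysis one of `"1A"`, `"1B"`, `"2A"`, `"2B"`, `"3A"`, `"3B"`,
#'   `"3C"`.
#' @param markers marker indices to test (default: all).
#' @param fit optional pre-computed [ImprintEstimates-class] (first step),
#'   reused across analyses of the same replicate.
#' @param relMin reliability filter threshold for deregressed records.
#' @param q FDR level.
#' @param start optional variance-component start values for the first step.
#' @return list with elements `scan` ([MarkerScan-class]) and `fit`.
#' @export
analyzePopulation <- function(pop, analysis = c("1A", "1B", "2A", "2B",
                                                "3A", "3B", "3C"),
                              markers = NULL, fit = NULL, relMin = 0.03,
                              q = 0.05, start = NULL) {
  analysis <- match.arg(analysis)
  ped <- pop@pedigree
  phen <- !is.na(pop@phenotype)
  markers <- markers %||% seq_len(sum(pop@loci$type == "marker"))
  scanParents <- sort(unique(c(ped$sire[phen], ped$dam[phen])))
  scanParents <- setdiff(scanParents, 0L)

  if (analysis %in% c("2A", "2B")) {
    warm <- start
    rows <- lapply(markers, function(m) {
      ft <- fitMeasuredGenotypeModel(pop, m,
                                     imprintingTerm = analysis == "2A",
                                     start = warm)
      if (!ft$skipped) warm <<- ft$varcomp
      if (analysis == "2A")
        data.frame(effect = ft$bP, se = ft$seP, F = ft$FImp, p = ft$pImp,
                   effectAdd = ft$bA, seAdd = ft$seA, FAdd = ft$FAdd,
                   pAdd = ft$pAdd)
      else
        data.frame(effect = ft$bA, se = ft$seA, F = ft$FAdd, p = ft$pAdd)
    })
    tab <- do.call(rbind, rows)
    tab <- cbind(marker = markers, chrom = rep(1L, nrow(tab)), tab)
    tab <- cbind(tab, fdrControl(tab$p, tab$chrom, q))
    return(list(scan = new("MarkerScan", table = tab, model = analysis,
                           details = list(q = q, n = sum(phen))),
                fit = NULL))
  }

  if (is.null(fit)) {
    fit <- if (analysis == "1B") fitAnimalModel(pop, start = start)
           else fitImprintingModel(pop, start = start)
  }
  est <- fit@estimates
  sel <- match(scanParents, est$id)
  gcAll <- geneCounts(pop, ids = scanParents)[, markers, drop = FALSE]
  colnames(gcAll) <- markers

  if (analysis %in% c("1A", "1B")) {
    vals <- if (analysis == "1A") est$epoe[sel] else est$taSire[sel]
    scan <- runScan(vals, gcAll, q = q, model = analysis)
    return(list(scan = scan, fit = fit))
  }

  # three-generation analyses: polygenic term with A among scanned parents
  # (ancestors included in the tabular recursion, then marginalized)
  anc <- unique(c(scanParents, .modelledParents(ped, scanParents)))
  A <- numeratorA(ped[ped$id %in% anc, c("id", "sire", "dam")])
  K <- A[as.character(scanParents), as.character(scanParents)]
  if (analysis == "3A") {
    scan <- runScan(est$epoe[sel], gcAll, K = K, q = q, model = "3A")
    return(list(scan = scan, fit = fit))
  }
  h <- varianceRatio(fit)
  drp <- deregressFit(fit, ped, what = "epoe", h = h)
  drp <- drp[match(scanParents, drp$id), , drop = FALSE]
  ok <- !drp$flagged & !is.na(drp$relDrp) & drp$relDrp >= relMin
  if (!any(ok)) stop("no records left after the reliability filter")
  Kok <- K[ok, ok, drop = FALSE]
  gok <- gcAll[ok, , drop = FALSE]
  yok <- drp$valueDrp[ok]
  if (analysis == "3B") {
    scan <- runScan(yok, gok, K = Kok, q = q, model = "3B")
    scan@details$nFiltered <- sum(!ok)
    return(list(scan = scan, fit = fit, dereg = drp))
  }
  # 3C: per-marker grid search over c
  rows <- lapply(seq_len(ncol(gok)), function(j) {
    gs <- gridSearchC(yok, gok[, j], relDrp = drp$relDrp[ok], h = h, K = Kok)
    data.frame(effect = gs$fit$effect, se = gs$fit$se, F = gs$fit$F,
               p = gs$fit$p, cBest = gs$cBest, logLik = gs$fit$logLik)
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(marker = markers, chrom = rep(1L, nrow(tab)), tab)
  tab <- cbind(tab, fdrControl(tab$p, tab$chrom, q))
  scan <- new("MarkerScan", table = tab, model = "3C",
              details = list(q = q, n = sum(ok), nFiltered = sum(!ok)))
  list(scan = scan, fit = fit, dereg = drp)
}
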