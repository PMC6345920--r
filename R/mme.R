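# User-level mixed models: the reduced imprinting model (two correlated
# transmitting abilities per parent), the reduced animal model (no
# imprinting), the measured genotype model for ordered offspring genotypes,
# and a full gametic-effects BLUP used as an equivalence oracle.

# Individuals modelled as random parental effects: every ancestor of a
# phenotyped individual. Returns ids in pedigree order.
.modelledParents <- function(ped, phenotyped) {
  need <- unique(c(ped$sire[ped$id %in% phenotyped],
                   ped$dam[ped$id %in% phenotyped]))
  need <- setdiff(need, 0L)
  repeat {
    more <- unique(c(ped$sire[ped$id %in% need], ped$dam[ped$id %in% need]))
    more <- setdiff(more, c(0L, need))
    if (!length(more)) break
    need <- c(need, more)
  }
  ped$id[ped$id %in% need]
}

.extractRecords <- function(pop) {
  ped <- pop@pedigree
  rec <- which(!is.na(pop@phenotype))
  if (!length(rec)) stop("population has no phenotypes")
  if (any(ped$sire[rec] == 0L | ped$dam[rec] == 0L))
    stop("every phenotyped individual needs both parents in the pedigree")
  parents <- .modelledParents(ped, ped$id[rec])
  pedPar <- ped[ped$id %in% parents, c("id", "sire", "dam")]
  list(y = pop@phenotype[rec],
       sire = ped$sire[rec], dam = ped$dam[rec],
       recId = ped$id[rec], pedPar = pedPar)
}

.estimatesFrame <- function(ids, eng) {
  if (eng$model == "imprinting") {
    data.frame(id = ids, taSire = eng$taSire, taDam = eng$taDam,
               epoe = eng$taDam - eng$taSire,
               relSire = eng$relSire, relDam = eng$relDam,
               relEpoe = eng$relEpoe)
  } else {
    data.frame(id = ids, taSire = eng$ta, taDam = eng$ta, epoe = 0,
               relSire = eng$relTa, relDam = eng$relTa, relEpoe = 0)
  }
}

#' Fit the reduced imprinting model
#'
#' Summarizes the phenotypes of un-genotyped progeny into two
#' sex-of-parent-specific transmitting abilities (TAs) per parent:
#' `y = mu + taSire(father) + taDam(mother) + e*`, where the stacked TAs
#' follow `N(0, Sigma (x) A)` with a free 2x2 covariance `Sigma` (variances
#' `sigma2s`, `sigma2d`, covariance `sigmasd`) and the progeny
#' Mendelian-sampling terms are absorbed into a per-record residual variance
#' `sigma2e + (1 - F_sire) sigma2s + (1 - F_dam) sigma2d`. Variance
#' components by REML; BLUPs, reliabilities and prediction-error covariances
#' from the inverse coefficient matrix. The estimated POE of a parent is
#' `epoe = taDam - taSire`, with reliability
#' `1 - PEV(epoe) / (a_ii * (sigma2s + sigma2d - 2 sigmasd))`.
#'
#' @param pop an [ImprintPop-class]; alternatively supply `y`, `sire`, `dam`
#'   and `pedigree` directly.
#' @param y,sire,dam phenotype vector and parent ids per record.
#' @param pedigree pedigree covering all parents (id, sire, dam).
#' @param start optional named variance-component start values.
#' @return An [ImprintEstimates-class].
#' @export
fitImprintingModel <- function(pop = NULL, y = NULL, sire = NULL, dam = NULL,
                               pedigree = NULL, start = NULL) {
  if (!is.null(pop)) {
    rc <- .extractRecords(pop)
  } else {
    # direct API: model every individual of the supplied pedigree (parents
    # without progeny or informative relatives then get reliability 0)
    rc <- list(y = y, sire = sire, dam = dam,
               pedPar = .checkPed(pedigree)[, c("id", "sire", "dam")])
  }
  A <- numeratorA(rc$pedPar)
  ids <- as.integer(rownames(A))
  eng <- .remlParentModel(rc$y, match(rc$sire, ids), match(rc$dam, ids), A,
                          model = "imprinting", start = start)
  new("ImprintEstimates", estimates = .estimatesFrame(ids, eng),
      varcomp = eng$varcomp, model = "imprinting", logLik = eng$logLik,
      details = list(fixef = eng$fixef, n = eng$n, trace = eng$trace,
                     pevEpoe = eng$pevEpoe))
}

#' Fit the reduced animal model (no imprinting)
#'
#' Single additive genetic effect per parent, `y = mu + 0.5 a(father) +
#' 0.5 a(mother) + e*` with `a ~ N(0, A sigma2a)` and the progeny
#' Mendelian-sampling variance absorbed into the residual. The transmitting
#' ability reported is half the estimated breeding value.
#'
#' @inheritParams fitImprintingModel
#' @return An [ImprintEstimates-class] with a single TA per parent.
#' @export
fitAnimalModel <- function(pop = NULL, y = NULL, sire = NULL, dam = NULL,
                           pedigree = NULL, start = NULL) {
  if (!is.null(pop)) {
    rc <- .extractRecords(pop)
  } else {
    rc <- list(y = y, sire = sire, dam = dam,
               pedPar = .checkPed(pedigree)[, c("id", "sire", "dam")])
  }
  A <- numeratorA(rc$pedPar)
  ids <- as.integer(rownames(A))
  eng <- .remlParentModel(rc$y, match(rc$sire, ids), match(rc$dam, ids), A,
                          model = "additive", start = start)
  new("ImprintEstimates", estimates = .estimatesFrame(ids, eng),
      varcomp = eng$varcomp, model = "additive", logLik = eng$logLik,
      details = list(fixef = eng$fixef, n = eng$n, trace = eng$trace))
}

setMethod("show", "ImprintEstimates", function(object) {
  cat(sprintf("ImprintEstimates (%s model): %d parents\n",
              object@model, nrow(object@estimates)))
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(object@varcomp), object@varcomp),
            collapse = ", "), "\n")
  cat(sprintf("  REML logLik = %.3f\n", object@logLik))
  if (object@model == "imprinting") {
    vc <- object@varcomp
    cat(sprintf("  imprinting variance (Var ePOE) = %.4g\n",
                vc["sigma2s"] + vc["sigma2d"] - 2 * vc["sigmasd"]))
  }
})

#' Variance ratio used for deregression weighting
#'
#' For an imprinting fit, the ratio of the imprinting variance
#' `sigma2s + sigma2d - 2 sigmasd` to the phenotypic variance
#' `2 sigma2s + 2 sigma2d + sigma2e`; for an additive fit the ordinary
#' heritability `sigma2a / (sigma2a + sigma2e)`.
#'
#' @param est an [ImprintEstimates-class].
#' @return scalar variance ratio in (0, 1).
#' @export
varianceRatio <- function(est) {
  vc <- est@varcomp
  if (est@model == "imprinting") {
    unname((vc["sigma2s"] + vc["sigma2d"] - 2 * vc["sigmasd"]) /
           (2 * vc["sigma2s"] + 2 * vc["sigma2d"] + vc["sigma2e"]))
  } else {
    unname(vc["sigma2a"] / (vc["sigma2a"] + vc["sigma2e"]))
  }
}

#' Fit the measured genotype model at one marker
#'
#' For phenotyped individuals with known ordered genotypes:
#' `y = mu + b_a x_a + b_p x_p + g_s + g_d + e`, where `x_a` is the gene
#' count, `x_p` codes the ordered genotypes BB, Bb, bB, bb as 0, 1, -1, 0,
#' and the random gametic effects follow `Sigma (x) G` with `G` the gametic
#' relationship matrix. `H0: b_p = 0` tests imprinting, `H0: b_a = 0` the
#' additive association; dropping the `x_p` term gives the additive-only
#' variant. Because the phenotyped individuals are terminal (they are nobody's
#' parents), their gametic effects are absorbed: the fit uses parental
#' transmitting abilities with the Mendelian-sampling residual inflation,
#' which yields BLUPs, likelihood and Wald tests identical to the full
#' gametic mixed model (see [gameticBlup()]). Variance components are
#' reported on the TA scale (half the gametic scale).
#'
#' @param pop an [ImprintPop-class] with phenotyped terminal offspring.
#' @param marker marker index (column of the marker gene-count matrix).
#' @param imprintingTerm include `b_p x_p` (set `FALSE` for the
#'   additive-only model).
#' @param start optional variance-component start values.
#' @return list with `bA`, `seA`, `FAdd`, `pAdd`, (`bP`, `seP`, `FImp`,
#'   `pImp`,) `varcomp`, `logLik`, `df2`, `skipped`.
#' @export
fitMeasuredGenotypeModel <- function(pop, marker, imprintingTerm = TRUE,
                                     start = NULL) {
  rc <- .extractRecords(pop)
  if (any(rc$recId %in% c(rc$pedPar$id)))
    stop("phenotyped individuals must be terminal; use gameticBlup() for ",
         "general pedigrees")
  mcol <- which(pop@loci$type == "marker")[marker]
  idx <- match(rc$recId, pop@pedigree$id)
  xa <- pop@hapPat[idx, mcol] + pop@hapMat[idx, mcol]
  xp <- pop@hapPat[idx, mcol] - pop@hapMat[idx, mcol]
  skipped <- length(unique(xa)) < 2L
  if (skipped)
    return(list(bA = NA_real_, seA = NA_real_, FAdd = NA_real_,
                pAdd = NA_real_, bP = NA_real_, seP = NA_real_,
                FImp = NA_real_, pImp = NA_real_, varcomp = NULL,
                logLik = NA_real_, df2 = NA_integer_, skipped = TRUE))
  XF <- if (imprintingTerm) cbind(xa = xa, xp = xp) else cbind(xa = xa)
  A <- numeratorA(rc$pedPar)
  ids <- as.integer(rownames(A))
  eng <- .remlParentModel(rc$y, match(rc$sire, ids), match(rc$dam, ids), A,
                          model = "imprinting", extraFixed = XF,
                          start = start)
  co <- eng$fixef; vcv <- eng$vcovFixef
  df2 <- eng$n - eng$p
  wald <- function(j) {
    b <- co[[j]]; se <- sqrt(vcv[j, j]); Fs <- (b / se)^2
    c(b = b, se = se, F = Fs, p = pf(Fs, 1, df2, lower.tail = FALSE))
  }
  wa <- wald(which(names(co) == "xa"))
  out <- list(bA = wa["b"], seA = wa["se"], FAdd = wa["F"], pAdd = wa["p"])
  if (imprintingTerm) {
    wp <- wald(which(names(co) == "xp"))
    out <- c(out, list(bP = wp["b"], seP = wp["se"], FImp = wp["F"],
                       pImp = wp["p"]))
  }
  out <- lapply(out, unname)
  c(out, list(varcomp = eng$varcomp, logLik = eng$logLik, df2 = df2,
              skipped = FALSE))
}

#' BLUP under the full gametic-effects model (fixed variance components)
#'
#' Direct dense mixed-model solve of `y = X b + Z_s g^s + Z_d g^d + e` where
#' every gamete in the pedigree carries two correlated expression effects
#' (as paternal and as maternal copy) with covariance `Sigma (x) G`, `G`
#' the 2n x 2n gametic relationship matrix. Intended as a desk-scale oracle:
#' the absorbed fits used by [fitMeasuredGenotypeModel()] and
#' [fitImprintingModel()] must reproduce its fixed effects, parental
#' transmitting abilities and restricted likelihood exactly.
#'
#' @param y phenotypes of `recId` individuals.
#' @param recId ids of the phenotyped individuals.
#' @param pedigree full pedigree (id, sire, dam).
#' @param Sigma 2x2 gametic covariance matrix
#'   (`[sigma2s, sigmasd; sigmasd, sigma2d]`, gametic scale).
#' @param sigma2e residual variance.
#' @param X fixed-effects design matrix (default intercept only).
#' @return list with `fixef`, `vcovFixef`, `gS`, `gD` (per-gamete effects),
#'   `taSire`, `taDam` (per-individual TAs, half the gamete sums), and the
#'   restricted log-likelihood `logLik`.
#' @export
gameticBlup <- function(y, recId, pedigree, Sigma, sigma2e, X = NULL) {
  ped <- .checkPed(pedigree)
  G <- gameticRel(ped)
  n <- nrow(ped)
  m <- 2L * n
  idx <- match(recId, ped$id)
  if (anyNA(idx)) stop("unknown record id")
  nr <- length(y)
  if (is.null(X)) X <- cbind(`(Intercept)` = rep(1, nr))
  p <- ncol(X)
  # random vector: (all gametes as-sire effects, all gametes as-dam effects)
  Z <- matrix(0, nr, 2L * m)
  Z[cbind(seq_len(nr), 2L * idx - 1L)] <- 1        # own paternal gamete, s
  Z[cbind(seq_len(nr), m + 2L * idx)] <- 1         # own maternal gamete, d
  G0inv <- kronecker(solve(Sigma), solve(G))
  W <- cbind(X, Z)
  C <- crossprod(W) / sigma2e
  ir <- (p + 1L):(p + 2L * m)
  C[ir, ir] <- C[ir, ir] + G0inv
  rhs <- crossprod(W, y) / sigma2e
  ch <- chol(C)
  sol <- backsolve(ch, forwardsolve(ch, rhs, upper.tri = TRUE,
                                    transpose = TRUE))
  gS <- sol[p + seq_len(m)]
  gD <- sol[p + m + seq_len(m)]
  yPy <- sum(y^2) / sigma2e - sum(rhs * sol)
  m2ll <- (nr - p) * log(2 * pi) + nr * log(sigma2e) +
    (m * determinant(Sigma, logarithm = TRUE)$modulus +
       2 * determinant(G, logarithm = TRUE)$modulus) +
    2 * sum(log(diag(ch))) + yPy
  pat <- 2L * seq_len(n) - 1L
  list(fixef = setNames(sol[seq_len(p)], colnames(X)),
       vcovFixef = chol2inv(ch)[seq_len(p), seq_len(p), drop = FALSE],
       gS = gS, gD = gD,
       taSire = setNames(0.5 * (gS[pat] + gS[pat + 1L]), ped$id),
       taDam = setNames(0.5 * (gD[pat] + gD[pat + 1L]), ped$id),
       logLik = -0.5 * as.numeric(m2ll))
}
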