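# Closed-form single-locus theory for a biallelic imprinted locus in a
# random-mating population. These functions are the analytic oracle for all
# simulation-based checks in the package.

#' Construct single-locus parameters
#'
#' @param p frequency of the B allele (q = 1 - p is the frequency of b).
#' @param a additive effect (half the difference between homozygote means).
#' @param d dominance effect.
#' @param i imprinting effect: half the difference between the reciprocal
#'   heterozygote means, paternal-B (`Bb`) minus maternal-B (`bB`).
#' @return A [LocusParams-class] object.
#' @examples
#' lp <- locusParams(p = 0.3, a = 1, d = 0.5, i = 0.2)
#' substitutionEffects(lp)
#' @export
locusParams <- function(p, a = 0, d = 0, i = 0) {
  new("LocusParams", p = as.numeric(p), a = as.numeric(a),
      d = as.numeric(d), i = as.numeric(i))
}

setMethod("show", "LocusParams", function(object) {
  cat(sprintf(
    "LocusParams: p = %.4g (q = %.4g), a = %.4g, d = %.4g, i = %.4g\n",
    object@p, 1 - object@p, object@a, object@d, object@i))
  se <- substitutionEffects(object)
  cat(sprintf("  alpha = %.4g, alpha_p = %.4g, alpha_m = %.4g\n",
              se["alpha"], se["alphaP"], se["alphaM"]))
})

#' Parent-specific allele-substitution effects
#'
#' The Mendelian allele-substitution effect is `alpha = a + (q - p) d`. Under
#' imprinting the substitution effect splits by parental origin: a paternally
#' transmitted B allele substitutes with `alpha + i`, a maternally transmitted
#' one with `alpha - i`.
#'
#' @param lp a [LocusParams-class] object.
#' @return Named numeric vector `alpha`, `alphaP`, `alphaM` with
#'   `alphaP - alphaM = 2 i`.
#' @export
substitutionEffects <- function(lp) {
  stopifnot(is(lp, "LocusParams"))
  validObject(lp)
  q <- 1 - lp@p
  alpha <- lp@a + (q - lp@p) * lp@d
  c(alpha = alpha, alphaP = alpha + lp@i, alphaM = alpha - lp@i)
}

#' Ordered-genotype table: frequencies, breeding values and POEs
#'
#' Enumerates the four ordered genotypes (`BB`, `Bb`, `bB`, `bb`; first allele
#' paternal) under Hardy-Weinberg proportions, with the gene count of B, the
#' breeding value of a carrier used as a father, as a mother, and its
#' parent-of-origin effect. The POE column follows the classical
#' father-minus-mother convention, i.e. half the difference between the
#' breeding value as father and as mother (`2qi`, `(q-p)i`, `(q-p)i`,
#' `-2pi`). Note that [truePOE()] and [fitImprintingModel()] use the opposite
#' (dam-minus-sire) sign so that estimated and true POEs correlate
#' positively; only the sign differs.
#'
#' @param lp a [LocusParams-class] object.
#' @return data.frame with columns `genotype`, `freq`, `gc`, `bvFather`,
#'   `bvMother`, `poe`.
#' @export
genotypeTable <- function(lp) {
  stopifnot(is(lp, "LocusParams"))
  validObject(lp)
  p <- lp@p; q <- 1 - p; i <- lp@i
  alpha <- unname(substitutionEffects(lp)["alpha"])
  data.frame(
    genotype = c("BB", "Bb", "bB", "bb"),
    freq     = c(p^2, p * q, p * q, q^2),
    gc       = c(2L, 1L, 1L, 0L),
    bvFather = c(2 * q * (alpha + i), (q - p) * (alpha + i),
                 (q - p) * (alpha + i), -2 * p * (alpha + i)),
    bvMother = c(2 * q * (alpha - i), (q - p) * (alpha - i),
                 (q - p) * (alpha - i), -2 * p * (alpha - i)),
    poe      = c(2 * q * i, (q - p) * i, (q - p) * i, -2 * p * i),
    stringsAsFactors = FALSE
  )
}

#' Population moments of the parent-of-origin effect
#'
#' Closed forms for a random-mating population: `E(POE) = 0`,
#' `Var(POE) = 2pq i^2` (the imprinting variance at the locus),
#' `Cov(POE, gc) = 2pq i`, and the regression of POE on the gene count,
#' `b = Cov(POE, gc) / Var(gc) = i`. At a monomorphic locus (`pq = 0`) the
#' regression is undefined and reported as `NA` with `defined = FALSE`,
#' never as 0.
#'
#' @param lp a [LocusParams-class] object.
#' @return list with elements `mean`, `var`, `cov`, `b`, `defined`.
#' @export
poeMoments <- function(lp) {
  stopifnot(is(lp, "LocusParams"))
  validObject(lp)
  p <- lp@p; q <- 1 - p; i <- lp@i
  pq <- p * q
  list(mean = 0,
       var = 2 * pq * i^2,
       cov = 2 * pq * i,
       b = if (pq > 0) i else NA_real_,
       defined = pq > 0)
}
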