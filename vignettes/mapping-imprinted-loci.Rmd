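---
title: "Mapping imprinted QTL from parental parent-of-origin effects"
author: "poescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping imprinted QTL from parental parent-of-origin effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poescan)
```

## The problem

Standard association mapping of imprinted QTL (iQTL) needs phenotypes and
*ordered* genotypes — genotypes whose parental allele origin is known — on
the same individuals. In many breeding populations the data are arranged
the other way around: large groups of progeny carry the phenotypes but are
never genotyped, while their parents are genotyped but have no phenotypes
of their own. `poescan` implements a two-step procedure for exactly this
situation:

1. **Summarize progeny phenotypes into parental parent-of-origin effects
   (ePOEs).** A reduced imprinting mixed model assigns every parent two
   sex-of-parent-specific transmitting abilities (TAs) — its mean progeny
   deviation when used as a sire and when used as a dam — with a free 2x2
   covariance between the two. The ePOE of a parent is the difference
   `taDam - taSire`, and its reliability follows from the inverse
   mixed-model coefficient matrix.
2. **Regress ePOEs on parental marker gene counts.** At a biallelic locus
   the regression of the POE on the number of B alleles equals the
   imprinting effect `i`, so only imprinted loci give a signal. Un-ordered
   parental genotypes suffice.

## Single-locus theory

For alleles B/b at frequencies `p`/`q`, genotypic means are parameterized
by the additive effect `a`, dominance `d` and imprinting effect `i` (half
the difference between the reciprocal heterozygotes). Parent-specific
substitution effects are `alpha + i` (sires) and `alpha - i` (dams), with
`alpha = a + (q - p) d`. Enumerating the four ordered genotypes under
random mating gives

* `E(POE) = 0`,
* `Var(POE) = 2pq i^2` — the imprinting variance of the locus,
* `Cov(POE, gc) = 2pq i`, hence the regression of POE on gene count
  `b = i`.

These closed forms (`poeMoments()`, `genotypeTable()`) are the analytic
oracle for everything else: the simulator's true POEs, the mixed-model
estimates and the scans are all tested against them.

```{r theory}
lp <- locusParams(p = 0.3, i = 0.5)
genotypeTable(lp)
poeMoments(lp)
```

A sign convention to be aware of: `genotypeTable()` reports the classical
father-minus-mother POE; the fitted ePOEs (and `truePOE()`) use
dam-minus-sire, matching the definition of the ePOE as the deviation of
the TA as dam from the TA as sire. Tests and detection are unaffected —
only the sign of estimated marker effects flips.

## The simulator

`simulatePopulation()` creates the two study designs:

* **two-generation**: 100 unrelated parents inter-mated in all 100 x 100
  ordered combinations (selfing included) with 3 full sibs per family —
  30,000 phenotyped, un-genotyped offspring;
* **three-generation**: 10 grandparents produce 100 full-sib families with
  Poisson(5) sizes (~500 parents); these are inter-mated cross-classified
  with Poisson(5) family sizes and 3% of the progeny are retained with
  records (~40,000). Phenotypes exist in the last generation only, so the
  middle generation's ePOEs contain parent-average information that must
  be removed before scanning.

Fifteen mutually unlinked markers are simulated; markers 2, 5, 8, 11, 14
are each 10 cM (Haldane recombination fraction 0.0906) from a QTL that is
Mendelian, fully paternally, fully maternally, partially paternally or
partially maternally expressed. QTL effects are calibrated so the five
loci exhaust a total additive variance of 1.35 and a total imprinting
variance of 0.27 (`calibrateQtlEffects()`); the residual variance is 2.
Dominance is zero throughout: the trait is built purely from additive and
imprinting genotype values (`BB = a`, `Bb = d + i`, `bB = d - i`,
`bb = -a`, first allele paternal).

Design choices that the configuration leaves open, decided once:

* **"LD of 0.1" is the haplotype-frequency covariance D.** The founder
  draw takes the QTL allele Bernoulli at its frequency and the linked
  marker allele from the conditional distribution
  `P(m = B | q = B) = p_m + D/p_q`, which is the construction D
  parameterizes directly (D', r or r^2 would need extra conventions and,
  at these frequencies, imply weaker association). Transmission then
  decays D by `(1 - c)` per meiosis.
* **Unlinked markers segregate at frequency 0.5**, the natural neutral
  default for anonymous null markers.
* **Three-generation matings are random ordered pairs with replacement**
  (selfing allowed), and the 3% thinning is i.i.d. Bernoulli per progeny.
* **Replication** (`runExperiment()`) fixes the pedigree skeleton once and
  redraws genotypes and residuals with seed `baseSeed + r` per replicate.

What the generator does *not* emulate: mutation, selection, non-random
mating, sex chromosomes, multi-allelic markers, genotyping error or
missingness. Passing tests therefore demonstrate the statistical machinery
under clean Fisher-Wright conditions, not robustness to real-data
artefacts.

## The mixed-model engine

All phenotyped individuals are terminal, so their Mendelian-sampling terms
can be absorbed exactly: the reduced imprinting model fits
`y = mu + taSire(father) + taDam(mother) + e*` with
`Var(e*) = sigma2e + (1 - F_sire) sigma2s + (1 - F_dam) sigma2d` per
record and `Var([taSire; taDam]) = Sigma (x) A`. The absorption makes the
coefficient matrix small (fixed effects + 2q parental effects) however
many records there are; a useful identity derived for this package is that
the paternal- and maternal-gamete Mendelian deviations are uncorrelated
even under selfing, so no residual covariance term is needed. The measured
genotype model (ordered offspring genotypes, gametic effects with a
`Sigma (x) G` covariance) is the same absorbed fit with the marker
covariates `x_a` (gene count) and `x_p` (0, 1, -1, 0 for BB, Bb, bB, bb)
added; `gameticBlup()` implements the full 2n-gamete mixed model densely
and the test suite verifies that both routes give identical fixed effects,
TAs and restricted likelihood (to 1e-8, selfing included).

REML maximizes the restricted likelihood by Nelder-Mead over
log-variances and the z-transformed TA correlation (the correlation is
kept strictly inside (-1, 1), so the 2x2 covariance never leaves the PSD
cone); convergence is declared when restarting from the optimum improves
-2logL by less than 1e-6. Per-marker scans (`fitMarkerModel()`) profile
the REML likelihood over the polygenic/residual variance ratio on the
spectral decomposition of the (weight-standardized) kinship, and test the
marker by a conditional Wald F with 1 and `n - rank(X)` degrees of
freedom. All likelihood constants are kept so fits under different known
weight structures remain comparable — the c grid search depends on this.

Reliabilities come from the inverse coefficient matrix:
`rel = 1 - PEV/(a_ii sigma2)`, and for the ePOE
`PEV(epoe) = PEV(taDam) + PEV(taSire) - 2 PEC`. They are invariant to the
overall mean, clipped to [0, 1], and 0 for a parent without information.

## Deregression, PA-correction and weighting

Using ePOEs directly as dependent variables lets the parent average (PA)
leak family information into the scan and shrinks marker-effect estimates.
`deregressEstimates()` removes both with the two-step absorption of the PA:
the PA reliability is `(r2_sire + r2_dam)/4`; the 2x2 mixed-model system of
(PA, individual) — whose inverse relationship matrix is
`[[4, -2], [-2, 2]]` — is solved in closed form for the effective record
contributions, giving the deregressed value and reliability. The system is
re-derived from the MME rather than transcribed, and a test reconstructs
known record contributions from their implied reliabilities to 1e-8.
Records whose reliability does not exceed their PA reliability carry no own
information and are flagged; deregressed reliabilities below 3% are
discarded by default. The variance ratio used for `lambda = (1 - h)/h` is
the imprinting-variance ratio
`(sigma2s + sigma2d - 2 sigmasd) / (2 sigma2s + 2 sigma2d + sigma2e)` for
ePOEs and the ordinary heritability for TAs. No additional
correlated-effect correction factor is applied to `lambda`: for this model
such a factor cancels from the deregression identically, so the plain
formulas are exact.

Weights for the weighted scan are
`w = (1 - h) / ((c + (1 - r2)/r2) h)` with `c` the fraction of the
(imprinting) variance not captured by markers; `gridSearchC()` scans
`c = 0, 0.05, ..., 0.95` per marker and keeps the REML-likelihood maximum,
breaking ties (within 1e-4) toward the smallest `c`. In the simulated
three-generation design the deregressed reliabilities are nearly
homogeneous (~0.73-0.85), the profile over `c` is almost flat and the
search settles at small `c` — weighting then changes neither the tests nor
the effects appreciably, while deregression itself inflates effect
estimates by roughly `1/reliability` (about one-third to two-thirds here)
without moving the F statistics.

## Scans, QC and FDR

`genotypeQC()` drops markers with MAF < 0.05 or an exact Hardy-Weinberg
test p <= 1e-5 (the conditional exact test is enumerated directly; a
permutation oracle backs it in the tests). `runScan()` fits every marker,
reports markers that are monomorphic in the scanned sample as `NA` rather
than dropping them, and applies Benjamini-Hochberg FDR once genome-wide
and once within each chromosome (independent within-chromosome step-up;
both flag sets are returned). For real-genotype scans the polygenic
covariance would be the VanRaden genomic matrix blended with 5% of A
(`genomicRel()`, `blendRel()`); the simulated scans use the pedigree A of
the scanned parents, and analyses of unrelated founders omit the polygenic
term entirely.

## Numerical and scale choices

Problem sizes used by the test suite were chosen to exercise the study
designs at full scale where it matters and small scale elsewhere: the
acceptance checks run 40 replicates of the full two-generation design
(100 parents, 30,000 records) for the ePOE/TA scans, 30 replicates for
the measured genotype model at the two interesting markers, and 10
replicates of the three-generation design; unit tests use 10-50 parents.
Monte-Carlo standard errors of mean F statistics at these replicate
counts are roughly 0.3-2 depending on the non-centrality.

Known limitations:

* The reduced models require phenotyped individuals to be terminal
  (nobody's parents). `gameticBlup()` handles general pedigrees but only
  at desk scale and fixed variance components.
* Reliability calculation inverts the coefficient matrix exactly; this is
  intended for up to a few thousand parents, not national evaluations.
* The weighted scan treats weights as known; uncertainty in `h` and in the
  reliabilities is ignored, as is conventional.
* Categorical traits (threshold models) are out of scope; dependent
  variables are treated as Gaussian.
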