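#' Gene counts of the B allele
#'
#' @param x object holding genotypes.
#' @param type locus type to extract (`"marker"` or `"qtl"`).
#' @param ids optional subset of individual ids.
#' @return integer matrix of 0/1/2 gene counts (individuals x loci).
#' @export
setGeneric("geneCounts", function(x, type = "marker", ids = NULL)
  standardGeneric("geneCounts"))

#' Phenotype records
#'
#' @param x object holding phenotypes.
#' @return named numeric vector of phenotypes (`NA` for unrecorded
#'   individuals).
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @describeIn phenotypes phenotypes of an [ImprintPop-class].
#' @export
setMethod("phenotypes", "ImprintPop", function(x)
  setNames(x@phenotype, x@pedigree$id))

#' Pedigree table
#'
#' @param x object holding a pedigree.
#' @return data.frame with columns `id`, `sire`, `dam`, `generation`.
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @describeIn pedigree pedigree of an [ImprintPop-class].
#' @export
setMethod("pedigree", "ImprintPop", function(x) x@pedigree)

#' Result table of an estimate set or scan
#'
#' @param x an [ImprintEstimates-class] or [MarkerScan-class].
#' @return data.frame of per-parent estimates or per-marker statistics.
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @describeIn resultTable per-parent estimates.
#' @export
setMethod("resultTable", "ImprintEstimates", function(x) x@estimates)

#' @describeIn resultTable per-marker scan statistics.
#' @export
setMethod("resultTable", "MarkerScan", function(x) x@table)

#' REML variance components
#'
#' @param x an [ImprintEstimates-class].
#' @return named numeric vector of variance components.
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @describeIn varComponents variance components of a fitted model.
#' @export
setMethod("varComponents", "ImprintEstimates", function(x) x@varcomp)
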