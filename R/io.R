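# Plain-text input/output: genotype tables (PLINK-style .ped/.map or
# gene-count TSV), estimate sets and scan results.

#' Read genotypes from a PLINK-style .ped/.map pair or a gene-count table
#'
#' Two layouts are supported. A *gene-count TSV* has one row per individual,
#' an `id` first column and one 0/1/2 column per marker. A *PLINK .ped* has
#' the six leading columns (family, id, sire, dam, sex, phenotype) followed
#' by two allele columns per marker; alleles are recoded as counts of the
#' minor allele (missing alleles coded 0 become `NA`). The accompanying map
#' (`.map`: chrom, marker, cM, bp; or a TSV with columns `marker`, `chrom`,
#' `bp`) provides marker names and chromosome labels for FDR control.
#'
#' @param file path to the genotype file.
#' @param map optional path to the marker map.
#' @param format `"auto"` (by extension), `"tsv"` or `"ped"`.
#' @return list with `geno` (individuals x markers gene-count matrix, ids as
#'   rownames) and `map` (data.frame `marker`, `chrom`, `bp`, or `NULL`).
#' @export
readGenotypes <- function(file, map = NULL, format = c("auto", "tsv", "ped")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ped$", file, ignore.case = TRUE)) "ped" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.table(file, header = TRUE, check.names = FALSE)
    geno <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(geno) <- as.character(tab[[1L]])
    storage.mode(geno) <- "integer"
    if (any(!is.na(geno) & !(geno %in% 0:2)))
      stop("gene counts must be 0, 1 or 2")
  } else {
    tab <- utils::read.table(file, header = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 8L || (ncol(tab) - 6L) %% 2L != 0L)
      stop("malformed .ped: expected 6 leading columns + 2 alleles/marker")
    ids <- tab[[2L]]
    al <- as.matrix(tab[, -(1:6), drop = FALSE])
    nm <- ncol(al) / 2L
    geno <- matrix(NA_integer_, nrow(al), nm)
    for (j in seq_len(nm)) {
      a1 <- al[, 2L * j - 1L]; a2 <- al[, 2L * j]
      obs <- c(a1, a2)
      obs <- obs[obs != "0"]
      alleles <- sort(unique(obs))
      if (length(alleles) > 2L)
        stop("marker ", j, " has more than two alleles")
      counted <- if (length(alleles) == 2L) {
        nc <- table(factor(obs, levels = alleles))
        alleles[which.min(nc)]            # count the minor allele
      } else alleles[1L]
      ok <- a1 != "0" & a2 != "0"
      geno[ok, j] <- (a1[ok] == counted) + (a2[ok] == counted)
    }
    rownames(geno) <- ids
  }
  mapTab <- NULL
  if (!is.null(map)) {
    mt <- utils::read.table(map, header = !grepl("\\.map$", map,
                                                 ignore.case = TRUE))
    mapTab <- if (grepl("\\.map$", map, ignore.case = TRUE))
      data.frame(marker = as.character(mt[[2L]]), chrom = mt[[1L]],
                 bp = mt[[4L]])
    else data.frame(marker = as.character(mt$marker), chrom = mt$chrom,
                    bp = mt$bp)
    if (nrow(mapTab) != ncol(geno))
      stop("map rows (", nrow(mapTab), ") do not match markers (",
           ncol(geno), ")")
    colnames(geno) <- mapTab$marker
  }
  list(geno = geno, map = mapTab)
}

#' Write an estimate set (or deregressed records) as TSV
#'
#' @param x an [ImprintEstimates-class] or a data.frame (e.g. from
#'   [deregressFit()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeEstimates <- function(x, file) {
  tab <- if (is(x, "ImprintEstimates")) resultTable(x) else as.data.frame(x)
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a marker scan as TSV
#'
#' One row per marker: position, effect, standard error, F, p-value and the
#' genome-/chromosome-wide FDR flags - the table backing a Manhattan plot.
#'
#' @param scan a [MarkerScan-class].
#' @param file output path.
#' @param map optional marker map (`marker`, `chrom`, `bp`) merged in.
#' @return `file`, invisibly.
#' @export
writeScan <- function(scan, file, map = NULL) {
  tab <- resultTable(scan)
  if (!is.null(map)) {
    m <- match(as.character(tab$marker), as.character(map$marker))
    tab$chrom <- map$chrom[m]
    tab$bp <- map$bp[m]
  }
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
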