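# Replicated simulation experiments: fixed pedigree structure, genotypes and
# residuals redrawn per replicate, per-analysis scans aggregated into mean
# F-statistics, p-values and effects per marker.

#' Run a replicated simulation experiment
#'
#' Draws the mating structure once from `baseSeed`, then simulates
#' `nReplicates` populations with seeds `baseSeed + r`, runs the requested
#' analyses on each and aggregates the per-marker statistics across the
#' replicates that converged. First-step variance components are warm-started
#' from the previous replicate (the designs are identical, so the REML
#' stationary point moves little between replicates).
#'
#' @param cfg a [simConfig()] object.
#' @param analyses character vector of analyses valid for the design
#'   (`"1A"`, `"1B"`, `"2A"`, `"2B"` for two-generation; `"3A"`, `"3B"`,
#'   `"3C"` for three-generation).
#' @param nReplicates number of replicates.
#' @param baseSeed integer base seed.
#' @param markers marker indices to test (default: all).
#' @param relMin reliability filter for deregressed analyses.
#' @param verbose print per-replicate progress.
#' @return list of class `"ExperimentReport"`: `summary` (data.frame with
#'   per analysis x marker means of F, p, effect, se, and for 3C of c and
#'   logLik), `nReplicates`, `nConverged`, `failures`, `unreliable`.
#' @export
runExperiment <- function(cfg, analyses, nReplicates, baseSeed = 1L,
                          markers = NULL, relMin = 0.03, verbose = FALSE) {
  stopifnot(inherits(cfg, "SimConfig"), nReplicates >= 1)
  twoGen <- c("1A", "1B", "2A", "2B")
  threeGen <- c("3A", "3B", "3C")
  valid <- if (cfg$design == "two_gen") twoGen else threeGen
  if (!all(analyses %in% valid))
    stop("analyses must be among ", paste(valid, collapse = ", "),
         " for this design")
  structure <- popStructure(cfg, baseSeed)
  markers <- markers %||% seq_len(cfg$nMarkers)
  acc <- list()
  failures <- character(0)
  startImp <- NULL; startAdd <- NULL
  for (r in seq_len(nReplicates)) {
    res <- tryCatch({
      pop <- simulatePopulation(cfg, seed = baseSeed + r, structure)
      impFit <- NULL; addFit <- NULL
      out <- list()
      for (an in analyses) {
        if (an %in% c("1A", "3A", "3B", "3C") && is.null(impFit)) {
          impFit <- fitImprintingModel(pop, start = startImp)
          startImp <- impFit@varcomp
        }
        if (an == "1B" && is.null(addFit)) {
          addFit <- fitAnimalModel(pop, start = startAdd)
          startAdd <- addFit@varcomp
        }
        fit <- if (an == "1B") addFit else impFit
        ana <- analyzePopulation(pop, an, markers = markers, fit = fit,
                                 relMin = relMin)
        out[[an]] <- ana$scan@table
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      if (verbose) message("replicate ", r, " failed: ",
                           conditionMessage(res))
      next
    }
    acc[[length(acc) + 1L]] <- res
    if (verbose) message("replicate ", r, " done")
  }
  if (!length(acc)) stop("all replicates failed:\n",
                         paste(failures, collapse = "\n"))
  perAnalysis <- lapply(analyses, function(an) {
    tabs <- lapply(acc, `[[`, an)
    mk <- tabs[[1L]]$marker
    agg <- function(col) {
      m <- sapply(tabs, function(t) as.numeric(t[[col]]))
      if (is.null(dim(m))) m <- matrix(m, nrow = length(mk))
      m
    }
    out <- data.frame(analysis = an, marker = mk,
                      meanF = rowMeans(agg("F"), na.rm = TRUE),
                      sdF = apply(agg("F"), 1L, sd, na.rm = TRUE),
                      meanP = rowMeans(agg("p"), na.rm = TRUE),
                      sdP = apply(agg("p"), 1L, sd, na.rm = TRUE),
                      meanEffect = rowMeans(agg("effect"), na.rm = TRUE),
                      sdEffect = apply(agg("effect"), 1L, sd, na.rm = TRUE),
                      meanSe = rowMeans(agg("se"), na.rm = TRUE))
    if (an == "2A") {
      out$meanFAdd <- rowMeans(agg("FAdd"), na.rm = TRUE)
      out$sdFAdd <- apply(agg("FAdd"), 1L, sd, na.rm = TRUE)
      out$meanPAdd <- rowMeans(agg("pAdd"), na.rm = TRUE)
      out$meanEffectAdd <- rowMeans(agg("effectAdd"), na.rm = TRUE)
    }
    if (an == "3C") {
      out$meanC <- rowMeans(agg("cBest"), na.rm = TRUE)
      out$sdC <- apply(agg("cBest"), 1L, sd, na.rm = TRUE)
      out$meanLogLik <- rowMeans(agg("logLik"), na.rm = TRUE)
    }
    out
  })
  allCols <- unique(unlist(lapply(perAnalysis, names)))
  summ <- do.call(rbind, lapply(perAnalysis, function(d) {
    d[setdiff(allCols, names(d))] <- NA_real_
    d[allCols]
  }))
  rownames(summ) <- NULL
  rep <- list(summary = summ, nReplicates = nReplicates,
              nConverged = length(acc), failures = failures,
              unreliable = length(failures) > 0.1 * nReplicates,
              design = cfg$design, baseSeed = baseSeed)
  class(rep) <- "ExperimentReport"
  rep
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat(sprintf("ExperimentReport (%s): %d/%d replicates converged%s\n",
              x$design, x$nConverged, x$nReplicates,
              if (x$unreliable) " [UNRELIABLE: >10% failures]" else ""))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
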