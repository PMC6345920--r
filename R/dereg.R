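# Parent-average correction, deregression and weighting of ePOEs/TAs,
# adapting the Garrick-style absorption of the parent average, plus the
# grid search for the weighting parameter c.

# Solve the 2x2 (parent-average, individual) mixed-model system for the
# effective record contributions, given the reliabilities. With
# lambda = (1 - h) / h and the inverse relationship matrix of an individual
# with one composite "parent-average parent" [[4, -2], [-2, 2]], the
# coefficient matrix is [[zPA + 4 lambda, -2 lambda], [-2 lambda,
# zI + 2 lambda]]; reliabilities determine zPA and zI through the diagonal
# of its inverse. Solved here in closed form via the quadratic for det(C).
.garrickSystem <- function(relPA, relI, lambda) {
  a1 <- (1 - relPA) * lambda   # lambda^2 * (zI + 2 lambda) / det = ...
  a2 <- (1 - relI) * lambda
  # det satisfies: a1 a2 det^2 / lambda^2 - lambda^2 det - 4 lambda^4 = 0
  A <- a1 * a2 / lambda^2
  dt <- (lambda^2 + sqrt(lambda^4 + 16 * A * lambda^4)) / (2 * A)
  zPA <- a2 * dt / lambda^2 - 4 * lambda
  zI <- a1 * dt / lambda^2 - 2 * lambda
  list(zPA = zPA, zI = zI, det = dt)
}

#' Parent-average correction and deregression of mixed-model estimates
#'
#' Removes the shrinkage and the parent-average (PA) contribution from
#' per-parent estimates (ePOEs or TAs) so they can serve as quasi-phenotypes
#' in association scans. The PA reliability is `(r2_sire + r2_dam) / 4`
#' (missing parents contribute 0); the individual's own information is
#' recovered by absorbing the PA in a 2x2 mixed-model system, yielding the
#' deregressed value and its deregressed reliability. Records without own
#' information (`rel <= relPA`) are flagged and not deregressed; founders
#' without PA collapse to the simple deregression `value / rel`.
#'
#' @param values per-parent estimates (ePOE or TA).
#' @param rel reliabilities of `values`, in (0, 1).
#' @param sireValues,damValues,sireRel,damRel estimates and reliabilities of
#'   the parents of each record (NA when unknown).
#' @param h variance ratio used for `lambda = (1 - h) / h`: the
#'   imprinting-variance ratio when deregressing ePOEs, the heritability
#'   analogue for TAs (see [varianceRatio()]).
#' @return data.frame with `value`, `rel`, `pa`, `relPA`, `valueDrp`,
#'   `relDrp`, `flagged`.
#' @export
deregressEstimates <- function(values, rel, sireValues = NA, damValues = NA,
                               sireRel = NA, damRel = NA, h) {
  stopifnot(h > 0, h < 1)
  n <- length(values)
  sireValues <- rep_len(sireValues, n); damValues <- rep_len(damValues, n)
  sireRel <- rep_len(sireRel, n); damRel <- rep_len(damRel, n)
  lambda <- (1 - h) / h
  pa <- ifelse(is.na(sireValues), 0, sireValues) / 2 +
        ifelse(is.na(damValues), 0, damValues) / 2
  relPA <- (ifelse(is.na(sireRel), 0, sireRel) +
            ifelse(is.na(damRel), 0, damRel)) / 4
  valueDrp <- rep(NA_real_, n)
  relDrp <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (k in seq_len(n)) {
    if (is.na(rel[k]) || rel[k] <= 0 || rel[k] <= relPA[k]) {
      flagged[k] <- TRUE
      next
    }
    if (relPA[k] <= 0) {
      valueDrp[k] <- values[k] / rel[k]
      relDrp[k] <- rel[k]
      next
    }
    gs <- .garrickSystem(relPA[k], min(rel[k], 1 - 1e-10), lambda)
    if (!is.finite(gs$zI) || gs$zI <= 0) {
      flagged[k] <- TRUE
      next
    }
    # own-information right-hand side of the individual's equation
    yStar <- -2 * lambda * pa[k] + (gs$zI + 2 * lambda) * values[k]
    valueDrp[k] <- yStar / gs$zI
    relDrp[k] <- gs$zI / (gs$zI + lambda)
  }
  data.frame(value = values, rel = rel, pa = pa, relPA = relPA,
             valueDrp = valueDrp, relDrp = relDrp, flagged = flagged)
}

#' Deregress the ePOEs (or TAs) of a fitted estimate set
#'
#' Convenience wrapper: looks up each parent's own sire and dam in the
#' pedigree, pulls their estimates and reliabilities from the same fit and
#' calls [deregressEstimates()].
#'
#' @param est an [ImprintEstimates-class].
#' @param pedigree pedigree containing the estimated parents.
#' @param what `"epoe"` (imprinting fit) or `"ta"` (additive fit: the single
#'   transmitting ability).
#' @param h variance ratio; default [varianceRatio()] of the fit.
#' @return data.frame as [deregressEstimates()], with an `id` column.
#' @export
deregressFit <- function(est, pedigree, what = c("epoe", "ta"),
                         h = varianceRatio(est)) {
  what <- match.arg(what)
  tab <- est@estimates
  ped <- .checkPed(pedigree)
  ps <- ped$sire[match(tab$id, ped$id)]
  pd <- ped$dam[match(tab$id, ped$id)]
  si <- match(ps, tab$id); di <- match(pd, tab$id)
  col <- if (what == "epoe") "epoe" else "taSire"
  rcol <- if (what == "epoe") "relEpoe" else "relSire"
  out <- deregressEstimates(tab[[col]], tab[[rcol]],
                            sireValues = tab[[col]][si],
                            damValues = tab[[col]][di],
                            sireRel = tab[[rcol]][si],
                            damRel = tab[[rcol]][di], h = h)
  cbind(id = tab$id, out)
}

#' Garrick-style weight for a deregressed record
#'
#' `w = (1 - h) / ((c + (1 - relDrp) / relDrp) * h)`, where `c` is the
#' proportion of the (imprinting) variance not captured by markers. Strictly
#' decreasing in `c`; records with equal deregressed reliability get equal
#' weights.
#'
#' @param relDrp deregressed reliability in (0, 1).
#' @param c weighting parameter in \[0, 1).
#' @param h variance ratio (as in [deregressEstimates()]).
#' @return positive weights.
#' @export
garrickWeight <- function(relDrp, c, h) {
  stopifnot(all(relDrp > 0), all(relDrp < 1), c >= 0, c < 1, h > 0, h < 1)
  (1 - h) / ((c + (1 - relDrp) / relDrp) * h)
}

#' Discard records with low deregressed reliability
#'
#' @param records data.frame from [deregressEstimates()]/[deregressFit()].
#' @param threshold minimum deregressed reliability (default 3%); flagged
#'   records (no own information) are always discarded.
#' @return the retained rows; errors if none remain.
#' @export
filterReliability <- function(records, threshold = 0.03) {
  keep <- !records$flagged & !is.na(records$relDrp) &
    records$relDrp >= threshold
  if (!any(keep)) stop("no records left after the reliability filter")
  nDrop <- sum(!keep)
  if (nDrop > 0)
    message(nDrop, " record(s) discarded (deregressed reliability < ",
            threshold, " or no own information)")
  records[keep, , drop = FALSE]
}

#' Grid search for the weighting parameter c
#'
#' Refits the single-marker mixed model over a grid of `c` values (default
#' step 0.05), weighting each record by [garrickWeight()], and returns the
#' `c` maximizing the REML log-likelihood together with the full profile.
#' Log-likelihood ties (within 1e-4) are broken toward the smallest `c`;
#' with homogeneous reliabilities the profile is flat and the smallest
#' candidate is returned.
#'
#' @param y deregressed dependent values.
#' @param x marker gene counts.
#' @param relDrp deregressed reliabilities.
#' @param h variance ratio.
#' @param K optional kinship matrix (see [fitMarkerModel()]).
#' @param cGrid candidate values of `c`.
#' @return list with `cBest`, `profile` (data.frame `c`, `logLik`), and
#'   `fit` (the [fitMarkerModel()] result at `cBest`).
#' @export
gridSearchC <- function(y, x, relDrp, h, K = NULL,
                        cGrid = seq(0, 0.95, by = 0.05)) {
  fits <- lapply(cGrid, function(cc)
    tryCatch(fitMarkerModel(y, x, K = K,
                            weights = garrickWeight(relDrp, cc, h)),
             error = function(e) NULL))
  ll <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$logLik,
               numeric(1))
  if (all(is.na(ll))) stop("all grid-search fits failed")
  best <- which(ll >= max(ll, na.rm = TRUE) - 1e-4)[1L]
  list(cBest = cGrid[best],
       profile = data.frame(c = cGrid, logLik = ll),
       fit = fits[[best]])
}
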