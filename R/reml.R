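# Internal REML machinery.
#
# Two engines:
#  * .remlParentModel(): the reduced imprinting model (two correlated
#    transmitting abilities per parent with an A x 2x2 Kronecker covariance)
#    and the reduced animal model (single breeding value, TA = BV/2). The
#    phenotyped progeny's Mendelian-sampling terms are absorbed into a
#    per-record residual variance, which makes the coefficient matrix small
#    (fixed effects + 2q or q parental effects) regardless of the number of
#    records. Restricted likelihood maximized by Nelder-Mead over
#    log-variances and the z-transformed TA correlation.
#  * .remlMarker(): single-marker mixed model y = Xb + u + e with
#    Var(u) = K * vu, Var(e) = ve * W^-1, profiled REML over the variance
#    ratio via the spectral decomposition of the (weight-standardized)
#    kinship; reduces to (weighted) least squares when K is absent.
#
# Both return full REML log-likelihoods (all constants kept) so that fits
# with different known weight structures remain comparable, as required by
# the c-parameter grid search.

# ---------------------------------------------------------------------------
# Parent-model engine

# Build per-residual-class crossproducts. M = [X | Z] sparse; records are
# grouped by the (few) distinct Mendelian-sampling multipliers so each
# likelihood evaluation is dense algebra on the coefficient matrix only.
.parentPrecompute <- function(y, sireIdx, damIdx, qpar, X, model) {
  n <- length(y)
  p <- ncol(X)
  if (model == "imprinting") {
    Z <- sparseMatrix(i = rep(seq_len(n), 2L),
                      j = c(sireIdx, qpar + damIdx),
                      x = 1, dims = c(n, 2L * qpar))
  } else {
    Z <- sparseMatrix(i = rep(seq_len(n), 2L),
                      j = c(sireIdx, damIdx),
                      x = 0.5, dims = c(n, qpar))
  }
  M <- cbind(Matrix(X, sparse = TRUE), Z)
  M
}

# Restricted log-likelihood (times -2) and, on request, solutions.
.parentEval <- function(theta, pre, want = c("ll", "fit")) {
  want <- match.arg(want)
  p <- pre$p; q <- pre$q; n <- pre$n
  if (pre$model == "imprinting") {
    if (any(!is.finite(theta))) return(list(m2ll = Inf))
    vs <- exp(theta[1L]); vd <- exp(theta[2L])
    # keep the TA correlation strictly inside (-1, 1) so Sigma stays
    # invertible when the imprinting variance approaches zero
    rho <- max(-0.99999, min(0.99999, tanh(theta[3L])))
    ve <- exp(theta[4L])
    cv <- rho * sqrt(vs * vd)
    Sig <- matrix(c(vs, cv, cv, vd), 2L)
    SigInv <- tryCatch(solve(Sig), error = function(e) NULL)
    if (is.null(SigInv)) return(list(m2ll = Inf))
    G0inv <- kronecker(SigInv, pre$Ainv)
    logdetG0 <- q * determinant(Sig, logarithm = TRUE)$modulus +
      2 * pre$logdetA
    rcl <- ve + pre$clsKs * vs + pre$clsKd * vd
  } else {
    va <- exp(theta[1L]); ve <- exp(theta[2L])
    G0inv <- pre$Ainv / va
    logdetG0 <- q * log(va) + pre$logdetA
    rcl <- ve + pre$clsKm * va
  }
  if (any(rcl <= 0)) return(list(m2ll = Inf))
  nr <- p + ifelse(pre$model == "imprinting", 2L, 1L) * q
  C <- matrix(0, nr, nr)
  rhs <- numeric(nr)
  yRy <- 0; logdetR <- 0
  for (k in seq_along(rcl)) {
    C <- C + pre$MtM[[k]] / rcl[k]
    rhs <- rhs + pre$Mty[[k]] / rcl[k]
    yRy <- yRy + pre$yty[k] / rcl[k]
    logdetR <- logdetR + pre$ncl[k] * log(rcl[k])
  }
  ir <- (p + 1L):nr
  C[ir, ir] <- C[ir, ir] + G0inv
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(list(m2ll = Inf))
  logdetC <- 2 * sum(log(diag(ch)))
  sol <- backsolve(ch, forwardsolve(ch, rhs, upper.tri = TRUE,
                                    transpose = TRUE))
  yPy <- yRy - sum(rhs * sol)
  m2ll <- (n - p) * log(2 * pi) + logdetR +
    as.numeric(logdetG0) + logdetC + yPy
  if (want == "ll") return(list(m2ll = m2ll))
  Cinv <- chol2inv(ch)
  list(m2ll = m2ll, sol = sol, Cinv = Cinv, resvar = rcl)
}

# y: records; sireIdx/damIdx: 1..q indices into the parent block (rows of A);
# A: relationship among the q modelled (un-phenotyped) individuals;
# extraFixed: additional fixed covariates beyond the intercept.
.remlParentModel <- function(y, sireIdx, damIdx, A,
                             model = c("imprinting", "additive"),
                             extraFixed = NULL, start = NULL,
                             fixed = FALSE, reltol = 1e-10, maxit = 1500L) {
  model <- match.arg(model)
  n <- length(y)
  q <- nrow(A)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(extraFixed)) X <- cbind(X, as.matrix(extraFixed))
  p <- ncol(X)
  Fped <- diag(A) - 1
  ks <- 1 - Fped[sireIdx]
  kd <- 1 - Fped[damIdx]
  km <- 0.5 - 0.25 * (Fped[sireIdx] + Fped[damIdx])
  key <- if (model == "imprinting") paste(signif(ks, 12), signif(kd, 12))
         else paste(signif(km, 12))
  cls <- match(key, unique(key))
  ncls <- max(cls)
  M <- .parentPrecompute(y, sireIdx, damIdx, q, X, model)
  MtM <- vector("list", ncls); Mty <- vector("list", ncls)
  yty <- numeric(ncls); ncl <- integer(ncls)
  clsKs <- numeric(ncls); clsKd <- numeric(ncls); clsKm <- numeric(ncls)
  for (k in seq_len(ncls)) {
    rows <- which(cls == k)
    Mk <- M[rows, , drop = FALSE]
    MtM[[k]] <- as.matrix(crossprod(Mk))
    Mty[[k]] <- as.numeric(crossprod(Mk, y[rows]))
    yty[k] <- sum(y[rows]^2)
    ncl[k] <- length(rows)
    clsKs[k] <- ks[rows[1L]]; clsKd[k] <- kd[rows[1L]]
    clsKm[k] <- km[rows[1L]]
  }
  chA <- chol(A)
  pre <- list(model = model, p = p, q = q, n = n,
              Ainv = chol2inv(chA), logdetA = 2 * sum(log(diag(chA))),
              MtM = MtM, Mty = Mty, yty = yty, ncl = ncl,
              clsKs = clsKs, clsKd = clsKd, clsKm = clsKm)
  vy <- var(y)
  theta0 <- if (model == "imprinting") {
    if (is.null(start)) c(log(0.15 * vy), log(0.15 * vy), atanh(0.5),
                          log(0.6 * vy))
    else c(log(start[["sigma2s"]]), log(start[["sigma2d"]]),
           atanh(max(-0.99, min(0.99, start[["sigmasd"]] /
             sqrt(start[["sigma2s"]] * start[["sigma2d"]])))),
           log(start[["sigma2e"]]))
  } else {
    if (is.null(start)) c(log(0.4 * vy), log(0.6 * vy))
    else c(log(start[["sigma2a"]]), log(start[["sigma2e"]]))
  }
  trace <- list()
  if (fixed) {
    best <- list(par = theta0, value = .parentEval(theta0, pre)$m2ll)
  } else {
    best <- NULL
    for (attempt in 1:4) {
      opt <- optim(theta0, function(th) .parentEval(th, pre)$m2ll,
                   method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit))
      trace[[attempt]] <- c(m2ll = opt$value, conv = opt$convergence)
      if (!is.null(best) && best$value - opt$value < 1e-6) { best <- if (opt$value < best$value) opt else best; break }
      best <- opt
      theta0 <- opt$par
    }
    if (is.null(best) || !is.finite(best$value))
      stop("REML did not converge; trace: ",
           paste(vapply(trace, function(t) sprintf("%.6f", t[1]), ""),
                 collapse = " -> "))
  }
  fit <- .parentEval(best$par, pre, want = "fit")
  th <- best$par
  vc <- if (model == "imprinting") {
    vs <- exp(th[1L]); vd <- exp(th[2L])
    rho <- max(-0.99999, min(0.99999, tanh(th[3L])))
    c(sigma2s = vs, sigma2d = vd, sigmasd = rho * sqrt(vs * vd),
      sigma2e = exp(th[4L]))
  } else {
    c(sigma2a = exp(th[1L]), sigma2e = exp(th[2L]))
  }
  sol <- fit$sol
  Cinv <- fit$Cinv
  out <- list(model = model, varcomp = vc, logLik = -0.5 * best$value,
              fixef = setNames(sol[seq_len(p)], colnames(X)),
              vcovFixef = Cinv[seq_len(p), seq_len(p), drop = FALSE],
              n = n, p = p, trace = trace)
  dA <- diag(A)
  if (model == "imprinting") {
    iS <- p + seq_len(q); iD <- p + q + seq_len(q)
    pevS <- diag(Cinv)[iS]; pevD <- diag(Cinv)[iD]
    pec <- Cinv[cbind(iS, iD)]
    vimp <- vc["sigma2s"] + vc["sigma2d"] - 2 * vc["sigmasd"]
    clip01 <- function(z) pmin(1, pmax(0, z))
    out$taSire <- sol[iS]; out$taDam <- sol[iD]
    out$relSire <- clip01(1 - pevS / (dA * vc["sigma2s"]))
    out$relDam <- clip01(1 - pevD / (dA * vc["sigma2d"]))
    pevE <- pevS + pevD - 2 * pec
    out$relEpoe <- if (vimp > 1e-12) clip01(1 - pevE / (dA * vimp))
                   else rep(0, q)
    out$pevSire <- pevS; out$pevDam <- pevD; out$pevEpoe <- pevE
  } else {
    iA <- p + seq_len(q)
    pev <- diag(Cinv)[iA]
    out$ta <- 0.5 * sol[iA]
    out$relTa <- pmin(1, pmax(0, 1 - pev / (dA * vc["sigma2a"])))
    out$pevTa <- 0.25 * pev
  }
  out
}

# ---------------------------------------------------------------------------
# Single-marker mixed model

# Weighted least squares with full REML log-likelihood.
.wlsFit <- function(y, X, w) {
  n <- length(y); p <- ncol(X)
  fit <- lm.wfit(X, y, w)
  if (fit$rank < p) stop("singular fixed-effects design")
  rss <- sum(w * fit$residuals^2)
  s2 <- rss / (n - p)
  XtWX <- crossprod(X * sqrt(w))
  vc <- chol2inv(chol(XtWX)) * s2
  m2ll <- (n - p) * (log(2 * pi) + log(s2) + 1) - sum(log(w)) +
    determinant(XtWX, logarithm = TRUE)$modulus
  list(coef = fit$coefficients, vcov = vc, s2 = s2,
       logLik = -0.5 * as.numeric(m2ll), df2 = n - p,
       varcomp = c(sigma2u = 0, sigma2e = s2))
}

# Spectral-decomposition REML (EMMA-style) for V = vu*K + ve*W^-1.
.kinshipReml <- function(y, X, K, w, eig = NULL) {
  n <- length(y); p <- ncol(X)
  sw <- sqrt(w)
  if (is.null(eig)) {
    Ks <- K * tcrossprod(sw)
    eig <- eigen(Ks, symmetric = TRUE)
    eig$values <- pmax(eig$values, 0)
  }
  U <- eig$vectors; d <- eig$values
  yr <- crossprod(U, y * sw)
  Xr <- crossprod(U, X * sw)
  sumlogw <- sum(log(w))
  prof <- function(lg) {
    g <- exp(lg)
    v <- 1 / (g * d + 1)
    fit <- lm.wfit(Xr, yr, v)
    rss <- sum(v * fit$residuals^2)
    s2 <- rss / (n - p)
    XtVX <- crossprod(Xr * sqrt(v))
    ld <- determinant(XtVX, logarithm = TRUE)$modulus
    (n - p) * (log(2 * pi) + log(s2) + 1) + sum(log(g * d + 1)) -
      sumlogw + as.numeric(ld)
  }
  op <- optimize(prof, c(-18, 12), tol = 1e-8)
  # guard the lower boundary: the no-kinship limit
  if (prof(-18) < op$objective) op <- list(minimum = -18, objective = prof(-18))
  g <- exp(op$minimum)
  v <- 1 / (g * d + 1)
  fit <- lm.wfit(Xr, yr, v)
  if (fit$rank < p) stop("singular fixed-effects design")
  rss <- sum(v * fit$residuals^2)
  s2 <- rss / (n - p)
  vc <- chol2inv(chol(crossprod(Xr * sqrt(v)))) * s2
  list(coef = fit$coefficients, vcov = vc, s2 = s2,
       logLik = -0.5 * op$objective, df2 = n - p,
       varcomp = c(sigma2u = g * s2, sigma2e = s2), eig = eig)
}

#' Single-marker mixed-model association fit
#'
#' Fits `y = intercept + covariates + b * x + u + e` with an optional random
#' polygenic term `u ~ N(0, K * sigma2u)` and residuals `e ~ N(0, sigma2e /
#' w)` for known weights `w`. Variance components are estimated by REML
#' (profiled over the variance ratio on the spectral decomposition of `K`);
#' without `K` the fit reduces to (weighted) least squares, where the F
#' statistic equals the squared t of the slope. The marker effect is tested
#' by a conditional Wald F with 1 numerator and `n - rank(X)` denominator
#' degrees of freedom.
#'
#' @param y response vector.
#' @param x marker gene counts (or any single covariate to test).
#' @param covariates optional additional fixed covariates (matrix).
#' @param K optional positive definite relationship matrix for the scanned
#'   individuals (blend upstream if rank deficient).
#' @param weights optional positive residual weights.
#' @param eig optional pre-computed spectral decomposition of the
#'   (weight-standardized) kinship, as returned in the `eig` element of a
#'   previous fit with identical `K` and `weights`; reused across the
#'   markers of a scan.
#' @return list with `effect`, `se`, `F`, `p`, `logLik`, `varcomp`, `df2`,
#'   `eig` (kinship path only), `skipped` (TRUE when `x` is constant and
#'   the marker cannot be tested).
#' @export
fitMarkerModel <- function(y, x, covariates = NULL, K = NULL,
                           weights = NULL, eig = NULL) {
  keep <- complete.cases(y, x)
  if (!all(keep)) eig <- NULL
  y <- y[keep]; x <- x[keep]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[keep]
  if (!is.null(K)) K <- K[keep, keep, drop = FALSE]
  if (length(unique(x)) < 2L)
    return(list(effect = NA_real_, se = NA_real_, F = NA_real_,
                p = NA_real_, logLik = NA_real_,
                varcomp = c(sigma2u = NA_real_, sigma2e = NA_real_),
                df2 = NA_integer_, skipped = TRUE))
  X <- cbind(`(Intercept)` = 1, covariates, marker = x)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  if (any(w <= 0)) stop("weights must be positive")
  ft <- if (is.null(K) && is.null(eig)) .wlsFit(y, X, w)
        else .kinshipReml(y, X, K, w, eig = eig)
  j <- ncol(X)
  b <- ft$coef[j]; se <- sqrt(ft$vcov[j, j])
  Fst <- (b / se)^2
  list(effect = unname(b), se = unname(se), F = unname(Fst),
       p = unname(pf(Fst, 1, ft$df2, lower.tail = FALSE)),
       logLik = ft$logLik, varcomp = ft$varcomp, df2 = ft$df2,
       eig = ft$eig, skipped = FALSE)
}
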