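# Deregression, PA-correction, weighting and the c grid search.

test_that("founders collapse to simple deregression", {
  d <- deregressEstimates(values = c(0.4, -0.2), rel = c(0.5, 0.25), h = 0.3)
  expect_equal(d$valueDrp, c(0.4 / 0.5, -0.2 / 0.25))
  expect_equal(d$relDrp, c(0.5, 0.25))
  expect_false(any(d$flagged))
})

test_that("perfect information leaves values unchanged", {
  d <- deregressEstimates(values = 2, rel = 1 - 1e-9,
                          sireValues = 1, damValues = 0.5,
                          sireRel = 0.8, damRel = 0.6, h = 0.3)
  expect_equal(d$valueDrp, 2, tolerance = 1e-4)
  expect_equal(d$relDrp, 1, tolerance = 1e-4)
})

test_that("the PA absorption system round-trips through reliabilities", {
  # independent construction: pick effective record contributions, build the
  # 2x2 MME, read reliabilities off its inverse, then recover the
  # contributions from those reliabilities
  lambda <- (1 - 0.25) / 0.25
  for (zs in list(c(zPA = 4.2, zI = 1.7), c(zPA = 0.8, zI = 6.0))) {
    C <- matrix(c(zs["zPA"] + 4 * lambda, -2 * lambda,
                  -2 * lambda, zs["zI"] + 2 * lambda), 2)
    Ci <- solve(C)
    relPA <- 1 - lambda * Ci[1, 1]
    relI <- 1 - lambda * Ci[2, 2]
    gs <- poescan:::.garrickSystem(relPA, relI, lambda)
    expect_equal(gs$zPA, unname(zs["zPA"]), tolerance = 1e-8)
    expect_equal(gs$zI, unname(zs["zI"]), tolerance = 1e-8)
  }
})

test_that("records without own information are flagged, not deregressed", {
  d <- deregressEstimates(values = 0.3, rel = 0.1,
                          sireRel = 0.8, damRel = 0.8, h = 0.3)
  expect_true(d$flagged)            # rel (0.1) <= relPA (0.4)
  expect_true(is.na(d$valueDrp))
})

test_that("deregression is reliability-monotone", {
  rels <- c(0.9, 0.6, 0.3, 0.1)
  d <- deregressEstimates(values = rep(0.5, 4), rel = rels, h = 0.3)
  expect_true(all(diff(abs(d$valueDrp)) > 0))
})

test_that("weights follow the Garrick formula and are monotone in c", {
  expect_equal(garrickWeight(0.5, 0, 0.5), 1)
  cs <- seq(0, 0.9, by = 0.1)
  w <- vapply(cs, function(cc) garrickWeight(0.4, cc, 0.3), numeric(1))
  expect_true(all(diff(w) < 0))
  expect_equal(garrickWeight(c(0.4, 0.4), 0.2, 0.3)[1],
               garrickWeight(c(0.4, 0.4), 0.2, 0.3)[2])
  expect_error(garrickWeight(0, 0.1, 0.3))
})

test_that("reliability filter applies the 3% cutoff", {
  rec <- data.frame(valueDrp = 1:4, relDrp = c(0.029, 0.031, 0.01, 0.5),
                    flagged = FALSE)
  kept <- suppressMessages(filterReliability(rec))
  expect_equal(kept$relDrp, c(0.031, 0.5))
  expect_equal(nrow(suppressMessages(
    filterReliability(data.frame(valueDrp = 1:3,
                                 relDrp = c(0.01, 0.05, 0.5),
                                 flagged = FALSE)))), 2)
  # threshold zero retains everything unflagged
  expect_equal(nrow(filterReliability(rec, threshold = 0)), 4)
  expect_error(filterReliability(rec, threshold = 0.9), "no records")
})

test_that("grid search over c: ties, custom grids and idempotence", {
  set.seed(80)
  n <- 60
  x <- rbinom(n, 2, 0.5)
  y <- 0.2 * x + rnorm(n)
  relHom <- rep(0.4, n)
  gs <- gridSearchC(y, x, relDrp = relHom, h = 0.3)
  # homogeneous reliabilities: flat profile, smallest c wins
  expect_equal(gs$cBest, 0)
  expect_lt(diff(range(gs$profile$logLik)), 1e-6)
  # custom two-point grid
  gs2 <- gridSearchC(y, x, relDrp = runif(n, 0.2, 0.8), h = 0.3,
                     cGrid = c(0, 0.5))
  expect_true(gs2$cBest %in% c(0, 0.5))
  expect_equal(nrow(gs2$profile), 2)
  # refitting at the returned c reproduces the profile value
  refit <- fitMarkerModel(y, x,
                          weights = garrickWeight(relHom, gs$cBest, 0.3))
  expect_equal(refit$logLik,
               gs$profile$logLik[gs$profile$c == gs$cBest])
})
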