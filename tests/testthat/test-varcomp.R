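test_that("component-to-summary formulas are exact", {
  expect_equal(h2FromComponents(1, 1), 0.5)
  expect_equal(h2FromComponents(0, 1), 0)
  expect_equal(h2FromComponents(0.53, 0.47), 0.53)
  expect_error(h2FromComponents(0, 0), "undefined")
  expect_error(h2FromComponents(-1, 1), ">= 0")

  expect_equal(rgFromComponents(0, 1, 1), 0)
  expect_equal(rgFromComponents(2, 4, 4), 0.5)
  sx <- 2.3; sy <- 0.7
  expect_equal(rgFromComponents(-0.14 * sqrt(sx * sy), sx, sy), -0.14)
  r <- rgFromComponents(1.2, 1, 1)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "clamped"))
  expect_error(rgFromComponents(0, 0, 1), "> 0")
})

test_that("boundary-mixture LRT follows the half-half chi-square reference", {
  mkFit <- function(logL) {
    new("VarCompFit", traits = "y", G = matrix(0.1), R = matrix(0.9),
        h2 = 0.1, seH2 = NA_real_, rG = NA_real_, seRG = NA_real_,
        rP = NA_real_, rE = NA_real_, logLik = logL, n = 100L,
        fixef = 0, vcovComponents = matrix(NA_real_, 2, 2),
        convergence = list(iterations = 1L, gradNorm = 0,
                           converged = TRUE, boundary = FALSE))
  }
  expect_equal(lrtVariance(mkFit(-50), mkFit(-50)), 0.5)
  expect_equal(lrtVariance(mkFit(-50 + 2.706 / 2), mkFit(-50)), 0.05,
               tolerance = 1e-3)
  # negative statistics are truncated at the boundary mass
  expect_equal(lrtVariance(mkFit(-51), mkFit(-50)), 0.5)
  bad <- mkFit(-50); bad@n <- 99L
  expect_error(lrtVariance(mkFit(-49), bad), "nested")
})

test_that("univariate REML matches a brute-force grid-search oracle", {
  sim <- remlFixture()                    # 10 families, 40 individuals
  fit <- remlUnivariate(sim$ped, sim$pheno, "y")

  ids <- sim$pheno$id
  A <- relationshipMatrix(sim$ped, ids = ids)
  X <- fixtureDesign(sim$pheno)
  y <- sim$pheno$y

  # coarse 50x50 grid, then Nelder-Mead refinement of the brute-force logL
  vp <- var(resid(lm(y ~ X - 1)))
  grid <- seq(0.02, 2, length.out = 50) * vp
  gridLogL <- outer(grid, grid, Vectorize(function(sa, se)
    bruteRemlLogL(A, X, y, sa, se)))
  best <- arrayInd(which.max(gridLogL), dim(gridLogL))
  ref <- optim(c(grid[best[1]], grid[best[2]]),
               function(th) {
                 if (any(th <= 0)) return(1e10)
                 -bruteRemlLogL(A, X, y, th[1], th[2])
               }, control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(fit@G[1, 1] - ref$par[1]), 1e-4)
  expect_lt(abs(fit@R[1, 1] - ref$par[2]), 1e-4)

  # returned restricted logL dominates every grid point
  expect_gte(fit@logLik, max(gridLogL) - 1e-8)
  expect_equal(fit@logLik,
               bruteRemlLogL(A, X, y, fit@G[1, 1], fit@R[1, 1]),
               tolerance = 1e-6)
})

test_that("estimates are invariant to row order and affine trait rescaling", {
  sim <- simulateCohort(simConfig(
    nFamilies = 150L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")), G = matrix(0.5), R = matrix(0.5),
    betaAge = 0.02, seed = 90L
  ))
  fit <- remlUnivariate(sim$ped, sim$pheno, "y")

  perm <- sample(nrow(sim$pheno))
  fitP <- remlUnivariate(sim$ped, sim$pheno[perm, ], "y")
  expect_equal(fitP@G[1, 1], fit@G[1, 1], tolerance = 1e-8)
  expect_equal(fitP@logLik, fit@logLik, tolerance = 1e-8)

  t2 <- sim$pheno
  t2$y <- 3.5 * t2$y + 10
  fitS <- remlUnivariate(sim$ped, t2, "y")
  expect_equal(fitS@h2, fit@h2, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fitS@G[1, 1], 3.5^2 * fit@G[1, 1], tolerance = 1e-5)
})

test_that("unrelated-founder cohorts trigger the confounding warning", {
  set.seed(91)
  ped <- pedigree(sprintf("i%03d", 1:80), rep(NA, 80), rep(NA, 80),
                  sex = rep(1:2, 40))
  t <- data.frame(id = pedIds(ped), family = families(ped),
                  age = rnorm(80, 40, 10), sex = rep(1:2, 40),
                  y = rnorm(80))
  expect_warning(fit <- remlUnivariate(ped, t, "y"), "confounded")
  expect_true(fit@convergence$flatLikelihood)
  expect_true(fit@convergence$boundary)
  expect_equal(fit@h2, 0, ignore_attr = TRUE)
})

test_that("bivariate fit with fixed off-diagonals factorizes to the univariate fits", {
  sim <- simulateCohort(simConfig(
    nFamilies = 200L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("x"), traitSpec("y")),
    G = matrix(c(0.5, 0.2, 0.2, 0.4), 2), R = diag(c(0.5, 0.6)), seed = 92L
  ))
  fitB <- remlBivariate(sim$ped, sim$pheno, c("x", "y"),
                        fixG12 = TRUE, fixR12 = TRUE)
  fitX <- remlUnivariate(sim$ped, sim$pheno, "x")
  fitY <- remlUnivariate(sim$ped, sim$pheno, "y")
  expect_equal(fitB@G[1, 1], fitX@G[1, 1], tolerance = 1e-6)
  expect_equal(fitB@R[1, 1], fitX@R[1, 1], tolerance = 1e-6)
  expect_equal(fitB@G[2, 2], fitY@G[1, 1], tolerance = 1e-6)
  expect_equal(fitB@rG, 0)
})

test_that("bivariate fits satisfy the correlation and decomposition identities", {
  sim <- simulateCohort(simConfig(
    nFamilies = 400L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("x"), traitSpec("y")),
    G = matrix(c(0.5, 0.25, 0.25, 0.4), 2),
    R = matrix(c(0.5, 0.1, 0.1, 0.6), 2), seed = 93L
  ))
  fit <- remlBivariate(sim$ped, sim$pheno, c("x", "y"))
  expect_lte(abs(fit@rG), 1)
  expect_lte(abs(fit@rP), 1)
  expect_lte(abs(fit@rE), 1)
  # phenotypic (co)variance decomposes into genetic + residual by definition
  P <- fit@G + fit@R
  expect_equal(fit@rP, P[1, 2] / sqrt(P[1, 1] * P[2, 2]), tolerance = 1e-12)

  # missing one-of-two traits: joint likelihood still identifies r_G
  t2 <- sim$pheno
  set.seed(94)
  t2$y[sample(nrow(t2), 300)] <- NA
  fitM <- remlBivariate(sim$ped, t2, c("x", "y"))
  expect_lt(abs(fitM@rG - fit@rG), 0.25)
  expect_true(fitM@convergence$converged)
})

test_that("pre-residualizing fixed effects approximates the joint fit", {
  sim <- simulateCohort(simConfig(
    nFamilies = 1000L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")), G = matrix(0.5), R = matrix(0.5),
    betaAge = 0.03, betaSex = 0.4, seed = 95L
  ))
  fit <- remlUnivariate(sim$ped, sim$pheno, "y")
  t2 <- sim$pheno
  t2$yr <- resid(lm(y ~ age + I(age^2) + factor(sex), data = t2))
  fitR <- remlUnivariate(sim$ped, t2, "yr", covariates = character(0))
  expect_lt(abs(fit@h2 - fitR@h2), 0.01)
})
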