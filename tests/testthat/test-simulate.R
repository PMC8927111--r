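test_that("liability thresholding hits the prevalence quantile", {
  y <- liabilityThreshold(c(-1, 0.1, 3), 0.5)
  expect_equal(attr(y, "threshold"), 0)
  expect_equal(as.integer(y), c(0L, 1L, 1L))

  expect_equal(attr(liabilityThreshold(0, 0.02275), "threshold"), 2.0,
               tolerance = 1e-4)
  expect_error(liabilityThreshold(0, 0), "prevalence")
  expect_error(liabilityThreshold(0, 1), "prevalence")

  set.seed(99)
  frac <- mean(liabilityThreshold(rnorm(100000), 0.15))
  expect_lt(abs(frac - 0.15), 0.004)   # 3 binomial sd
})

test_that("assortative rank-matching hits the target spouse correlation", {
  set.seed(21)
  x <- rnorm(10000)
  y <- rnorm(10000)
  j <- applyAssortativeMating(x, y, 0.3)
  expect_setequal(j, seq_along(y))        # a permutation: marginals unchanged
  expect_lt(abs(cor(x, y[j]) - 0.30), 0.03)

  j0 <- applyAssortativeMating(x, y, 0)
  expect_lt(abs(cor(x, y[j0])), 0.03)

  expect_identical(applyAssortativeMating(1.2, -0.5, 0.9), 1L)
  expect_error(applyAssortativeMating(x, y, 1), "correlation")
})

test_that("simulation is bit-identical under a fixed configuration", {
  cfg <- simConfig(nFamilies = 50L, structure = "three_generation",
                   traits = list(traitSpec("y"),
                                 traitSpec("d", "binary", prevalence = 0.2)),
                   G = diag(c(0.5, 0.5)), R = diag(c(0.5, 0.5)),
                   spouseModel = list(type = "shared_env", variance = 0.1),
                   missingRate = 0.05, seed = 7L)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$breedingValues, s2$truth$breedingValues)
})

test_that("additive model identities hold in large simulations", {
  sim <- simulateCohort(simConfig(
    nFamilies = 2000L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")), G = matrix(1), R = matrix(1), seed = 31L
  ))
  pairs <- classifyPairs(sim$ped)
  y <- setNames(sim$pheno$y, sim$pheno$id)
  po <- pairs[pairs$relation == "parent-offspring", ]
  expect_lt(abs(cov(y[po$id1], y[po$id2]) - 0.5), 0.06)

  # no genetic variance: sibling phenotypes uncorrelated
  sim0 <- simulateCohort(simConfig(
    nFamilies = 2000L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")), G = matrix(0), R = matrix(1), seed = 32L
  ))
  p0 <- classifyPairs(sim0$ped)
  sib0 <- p0[p0$relation == "full-sibling", ]
  y0 <- setNames(sim0$pheno$y, sim0$pheno$id)
  expect_lt(abs(cor(y0[sib0$id1], y0[sib0$id2])), 0.05)
})

test_that("sibling correlation approaches h2/2 (no shared environment)", {
  h2 <- 0.6
  sim <- simulateCohort(simConfig(
    nFamilies = 5000L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")), G = matrix(h2), R = matrix(1 - h2),
    seed = 33L
  ))
  pairs <- classifyPairs(sim$ped)
  sib <- pairs[pairs$relation == "full-sibling", ]
  y <- setNames(sim$pheno$y, sim$pheno$id)
  r <- cor(y[sib$id1], y[sib$id2])
  expect_lt(abs(r - h2 / 2), 3 / sqrt(nrow(sib)))
})

test_that("first-degree recurrence risk increases with heritability", {
  lam <- vapply(c(0, 0.3, 0.6), function(h2) {
    sim <- simulateCohort(simConfig(
      nFamilies = 1500L, structure = "nuclear", kChildren = 2L,
      traits = list(traitSpec("d", "binary", prevalence = 0.15)),
      G = matrix(h2), R = matrix(1 - h2), seed = 55L
    ))
    ex <- suppressMessages(
      buildExposure(sim$ped, sim$pheno, "d", "first_degree"))
    lambdaNaive(sim$pheno, ex, "d", nBoot = 200L, seed = 56L)@lambda
  }, numeric(1))
  expect_true(all(diff(lam) > 0))
  expect_lt(abs(lam[1] - 1), 0.15)
})

test_that("shared spouse environment and assortative mating induce spouse correlation", {
  simA <- simulateCohort(simConfig(
    nFamilies = 3000L, structure = "nuclear", kChildren = 1L,
    traits = list(traitSpec("y")), G = matrix(0.5), R = matrix(0.5),
    spouseModel = list(type = "assortative", rho = 0.4), seed = 61L
  ))
  pairs <- classifyPairs(simA$ped)
  sp <- pairs[pairs$relation == "spouse", ]
  y <- setNames(simA$pheno$y, simA$pheno$id)
  expect_lt(abs(cor(y[sp$id1], y[sp$id2]) - 0.4), 0.05)

  simE <- simulateCohort(simConfig(
    nFamilies = 3000L, structure = "nuclear", kChildren = 1L,
    traits = list(traitSpec("y")), G = matrix(0.5), R = matrix(0.5),
    spouseModel = list(type = "shared_env", variance = 0.5), seed = 62L
  ))
  pairsE <- classifyPairs(simE$ped)
  spE <- pairsE[pairsE$relation == "spouse", ]
  yE <- setNames(simE$pheno$y, simE$pheno$id)
  # shared variance v on top of unit variance: expected correlation v/(1+v)
  expect_lt(abs(cor(yE[spE$id1], yE[spE$id2]) - 1 / 3), 0.05)
})

test_that("cohort files round-trip losslessly through the readers", {
  cfg <- simConfig(nFamilies = 20L, structure = "three_generation",
                   traits = list(traitSpec("y"),
                                 traitSpec("d", "binary", prevalence = 0.3)),
                   G = diag(c(0.4, 0.4)), R = diag(c(0.6, 0.6)), seed = 8L)
  sim <- simulateCohort(cfg)
  dir <- tempfile("cohort")
  writeCohort(sim, dir)
  ped <- readPedigree(file.path(dir, "cohort.fam"), "plink_fam")
  expect_setequal(pedIds(ped), pedIds(sim$ped))
  expect_identical(pedFather(ped)[pedIds(sim$ped)], pedFather(sim$ped))
  expect_identical(pedSex(ped)[pedIds(sim$ped)], pedSex(sim$ped))
  pheno <- readPhenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(pheno$y, sim$pheno$y, tolerance = 1e-12)
  expect_identical(pheno$d, sim$pheno$d)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$trueH2[["y"]], 0.4, tolerance = 1e-12)

  # invalid covariance structures are rejected before sampling
  expect_error(
    simConfig(nFamilies = 5L, traits = list(traitSpec("a"), traitSpec("b")),
              G = matrix(c(1, 2, 2, 1), 2), R = diag(2)),
    "positive semi-definite"
  )
})
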