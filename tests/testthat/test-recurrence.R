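test_that("exposure indicators follow the relative-set definitions", {
  trio <- makeTrio()
  t <- data.frame(id = c("fa", "mo", "ch"), family = "f1",
                  d = c(1L, 0L, 0L), stringsAsFactors = FALSE)
  exFD <- suppressMessages(buildExposure(trio, t, "d", "first_degree"))
  expect_true(exFD[["ch"]])           # father affected
  expect_false(exFD[["fa"]])          # child unaffected
  exSp <- suppressMessages(buildExposure(trio, t, "d", "spouse"))
  expect_true(exSp[["mo"]])
  expect_false(exSp[["fa"]])
  expect_true(is.na(exSp[["ch"]]))    # child has no spouse: dropped

  # mutual sibling exposure (own status never enters)
  sibs <- pedigree(c("f", "m", "s1", "s2"), c(NA, NA, "f", "f"),
                   c(NA, NA, "m", "m"), sex = c(1, 2, 1, 2))
  ts <- data.frame(id = c("f", "m", "s1", "s2"), family = "f1",
                   d = c(0L, 0L, 1L, 1L))
  ex <- suppressMessages(buildExposure(sibs, ts, "d", "first_degree"))
  expect_true(ex[["s1"]] && ex[["s2"]])

  # relatives with missing exposure trait: individual dropped and logged
  tm <- data.frame(id = c("fa", "mo", "ch"), family = "f1",
                   d = c(NA, NA, 1L))
  expect_message(
    exm <- buildExposure(trio, tm, "d", "first_degree"),
    "dropped"
  )
  expect_true(is.na(exm[["ch"]]))
  expect_true(exm[["fa"]])
})

test_that("naive lambda is the prevalence ratio against the total population", {
  # 100 individuals: 20 exposed of whom 8 affected; 80 unexposed, 12 affected
  # prevalence among exposed 0.40, overall 0.20 -> lambda 2.0
  t <- data.frame(
    id = as.character(1:100),
    family = as.character(rep(1:50, each = 2)),
    d = c(rep(1L, 8), rep(0L, 12), rep(1L, 12), rep(0L, 68))
  )
  ex <- c(rep(TRUE, 20), rep(FALSE, 80))
  res <- lambdaNaive(t, ex, "d", nBoot = 500L, seed = 4L)
  expect_equal(res@lambda, 2.0)
  expect_equal(res@lambdaPop, 2.0)
  expect_equal(res@lambdaUnexposed, (8 / 20) / (12 / 80))
  expect_equal(res@nExposed, 20L)
  expect_equal(res@nEvents, 20L)

  # boundary: all exposed affected, overall prevalence 0.5
  t2 <- data.frame(id = as.character(1:40), family = as.character(1:40),
                   d = c(rep(1L, 10), rep(1L, 10), rep(0L, 20)))
  ex2 <- c(rep(TRUE, 10), rep(FALSE, 30))
  expect_equal(lambdaNaive(t2, ex2, "d", nBoot = 200L, seed = 5L)@lambda, 2.0)

  expect_error(lambdaNaive(t, rep(TRUE, 100), "d"), "empty")
  t$d <- 0L
  expect_error(lambdaNaive(t, ex, "d"), "zero outcome prevalence")
})

test_that("naive lambda is invariant to family relabeling and row order", {
  set.seed(8)
  t <- data.frame(
    id = as.character(1:300), family = as.character(rep(1:100, 3)),
    d = rbinom(300, 1, 0.3)
  )
  ex <- runif(300) < 0.4
  r1 <- lambdaNaive(t, ex, "d", nBoot = 300L, seed = 9L)
  perm <- sample(300)
  t2 <- t[perm, ]
  t2$family <- paste0("X", t2$family)
  r2 <- lambdaNaive(t2, ex[perm], "d", nBoot = 300L, seed = 9L)
  expect_equal(r2@lambda, r1@lambda)
  expect_equal(r2@ciLow, r1@ciLow, tolerance = 1e-12)
})

test_that("adjusted estimator equals the closed-form ratio without covariates", {
  # exposed 30/100 vs unexposed 15/100 -> prevalence ratio 2.0
  t <- data.frame(
    id = as.character(1:200), family = as.character(rep(1:100, each = 2)),
    d = c(rep(1L, 30), rep(0L, 70), rep(1L, 15), rep(0L, 85))
  )
  ex <- c(rep(TRUE, 100), rep(FALSE, 100))
  res <- lambdaAdjusted(t, ex, "d", covariates = character(0))
  expect_equal(res@lambda, 2.0, tolerance = 1e-8)
  expect_equal(res@estimator, "adjusted")
  expect_true(res@ciLow <= 2 && res@ciHigh >= 2)
})

test_that("singleton clusters reduce the clustered sandwich to plain HC0", {
  set.seed(12)
  n <- 400
  t <- data.frame(
    id = as.character(1:n), family = as.character(1:n),   # all singletons
    age = rnorm(n, 40, 10), sex = sample(1:2, n, TRUE),
    d = rbinom(n, 1, 0.3)
  )
  ex <- runif(n) < 0.5
  t$age2 <- t$age^2
  fit <- glm(d ~ ex + age + age2 + sex, family = poisson, data = t)
  vCl <- sandwich::vcovCL(fit, cluster = t$family, type = "HC0",
                          cadjust = FALSE)
  vHC <- sandwich::vcovHC(fit, type = "HC0")
  expect_lt(max(abs(vCl - vHC)), 1e-10)

  res <- lambdaAdjusted(t, ex, "d")
  seCl <- sqrt(vCl["exTRUE", "exTRUE"])
  expect_equal(res@ciHigh / res@lambda, exp(qnorm(0.975) * seCl),
               tolerance = 1e-8)
})

test_that("adjusted and naive estimators agree under covariate independence", {
  sim <- simulateCohort(simConfig(
    nFamilies = 2000L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("d", "binary", prevalence = 0.15)),
    G = matrix(0.5), R = matrix(0.5), seed = 71L
  ))
  ex <- suppressMessages(
    buildExposure(sim$ped, sim$pheno, "d", "first_degree"))
  nv <- lambdaNaive(sim$pheno, ex, "d", nBoot = 500L, seed = 72L)
  ad <- lambdaAdjusted(sim$pheno, ex, "d")
  # binary traits are thresholded before fixed effects, so age/sex are
  # independent of both exposure and outcome here
  expect_lt(abs(ad@lambda - nv@lambdaUnexposed), 0.15)

  # sandwich variance vs a direct family-cluster bootstrap of the same
  # estimand (the exposed-vs-unexposed log prevalence ratio)
  keep <- !is.na(ex) & !is.na(sim$pheno$d)
  y <- sim$pheno$d[keep]
  e <- ex[keep]
  fam <- sim$pheno$family[keep]
  famStats <- rowsum(cbind(y * e, as.numeric(e), y * !e, as.numeric(!e)),
                     fam)
  set.seed(73)
  w <- rmultinom(2000, nrow(famStats), rep(1 / nrow(famStats),
                                           nrow(famStats)))
  s <- crossprod(w, famStats)
  bootLogLam <- log((s[, 1] / s[, 2]) / (s[, 3] / s[, 4]))
  bootVar <- var(bootLogLam[is.finite(bootLogLam)])
  adSE <- (log(ad@ciHigh) - log(ad@lambda)) / qnorm(0.975)
  ratio <- adSE^2 / bootVar
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("co-aggregation matrix is self-consistent and error-tolerant", {
  sim <- simulateCohort(simConfig(
    nFamilies = 600L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("a", "binary", prevalence = 0.2),
                  traitSpec("b", "binary", prevalence = 0.2)),
    G = diag(c(0.5, 0.5)), R = diag(c(0.5, 0.5)), seed = 81L
  ))
  t <- sim$pheno
  mat <- coaggregationMatrix(sim$ped, t, c("a", "b"), "first_degree")
  expect_equal(nrow(mat), 4L)
  diagCell <- mat[mat$exposure == "a" & mat$outcome == "a", ]
  ex <- suppressMessages(buildExposure(sim$ped, t, "a", "first_degree"))
  direct <- lambdaAdjusted(t, ex, "a")
  expect_equal(diagCell$lambda, direct@lambda, tolerance = 1e-12)

  # a constant trait breaks its cells but not the matrix
  t$c <- 0L
  mat2 <- coaggregationMatrix(sim$ped, t, c("a", "c"), "first_degree")
  expect_equal(nrow(mat2), 4L)
  expect_true(any(!is.na(mat2$error)))
  expect_true(all(!is.na(mat2$lambda[mat2$exposure == "a" &
                                       mat2$outcome == "a"])))

  # cross-trait lambda is ~1 for genetically and environmentally
  # uncorrelated traits
  cross <- mat[mat$exposure != mat$outcome, ]
  expect_lt(max(abs(cross$lambda - 1)), 0.35)
})
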