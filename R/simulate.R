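#' Trait specification for the cohort simulator
#'
#' @param name trait name (column name in the simulated phenotype table).
#' @param kind `"continuous"` or `"binary"`.
#' @param prevalence population prevalence in (0,1); required for binary
#'   traits, disallowed for continuous ones.
#' @return list of class `TraitSpec`.
#' @export
traitSpec <- function(name, kind = c("continuous", "binary"),
                      prevalence = NULL) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1) {
      stop("binary trait '", name, "' needs a prevalence in (0, 1)")
    }
  } else if (!is.null(prevalence)) {
    stop("continuous trait '", name, "' must not carry a prevalence")
  }
  structure(list(name = name, kind = kind, prevalence = prevalence),
            class = "TraitSpec")
}

#' Simulation configuration
#'
#' Defines a multi-generation family cohort with known additive-genetic
#' ground truth. Traits share an additive genetic covariance matrix `G` and a
#' residual covariance matrix `R` (trait-squared units); per-trait fixed
#' effects of age, age squared and sex are added to continuous phenotypes.
#' Binary traits are liability-threshold indicators at their specified
#' prevalences, thresholded on the standardized total liability before fixed
#' effects. Spouse resemblance is optional: a couple-shared residual
#' component (`shared_env`) or assortative mating by Gaussian rank-matching
#' on the first trait's liability (`assortative`).
#'
#' Default ages are drawn per generation: grandparents 65 +/- 8, parents
#' 40 +/- 6, children 15 +/- 4 years (configurable), so age and age-squared
#' effects are estimable.
#'
#' @param nFamilies number of families.
#' @param structure `"trio"`, `"nuclear"` or `"three_generation"`.
#' @param kChildren children per couple (middle generation for
#'   `three_generation`); ignored for `trio` (always 1).
#' @param kGrandchildren children of the middle couple
#'   (`three_generation` only).
#' @param traits list of [traitSpec()] objects.
#' @param G,R genetic and residual covariance matrices, conformable with the
#'   number of traits; both must be symmetric positive semi-definite.
#' @param betaAge,betaAge2,betaSex numeric fixed-effect coefficients per
#'   trait (recycled); sex is coded 1 for female, 0 otherwise.
#' @param spouseModel list: `list(type = "none")`,
#'   `list(type = "shared_env", variance = v)` or
#'   `list(type = "assortative", rho = r)` with `0 <= r < 1`.
#' @param ageDistribution matrix with one row per generation and columns
#'   `mean`, `sd`; `NULL` for structure-specific defaults.
#' @param missingRate uniform missing-at-random masking rate per trait value.
#' @param seed integer seed recorded in the truth record; all randomness in
#'   [simulateCohort()] flows from it.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(nFamilies,
                      structure = c("nuclear", "trio", "three_generation"),
                      kChildren = 2L, kGrandchildren = 2L,
                      traits = list(traitSpec("y1")),
                      G = diag(length(traits)) * 0.5,
                      R = diag(length(traits)) * 0.5,
                      betaAge = 0, betaAge2 = 0, betaSex = 0,
                      spouseModel = list(type = "none"),
                      ageDistribution = NULL,
                      missingRate = 0,
                      seed = 1L) {
  structure <- match.arg(structure)
  nt <- length(traits)
  if (!all(vapply(traits, inherits, logical(1), "TraitSpec"))) {
    stop("'traits' must be a list of traitSpec() objects")
  }
  G <- as.matrix(G); R <- as.matrix(R)
  checkCovMatrix(G, nt, "G")
  checkCovMatrix(R, nt, "R")
  if (is.null(ageDistribution)) {
    ageDistribution <- switch(structure,
      three_generation = rbind(c(65, 8), c(40, 6), c(15, 4)),
      rbind(c(40, 6), c(15, 4))
    )
  }
  ageDistribution <- as.matrix(ageDistribution)
  colnames(ageDistribution) <- c("mean", "sd")
  if (!spouseModel$type %in% c("none", "shared_env", "assortative")) {
    stop("unknown spouse model type: ", spouseModel$type)
  }
  if (spouseModel$type == "assortative") {
    if (spouseModel$rho < 0 || spouseModel$rho >= 1) {
      stop("assortative mating target correlation must be in [0, 1)")
    }
  }
  if (spouseModel$type == "shared_env" && spouseModel$variance < 0) {
    stop("shared-environment variance must be >= 0")
  }
  structure(list(
    nFamilies = as.integer(nFamilies), structure = structure,
    kChildren = as.integer(if (structure == "trio") 1L else kChildren),
    kGrandchildren = as.integer(kGrandchildren),
    traits = traits, G = G, R = R,
    betaAge = rep_len(betaAge, nt), betaAge2 = rep_len(betaAge2, nt),
    betaSex = rep_len(betaSex, nt),
    spouseModel = spouseModel, ageDistribution = ageDistribution,
    missingRate = missingRate, seed = as.integer(seed)
  ), class = "SimConfig")
}

checkCovMatrix <- function(M, nt, label) {
  if (nrow(M) != nt || ncol(M) != nt) {
    stop("'", label, "' must be ", nt, "x", nt)
  }
  if (max(abs(M - t(M))) > 1e-10) stop("'", label, "' must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("'", label, "' is not positive semi-definite")
  }
  invisible(TRUE)
}

#' Threshold a liability into a binary trait
#'
#' An individual is affected iff its standardized liability exceeds the
#' (1 - K) quantile of the standard normal, so the expected affected fraction
#' equals the prevalence K. The liability is expected on the standard-normal
#' scale (the simulator standardizes the total liability before calling
#' this).
#'
#' @param liability numeric vector of standardized liabilities.
#' @param prevalence K in (0, 1).
#' @return integer 0/1 vector with attribute `threshold` (= `qnorm(1 - K)`).
#' @examples
#' liabilityThreshold(c(-1, 0.1, 3), 0.5)   # threshold 0
#' attr(liabilityThreshold(rnorm(5), 0.02275), "threshold")  # ~ 2.0
#' @export
liabilityThreshold <- function(liability, prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be a single number in (0, 1)")
  }
  thr <- qnorm(1 - prevalence)
  out <- ifelse(is.na(liability), NA_integer_,
                as.integer(liability > thr))
  attr(out, "threshold") <- thr
  out
}

#' Assortative spouse pairing by Gaussian rank-matching
#'
#' Pairs each value of `x` (one sex's liabilities) with a value of `y` (the
#' other sex's) so that the paired values correlate at approximately `rho`
#' while both marginal distributions are left unchanged: `y` is sorted and
#' paired against the ranks of `rho * scale(x) + sqrt(1 - rho^2) * noise`.
#' `rho = 0` reduces to random pairing; a single couple is returned
#' unchanged.
#'
#' @param x,y numeric vectors of equal length.
#' @param rho target correlation, `0 <= rho < 1`.
#' @return integer vector `j`: `x[i]` is paired with `y[j[i]]` (a permutation
#'   of `seq_along(y)`).
#' @export
applyAssortativeMating <- function(x, y, rho) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (rho < 0 || rho >= 1) {
    stop("target correlation must be in [0, 1)")
  }
  n <- length(x)
  if (n == 1L) return(1L)
  z <- as.numeric(scale(x))
  target <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  ordY <- order(y)
  ordY[rank(target, ties.method = "first")]
}

#' Simulate a multi-generation family cohort with known ground truth
#'
#' Founders receive additive genetic vectors a ~ MVN(0, G); each offspring
#' receives a = (a_father + a_mother)/2 + m with Mendelian-sampling deviation
#' m ~ MVN(0, G/2 * (1 - (F_f + F_m)/2)), where F are the parental inbreeding
#' coefficients (zero in the built-in structures, but the correction keeps
#' the generator valid for arbitrary pedigrees). Residuals e ~ MVN(0, R),
#' plus a couple-shared component under the `shared_env` spouse model.
#' Continuous phenotypes are y = betaAge*age + betaAge2*age^2 + betaSex*sex
#' + a + e; binary traits threshold the standardized total liability (a + e,
#' without fixed effects) at their prevalence quantile.
#'
#' Regeneration with the same configuration (including seed) is
#' bit-identical; the call does not disturb the caller's random state.
#'
#' @param cfg A [simConfig()] object.
#' @return list with elements `ped` ([Pedigree-class]), `pheno` (data.frame:
#'   id, family, age, sex, one column per trait) and `truth` (generating
#'   parameters, seed, per-trait true h2, true genetic correlation matrix,
#'   breeding-value matrix).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  runWithSeed(cfg$seed, {
    struct <- buildStructure(cfg)
    ped <- pedigree(struct$id, struct$father, struct$mother, struct$sex)
    nt <- length(cfg$traits)
    n <- length(struct$id)

    # breeding values in generation order, with assortative founder pairing
    a <- matrix(0, n, nt)
    Fcoef <- inbreeding(ped)[struct$id]
    e <- MASS::mvrnorm(n, mu = rep(0, nt),
                       Sigma = cfg$R, empirical = FALSE)
    e <- matrix(e, n, nt)

    founder <- is.na(struct$father) & is.na(struct$mother)
    nf <- sum(founder)
    a[founder, ] <- matrix(MASS::mvrnorm(nf, rep(0, nt), cfg$G), nf, nt)

    # spouse resemblance among founder couples
    coupleOf <- struct$couple          # couple index or NA
    inCouple <- !is.na(coupleOf)
    if (cfg$spouseModel$type == "assortative" && any(founder & inCouple)) {
      # founder couples: pair mothers to fathers by rank-matching total
      # liability of trait 1, swapping genetic+residual draws among mothers
      fa <- which(founder & struct$sex == 1L & inCouple)
      mo <- which(founder & struct$sex == 2L & inCouple)
      fa <- fa[order(coupleOf[fa])]
      mo <- mo[order(coupleOf[mo])]
      liabF <- a[fa, 1L] + e[fa, 1L]
      liabM <- a[mo, 1L] + e[mo, 1L]
      j <- applyAssortativeMating(liabF, liabM, cfg$spouseModel$rho)
      a[mo, ] <- a[mo[j], , drop = FALSE]
      e[mo, ] <- e[mo[j], , drop = FALSE]
    }

    # non-founders by generation: Mendelian sampling around parental mean
    fi <- match(struct$father, struct$id)
    mi <- match(struct$mother, struct$id)
    gen <- generations(ped)[struct$id]
    sqrtHalfG <- matSqrt(cfg$G / 2)
    for (g in sort(unique(gen[!founder]))) {
      kids <- which(gen == g & !founder)
      if (!length(kids)) next
      scaleF <- sqrt(pmax(0, 1 - (Fcoef[fi[kids]] + Fcoef[mi[kids]]) / 2))
      m <- matrix(rnorm(length(kids) * nt), length(kids), nt) %*% sqrtHalfG
      a[kids, ] <- (a[fi[kids], , drop = FALSE] +
                    a[mi[kids], , drop = FALSE]) / 2 + m * scaleF
    }

    # couple-shared environment
    extraVar <- rep(0, n)
    if (cfg$spouseModel$type == "shared_env" && any(inCouple)) {
      v <- cfg$spouseModel$variance
      nc <- max(coupleOf, na.rm = TRUE)
      cShared <- matrix(rnorm(nc * nt, sd = sqrt(v)), nc, nt)
      e[inCouple, ] <- e[inCouple, ] + cShared[coupleOf[inCouple], ,
                                               drop = FALSE]
      extraVar[inCouple] <- v
    }

    age <- rnorm(n,
                 mean = cfg$ageDistribution[gen + 1L, "mean"],
                 sd = cfg$ageDistribution[gen + 1L, "sd"])
    age <- pmax(age, 1)
    female <- as.numeric(struct$sex == 2L)

    pheno <- data.frame(
      id = struct$id, family = families(ped)[struct$id],
      age = age, sex = struct$sex, stringsAsFactors = FALSE
    )
    thresholds <- list()
    for (t in seq_len(nt)) {
      tr <- cfg$traits[[t]]
      liab <- a[, t] + e[, t]
      if (tr$kind == "binary") {
        sdLiab <- sqrt(cfg$G[t, t] + cfg$R[t, t] + extraVar)
        y <- liabilityThreshold(liab / sdLiab, tr$prevalence)
        thresholds[[tr$name]] <- attr(y, "threshold")
        pheno[[tr$name]] <- as.integer(y)
      } else {
        pheno[[tr$name]] <- cfg$betaAge[t] * age +
          cfg$betaAge2[t] * age^2 + cfg$betaSex[t] * female + liab
      }
    }
    if (cfg$missingRate > 0) {
      for (tr in cfg$traits) {
        mask <- runif(n) < cfg$missingRate
        pheno[[tr$name]][mask] <- NA
      }
    }

    rownames(a) <- struct$id
    truth <- list(
      seed = cfg$seed,
      G = cfg$G, R = cfg$R,
      betaAge = cfg$betaAge, betaAge2 = cfg$betaAge2, betaSex = cfg$betaSex,
      spouseModel = cfg$spouseModel,
      traitNames = vapply(cfg$traits, `[[`, character(1), "name"),
      traitKinds = vapply(cfg$traits, `[[`, character(1), "kind"),
      trueH2 = setNames(diag(cfg$G) / (diag(cfg$G) + diag(cfg$R)),
                        vapply(cfg$traits, `[[`, character(1), "name")),
      trueRG = structure(cov2corSafe(cfg$G), dimnames = list(
        vapply(cfg$traits, `[[`, character(1), "name"),
        vapply(cfg$traits, `[[`, character(1), "name"))),
      thresholds = thresholds,
      breedingValues = a
    )
    list(ped = ped, pheno = pheno, truth = truth)
  })
}

# run expr under a local RNG state seeded with `seed`
runWithSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

cov2corSafe <- function(M) {
  d <- sqrt(diag(M))
  out <- M / outer(d, d)
  out[!is.finite(out)] <- NA
  out
}

# symmetric matrix square root, tolerant of PSD-boundary input
matSqrt <- function(M) {
  ev <- eigen(M, symmetric = TRUE)
  lam <- sqrt(pmax(ev$values, 0))
  ev$vectors %*% (lam * t(ev$vectors))
}

# family structures as parallel vectors; couple = couple index shared by
# both spouses (founder couples and, for three_generation, the middle couple)
buildStructure <- function(cfg) {
  F <- cfg$nFamilies
  k <- cfg$kChildren
  fam <- function(i, tag) sprintf("F%05d_%s", i, tag)
  if (cfg$structure %in% c("trio", "nuclear")) {
    famIdx <- seq_len(F)
    idF <- fam(famIdx, "P1"); idM <- fam(famIdx, "P2")
    kidTags <- paste0("C", seq_len(k))
    idK <- as.vector(t(outer(famIdx, kidTags, fam)))
    kidFam <- rep(famIdx, each = k)
    id <- c(idF, idM, idK)
    father <- c(rep(NA_character_, 2L * F), idF[kidFam])
    mother <- c(rep(NA_character_, 2L * F), idM[kidFam])
    sex <- c(rep(1L, F), rep(2L, F),
             sample(c(1L, 2L), F * k, replace = TRUE))
    couple <- c(famIdx, famIdx, rep(NA_integer_, F * k))
    return(list(id = id, father = father, mother = mother, sex = sex,
                couple = couple))
  }
  # three_generation: two founder couples; each has k children; the first
  # child of couple A marries the first child of couple B; they have
  # kGrandchildren children. Remaining middle-generation children are
  # unmarried aunts/uncles.
  kg <- cfg$kGrandchildren
  famIdx <- seq_len(F)
  gpA1 <- fam(famIdx, "GA1"); gpA2 <- fam(famIdx, "GA2")
  gpB1 <- fam(famIdx, "GB1"); gpB2 <- fam(famIdx, "GB2")
  tagsA <- paste0("PA", seq_len(k)); tagsB <- paste0("PB", seq_len(k))
  midA <- as.vector(t(outer(famIdx, tagsA, fam)))
  midB <- as.vector(t(outer(famIdx, tagsB, fam)))
  midFam <- rep(famIdx, each = k)
  tagsG <- paste0("C", seq_len(kg))
  kids <- as.vector(t(outer(famIdx, tagsG, fam)))
  kidFam <- rep(famIdx, each = kg)
  id <- c(gpA1, gpA2, gpB1, gpB2, midA, midB, kids)
  father <- c(rep(NA_character_, 4L * F),
              gpA1[midFam], gpB1[midFam], midA[(kidFam - 1L) * k + 1L])
  mother <- c(rep(NA_character_, 4L * F),
              gpA2[midFam], gpB2[midFam], midB[(kidFam - 1L) * k + 1L])
  sexMidA <- rep(sample(c(1L, 2L), F * k, replace = TRUE))
  sexMidB <- rep(sample(c(1L, 2L), F * k, replace = TRUE))
  first <- rep(seq_len(k) == 1L, times = F)[order(rep(seq_len(F), k))]
  # the marrying children have fixed opposite sexes
  firstOfFam <- (seq_len(F) - 1L) * k + 1L
  sexMidA[firstOfFam] <- 1L
  sexMidB[firstOfFam] <- 2L
  sex <- c(rep(1L, F), rep(2L, F), rep(1L, F), rep(2L, F),
           sexMidA, sexMidB,
           sample(c(1L, 2L), F * kg, replace = TRUE))
  couple <- c(famIdx, famIdx, F + famIdx, F + famIdx,
              rep(NA_integer_, 2L * F * k + F * kg))
  # middle couple index (for shared_env): after the founder couples
  midCouple <- rep(NA_integer_, 2L * F * k)
  midCouple[firstOfFam] <- 2L * F + famIdx                 # within midA
  midCouple[F * k + firstOfFam] <- 2L * F + famIdx         # within midB
  couple[(4L * F + 1L):(4L * F + 2L * F * k)] <- midCouple
  list(id = id, father = father, mother = mother, sex = sex,
       couple = couple)
}

#' Write a simulated cohort to disk
#'
#' Writes the pedigree as PLINK `.fam`, the phenotype table as TSV, and the
#' truth record (generating parameters, seed, per-trait true h2 and the true
#' genetic correlation matrix; not the per-individual breeding values) as
#' JSON.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return character vector of the three file paths, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  famPath <- file.path(dir, "cohort.fam")
  phenoPath <- file.path(dir, "phenotypes.tsv")
  truthPath <- file.path(dir, "truth.json")
  writeFam(sim$ped, famPath)
  writePhenotypes(sim$pheno, phenoPath)
  truth <- sim$truth
  truth$breedingValues <- NULL
  truth$trueH2 <- as.list(truth$trueH2)
  truth$thresholds <- as.list(truth$thresholds)
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(c(famPath, phenoPath, truthPath))
}
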