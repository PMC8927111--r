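# shared fixtures and independent oracles, built in code

makeTrio <- function() {
  pedigree(
    id = c("fa", "mo", "ch"),
    father = c(NA, NA, "fa"),
    mother = c(NA, NA, "mo"),
    sex = c(1, 2, 2)
  )
}

# 4 grandparents, 2 parents, 1 child
makeThreeGen7 <- function() {
  pedigree(
    id = c("g1", "g2", "g3", "g4", "pa", "ma", "kid"),
    father = c(NA, NA, NA, NA, "g1", "g3", "pa"),
    mother = c(NA, NA, NA, NA, "g2", "g4", "ma"),
    sex = c(1, 2, 1, 2, 1, 2, 1)
  )
}

# random multi-generation pedigree of at most maxSize members; each new
# member either marries in as a founder or is born to an existing couple
randomPedigree <- function(maxSize = 20L, seed = 1L) {
  set.seed(seed)
  id <- c("m1", "f1")
  fa <- c(NA_character_, NA_character_)
  mo <- c(NA_character_, NA_character_)
  sex <- c(1L, 2L)
  couples <- matrix(c(1L, 2L), ncol = 2)   # father idx, mother idx
  k <- 2L
  while (k < maxSize) {
    k <- k + 1L
    newId <- paste0("i", k)
    if (runif(1) < 0.35 || nrow(couples) == 0L) {
      # marry-in founder: pair with a random existing member of opposite sex
      id <- c(id, newId)
      fa <- c(fa, NA_character_)
      mo <- c(mo, NA_character_)
      mate <- sample(seq_along(sex)[-k], 1L)
      newSex <- if (sex[mate] == 1L) 2L else 1L
      sex <- c(sex, newSex)
      couples <- rbind(couples,
                       if (newSex == 2L) c(mate, k) else c(k, mate))
    } else {
      cp <- couples[sample(nrow(couples), 1L), ]
      id <- c(id, newId)
      fa <- c(fa, id[cp[1]])
      mo <- c(mo, id[cp[2]])
      sex <- c(sex, sample(c(1L, 2L), 1L))
    }
  }
  pedigree(id, fa, mo, sex)
}

# independent dense REML restricted log-likelihood (same dropped constants
# as the fitted logL): brute-force linear algebra, no shared code path with
# the AI-REML engine
bruteRemlLogL <- function(A, X, y, sa, se) {
  V <- sa * A + se * diag(nrow(A))
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtVX)$modulus +
                       t(r) %*% Vi %*% r))
}

# fixed small-cohort fixture for the REML grid oracle: 10 nuclear families
# (40 individuals), one continuous trait, age/sex covariates
remlFixture <- function() {
  cfg <- simConfig(
    nFamilies = 10L, structure = "nuclear", kChildren = 2L,
    traits = list(traitSpec("y")),
    G = matrix(0.6), R = matrix(0.4),
    betaAge = 0.02, betaSex = 0.3, seed = 424L
  )
  simulateCohort(cfg)
}

# design matrix matching the package's internal convention
fixtureDesign <- function(pheno) {
  cbind(1, pheno$age, pheno$age^2, as.numeric(pheno$sex == 2))
}
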