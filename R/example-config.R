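#' Example population-cohort simulation configuration
#'
#' A ready-made [simConfig()] emulating a multi-generation population cohort
#' with co-occurring cardiometabolic, psychiatric and substance-use
#' phenotypes. Four continuous traits (BMI-like, depression and anxiety
#' sum-score-like, daily-alcohol-like) carry heritabilities 0.53, 0.25, 0.30
#' and 0.35 and a genetic correlation structure with a high
#' depression-anxiety correlation (0.94), moderate positive correlations of
#' the psychiatric traits with BMI (0.26) and negative correlations of BMI
#' with alcohol use (-0.14) and of the psychiatric traits with alcohol use
#' (-0.16, -0.10). Each continuous trait has a binary diagnosis twin sharing
#' its liability exactly, thresholded at prevalences 15.04% (obesity), 3.44%
#' (depression), 7.74% (anxiety) and 15.57% (high alcohol consumption).
#' Spouses resemble each other through assortative mating on the BMI-like
#' trait (target correlation 0.25). Modest age, age-squared and sex effects
#' are added to the continuous traits.
#'
#' @param nFamilies number of three-generation families; default 1500.
#' @param structure family structure; default `"three_generation"`.
#' @param seed integer seed.
#' @return A [simConfig()] object.
#' @export
exampleCohortConfig <- function(nFamilies = 1500L,
                                structure = "three_generation",
                                seed = 1L) {
  contNames <- c("bmi", "sumDepression", "sumAnxiety", "dailyAlcohol")
  binNames <- c("obesity", "depression", "anxiety", "alcoholHigh")
  prevalences <- c(0.1504, 0.0344, 0.0774, 0.1557)
  h2 <- c(0.53, 0.25, 0.30, 0.35)
  C4 <- matrix(c(
    1.00, 0.26, 0.26, -0.14,
    0.26, 1.00, 0.94, -0.16,
    0.26, 0.94, 1.00, -0.10,
    -0.14, -0.16, -0.10, 1.00
  ), 4, 4, byrow = TRUE)
  CR4 <- diag(4)
  CR4[2, 3] <- CR4[3, 2] <- 0.30        # residual depression-anxiety overlap
  G4 <- diag(sqrt(h2)) %*% C4 %*% diag(sqrt(h2))
  R4 <- diag(sqrt(1 - h2)) %*% CR4 %*% diag(sqrt(1 - h2))
  J2 <- matrix(1, 2, 2)
  G8 <- kronecker(J2, G4)               # binary twins share the liability
  R8 <- kronecker(J2, R4)
  traits <- c(
    lapply(contNames, traitSpec, kind = "continuous"),
    mapply(function(nm, k) traitSpec(nm, "binary", prevalence = k),
           binNames, prevalences, SIMPLIFY = FALSE)
  )
  simConfig(
    nFamilies = nFamilies, structure = structure,
    kChildren = 2L, kGrandchildren = 2L,
    traits = traits, G = G8, R = R8,
    betaAge = c(0.020, 0.008, 0.008, 0.010, rep(0, 4)),
    betaAge2 = c(-2e-4, -5e-5, -5e-5, -1e-4, rep(0, 4)),
    betaSex = c(-0.10, 0.30, 0.40, -0.40, rep(0, 4)),
    spouseModel = list(type = "assortative", rho = 0.25),
    seed = seed
  )
}
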