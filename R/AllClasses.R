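#' Pedigree of related individuals
#'
#' Directed acyclic family structure. Each individual has at most one father
#' and one mother; an individual with neither parent recorded is a founder.
#' Generation indices are longest-path depths from the founders (founders are
#' generation 0), which guarantees that parents precede offspring when the
#' pedigree is processed in generation order. Family identifiers are the
#' connected components of the undirected parent/partner graph, recomputed at
#' construction rather than trusted from input files.
#'
#' @slot id character vector of unique individual identifiers.
#' @slot father,mother character vectors, `NA` when the parent is unknown.
#' @slot sex integer; 1 = male, 2 = female, 0 = unknown.
#' @slot generation integer longest-path depth from founders (founders 0).
#' @slot familyId character; connected-component label.
#' @slot partners two-column character matrix of declared partner links
#'   (possibly with zero rows); used in addition to the common-child rule
#'   when classifying spouse pairs.
#'
#' @seealso [pedigree()], [readPedigree()], [relationshipMatrix()],
#'   [classifyPairs()]
#' @exportClass Pedigree
setClass("Pedigree",
  representation(
    id = "character",
    father = "character",
    mother = "character",
    sex = "integer",
    generation = "integer",
    familyId = "character",
    partners = "matrix"
  )
)

setValidity("Pedigree", function(object) {
  msgs <- character()
  n <- length(object@id)
  if (anyDuplicated(object@id)) {
    msgs <- c(msgs, paste(
      "duplicate individual id(s):",
      paste(unique(object@id[duplicated(object@id)]), collapse = ", ")
    ))
  }
  for (sl in c("father", "mother", "sex", "generation", "familyId")) {
    if (length(slot(object, sl)) != n) {
      msgs <- c(msgs, sprintf("slot '%s' length differs from 'id'", sl))
    }
  }
  self <- which(object@id == object@father | object@id == object@mother)
  if (length(self)) {
    msgs <- c(msgs, paste(
      "individual(s) recorded as own parent:",
      paste(object@id[self], collapse = ", ")
    ))
  }
  bad <- setdiff(c(object@father, object@mother), c(object@id, NA))
  if (length(bad)) {
    msgs <- c(msgs, paste(
      "parent id(s) absent from pedigree:", paste(bad, collapse = ", ")
    ))
  }
  # parent sex consistency (when sex is known)
  sex <- object@sex
  names(sex) <- object@id
  faSex <- sex[object@father]
  moSex <- sex[object@mother]
  badFa <- which(!is.na(object@father) & !is.na(faSex) & faSex == 2L)
  badMo <- which(!is.na(object@mother) & !is.na(moSex) & moSex == 1L)
  if (length(badFa) || length(badMo)) {
    tri <- c(
      sprintf("(%s, father %s)", object@id[badFa], object@father[badFa]),
      sprintf("(%s, mother %s)", object@id[badMo], object@mother[badMo])
    )
    msgs <- c(msgs, paste(
      "parent sex inconsistent for:", paste(tri, collapse = "; ")
    ))
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted pedigree variance components
#'
#' Result of a univariate or bivariate REML animal-model fit: additive
#' genetic and residual (co)variance components, derived heritabilities and
#' genetic/phenotypic/environmental correlations with delta-method standard
#' errors from the average-information matrix, the restricted log-likelihood
#' and a convergence record.
#'
#' @slot traits character; one (univariate) or two (bivariate) trait names.
#' @slot G,R numeric matrices: additive genetic and residual (co)variance
#'   components (1x1 univariate, 2x2 bivariate).
#' @slot h2,seH2 numeric per-trait heritability and its standard error.
#' @slot rG,seRG,rP,rE numeric; correlations (bivariate fits; `NA` otherwise).
#' @slot logLik numeric restricted log-likelihood (constant terms dropped).
#' @slot n integer number of phenotypic observations used.
#' @slot fixef numeric fixed-effect estimates (per trait, concatenated).
#' @slot vcovComponents numeric matrix: inverse average-information matrix
#'   over the free components, in the order recorded in its dimnames.
#' @slot convergence list: iterations, final gradient norm, converged flag,
#'   boundary flag, identifiability warning flag.
#'
#' @exportClass VarCompFit
setClass("VarCompFit",
  representation(
    traits = "character",
    G = "matrix",
    R = "matrix",
    h2 = "numeric",
    seH2 = "numeric",
    rG = "numeric",
    seRG = "numeric",
    rP = "numeric",
    rE = "numeric",
    logLik = "numeric",
    n = "integer",
    fixef = "numeric",
    vcovComponents = "matrix",
    convergence = "list"
  )
)

setValidity("VarCompFit", function(object) {
  msgs <- character()
  if (any(diag(object@G) < -1e-8) || any(diag(object@R) < -1e-8)) {
    msgs <- c(msgs, "negative variance component")
  }
  if (any(object@h2 < -1e-8 | object@h2 > 1 + 1e-8, na.rm = TRUE)) {
    msgs <- c(msgs, "h2 outside [0, 1]")
  }
  if (!is.na(object@rG) && abs(object@rG) > 1 + 1e-8) {
    msgs <- c(msgs, "rG outside [-1, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Recurrence risk ratio estimate
#'
#' A lambda_R estimate for one outcome/exposure-trait/relative-set design:
#' the point estimate, 95% confidence interval, two-sided p-value, the counts
#' entering the estimate and the estimator used. For the naive estimator the
#' primary `lambda` uses the total analysis population in the denominator
#' (`lambdaPop`); the exposed-vs-unexposed contrast is also reported
#' (`lambdaUnexposed`) because regression-based adjustment targets the latter.
#'
#' @slot outcome,exposureTrait,relativeSet character design metadata.
#' @slot estimator character, `"naive"` or `"adjusted"`.
#' @slot lambda,ciLow,ciHigh,pValue numeric estimate and inference.
#' @slot lambdaPop,lambdaUnexposed numeric: prevalence ratio against the total
#'   analysis population and against the unexposed group.
#' @slot nExposed,nUnexposed,nEvents integer counts.
#'
#' @exportClass RecurrenceResult
setClass("RecurrenceResult",
  representation(
    outcome = "character",
    exposureTrait = "character",
    relativeSet = "character",
    estimator = "character",
    lambda = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pValue = "numeric",
    lambdaPop = "numeric",
    lambdaUnexposed = "numeric",
    nExposed = "integer",
    nUnexposed = "integer",
    nEvents = "integer"
  )
)

setValidity("RecurrenceResult", function(object) {
  msgs <- character()
  if (!is.na(object@lambda) && object@lambda < 0) {
    msgs <- c(msgs, "lambda must be >= 0")
  }
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !is.na(object@lambda) &&
      (object@ciLow > object@lambda + 1e-10 ||
       object@ciHigh < object@lambda - 1e-10)) {
    msgs <- c(msgs, "confidence interval does not bracket the estimate")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Pedigree", function(object) {
  nf <- length(unique(object@familyId))
  cat(sprintf(
    "Pedigree: %d individuals in %d famil%s (%d founders, %d generations)\n",
    length(object@id), nf, if (nf == 1L) "y" else "ies",
    sum(is.na(object@father) & is.na(object@mother)),
    max(object@generation) + 1L
  ))
})

setMethod("show", "VarCompFit", function(object) {
  k <- length(object@traits)
  cat(sprintf(
    "VarCompFit (%s REML, n = %d)\n",
    if (k == 1L) "univariate" else "bivariate", object@n
  ))
  for (i in seq_len(k)) {
    cat(sprintf(
      "  %s: sigma2_a = %.4f, sigma2_e = %.4f, h2 = %.3f (SE %.3f)\n",
      object@traits[i], object@G[i, i], object@R[i, i],
      object@h2[i], object@seH2[i]
    ))
  }
  if (k == 2L) {
    cat(sprintf(
      "  r_G = %.3f (SE %.3f), r_P = %.3f, r_E = %.3f\n",
      object@rG, object@seRG, object@rP, object@rE
    ))
  }
  cat(sprintf(
    "  restricted logL = %.4f, %d iterations%s%s\n",
    object@logLik, object@convergence$iterations,
    if (isTRUE(object@convergence$converged)) "" else " (NOT converged)",
    if (isTRUE(object@convergence$boundary)) " [boundary]" else ""
  ))
})

setMethod("show", "RecurrenceResult", function(object) {
  cat(sprintf(
    "lambda_R (%s, %s -> %s, %s): %.3f [%.3f, %.3f], p = %.3g\n",
    object@estimator, object@exposureTrait,
    object@outcome, object@relativeSet,
    object@lambda, object@ciLow, object@ciHigh, object@pValue
  ))
  cat(sprintf(
    "  lambda vs total population: %.3f; vs unexposed: %.3f\n",
    object@lambdaPop, object@lambdaUnexposed
  ))
  cat(sprintf(
    "  n exposed = %d, n unexposed = %d, events = %d\n",
    object@nExposed, object@nUnexposed, object@nEvents
  ))
})
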