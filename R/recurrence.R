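#' Build the per-individual familial exposure indicator
#'
#' An individual is exposed iff at least one relative in the chosen set
#' (first-degree relatives: parents, offspring, full siblings; or spouses)
#' has the exposure trait affected. The individual's own outcome status never
#' enters its exposure. Individuals with no relative having an observed
#' exposure trait are dropped (returned `NA`) and the count logged.
#' Consanguineous spouse pairs are excluded from spouse-based exposure.
#'
#' @param ped A [Pedigree-class].
#' @param t phenotype data.frame with an `id` column.
#' @param exposureTrait binary trait column name in `t`.
#' @param relativeSet `"first_degree"` or `"spouse"`.
#' @return named logical vector over `t$id`; `NA` for dropped individuals.
#' @export
buildExposure <- function(ped, t, exposureTrait,
                          relativeSet = c("first_degree", "spouse")) {
  relativeSet <- match.arg(relativeSet)
  stopifnot(exposureTrait %in% names(t))
  pairs <- classifyPairs(ped)
  pairs <- if (relativeSet == "first_degree") {
    pairs[pairs$relation %in% c("parent-offspring", "full-sibling"), ]
  } else {
    pairs[pairs$relation == "spouse" & !(pairs$consanguineous %in% TRUE), ]
  }
  trait <- setNames(t[[exposureTrait]], t$id)

  # relatives of each individual, as an edge list in both directions
  edges <- rbind(
    data.frame(self = pairs$id1, rel = pairs$id2, stringsAsFactors = FALSE),
    data.frame(self = pairs$id2, rel = pairs$id1, stringsAsFactors = FALSE)
  )
  edges$relTrait <- trait[edges$rel]
  edges <- edges[!is.na(edges$relTrait), , drop = FALSE]

  exposed <- setNames(rep(NA, nrow(t)), t$id)
  if (nrow(edges)) {
    agg <- tapply(edges$relTrait, edges$self, function(x) any(x == 1))
    exposed[names(agg)] <- as.logical(agg)
  }
  nDropped <- sum(is.na(exposed))
  if (nDropped) {
    message(nDropped,
            " individual(s) without an observed ", relativeSet,
            " exposure trait dropped from exposure")
  }
  attr(exposed, "nDropped") <- nDropped
  exposed
}

#' Naive recurrence risk ratio
#'
#' lambda_R as the ratio between the outcome prevalence among exposed
#' individuals (those with an affected relative) and the prevalence in the
#' total analysis population, with a family-cluster bootstrap confidence
#' interval and p-value (families are resampled whole, the exchangeable
#' unit). The exposed-vs-unexposed prevalence ratio is reported alongside,
#' because adjustment by regression targets that contrast instead.
#'
#' @param t phenotype data.frame with `id` and `family` columns.
#' @param exposure logical vector as returned by [buildExposure()] (aligned
#'   with `t$id`; `NA` rows are dropped).
#' @param outcome binary outcome column name in `t`.
#' @param nBoot bootstrap resamples; default 2000.
#' @param seed optional integer seed (local to this call).
#' @param design optional list of metadata (outcome, exposureTrait,
#'   relativeSet) carried into the result.
#' @return A [RecurrenceResult-class] with `estimator = "naive"`; `lambda`
#'   is the total-population variant.
#' @export
lambdaNaive <- function(t, exposure, outcome, nBoot = 2000L, seed = NULL,
                        design = list()) {
  stopifnot(outcome %in% names(t))
  y <- t[[outcome]]
  keep <- !is.na(exposure) & !is.na(y)
  y <- as.numeric(y[keep])
  ex <- exposure[keep]
  fam <- t$family[keep]
  if (!any(ex) || all(ex)) {
    stop("empty exposed or unexposed group (exposed: ", sum(ex),
         ", unexposed: ", sum(!ex), ")")
  }
  pAll <- mean(y)
  if (pAll == 0) stop("zero outcome prevalence; lambda undefined")
  lam <- mean(y[ex]) / pAll
  lamUnexp <- if (mean(y[!ex]) > 0) mean(y[ex]) / mean(y[!ex]) else Inf

  # family-cluster bootstrap via multinomial family weights
  famStats <- rowsum(cbind(evExp = y * ex, nExp = as.numeric(ex),
                           ev = y, n = 1), fam)
  nf <- nrow(famStats)
  bootLam <- runWithSeed(if (is.null(seed)) sample.int(2^30, 1) else seed, {
    w <- rmultinom(nBoot, nf, rep(1 / nf, nf))
    s <- crossprod(w, famStats)
    num <- s[, "evExp"] / s[, "nExp"]
    den <- s[, "ev"] / s[, "n"]
    num / den
  })
  bootLam <- bootLam[is.finite(bootLam) & bootLam > 0]
  ci <- quantile(bootLam, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  # bootstrap-z p-value on the log scale
  seLog <- sd(log(bootLam))
  p <- if (is.finite(seLog) && seLog > 0) {
    2 * pnorm(-abs(log(lam)) / seLog)
  } else NA_real_

  new("RecurrenceResult",
    outcome = outcome,
    exposureTrait = design$exposureTrait %||% outcome,
    relativeSet = design$relativeSet %||% NA_character_,
    estimator = "naive",
    lambda = lam, ciLow = min(ci[1], lam), ciHigh = max(ci[2], lam),
    pValue = p,
    lambdaPop = lam, lambdaUnexposed = lamUnexp,
    nExposed = as.integer(sum(ex)), nUnexposed = as.integer(sum(!ex)),
    nEvents = as.integer(sum(y))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Covariate-adjusted recurrence risk ratio
#'
#' Prevalence-ratio regression: binary outcome on exposure plus covariates
#' with a log link and constant time at risk (Poisson working likelihood),
#' variance by a robust sandwich estimator clustered on family. lambda_R is
#' the exponentiated exposure coefficient, with Wald 95% interval and
#' two-sided p-value. With no covariates this reduces exactly to the
#' exposed-vs-unexposed prevalence ratio.
#'
#' No small-sample cluster adjustment is applied, so with all clusters of
#' size one the variance equals the ordinary heteroscedasticity-robust
#' sandwich.
#'
#' @param t phenotype data.frame with `id` and `family` columns.
#' @param exposure logical vector aligned with `t$id` (`NA` dropped).
#' @param outcome binary outcome column name.
#' @param covariates character vector of covariate column names; `"age2"` is
#'   derived as `age^2` if absent. Default `c("age", "age2", "sex")`.
#' @param design optional metadata list as in [lambdaNaive()].
#' @return A [RecurrenceResult-class] with `estimator = "adjusted"`.
#' @export
lambdaAdjusted <- function(t, exposure, outcome,
                           covariates = c("age", "age2", "sex"),
                           design = list()) {
  stopifnot(outcome %in% names(t))
  if ("age2" %in% covariates && !"age2" %in% names(t) && "age" %in% names(t)) {
    t$age2 <- t$age^2
  }
  miss <- setdiff(covariates, names(t))
  if (length(miss)) stop("covariate(s) not in table: ",
                         paste(miss, collapse = ", "))
  dat <- data.frame(.y = t[[outcome]], .exposed = as.numeric(exposure),
                    .family = t$family, t[, covariates, drop = FALSE],
                    check.names = FALSE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (!any(dat$.exposed == 1) || !any(dat$.exposed == 0)) {
    stop("empty exposed or unexposed group after complete-case filtering")
  }
  if (all(dat$.y == 0)) stop("zero outcome prevalence; lambda undefined")
  if (all(dat$.y == 1)) stop("outcome prevalence is 1; lambda undefined")
  form <- stats::as.formula(paste(
    ".y ~ .exposed",
    if (length(covariates)) paste("+", paste(sprintf("`%s`", covariates),
                                             collapse = " + ")) else ""
  ))
  fit <- suppressWarnings(glm(form, family = poisson(link = "log"),
                              data = dat))
  if (!fit$converged) {
    stop("prevalence-ratio regression did not converge after ",
         fit$iter, " IWLS iterations")
  }
  if (any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    stop("(quasi-)separation suspected in prevalence-ratio regression; ",
         "consider the naive estimator")
  }
  V <- sandwich::vcovCL(fit, cluster = dat$.family, type = "HC0",
                        cadjust = FALSE)
  b <- coef(fit)[".exposed"]
  se <- sqrt(V[".exposed", ".exposed"])
  lam <- exp(b)
  ci <- exp(b + c(-1, 1) * qnorm(0.975) * se)
  p <- 2 * pnorm(-abs(b / se))

  new("RecurrenceResult",
    outcome = outcome,
    exposureTrait = design$exposureTrait %||% outcome,
    relativeSet = design$relativeSet %||% NA_character_,
    estimator = "adjusted",
    lambda = unname(lam), ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
    pValue = unname(p),
    lambdaPop = mean(dat$.y[dat$.exposed == 1]) / mean(dat$.y),
    lambdaUnexposed = unname(lam),
    nExposed = as.integer(sum(dat$.exposed == 1)),
    nUnexposed = as.integer(sum(dat$.exposed == 0)),
    nEvents = as.integer(sum(dat$.y))
  )
}

#' Familial co-aggregation matrix
#'
#' lambda_R for every ordered (exposure trait in relatives -> outcome in
#' probands) pair of binary traits, for one relative set. Diagonal cells are
#' the same-trait aggregation estimates. Per-cell estimation errors are
#' recorded in the cell (NA estimate, message in `error`), and the matrix is
#' still returned. Significance stars: *** p < 0.001, ** p < 0.01,
#' * p < 0.05 (two-sided, unadjusted).
#'
#' @param ped A [Pedigree-class].
#' @param t phenotype data.frame with `id`, `family` and the trait columns.
#' @param traits character vector of at least two binary trait names (a
#'   single trait gives the 1x1 aggregation-only "matrix").
#' @param relativeSet `"first_degree"` or `"spouse"`.
#' @param adjusted logical; use [lambdaAdjusted()] (default) or
#'   [lambdaNaive()].
#' @param covariates covariates for the adjusted estimator.
#' @param nBoot bootstrap resamples for the naive estimator.
#' @param seed optional seed for the naive bootstrap.
#' @return data.frame, one row per exposure-outcome pair: `exposure`,
#'   `outcome`, `relativeSet`, `lambda`, `ciLow`, `ciHigh`, `pValue`,
#'   `stars`, `nExposed`, `nUnexposed`, `nEvents`, `error`.
#' @export
coaggregationMatrix <- function(ped, t, traits,
                                relativeSet = c("first_degree", "spouse"),
                                adjusted = TRUE,
                                covariates = c("age", "age2", "sex"),
                                nBoot = 2000L, seed = NULL) {
  relativeSet <- match.arg(relativeSet)
  stopifnot(all(traits %in% names(t)))
  exposures <- lapply(traits, function(tr) {
    suppressMessages(buildExposure(ped, t, tr, relativeSet))
  })
  names(exposures) <- traits
  rows <- list()
  for (ex in traits) {
    for (out in traits) {
      res <- tryCatch({
        d <- list(exposureTrait = ex, relativeSet = relativeSet)
        if (adjusted) {
          lambdaAdjusted(t, exposures[[ex]], out, covariates, design = d)
        } else {
          lambdaNaive(t, exposures[[ex]], out, nBoot = nBoot, seed = seed,
                      design = d)
        }
      }, error = function(e) e)
      rows[[paste(ex, out)]] <- if (inherits(res, "error")) {
        data.frame(exposure = ex, outcome = out, relativeSet = relativeSet,
                   lambda = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                   pValue = NA_real_, stars = "",
                   nExposed = NA_integer_, nUnexposed = NA_integer_,
                   nEvents = NA_integer_,
                   error = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        data.frame(exposure = ex, outcome = out, relativeSet = relativeSet,
                   lambda = res@lambda, ciLow = res@ciLow,
                   ciHigh = res@ciHigh, pValue = res@pValue,
                   stars = significanceStars(res@pValue),
                   nExposed = res@nExposed, nUnexposed = res@nUnexposed,
                   nEvents = res@nEvents, error = NA_character_,
                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

significanceStars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
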