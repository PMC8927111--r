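#' Heritability from variance components
#'
#' Narrow-sense heritability h2 = sigma2_a / (sigma2_a + sigma2_e): the
#' proportion of phenotypic variance attributable to additive genetic
#' variance.
#'
#' @param sigma2a,sigma2e additive genetic and residual variances, both >= 0
#'   and not both zero.
#' @return numeric in [0, 1].
#' @export
h2FromComponents <- function(sigma2a, sigma2e) {
  if (sigma2a < 0 || sigma2e < 0) stop("variance components must be >= 0")
  if (sigma2a + sigma2e == 0) stop("both components zero; h2 undefined")
  sigma2a / (sigma2a + sigma2e)
}

#' Genetic correlation from (co)variance components
#'
#' r_G = sigma_AxAy / sqrt(sigma2_Ax * sigma2_Ay). Values numerically outside
#' [-1, 1] are clamped, with attribute `clamped = TRUE`.
#'
#' @param covAxy additive genetic covariance between the traits.
#' @param varAx,varAy additive genetic variances, both > 0.
#' @return numeric in [-1, 1].
#' @export
rgFromComponents <- function(covAxy, varAx, varAy) {
  if (varAx <= 0 || varAy <= 0) stop("genetic variances must be > 0")
  r <- covAxy / sqrt(varAx * varAy)
  if (abs(r) > 1) {
    r <- sign(r) * 1
    attr(r, "clamped") <- TRUE
  }
  r
}

#' Likelihood-ratio test for a variance component on the boundary
#'
#' Tests sigma2_a = 0 by referring the restricted likelihood-ratio statistic
#' to the boundary mixture 0.5*chi2_0 + 0.5*chi2_1, i.e.
#' p = 0.5 * P(chi2_1 > LRT) for LRT >= 0 (p = 0.5 at LRT = 0).
#'
#' @param fitFull,fitNull [VarCompFit-class] objects from the same data; the
#'   null has the genetic variance fixed at zero (see
#'   `fixSigmaA` in [remlUnivariate()]).
#' @return two-sided p-value under the boundary mixture.
#' @export
lrtVariance <- function(fitFull, fitNull) {
  if (!is(fitFull, "VarCompFit") || !is(fitNull, "VarCompFit")) {
    stop("both arguments must be VarCompFit objects")
  }
  if (fitFull@n != fitNull@n ||
      length(fitFull@traits) != length(fitNull@traits)) {
    stop("fits are not nested (different data or trait dimension)")
  }
  stat <- max(0, 2 * (fitFull@logLik - fitNull@logLik))
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Wald tests for the genetic correlation
#'
#' The test against 0 is Wald on the Fisher-z-transformed scale
#' (z = atanh(r_G), SE_z = SE_r / (1 - r_G^2)). Because atanh(1) is infinite,
#' the test against 1 uses the raw scale, and is skipped (NA) when the
#' estimate is at the boundary (|r_G| > 0.999) or the SE is unavailable.
#'
#' @param fit a bivariate [VarCompFit-class].
#' @param null 0 or 1.
#' @return list with `statistic` (z) and `pValue` (two-sided).
#' @export
rgWaldTest <- function(fit, null = 0) {
  stopifnot(is(fit, "VarCompFit"), length(fit@traits) == 2L)
  r <- fit@rG
  se <- fit@seRG
  if (is.na(r) || is.na(se) || se <= 0) {
    return(list(statistic = NA_real_, pValue = NA_real_))
  }
  if (null == 0) {
    z <- atanh(min(max(r, -0.999999), 0.999999)) / (se / (1 - r^2))
  } else if (null == 1) {
    if (abs(r) > 0.999) {
      return(list(statistic = NA_real_, pValue = NA_real_))
    }
    z <- (r - 1) / se
  } else {
    stop("'null' must be 0 or 1")
  }
  list(statistic = z, pValue = 2 * pnorm(-abs(z)))
}

# ---- shared data preparation ------------------------------------------------

# complete-case on covariates, id matched to the pedigree; returns the design
# matrix (intercept + covariates; sex recoded to a female indicator, age2
# derived from age when absent) and the trait columns
prepareModelFrame <- function(ped, t, traits, covariates) {
  stopifnot("id" %in% names(t))
  if ("age2" %in% covariates && !"age2" %in% names(t) &&
      "age" %in% names(t)) {
    t$age2 <- t$age^2
  }
  miss <- setdiff(c(traits, covariates), names(t))
  if (length(miss)) stop("column(s) not in table: ",
                         paste(miss, collapse = ", "))
  inPed <- t$id %in% pedIds(ped)
  if (!all(inPed)) {
    message(sum(!inPed), " phenotyped individual(s) not in pedigree dropped")
    t <- t[inPed, , drop = FALSE]
  }
  covs <- t[, covariates, drop = FALSE]
  if ("sex" %in% covariates) covs$sex <- as.numeric(covs$sex == 2)
  keep <- complete.cases(covs) &
    rowSums(!is.na(t[, traits, drop = FALSE])) > 0
  t <- t[keep, , drop = FALSE]
  covs <- covs[keep, , drop = FALSE]
  if (!nrow(t)) stop("no usable rows after complete-case filtering")
  X <- cbind(`(Intercept)` = 1, as.matrix(covs))
  list(t = t, X = X)
}

# restrict the per-family A blocks to the phenotyped ids; returns blocks with
# row indices into `ids`
restrictedBlocks <- function(ped, ids) {
  blocks <- relationshipBlocks(ped)
  out <- list()
  for (b in blocks) {
    pos <- match(pedIds(ped)[b$idx], ids)
    keep <- which(!is.na(pos))
    if (!length(keep)) next
    out[[length(out) + 1L]] <- list(
      rows = pos[keep],
      A = b$A[keep, keep, drop = FALSE]
    )
  }
  out
}

# ---- univariate REML --------------------------------------------------------

#' Univariate animal-model REML
#'
#' Fits y = X beta + a + e with a ~ N(0, sigma2_a A) and e ~ N(0, sigma2_e I)
#' by average-information REML, where A is the pedigree additive relationship
#' matrix (computed over the full pedigree, restricted to phenotyped
#' individuals, so unphenotyped connecting ancestors still contribute
#' relatedness). Convergence requires |change in restricted logL| < 1e-8 and
#' gradient norm < 1e-6 within 200 iterations; out-of-cone average-information
#' proposals fall back to step-halving and EM-type natural-gradient steps.
#' Estimates at the zero boundary are flagged, not silently clamped away.
#'
#' If the relationship matrix restricted to the phenotyped individuals is
#' (numerically) the identity, sigma2_a and sigma2_e are confounded: a
#' warning is issued and the fit is returned at the sigma2_a = 0 boundary
#' with a flat-likelihood flag.
#'
#' @param ped A [Pedigree-class].
#' @param t phenotype data.frame with `id`, covariates and the trait.
#' @param trait continuous trait column name.
#' @param covariates fixed-effect columns; default `c("age", "age2", "sex")`
#'   (`age2` derived from `age` if absent, sex recoded to a female
#'   indicator). Use `character(0)` for an intercept-only model.
#' @param fixSigmaA fit the null model with sigma2_a fixed at zero (for
#'   [lrtVariance()]).
#' @return A [VarCompFit-class].
#' @export
remlUnivariate <- function(ped, t, trait,
                           covariates = c("age", "age2", "sex"),
                           fixSigmaA = FALSE) {
  mf <- prepareModelFrame(ped, t, trait, covariates)
  y <- mf$t[[trait]]
  keep <- !is.na(y)
  y <- y[keep]
  X <- mf$X[keep, , drop = FALSE]
  ids <- mf$t$id[keep]
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1L) stop("too few observations to fit the model")

  blocks <- restrictedBlocks(ped, ids)
  maxOff <- 0
  for (b in blocks) {
    if (nrow(b$A) > 1L) {
      maxOff <- max(maxOff, max(abs(b$A[upper.tri(b$A)])))
    }
  }
  flat <- maxOff < 1e-8
  if (flat && !fixSigmaA) {
    warning("relationship matrix over phenotyped individuals is ~identity; ",
            "sigma2_a and sigma2_e are confounded")
  }

  # rotate into the per-family eigenbasis of A
  cSd <- sd(y)
  ys <- y / cSd
  d <- numeric(n)
  yt <- numeric(n)
  Xt <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  for (b in blocks) {
    eg <- eigen(b$A, symmetric = TRUE)
    d[b$rows] <- eg$values
    yt[b$rows] <- crossprod(eg$vectors, ys[b$rows])
    Xt[b$rows, ] <- crossprod(eg$vectors, X[b$rows, , drop = FALSE])
  }

  evalFn <- univariateEval(list(d = d, y = yt, X = Xt))
  lb <- 1e-8
  ols <- lm.fit(Xt, yt)
  v0 <- sum(ols$residuals^2) / (n - p)

  if (fixSigmaA || flat) {
    theta <- c(0, v0)
    ev <- evalFn(theta)
    res <- list(theta = theta, eval = ev, iterations = 0L,
                converged = TRUE, usedEM = FALSE, gradNorm = NA_real_)
    boundary <- TRUE
  } else {
    emStep <- function(theta, score) theta + 2 * theta^2 / n * score
    isValid <- function(theta) all(theta >= c(0, lb)) && all(is.finite(theta))
    res <- aiRemlDriver(evalFn, theta0 = c(v0 / 2, v0 / 2),
                        isValid = isValid, emStep = emStep,
                        lowerIdx = 1:2, lb = lb)
    if (!res$converged) {
      stop("REML did not converge in 200 iterations (last logL ",
           format(res$eval$logL), ", gradient norm ",
           format(res$gradNorm), ")")
    }
    boundary <- any(res$theta <= lb * 1.01)
  }

  sa <- res$theta[1] * cSd^2
  se <- res$theta[2] * cSd^2
  h2 <- if (sa + se > 0) sa / (sa + se) else NA_real_

  vcovTheta <- matrix(NA_real_, 2, 2,
                      dimnames = list(c("sigma2_a", "sigma2_e"),
                                      c("sigma2_a", "sigma2_e")))
  seH2 <- NA_real_
  if (!fixSigmaA && !flat) {
    Vi <- tryCatch(solve(res$eval$AI), error = function(e) NULL)
    if (!is.null(Vi)) {
      vcovTheta[] <- Vi * cSd^4
      gr <- c(se, -sa) / (sa + se)^2
      vh <- as.numeric(gr %*% vcovTheta %*% gr)
      if (is.finite(vh) && vh >= 0) seH2 <- sqrt(vh)
    }
  }

  new("VarCompFit",
    traits = trait,
    G = matrix(sa, 1, 1, dimnames = list(trait, trait)),
    R = matrix(se, 1, 1, dimnames = list(trait, trait)),
    h2 = h2, seH2 = seH2,
    rG = NA_real_, seRG = NA_real_, rP = NA_real_, rE = NA_real_,
    logLik = res$eval$logL - (n - p) * log(cSd),
    n = as.integer(n),
    fixef = setNames(res$eval$beta * cSd, colnames(X)),
    vcovComponents = vcovTheta,
    convergence = list(iterations = res$iterations,
                       gradNorm = res$gradNorm,
                       converged = res$converged,
                       boundary = boundary,
                       flatLikelihood = flat,
                       usedEM = res$usedEM)
  )
}

# ---- bivariate REML ---------------------------------------------------------

#' Bivariate animal-model REML
#'
#' Joint REML fit of two continuous traits with additive genetic covariance
#' matrix G and residual covariance matrix R. Individuals with one of the two
#' traits missing contribute through the joint likelihood over their observed
#' entries (per-family dense algebra); with complete trait pairs a fast
#' canonical-transformation path is used. Reports G, R, per-trait h2, the
#' genetic correlation r_G with delta-method SE, the phenotypic correlation
#' r_P (from G + R) and the residual correlation r_E.
#'
#' `fixG12`/`fixR12` fix the genetic/residual covariance at zero (dropping it
#' from the parameter set); with both fixed the likelihood factorises and the
#' per-trait components coincide with the univariate fits.
#'
#' @param ped A [Pedigree-class].
#' @param t phenotype data.frame with `id`, covariates and both traits.
#' @param traits character vector of two continuous trait names.
#' @param covariates as in [remlUnivariate()].
#' @param fixG12,fixR12 logical; fix the respective covariance at zero.
#' @return A [VarCompFit-class].
#' @export
remlBivariate <- function(ped, t, traits,
                          covariates = c("age", "age2", "sex"),
                          fixG12 = FALSE, fixR12 = FALSE) {
  stopifnot(length(traits) == 2L)
  mf <- prepareModelFrame(ped, t, traits, covariates)
  y1 <- mf$t[[traits[1]]]
  y2 <- mf$t[[traits[2]]]
  X <- mf$X
  ids <- mf$t$id
  p <- ncol(X)
  n1 <- sum(!is.na(y1)); n2 <- sum(!is.na(y2))
  if (min(n1, n2) <= p + 1L) stop("too few observations per trait")
  nObs <- n1 + n2

  c1 <- sd(y1, na.rm = TRUE)
  c2 <- sd(y2, na.rm = TRUE)
  y1s <- y1 / c1
  y2s <- y2 / c2

  complete <- !anyNA(y1) && !anyNA(y2)
  free <- c(TRUE, !fixG12, TRUE, TRUE, !fixR12, TRUE)

  if (complete) {
    n <- length(ids)
    d <- numeric(n)
    Y1 <- numeric(n); Y2 <- numeric(n)
    X1 <- matrix(0, n, p)
    blocks <- restrictedBlocks(ped, ids)
    for (b in blocks) {
      eg <- eigen(b$A, symmetric = TRUE)
      d[b$rows] <- eg$values
      Y1[b$rows] <- crossprod(eg$vectors, y1s[b$rows])
      Y2[b$rows] <- crossprod(eg$vectors, y2s[b$rows])
      X1[b$rows, ] <- crossprod(eg$vectors, X[b$rows, , drop = FALSE])
    }
    evalFn <- bivariateEvalFast(list(d = d, Y1 = Y1, Y2 = Y2,
                                     X1 = X1, X2 = X1), free)
    nInd <- n
  } else {
    blocks0 <- restrictedBlocks(ped, ids)
    blocks <- lapply(blocks0, function(b) {
      m <- length(b$rows)
      o1 <- which(!is.na(y1s[b$rows]))
      o2 <- which(!is.na(y2s[b$rows]))
      obs <- rbind(cbind(ind = o1, trait = 1L), cbind(ind = o2, trait = 2L))
      list(A = b$A, obs = obs, X = X[b$rows, , drop = FALSE],
           y1 = y1s[b$rows], y2 = y2s[b$rows])
    })
    blocks <- blocks[vapply(blocks, function(b) nrow(b$obs) > 0L, logical(1))]
    evalFn <- bivariateEvalDense(blocks, p, free)
    nInd <- length(ids)
  }

  # starting values: half the phenotypic (co)variance to each side
  r1 <- resid(lm(y1s ~ X - 1, na.action = na.exclude))
  r2 <- resid(lm(y2s ~ X - 1, na.action = na.exclude))
  v1 <- var(r1, na.rm = TRUE); v2 <- var(r2, na.rm = TRUE)
  cv <- cov(r1, r2, use = "complete.obs")
  if (!is.finite(cv)) cv <- 0
  theta0 <- c(v1 / 2, if (fixG12) 0 else cv / 2, v2 / 2,
              v1 / 2, if (fixR12) 0 else cv / 2, v2 / 2)

  lb <- 1e-8
  isValid <- function(th) {
    all(is.finite(th)) && th[1] >= 0 && th[3] >= 0 &&
      th[4] >= lb && th[6] >= lb &&
      th[1] * th[3] - th[2]^2 >= -1e-12 &&
      th[4] * th[6] - th[5]^2 > 0
  }
  emStep <- function(th, score) {
    G <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
    R <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2)
    SG <- matrix(c(score[1], score[2] / 2, score[2] / 2, score[3]), 2, 2)
    SR <- matrix(c(score[4], score[5] / 2, score[5] / 2, score[6]), 2, 2)
    Gn <- G + 2 / nInd * G %*% SG %*% G
    Rn <- R + 2 / nObs * R %*% SR %*% R
    out <- c(Gn[1, 1], Gn[1, 2], Gn[2, 2], Rn[1, 1], Rn[1, 2], Rn[2, 2])
    out[!free] <- 0
    out
  }
  res <- aiRemlDriver(evalFn, theta0, isValid, emStep,
                      lowerIdx = c(1, 3, 4, 6), lb = lb)
  if (!res$converged) {
    stop("bivariate REML did not converge in 200 iterations ",
         "(gradient norm ", format(res$gradNorm), ")")
  }

  scl <- c(c1^2, c1 * c2, c2^2, c1^2, c1 * c2, c2^2)
  th <- res$theta * scl
  G <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2,
              dimnames = list(traits, traits))
  R <- matrix(c(th[4], th[5], th[5], th[6]), 2, 2,
              dimnames = list(traits, traits))
  boundary <- any(res$theta[c(1, 3, 4, 6)] <= lb * 1.01) ||
    abs(res$theta[2]) >= sqrt(res$theta[1] * res$theta[3]) * 0.9999

  h2 <- diag(G) / (diag(G) + diag(R))
  rG <- if (fixG12) 0 else if (G[1, 1] > 0 && G[2, 2] > 0) {
    as.numeric(rgFromComponents(G[1, 2], G[1, 1], G[2, 2]))
  } else NA_real_
  rE <- if (R[1, 1] > 0 && R[2, 2] > 0) {
    R[1, 2] / sqrt(R[1, 1] * R[2, 2])
  } else NA_real_
  Pm <- G + R
  rP <- Pm[1, 2] / sqrt(Pm[1, 1] * Pm[2, 2])

  # delta-method SEs from the inverse AI over the free components
  parNames <- c("g11", "g12", "g22", "r11", "r12", "r22")
  vcovTheta <- matrix(NA_real_, 6, 6, dimnames = list(parNames, parNames))
  seH2 <- c(NA_real_, NA_real_)
  seRG <- NA_real_
  fIdx <- which(free)
  Vi <- tryCatch(solve(res$eval$AI[fIdx, fIdx, drop = FALSE]),
                 error = function(e) NULL)
  if (!is.null(Vi)) {
    vcovTheta[fIdx, fIdx] <- Vi * outer(scl[fIdx], scl[fIdx])
    for (tr in 1:2) {
      iA <- if (tr == 1) 1L else 3L
      iE <- if (tr == 1) 4L else 6L
      sub <- vcovTheta[c(iA, iE), c(iA, iE)]
      if (!anyNA(sub)) {
        tot <- G[tr, tr] + R[tr, tr]
        gr <- c(R[tr, tr], -G[tr, tr]) / tot^2
        vh <- as.numeric(gr %*% sub %*% gr)
        if (is.finite(vh) && vh >= 0) seH2[tr] <- sqrt(vh)
      }
    }
    if (!fixG12 && G[1, 1] > 0 && G[2, 2] > 0) {
      sub <- vcovTheta[1:3, 1:3]
      if (!anyNA(sub)) {
        g11 <- G[1, 1]; g12 <- G[1, 2]; g22 <- G[2, 2]
        gr <- c(-0.5 * g12 / (g11^1.5 * sqrt(g22)),
                1 / sqrt(g11 * g22),
                -0.5 * g12 / (sqrt(g11) * g22^1.5))
        vr <- as.numeric(gr %*% sub %*% gr)
        if (is.finite(vr) && vr >= 0) seRG <- sqrt(vr)
      }
    }
  }

  logLAdj <- res$eval$logL - (n1 - p) * log(c1) - (n2 - p) * log(c2)
  fixef <- res$eval$beta * rep(c(c1, c2), each = p)
  names(fixef) <- paste(rep(traits, each = p), rep(colnames(X), 2), sep = ".")

  new("VarCompFit",
    traits = traits, G = G, R = R,
    h2 = setNames(h2, traits), seH2 = setNames(seH2, traits),
    rG = rG, seRG = seRG, rP = rP, rE = rE,
    logLik = logLAdj, n = as.integer(nObs), fixef = fixef,
    vcovComponents = vcovTheta,
    convergence = list(iterations = res$iterations,
                       gradNorm = res$gradNorm,
                       converged = res$converged,
                       boundary = boundary,
                       flatLikelihood = FALSE,
                       usedEM = res$usedEM)
  )
}
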