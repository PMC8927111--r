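# AI-REML engine.
#
# The restricted log-likelihood (constants dropped) is
#   lR = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ],
#   P  = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1,
# with V block diagonal over families. For one trait, V_f = sa * A_f + se * I;
# eigendecomposing each family block A_f = U D U' once makes every iteration
# a set of O(n) vector operations in the rotated basis ("canonical
# transformation"). For two traits with both traits observed on everyone, the
# same rotation leaves 2x2 blocks B_k = d_k G + R, handled with vectorized
# analytic inverses. Partially observed trait pairs fall back to per-family
# dense algebra on the observed entries (joint likelihood, not listwise
# deletion).
#
# Scores and average information use the standard identities
#   d lR / d th  = -1/2 [ tr(P dV) - y'P dV P y ]
#   AI[th, et]   =  1/2 (dV_th P y)' P (dV_et P y).

# ---- driver ----------------------------------------------------------------

# evalFn(theta) -> list(logL, score, AI); isValid(theta) -> logical;
# emStep(theta, score) -> theta proposal kept inside the cone; lowerIdx are
# indices of pure variances clamped at `lb` (boundary detection).
aiRemlDriver <- function(evalFn, theta0, isValid, emStep, lowerIdx, lb,
                         maxit = 200L, tolL = 1e-8, tolG = 1e-6) {
  theta <- theta0
  cur <- evalFn(theta)
  usedEM <- FALSE
  stall <- 0L
  for (it in seq_len(maxit)) {
    # active-set handling: variances stuck at the lower clamp with an
    # outward-pointing gradient are held fixed this iteration
    bound <- rep(FALSE, length(theta))
    bound[lowerIdx] <- theta[lowerIdx] <= lb * 1.0001 &
      cur$score[lowerIdx] < 0
    free <- which(!bound)

    AIf <- cur$AI[free, free, drop = FALSE]
    scf <- cur$score[free]
    delta <- rep(0, length(theta))
    ridge <- 0
    repeat {
      ok <- tryCatch({
        delta[free] <- solve(AIf + diag(ridge, length(free)), scf)
        TRUE
      }, error = function(e) FALSE)
      if (ok && all(is.finite(delta))) break
      ridge <- if (ridge == 0) 1e-8 * max(abs(diag(AIf)), 1) else ridge * 10
      if (ridge > 1e8 * max(abs(diag(AIf)), 1)) {
        delta[] <- 0
        break
      }
    }

    step <- 1
    newTheta <- NULL
    newEval <- NULL
    while (step >= 1e-4) {
      cand <- theta + step * delta
      cand[lowerIdx] <- pmax(cand[lowerIdx], lb)
      if (isValid(cand)) {
        ev <- tryCatch(evalFn(cand), error = function(e) NULL)
        if (!is.null(ev) && is.finite(ev$logL) &&
            ev$logL >= cur$logL - 1e-10) {
          newTheta <- cand
          newEval <- ev
          break
        }
      }
      step <- step / 2
    }
    if (is.null(newTheta)) {
      # EM-type fallback: guaranteed-direction natural-gradient step,
      # shrunk until it stays in the cone and does not lose likelihood
      usedEM <- TRUE
      gamma <- 1
      while (gamma >= 1e-6) {
        cand <- emStep(theta, cur$score * gamma)
        cand[lowerIdx] <- pmax(cand[lowerIdx], lb)
        if (isValid(cand)) {
          ev <- tryCatch(evalFn(cand), error = function(e) NULL)
          if (!is.null(ev) && is.finite(ev$logL) &&
              ev$logL >= cur$logL - 1e-10) {
            newTheta <- cand
            newEval <- ev
            break
          }
        }
        gamma <- gamma / 4
      }
    }
    if (is.null(newTheta)) {
      # no improving step found: converged to working precision
      return(list(theta = theta, eval = cur, iterations = it,
                  converged = TRUE, usedEM = usedEM,
                  gradNorm = max(abs(cur$score[free]), 0)))
    }
    dL <- newEval$logL - cur$logL
    theta <- newTheta
    cur <- newEval
    bound[lowerIdx] <- theta[lowerIdx] <= lb * 1.0001 &
      cur$score[lowerIdx] < 0
    gnorm <- max(abs(cur$score[!bound]), 0)
    if (abs(dL) < tolL && gnorm < tolG) {
      return(list(theta = theta, eval = cur, iterations = it,
                  converged = TRUE, usedEM = usedEM, gradNorm = gnorm))
    }
    # at a constrained optimum on the PSD-cone boundary the free gradient
    # does not vanish; repeated negligible likelihood gains are the stopping
    # signal there (the caller flags the boundary)
    stall <- if (abs(dL) < tolL) stall + 1L else 0L
    if (stall >= 3L) {
      return(list(theta = theta, eval = cur, iterations = it,
                  converged = TRUE, usedEM = usedEM, gradNorm = gnorm))
    }
  }
  list(theta = theta, eval = cur, iterations = maxit, converged = FALSE,
       usedEM = usedEM, gradNorm = max(abs(cur$score), 0))
}

# ---- univariate evaluator ---------------------------------------------------

# data: list(d, y, X) in the rotated (per-family eigen) basis
univariateEval <- function(data) {
  d <- data$d
  y <- data$y
  X <- data$X
  n <- length(y)
  p <- ncol(X)
  function(theta) {
    sa <- theta[1]
    se <- theta[2]
    v <- sa * d + se
    w <- 1 / v
    Xw <- X * w
    C <- crossprod(X, Xw)
    Cchol <- chol(C)
    Cinv <- chol2inv(Cchol)
    beta <- Cinv %*% crossprod(Xw, y)
    e <- y - as.vector(X %*% beta)
    r <- w * e
    logL <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(Cchol))) + sum(e * r))

    w2 <- w * w
    MA <- crossprod(X, (w2 * d) * X)
    MI <- crossprod(X, w2 * X)
    trPA <- sum(w * d) - sum(Cinv * MA)
    trPI <- sum(w) - sum(Cinv * MI)
    scoreA <- -0.5 * (trPA - sum(d * r * r))
    scoreE <- -0.5 * (trPI - sum(r * r))

    tA <- d * r
    tE <- r
    Pv <- function(t) w * t - as.vector(Xw %*% (Cinv %*% crossprod(X, w * t)))
    PtA <- Pv(tA)
    PtE <- Pv(tE)
    AI <- matrix(0, 2, 2)
    AI[1, 1] <- 0.5 * sum(tA * PtA)
    AI[1, 2] <- AI[2, 1] <- 0.5 * sum(tA * PtE)
    AI[2, 2] <- 0.5 * sum(tE * PtE)
    list(logL = logL, score = c(scoreA, scoreE), AI = AI,
         beta = as.vector(beta), n = n, p = p)
  }
}

# ---- bivariate evaluator, complete-pair fast path --------------------------

# data: list(d, Y1, Y2, X1, X2) in the rotated basis; free: logical over the
# parameter order (g11, g12, g22, r11, r12, r22); fixed entries stay 0.
bivariateEvalFast <- function(data, free) {
  d <- data$d
  Y1 <- data$Y1; Y2 <- data$Y2
  X1 <- data$X1; X2 <- data$X2
  N <- length(d)
  p <- ncol(X1)
  pattern <- c("11", "12", "22", "11", "12", "22")
  genetic <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)

  function(theta) {
    G <- matrix(c(theta[1], theta[2], theta[2], theta[3]), 2, 2)
    R <- matrix(c(theta[4], theta[5], theta[5], theta[6]), 2, 2)
    B11 <- d * G[1, 1] + R[1, 1]
    B12 <- d * G[1, 2] + R[1, 2]
    B22 <- d * G[2, 2] + R[2, 2]
    det <- B11 * B22 - B12 * B12
    if (any(det <= 0)) stop("covariance left the PSD cone")
    W11 <- B22 / det
    W22 <- B11 / det
    W12 <- -B12 / det

    C <- matrix(0, 2 * p, 2 * p)
    i1 <- seq_len(p); i2 <- p + i1
    C[i1, i1] <- crossprod(X1, W11 * X1)
    C[i1, i2] <- crossprod(X1, W12 * X2)
    C[i2, i1] <- t(C[i1, i2])
    C[i2, i2] <- crossprod(X2, W22 * X2)
    Cchol <- chol(C)
    Cinv <- chol2inv(Cchol)
    rhs <- c(crossprod(X1, W11 * Y1 + W12 * Y2),
             crossprod(X2, W12 * Y1 + W22 * Y2))
    beta <- as.vector(Cinv %*% rhs)
    e1 <- Y1 - as.vector(X1 %*% beta[i1])
    e2 <- Y2 - as.vector(X2 %*% beta[i2])
    r1 <- W11 * e1 + W12 * e2
    r2 <- W12 * e1 + W22 * e2
    logL <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(Cchol))) +
                      sum(e1 * r1 + e2 * r2))

    # per-parameter pieces
    freeIdx <- which(free)
    nf <- length(freeIdx)
    score <- numeric(6)
    tList <- vector("list", 6)
    WtList <- vector("list", 6)
    aList <- vector("list", 6)
    for (q in freeIdx) {
      cvec <- if (genetic[q]) d else 1
      pat <- pattern[q]
      if (pat == "11") {
        trV <- sum(cvec * W11)
        m11 <- cvec * W11 * W11
        m12 <- cvec * W11 * W12
        m22 <- cvec * W12 * W12
        t1 <- cvec * r1; t2 <- 0 * r2
        quad <- sum(cvec * r1 * r1)
      } else if (pat == "22") {
        trV <- sum(cvec * W22)
        m11 <- cvec * W12 * W12
        m12 <- cvec * W12 * W22
        m22 <- cvec * W22 * W22
        t1 <- 0 * r1; t2 <- cvec * r2
        quad <- sum(cvec * r2 * r2)
      } else {
        trV <- 2 * sum(cvec * W12)
        m11 <- cvec * 2 * W11 * W12
        m12 <- cvec * (W11 * W22 + W12 * W12)
        m22 <- cvec * 2 * W12 * W22
        t1 <- cvec * r2; t2 <- cvec * r1
        quad <- 2 * sum(cvec * r1 * r2)
      }
      M <- matrix(0, 2 * p, 2 * p)
      M[i1, i1] <- crossprod(X1, m11 * X1)
      M[i1, i2] <- crossprod(X1, m12 * X2)
      M[i2, i1] <- t(M[i1, i2])
      M[i2, i2] <- crossprod(X2, m22 * X2)
      trPD <- trV - sum(Cinv * M)
      score[q] <- -0.5 * (trPD - quad)
      Wt1 <- W11 * t1 + W12 * t2
      Wt2 <- W12 * t1 + W22 * t2
      tList[[q]] <- list(t1 = t1, t2 = t2)
      WtList[[q]] <- list(w1 = Wt1, w2 = Wt2)
      aList[[q]] <- c(crossprod(X1, Wt1), crossprod(X2, Wt2))
    }
    AI <- matrix(0, 6, 6)
    for (a in seq_len(nf)) {
      qa <- freeIdx[a]
      for (b in a:nf) {
        qb <- freeIdx[b]
        v <- 0.5 * (sum(tList[[qa]]$t1 * WtList[[qb]]$w1 +
                          tList[[qa]]$t2 * WtList[[qb]]$w2) -
                      as.numeric(aList[[qa]] %*% Cinv %*% aList[[qb]]))
        AI[qa, qb] <- AI[qb, qa] <- v
      }
    }
    list(logL = logL, score = score, AI = AI, beta = beta,
         n = 2L * N, p = 2L * p)
  }
}

# ---- bivariate evaluator, dense per-family path (missing traits) -----------

# blocks: list per family of list(A (m x m), obs matrix with columns
# ind (local index) and trait (1/2), X (m x p covariates), y1, y2 (length m,
# NA allowed). Entries are the observed (individual, trait) pairs.
bivariateEvalDense <- function(blocks, p, free) {
  pattern <- c("11", "12", "22", "11", "12", "22")
  genetic <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  Epat <- list("11" = matrix(c(1, 0, 0, 0), 2),
               "12" = matrix(c(0, 1, 1, 0), 2),
               "22" = matrix(c(0, 0, 0, 1), 2))
  nObs <- sum(vapply(blocks, function(b) nrow(b$obs), integer(1)))

  function(theta) {
    G <- matrix(c(theta[1], theta[2], theta[2], theta[3]), 2, 2)
    R <- matrix(c(theta[4], theta[5], theta[5], theta[6]), 2, 2)
    P2 <- 2L * p
    i1 <- seq_len(p); i2 <- p + i1
    C <- matrix(0, P2, P2)
    rhs <- numeric(P2)
    logdetV <- 0
    pre <- vector("list", length(blocks))
    for (f in seq_along(blocks)) {
      b <- blocks[[f]]
      ii <- b$obs[, "ind"]
      tt <- b$obs[, "trait"]
      m <- length(ii)
      V <- matrix(0, m, m)
      for (a in seq_len(m)) {
        for (c2 in a:m) {
          v <- b$A[ii[a], ii[c2]] * G[tt[a], tt[c2]] +
            (ii[a] == ii[c2]) * R[tt[a], tt[c2]]
          V[a, c2] <- V[c2, a] <- v
        }
      }
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) stop("covariance left the PSD cone")
      logdetV <- logdetV + 2 * sum(log(diag(ch)))
      Vinv <- chol2inv(ch)
      Xf <- matrix(0, m, P2)
      for (a in seq_len(m)) {
        cols <- if (tt[a] == 1L) i1 else i2
        Xf[a, cols] <- b$X[ii[a], ]
      }
      yf <- ifelse(tt == 1L, b$y1[ii], b$y2[ii])
      VX <- Vinv %*% Xf
      C <- C + crossprod(Xf, VX)
      rhs <- rhs + crossprod(VX, yf)
      pre[[f]] <- list(Vinv = Vinv, X = Xf, y = yf, ii = ii, tt = tt, m = m)
    }
    Cchol <- chol(C)
    Cinv <- chol2inv(Cchol)
    beta <- as.vector(Cinv %*% rhs)

    freeIdx <- which(free)
    score <- numeric(6)
    trV <- numeric(6)
    quad <- numeric(6)
    Msum <- lapply(seq_len(6), function(q) matrix(0, P2, P2))
    aSum <- lapply(seq_len(6), function(q) numeric(P2))
    cross <- matrix(0, 6, 6)
    yPy <- 0
    for (f in seq_along(blocks)) {
      b <- blocks[[f]]
      pf <- pre[[f]]
      e <- pf$y - as.vector(pf$X %*% beta)
      r <- as.vector(pf$Vinv %*% e)
      yPy <- yPy + sum(e * r)
      Dlist <- vector("list", 6)
      for (q in freeIdx) {
        E <- Epat[[pattern[q]]]
        base <- if (genetic[q]) b$A[pf$ii, pf$ii, drop = FALSE] else
          outer(pf$ii, pf$ii, "==") * 1
        D <- base * E[cbind(rep(pf$tt, pf$m),
                            rep(pf$tt, each = pf$m))]
        dim(D) <- c(pf$m, pf$m)
        Dlist[[q]] <- D
        VD <- pf$Vinv %*% D
        trV[q] <- trV[q] + sum(diag(VD))
        Msum[[q]] <- Msum[[q]] + crossprod(pf$X, VD %*% pf$Vinv %*% pf$X)
        tq <- as.vector(D %*% r)
        quad[q] <- quad[q] + sum(r * tq)
        aSum[[q]] <- aSum[[q]] + as.vector(crossprod(pf$X, pf$Vinv %*% tq))
        Dlist[[q]] <- tq     # keep only D r for the AI cross terms
      }
      for (a in seq_along(freeIdx)) {
        qa <- freeIdx[a]
        for (bq in a:length(freeIdx)) {
          qb <- freeIdx[bq]
          cross[qa, qb] <- cross[qa, qb] +
            as.numeric(Dlist[[qa]] %*% pf$Vinv %*% Dlist[[qb]])
        }
      }
    }
    logL <- -0.5 * (logdetV + 2 * sum(log(diag(Cchol))) + yPy)
    AI <- matrix(0, 6, 6)
    for (a in seq_along(freeIdx)) {
      qa <- freeIdx[a]
      for (bq in a:length(freeIdx)) {
        qb <- freeIdx[bq]
        v <- 0.5 * (cross[qa, qb] -
                      as.numeric(aSum[[qa]] %*% Cinv %*% aSum[[qb]]))
        AI[qa, qb] <- AI[qb, qa] <- v
      }
    }
    for (q in freeIdx) {
      score[q] <- -0.5 * ((trV[q] - sum(Cinv * Msum[[q]])) - quad[q])
    }
    list(logL = logL, score = score, AI = AI, beta = beta,
         n = nObs, p = P2)
  }
}
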