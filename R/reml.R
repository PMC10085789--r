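## AI-REML engine for Gaussian mixed models with independent random terms,
## each carrying an identity, supplied, or Kronecker covariance structure.
##
## The engine works in Henderson's mixed-model equations with
## variance-ratio-scaled covariances: with V = sigma2e * (I + Z G Z'),
## G = blockdiag(gamma_k K_k), gamma_k = sigma2_k / sigma2e, and
## C = [X'X X'Z; Z'X Z'Z + G^-1], the REML deviance is
##   -2 l = (n-p) log sigma2e + sum_k (q_k log gamma_k + log|K_k|)
##        + log|C| + y'Py + (n-p) log 2pi,
## with y'Py = (y'y - bhat'X'y - uhat'Z'y) / sigma2e. Traces needed for the
## scores come from the u-blocks of C^-1:
##   tr(P Z_k K_k Z_k') = (q_k/gamma_k - tr(K_k^-1 Cuu_kk)/gamma_k^2)/sigma2e.
## Updates are average-information steps with step halving and an EM
## fallback; non-negativity is enforced by projection onto a small floor,
## and components ending on the floor are reported as 0.

.encodeFixed <- function(data, fixed) {
  n <- nrow(data)
  if (length(fixed) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    info <- data.frame(term = "(Intercept)", level = "",
                       stringsAsFactors = FALSE)
    return(list(X = X, info = info))
  }
  df <- data[, fixed, drop = FALSE]
  for (f in fixed) df[[f]] <- factor(as.character(df[[f]]))
  fml <- as.formula(paste("~", paste(fixed, collapse = " + ")))
  X <- model.matrix(fml, df)
  asgn <- attr(X, "assign")
  term <- c("(Intercept)", fixed)[asgn + 1]
  level <- vapply(seq_along(term), function(i) {
    if (term[i] == "(Intercept)") "" else
      substring(colnames(X)[i], nchar(term[i]) + 1)
  }, character(1))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  list(X = X, info = data.frame(term = term, level = level,
                                stringsAsFactors = FALSE))
}

.encodeRandom <- function(data, term) {
  vals <- do.call(paste, c(lapply(term@factors, function(f)
    as.character(data[[f]])), sep = ":"))
  struct <- .withIds(term@struct, sort(unique(vals)))
  ids <- covIds(struct)
  j <- match(vals, ids)
  if (anyNA(j)) {
    miss <- unique(vals[is.na(j)])
    stop("levels of term '", term@name,
         "' absent from its covariance structure: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  }
  Z <- Matrix::sparseMatrix(i = seq_along(j), j = j,
                            x = 1, dims = c(nrow(data), length(ids)))
  list(Z = Z, struct = struct, ids = ids)
}

.buildDesign <- function(data, spec) {
  y <- data[[spec@response]]
  if (is.null(y)) stop("response column '", spec@response, "' not found")
  keep <- !is.na(y)
  nDropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(y[keep])
  if (length(y) < 2) stop("fewer than 2 non-missing observations")
  fx <- .encodeFixed(data, spec@fixed)
  rn <- lapply(spec@random, function(t) .encodeRandom(data, t))
  names(rn) <- vapply(spec@random, function(t) t@name, character(1))
  list(y = y, X = fx$X, fixedInfo = fx$info, random = rn,
       nDropped = nDropped)
}

## Core engine on prepared matrices. thetaFixed: optional named full vector
## of variance components (terms then "residual"); when given, no estimation.
.remlEngine <- function(y, X, random, init = NULL, thetaFixed = NULL,
                        maxIter = 200L, tol = 1e-8, verbose = FALSE) {
  n <- length(y)
  p <- ncol(X)
  K <- length(random)
  termNames <- names(random)
  vary <- var(y)
  floorv <- 1e-10 * max(vary, .Machine$double.eps)

  if (K == 0 && is.null(thetaFixed)) {
    qrX <- qr(X)
    beta <- qr.coef(qrX, y)
    rss <- sum(qr.resid(qrX, y)^2)
    s2 <- rss / (n - p)
    m2ll <- (n - p) * log(s2) + 2 * sum(log(abs(diag(qr.R(qrX))))) +
      (n - p) + (n - p) * log(2 * pi)
    return(list(theta = c(residual = s2), beta = beta, u = list(),
                pev = list(), logLik = -m2ll / 2, converged = TRUE,
                nIter = 0L, se = c(residual = NA_real_),
                boundary = logical(0)))
  }

  qk <- vapply(random, function(r) ncol(r$Z), numeric(1))
  Kinv <- lapply(random, function(r) covInverse(r$struct))
  logdetK <- vapply(random, function(r) covLogDet(r$struct), numeric(1))
  W <- cbind(Matrix::Matrix(X, sparse = TRUE),
             do.call(cbind, lapply(random, `[[`, "Z")))
  WtW <- as.matrix(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y * y)
  idxList <- vector("list", K)
  off <- p
  for (k in seq_len(K)) {
    idxList[[k]] <- off + seq_len(qk[k])
    off <- off + qk[k]
  }

  cholC <- function(theta) {
    gam <- theta[seq_len(K)] / theta[K + 1]
    C <- WtW
    for (k in seq_len(K)) {
      ii <- idxList[[k]]
      C[ii, ii] <- C[ii, ii] + Kinv[[k]] / gam[k]
    }
    R <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(R)) {
      diag(C) <- diag(C) * (1 + 1e-10) + 1e-10
      R <- chol(C)
    }
    R
  }
  solveC <- function(R, b) backsolve(R, backsolve(R, b, transpose = TRUE))

  deviance <- function(theta, R = NULL, sol = NULL) {
    s2 <- unname(theta[K + 1])
    gam <- theta[seq_len(K)] / s2
    if (is.null(R)) R <- cholC(theta)
    if (is.null(sol)) sol <- solveC(R, Wty)
    yPy <- (yty - sum(sol * Wty)) / s2
    (n - p) * log(s2) + sum(qk * log(gam) + logdetK) +
      2 * sum(log(diag(R))) + yPy + (n - p) * log(2 * pi)
  }

  if (!is.null(thetaFixed)) {
    theta <- c(thetaFixed[termNames], residual = unname(thetaFixed["residual"]))
    names(theta) <- c(termNames, "residual")
    active <- which(theta[seq_len(K)] > 0)
    if (length(active) < K) {
      sub <- .remlEngine(y, X, random[active],
                         thetaFixed = c(theta[active],
                                        residual = theta[[K + 1]]),
                         maxIter = maxIter, tol = tol)
      u <- setNames(vector("list", K), termNames)
      pev <- setNames(vector("list", K), termNames)
      for (k in seq_len(K)) {
        if (termNames[k] %in% names(sub$u)) {
          u[[k]] <- sub$u[[termNames[k]]]
          pev[[k]] <- sub$pev[[termNames[k]]]
        } else {
          u[[k]] <- setNames(rep(0, qk[k]), random[[k]]$ids)
          pev[[k]] <- setNames(rep(theta[k], qk[k]), random[[k]]$ids)
        }
      }
      return(list(theta = theta, beta = sub$beta, u = u, pev = pev,
                  logLik = sub$logLik, converged = TRUE, nIter = 0L,
                  se = setNames(rep(NA_real_, K + 1), names(theta)),
                  boundary = theta[seq_len(K)] <= 0))
    }
    R <- cholC(theta)
    sol <- solveC(R, Wty)
    Cinv <- chol2inv(R)
    out <- .extractFit(theta, sol, Cinv, random, idxList, p, termNames)
    out$logLik <- -deviance(theta, R, sol) / 2
    out$converged <- TRUE
    out$nIter <- 0L
    out$se <- setNames(rep(NA_real_, K + 1), names(theta))
    out$boundary <- rep(FALSE, K)
    return(out)
  }

  theta <- if (is.null(init)) c(rep(vary / (2 * K), K), vary / 2) else init
  theta <- pmax(theta, floorv)
  names(theta) <- c(termNames, "residual")
  dev <- Inf
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  shrink <- integer(K)

  ## A component the likelihood clearly wants at zero is removed from the
  ## equations for good (its gamma^-1-scaled K^-1 block would otherwise
  ## ill-condition the whole system): the remaining terms are refit by a
  ## recursive call starting from the current point.
  dropAndRefit <- function(drop) {
    keep <- setdiff(seq_len(K), drop)
    sub <- .remlEngine(y, X, random[keep],
                       init = unname(c(theta[keep], theta[K + 1])),
                       maxIter = max(10L, maxIter - iter), tol = tol,
                       verbose = verbose)
    thetaFull <- c(rep(0, K), sub$theta[length(sub$theta)])
    names(thetaFull) <- c(termNames, "residual")
    thetaFull[keep] <- sub$theta[seq_along(keep)]
    u <- setNames(vector("list", K), termNames)
    pev <- setNames(vector("list", K), termNames)
    seFull <- setNames(rep(NA_real_, K + 1), names(thetaFull))
    boundary <- rep(TRUE, K)
    for (j in seq_along(keep)) {
      k <- keep[j]
      u[[k]] <- sub$u[[j]]
      pev[[k]] <- sub$pev[[j]]
      seFull[k] <- sub$se[j]
      boundary[k] <- sub$boundary[j]
    }
    seFull[K + 1] <- sub$se[length(sub$se)]
    for (k in drop) {
      u[[k]] <- setNames(rep(0, qk[k]), random[[k]]$ids)
      pev[[k]] <- setNames(rep(0, qk[k]), random[[k]]$ids)
    }
    list(theta = thetaFull, beta = sub$beta, u = u, pev = pev,
         logLik = sub$logLik, converged = sub$converged,
         nIter = iter + sub$nIter, se = seFull, boundary = boundary)
  }

  for (iter in seq_len(maxIter)) {
    s2 <- theta[K + 1]
    gam <- theta[seq_len(K)] / s2
    R <- cholC(theta)
    sol <- solveC(R, Wty)
    devNow <- deviance(theta, R, sol)
    Cinv <- chol2inv(R)
    beta <- sol[seq_len(p)]

    tk <- numeric(K); uKu <- numeric(K); trPZKZ <- numeric(K)
    for (k in seq_len(K)) {
      ii <- idxList[[k]]
      uk <- sol[ii]
      tk[k] <- sum(Kinv[[k]] * Cinv[ii, ii])
      uKu[k] <- as.numeric(crossprod(uk, Kinv[[k]] %*% uk))
      trPZKZ[k] <- (qk[k] / gam[k] - tk[k] / gam[k]^2) / s2
    }
    yPy <- (yty - sum(sol * Wty)) / s2
    Py <- as.numeric(y - W %*% sol) / s2
    trP <- (n - p - sum(theta[seq_len(K)] * trPZKZ)) / s2
    score <- c(-0.5 * (trPZKZ - uKu / theta[seq_len(K)]^2),
               -0.5 * (trP - sum(Py * Py)))

    ## EM candidates (ascent-guaranteed fallback)
    thetaEM <- c((uKu + s2 * tk) / qk, yPy * s2 / (n - p))
    thetaEM <- pmax(thetaEM, floorv)

    ## boundary handling: a component repeatedly shrinking geometrically
    ## while already negligible, or pinned at the floor with a downhill
    ## score, is dropped from the system permanently
    shrink <- ifelse(thetaEM[seq_len(K)] < 0.7 * theta[seq_len(K)],
                     shrink + 1L, 0L)
    dropk <- which((shrink >= 3L & theta[seq_len(K)] < 1e-3 * vary) |
                   (theta[seq_len(K)] <= 1.5 * floorv &
                      score[seq_len(K)] < 0))
    if (length(dropk)) return(dropAndRefit(dropk))

    ## components pinned at the floor whose score points further down are
    ## excluded from the AI update this iteration
    pinned <- c(theta[seq_len(K)] <= 1.5 * floorv, FALSE) &
      score < 0
    free <- which(!pinned)
    thetaEM[pinned[seq_len(K)]] <- floorv

    ## Average-information matrix
    ## f_k = Z_k K_k Z_k' P y = Z_k u_k / sigma2_k (BLUP identity)
    Fm <- matrix(0, n, K + 1)
    for (k in seq_len(K))
      Fm[, k] <- as.numeric(random[[k]]$Z %*% sol[idxList[[k]]]) / theta[k]
    Fm[, K + 1] <- Py
    WtF <- as.matrix(Matrix::crossprod(W, Fm))
    PF <- (Fm - as.matrix(W %*% solveC(R, WtF))) / s2
    AI <- 0.5 * crossprod(Fm, PF)
    AI <- (AI + t(AI)) / 2

    step <- rep(0, K + 1)
    stepFree <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                         error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(stepFree) && all(is.finite(stepFree))) {
      step[free] <- stepFree
      h <- 1
      for (try in 1:4) {
        cand <- pmax(theta + h * step, floorv)
        devCand <- tryCatch(deviance(cand), error = function(e) Inf)
        if (is.finite(devCand) && devCand <= devNow + 1e-10) {
          thetaNew <- cand; devNew <- devCand; accepted <- TRUE; break
        }
        h <- h / 2
      }
    }
    if (!accepted) {
      thetaNew <- thetaEM
      devNew <- tryCatch(deviance(thetaNew), error = function(e) devNow)
    }

    relChange <- max(abs(thetaNew - theta) / (theta + 1))
    devDelta <- abs(devNew - devNow)
    if (verbose)
      cat(sprintf("it %3d %s dev %.8f d %.2e theta %s\n", iter,
                  if (accepted) "AI" else "EM", devNew, relChange,
                  paste(signif(thetaNew, 4), collapse = " ")))
    theta <- thetaNew
    names(theta) <- c(termNames, "residual")
    if (relChange < tol || devDelta < 1e-10 * (1 + abs(devNow))) {
      converged <- TRUE
      dev <- devNew
      break
    }
    dev <- devNew
  }

  R <- cholC(theta)
  sol <- solveC(R, Wty)
  Cinv <- chol2inv(R)
  out <- .extractFit(theta, sol, Cinv, random, idxList, p, termNames)
  out$logLik <- -deviance(theta, R, sol) / 2
  out$converged <- converged
  out$nIter <- iter
  boundary <- theta[seq_len(K)] <= 1.5 * floorv
  se <- rep(NA_real_, K + 1)
  if (!is.null(AI)) {
    AIinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(AIinv)) se <- sqrt(pmax(diag(AIinv), 0))
  }
  se[c(boundary, FALSE)] <- NA_real_
  names(se) <- names(theta)
  out$se <- se
  out$boundary <- boundary
  ## report boundary components as 0
  out$theta[seq_len(K)][boundary] <- 0
  out
}

.extractFit <- function(theta, sol, Cinv, random, idxList, p, termNames) {
  K <- length(random)
  s2 <- theta[K + 1]
  u <- setNames(vector("list", K), termNames)
  pev <- setNames(vector("list", K), termNames)
  for (k in seq_len(K)) {
    ii <- idxList[[k]]
    u[[k]] <- setNames(sol[ii], random[[k]]$ids)
    pev[[k]] <- setNames(s2 * diag(Cinv)[ii], random[[k]]$ids)
  }
  list(theta = theta, beta = sol[seq_len(p)], u = u, pev = pev)
}

#' Fit a linear mixed model by REML
#'
#' Average-information REML with EM fallback steps; variance components are
#' kept non-negative by projection onto a small floor and reported as 0 when
#' they finish on it. Fixed effects are estimated by generalized least
#' squares at the converged components and random effects by BLUP from the
#' mixed-model equations. Rows with a missing response are dropped (their
#' count is recorded in the fit).
#'
#' @param data a data.frame (plot-level phenotype table).
#' @param spec a [ModelSpec].
#' @param init optional numeric vector of starting values, one per random
#'   term plus the residual.
#' @param varCompFixed optional named vector (term names plus
#'   \code{"residual"}): solve the mixed-model equations at these fixed
#'   components instead of estimating (terms with value 0 are dropped from
#'   the equations and get zero BLUPs).
#' @param maxIter,tol iteration cap and relative-change convergence
#'   tolerance.
#' @return a [ModelFit]. `varComp()` and `fixedEffects()` access the
#'   components and the fixed-effect table; [blupTable()] the per-level
#'   BLUPs.
#' @export
remlFit <- function(data, spec, init = NULL, varCompFixed = NULL,
                    maxIter = 200L, tol = 1e-8) {
  des <- .buildDesign(data, spec)
  eng <- .remlEngine(des$y, des$X, des$random, init = init,
                     thetaFixed = varCompFixed, maxIter = maxIter, tol = tol)
  n <- length(des$y)
  nvc <- length(eng$theta)
  fixedEff <- des$fixedInfo
  fixedEff$estimate <- as.numeric(eng$beta)
  fit <- new("ModelFit",
    varComp = eng$theta, varCompSE = eng$se, fixedEffects = fixedEff,
    blup = eng$u, pev = eng$pev, logLik = eng$logLik,
    aic = -2 * eng$logLik + 2 * nvc,
    bic = -2 * eng$logLik + log(n) * nvc,
    converged = eng$converged, nIter = as.integer(eng$nIter),
    nObs = as.integer(n), nDropped = as.integer(des$nDropped), spec = spec)
  fit
}

setMethod("varComp", "ModelFit", function(fit) fit@varComp)
setMethod("fixedEffects", "ModelFit", function(fit) fit@fixedEffects)

#' Per-level BLUPs and prediction error variances for one random term
#'
#' @param fit a [ModelFit].
#' @param term random-term name.
#' @return data.frame (level, blup, pev) ordered as the term's covariance
#'   structure ids.
#' @export
blupTable <- function(fit, term) {
  if (!term %in% names(fit@blup)) stop("unknown random term: ", term)
  data.frame(level = names(fit@blup[[term]]),
             blup = as.numeric(fit@blup[[term]]),
             pev = as.numeric(fit@pev[[term]]),
             stringsAsFactors = FALSE)
}

#' Direct dense evaluation of the REML log-likelihood
#'
#' Builds V = sigma2e I + sum_k sigma2_k Z_k K_k Z_k' explicitly and
#' evaluates the restricted likelihood by dense factorization. Intended as
#' an independent numerical cross-check of the mixed-model-equation engine
#' (use only at small n).
#'
#' @param data,spec as in [remlFit()].
#' @param varComp named components (terms plus \code{"residual"}).
#' @return REML log-likelihood (constants included).
#' @export
denseREMLLogLik <- function(data, spec, varComp) {
  des <- .buildDesign(data, spec)
  y <- des$y; X <- des$X
  n <- length(y); p <- ncol(X)
  V <- diag(varComp[["residual"]], n)
  for (k in seq_along(des$random)) {
    r <- des$random[[k]]
    Zk <- as.matrix(r$Z)
    V <- V + varComp[[names(des$random)[k]]] *
      (Zk %*% covMatrix(r$struct) %*% t(Zk))
  }
  cV <- chol(V)
  logdetV <- 2 * sum(log(diag(cV)))
  Vi <- chol2inv(cV)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  yPy <- as.numeric(t(r) %*% Vi %*% r)
  m2ll <- logdetV + determinant(XtVX, logarithm = TRUE)$modulus + yPy +
    (n - p) * log(2 * pi)
  -as.numeric(m2ll) / 2
}

#' Export a fit as JSON (components, logLik, AIC/BIC) and TSV tables
#'
#' @param fit a [ModelFit].
#' @param prefix output path prefix; writes `<prefix>.json`,
#'   `<prefix>_fixed.tsv` and `<prefix>_blup_<term>.tsv`.
#' @return invisibly, the files written.
#' @export
exportFit <- function(fit, prefix) {
  files <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    varComp = as.list(fit@varComp), logLik = fit@logLik, aic = fit@aic,
    bic = fit@bic, converged = fit@converged, nObs = fit@nObs),
    files, auto_unbox = TRUE, digits = NA)
  f <- paste0(prefix, "_fixed.tsv")
  write.table(fit@fixedEffects, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  for (term in names(fit@blup)) {
    f <- paste0(prefix, "_blup_", gsub("[^A-Za-z0-9_]", "_", term), ".tsv")
    write.table(blupTable(fit, term), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
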