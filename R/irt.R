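#' Rasch response probability
#'
#' @param theta ability (logits).
#' @param xi item difficulty (logits).
#' @return \code{plogis(theta - xi)}, the probability of a correct
#'   response under the Rasch model.
#' @examples
#' raschProb(0, 0)    # 0.5
#' raschProb(1, 0)    # 0.731
#' @export
raschProb <- function(theta, xi) {
    plogis(theta - xi)
}

## Quadrature grid shared by both fitters: equally spaced nodes on a
## fixed interval. The grid is chosen once and held fixed during EM so
## that the marginal likelihood of the discretised model is exactly
## nondecreasing across iterations.
quadratureNodes <- function(nQuad = 61L, gridBounds = c(-6, 6)) {
    if (nQuad < 5L)
        stop("at least 5 quadrature nodes are required")
    seq(gridBounds[1L], gridBounds[2L], length.out = nQuad)
}

## Person x node log-likelihood of the observed responses under fixed
## difficulties. Items with NA difficulty contribute nothing.
itemLogLik <- function(Y, xi, nodes) {
    Y <- as.matrix(Y)
    use <- !is.na(xi)
    Yu <- Y[, use, drop = FALSE]
    xiu <- xi[use]
    eta <- outer(nodes, xiu, "-")              # Q x J
    logp <- plogis(eta, log.p = TRUE)
    log1mp <- plogis(-eta, log.p = TRUE)
    obs <- !is.na(Yu)
    y1 <- matrix(0, nrow(Yu), ncol(Yu))
    y1[obs & Yu == 1] <- 1
    y0 <- matrix(0, nrow(Yu), ncol(Yu))
    y0[obs & Yu == 0] <- 1
    y1 %*% t(logp) + y0 %*% t(log1mp)          # n x Q
}

#' Fit a Rasch model by marginal maximum likelihood
#'
#' EM estimation over a fixed equally spaced quadrature grid with a
#' normal latent population whose mean is fixed at 0 (identification)
#' and whose variance is estimated. Item difficulties are free. Items
#' without both a correct and an incorrect observed response cannot be
#' estimated and are excluded with a warning (their difficulty is NA).
#' Missing responses are skipped in the likelihood.
#'
#' Convergence is declared when the relative change in the marginal
#' log-likelihood falls below \code{tol} or the largest parameter change
#' falls below \code{parTol}; otherwise the fit is flagged as
#' non-converged after \code{maxit} iterations.
#'
#' @param Y persons x items 0/1/NA response matrix.
#' @param nQuad number of quadrature nodes.
#' @param gridBounds interval covered by the quadrature grid (logits).
#' @param tol relative log-likelihood convergence tolerance.
#' @param parTol maximum-parameter-change convergence tolerance.
#' @param maxit iteration cap.
#' @return a [RaschFit-class].
#' @examples
#' cond <- makeCondition(0.5, 0.05, nPerGroup = 100)
#' Y <- responseMatrix(simulateCondition(cond, seed = 1))
#' fit <- fitRaschMML(Y)
#' head(fit@difficulty)
#' @export
fitRaschMML <- function(Y, nQuad = 61L, gridBounds = c(-6, 6),
                        tol = 1e-9, parTol = 1e-4, maxit = 500L) {
    Y <- as.matrix(Y)
    J <- ncol(Y)
    nCorrect <- colSums(Y == 1, na.rm = TRUE)
    nWrong <- colSums(Y == 0, na.rm = TRUE)
    excluded <- which(nCorrect < 1L | nWrong < 1L)
    if (length(excluded))
        warning(sprintf(
            "%d item(s) without response variation excluded: %s",
            length(excluded), paste(excluded, collapse = ", ")))
    use <- setdiff(seq_len(J), excluded)
    Yu <- Y[, use, drop = FALSE]
    obs <- !is.na(Yu)
    y1 <- matrix(0, nrow(Yu), ncol(Yu)); y1[obs & Yu == 1] <- 1
    y0 <- matrix(0, nrow(Yu), ncol(Yu)); y0[obs & Yu == 0] <- 1
    nodes <- quadratureNodes(nQuad, gridBounds)
    delta <- nodes[2L] - nodes[1L]
    pbar <- nCorrect[use] / (nCorrect[use] + nWrong[use])
    xi <- qlogis(1 - pbar)
    sigma2 <- 1
    trace <- numeric(maxit)
    nIter <- 0L
    converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- outer(nodes, xi, "-")
        logp <- plogis(eta, log.p = TRUE)
        log1mp <- plogis(-eta, log.p = TRUE)
        logL <- y1 %*% t(logp) + y0 %*% t(log1mp)
        logw <- dnorm(nodes, 0, sqrt(sigma2), log = TRUE) + log(delta)
        A <- sweep(logL, 2L, logw, "+")
        lli <- rowLogSumExp(A)
        LL <- sum(lli)
        trace[it] <- LL
        nIter <- it
        P <- exp(A - lli)                      # n x Q posterior weights
        njq <- crossprod(obs * 1, P)           # J x Q expected exposure
        rjq <- crossprod(y1, P)                # J x Q expected correct
        Rj <- rowSums(rjq)
        xiNew <- xi
        for (nr in 1:50) {
            p <- plogis(outer(nodes, xiNew, "-"))    # Q x J
            g <- rowSums(njq * t(p)) - Rj
            h <- -rowSums(njq * t(p * (1 - p)))
            step <- g / h
            xiNew <- xiNew - step
            if (max(abs(g)) < 1e-10)
                break
        }
        sigma2New <- mean(P %*% nodes^2)
        parChange <- max(abs(c(xiNew - xi, sigma2New - sigma2)))
        xi <- xiNew
        sigma2 <- sigma2New
        if (it > 1L) {
            rel <- abs(LL - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
            if (rel < tol || parChange < parTol) {
                converged <- TRUE
                break
            }
        }
    }
    trace <- trace[seq_len(nIter)]
    diffFull <- rep(NA_real_, J)
    diffFull[use] <- xi
    names(diffFull) <- colnames(Y)
    new("RaschFit",
        difficulty = diffFull, latentMean = 0, latentVar = sigma2,
        logLik = trace[nIter], logLikTrace = trace,
        converged = converged, iterations = nIter,
        excludedItems = as.integer(excluded), nodes = nodes)
}

#' Effort-moderated filtering of a response matrix
#'
#' Operationalizes the effort-moderated measurement model for plausible
#' value estimation: responses flagged as rapid guesses carry no
#' information about ability and are recoded as missing; all other cells
#' are unchanged. The number of recoded cells is attached as attribute
#' \code{"nRecoded"} and optionally reported.
#'
#' @param Y persons x items response matrix.
#' @param flags persons x items 0/1/NA engagement flags.
#' @param verbose report the number of recoded cells.
#' @return the filtered response matrix.
#' @examples
#' applyEmmFilter(matrix(1, 2, 2), matrix(c(1, 0, 1, 1), 2))
#' @export
applyEmmFilter <- function(Y, flags, verbose = FALSE) {
    Y <- as.matrix(Y)
    flags <- as.matrix(flags)
    if (!identical(dim(Y), dim(flags)))
        stop("responses and flags must share dimensions")
    recode <- !is.na(flags) & flags == 0L & !is.na(Y)
    Y[recode] <- NA
    attr(Y, "nRecoded") <- sum(recode)
    if (verbose)
        message(sprintf("effort-moderated filter: %d response(s) recoded as missing",
                        sum(recode)))
    Y
}

#' Fit the latent-regression background model
#'
#' EM estimation of the conditioning model of plausible value
#' estimation: abilities follow a normal prior whose mean is a linear
#' regression on covariates, \code{theta_i ~ N(psi0 + psiX' X_i,
#' residVar)}, combined with a Rasch likelihood whose difficulties are
#' fixed (typically from a prior [fitRaschMML()] step). Persons whose
#' responses are all missing contribute a flat likelihood and stay in
#' the fit.
#'
#' @param Y persons x items 0/1/NA response matrix.
#' @param difficulty fixed item difficulties (NA entries are dropped).
#' @param X covariate matrix or data.frame (no intercept column), or
#'   \code{NULL} for an intercept-only model.
#' @param nQuad,gridBounds,tol,parTol,maxit as in [fitRaschMML()].
#' @param computeSE also compute the large-sample covariance of the
#'   estimates from the numerically differentiated observed information.
#' @return a [LatentRegressionFit-class].
#' @examples
#' cond <- makeCondition(0.5, 0.05, nPerGroup = 100)
#' re <- simulateCondition(cond, seed = 1)
#' Y <- responseMatrix(re)
#' step1 <- fitRaschMML(Y)
#' X <- data.frame(group = as.integer(groupLabels(re) == "2"))
#' fit <- fitLatentRegression(Y, step1@difficulty, X)
#' coef(fit)
#' @export
fitLatentRegression <- function(Y, difficulty, X = NULL, nQuad = 61L,
                                gridBounds = c(-6, 6), tol = 1e-9,
                                parTol = 1e-4, maxit = 500L,
                                computeSE = FALSE) {
    Y <- as.matrix(Y)
    n <- nrow(Y)
    if (length(difficulty) != ncol(Y))
        stop("'difficulty' must supply one value per item")
    covNames <- character()
    if (!is.null(X)) {
        X <- as.matrix(as.data.frame(X))
        if (nrow(X) != n)
            stop("covariates must have one row per person")
        covNames <- colnames(X)
        if (is.null(covNames))
            covNames <- paste0("x", seq_len(ncol(X)))
    }
    Xt <- cbind(intercept = rep(1, n), X)
    colnames(Xt) <- c("intercept", covNames)
    qrX <- qr(Xt)
    if (qrX$rank < ncol(Xt)) {
        bad <- colnames(Xt)[-seq_len(qrX$rank)]
        dropped <- setdiff(colnames(Xt),
                           colnames(Xt)[qrX$pivot[seq_len(qrX$rank)]])
        stop("collinear covariate column(s): ",
             paste(unique(c(bad, dropped)), collapse = ", "))
    }
    nodes <- quadratureNodes(nQuad, gridBounds)
    delta <- nodes[2L] - nodes[1L]
    logL <- itemLogLik(Y, difficulty, nodes)
    nodesMat <- matrix(nodes, n, length(nodes), byrow = TRUE)
    psi <- rep(0, ncol(Xt))
    sigma2 <- 1
    XtX <- crossprod(Xt)
    trace <- numeric(maxit)
    nIter <- 0L
    converged <- FALSE
    for (it in seq_len(maxit)) {
        m <- drop(Xt %*% psi)
        dev <- nodesMat - m
        logw <- -dev^2 / (2 * sigma2) -
            0.5 * log(2 * pi * sigma2) + log(delta)
        A <- logL + logw
        lli <- rowLogSumExp(A)
        LL <- sum(lli)
        trace[it] <- LL
        nIter <- it
        P <- exp(A - lli)
        t1 <- drop(P %*% nodes)
        t2 <- drop(P %*% nodes^2)
        psiNew <- drop(solve(XtX, crossprod(Xt, t1)))
        mHat <- drop(Xt %*% psiNew)
        sigma2New <- mean(t2 - 2 * t1 * mHat + mHat^2)
        parChange <- max(abs(c(psiNew - psi, sigma2New - sigma2)))
        psi <- psiNew
        sigma2 <- sigma2New
        if (it > 1L) {
            rel <- abs(LL - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
            if (rel < tol || parChange < parTol) {
                converged <- TRUE
                break
            }
        }
    }
    trace <- trace[seq_len(nIter)]
    names(psi) <- colnames(Xt)
    V <- matrix(numeric(), 0L, 0L)
    if (computeSE) {
        llFun <- function(par) {
            p <- par[seq_len(ncol(Xt))]
            s2 <- par[length(par)]
            if (s2 <= 0)
                return(-Inf)
            m <- drop(Xt %*% p)
            dev <- nodesMat - m
            lw <- -dev^2 / (2 * s2) - 0.5 * log(2 * pi * s2) + log(delta)
            sum(rowLogSumExp(logL + lw))
        }
        par <- c(psi, sigma2)
        H <- numericHessian(llFun, par)
        V <- tryCatch(solve(-H), error = function(e)
            matrix(NA_real_, length(par), length(par)))
        dimnames(V) <- list(c(names(psi), "residVar"),
                            c(names(psi), "residVar"))
    }
    new("LatentRegressionFit",
        coefficients = psi, residVar = sigma2,
        difficulty = difficulty, covariates = covNames,
        logLik = trace[nIter], logLikTrace = trace,
        converged = converged, iterations = nIter,
        nodes = nodes, vcov = V)
}

## Central-difference Hessian; step scaled to parameter magnitude.
numericHessian <- function(f, par, h = 1e-4) {
    p <- length(par)
    hh <- h * (abs(par) + 1)
    H <- matrix(NA_real_, p, p)
    f0 <- f(par)
    for (i in seq_len(p)) {
        for (j in i:p) {
            ei <- ej <- rep(0, p)
            ei[i] <- hh[i]; ej[j] <- hh[j]
            if (i == j) {
                H[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / hh[i]^2
            } else {
                H[i, j] <- H[j, i] <-
                    (f(par + ei + ej) - f(par + ei - ej) -
                     f(par - ei + ej) + f(par - ei - ej)) /
                    (4 * hh[i] * hh[j])
            }
        }
    }
    H
}

## Posterior node weights for each person under a latent-regression fit.
posteriorWeights <- function(fit, Y, X = NULL) {
    Y <- as.matrix(Y)
    n <- nrow(Y)
    Xt <- cbind(rep(1, n), if (is.null(X)) NULL
                else as.matrix(as.data.frame(X)))
    if (ncol(Xt) != length(fit@coefficients))
        stop("covariates do not match the fitted background model")
    nodes <- fit@nodes
    logL <- itemLogLik(Y, fit@difficulty, nodes)
    m <- drop(Xt %*% fit@coefficients)
    dev <- matrix(nodes, n, length(nodes), byrow = TRUE) - m
    logw <- -dev^2 / (2 * fit@residVar) -
        0.5 * log(2 * pi * fit@residVar)
    A <- logL + logw
    exp(A - rowLogSumExp(A))
}

#' Draw plausible values
#'
#' Draws \code{nPV} independent values per person from the discrete-grid
#' approximation of the ability posterior
#' \code{P(theta | Y_i, X_i) \%prop\% P(Y_i | theta) N(theta; psi0 +
#' psiX' X_i, residVar)}. Each draw samples a quadrature node from the
#' posterior weights and adds uniform jitter of half a node spacing to
#' avoid lattice artifacts.
#'
#' @param fit a converged [LatentRegressionFit-class].
#' @param Y persons x items response matrix used in the fit.
#' @param X covariates used in the fit (or \code{NULL}).
#' @param nPV number of plausible value sets (at least 2).
#' @param seed integer seed (optional).
#' @return a [PlausibleValues-class] with a \code{nPV} x persons draw
#'   matrix.
#' @examples
#' cond <- makeCondition(0.5, 0.05, nPerGroup = 50)
#' Y <- responseMatrix(simulateCondition(cond, seed = 1))
#' fit <- fitLatentRegression(Y, fitRaschMML(Y)@difficulty)
#' pv <- drawPlausibleValues(fit, Y, nPV = 5, seed = 2)
#' dim(pvMatrix(pv))
#' @export
drawPlausibleValues <- function(fit, Y, X = NULL, nPV = 25L, seed = NULL) {
    if (!fit@converged)
        stop("background model did not converge; refusing to draw plausible values")
    if (nPV < 2L)
        stop("at least 2 plausible value sets are required")
    P <- posteriorWeights(fit, Y, X)
    n <- nrow(P)
    nodes <- fit@nodes
    delta <- nodes[2L] - nodes[1L]
    cum <- rowCumsum(P)
    withSeed(seed, {
        draws <- matrix(NA_real_, nPV, n)
        for (m in seq_len(nPV)) {
            u <- runif(n)
            idx <- max.col(cum >= u, ties.method = "first")
            draws[m, ] <- nodes[idx] + runif(n, -delta / 2, delta / 2)
        }
        colnames(draws) <- rownames(Y)
        new("PlausibleValues", draws = draws,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    })
}

#' Expected a posteriori ability estimates
#'
#' Posterior mean and SD of ability per person under a latent-regression
#' fit, by direct summation over the quadrature grid.
#'
#' @param fit a [LatentRegressionFit-class].
#' @param Y persons x items response matrix.
#' @param X covariates used in the fit (or \code{NULL}).
#' @return data.frame with columns \code{eap} and \code{sd}.
#' @export
eapAbility <- function(fit, Y, X = NULL) {
    P <- posteriorWeights(fit, Y, X)
    nodes <- fit@nodes
    m1 <- drop(P %*% nodes)
    m2 <- drop(P %*% nodes^2)
    data.frame(eap = m1, sd = sqrt(pmax(m2 - m1^2, 0)),
               row.names = rownames(Y))
}

#' @rdname RaschFit-class
#' @export
setMethod("converged", "RaschFit", function(x) x@converged)

#' @rdname LatentRegressionFit-class
#' @param x an object.
#' @export
setMethod("converged", "LatentRegressionFit", function(x) x@converged)

#' @rdname RaschFit-class
#' @export
setMethod("logLikTrace", "RaschFit", function(x) x@logLikTrace)

#' @rdname LatentRegressionFit-class
#' @export
setMethod("logLikTrace", "LatentRegressionFit", function(x) x@logLikTrace)

#' @rdname RaschFit-class
#' @export
setMethod("difficulty", "RaschFit", function(x) x@difficulty)

#' @rdname LatentRegressionFit-class
#' @param object a fit.
#' @export
setMethod("coef", "LatentRegressionFit", function(object) {
    object@coefficients
})

#' @rdname LatentRegressionFit-class
#' @export
setMethod("vcov", "LatentRegressionFit", function(object) {
    if (!length(object@vcov))
        stop("fit was computed without standard errors; refit with computeSE = TRUE")
    object@vcov
})

#' @rdname RaschFit-class
#' @param object a fit.
#' @export
setMethod("show", "RaschFit", function(object) {
    cat(sprintf("RaschFit: %d items (%d excluded), latent N(0, %.3f)\n",
                length(object@difficulty), length(object@excludedItems),
                object@latentVar))
    cat(sprintf("  logLik %.2f after %d iterations (%sconverged)\n",
                object@logLik, object@iterations,
                if (object@converged) "" else "NOT "))
})

#' @rdname LatentRegressionFit-class
#' @export
setMethod("show", "LatentRegressionFit", function(object) {
    cat("LatentRegressionFit\n")
    cat("  coefficients: ",
        paste(sprintf("%s=%.3f", names(object@coefficients),
                      object@coefficients), collapse = ", "), "\n",
        sep = "")
    cat(sprintf("  residual variance: %.3f\n", object@residVar))
    cat(sprintf("  logLik %.2f after %d iterations (%sconverged)\n",
                object@logLik, object@iterations,
                if (object@converged) "" else "NOT "))
})

#' @rdname PlausibleValues-class
#' @export
setMethod("pvMatrix", "PlausibleValues", function(x) x@draws)

#' @rdname PlausibleValues-class
#' @export
setMethod("nSets", "PlausibleValues", function(x) nrow(x@draws))

#' @rdname PlausibleValues-class
#' @param object a \code{PlausibleValues}.
#' @export
setMethod("show", "PlausibleValues", function(object) {
    cat(sprintf("PlausibleValues: %d sets x %d persons\n",
                nrow(object@draws), ncol(object@draws)))
})

#' Export plausible values as delimited text
#'
#' One row per person: person id, optional covariates, then one column
#' per plausible value set (\code{PV1..PVM}) -- the layout expected by
#' downstream secondary analyses.
#'
#' @param pv a [PlausibleValues-class].
#' @param path output file path.
#' @param covariates optional data.frame of per-person columns to carry.
#' @return invisibly, \code{path}.
#' @export
writePlausibleValues <- function(pv, path, covariates = NULL) {
    draws <- t(pvMatrix(pv))
    colnames(draws) <- paste0("PV", seq_len(ncol(draws)))
    out <- data.frame(person = rownames(draws) %||%
                          sprintf("p%04d", seq_len(nrow(draws))))
    if (!is.null(covariates))
        out <- cbind(out, covariates)
    out <- cbind(out, draws)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
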