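## Shared fixtures built in code. defaultSigma("covariance") emits a
## repair message; cache both readings once.
SIGMA <- defaultSigma()
SIGMA_COV <- suppressMessages(defaultSigma("covariance"))

## A small condition for fast end-to-end runs.
smallCondition <- function(nPerGroup = 60, gap = 0.5, rgr = 0.15,
                           delta = 0, id = NA_integer_) {
    makeCondition(gap, rgr, delta, nPerGroup = nPerGroup, Sigma = SIGMA,
                  conditionId = id)
}

## Simulated responses from known persons, rapid guessing disabled.
cleanResponses <- function(n, gap = 0, seed = 1) {
    cond <- makeCondition(gap, 0, 0, nPerGroup = ceiling(n / 2),
                          Sigma = SIGMA)
    simulateConditionRaw <- getFromNamespace("simulateConditionRaw", "rgpv")
    simulateConditionRaw(cond, seed = seed)
}

## Independent marginal log-likelihood by fine trapezoid integration,
## used as the brute-force oracle for both fitters. Never calls the
## package's quadrature code.
oracleMarginalLL <- function(Y, xi, mean, sd, lo = -8, hi = 8,
                             nGrid = 481L) {
    gr <- seq(lo, hi, length.out = nGrid)
    d <- gr[2L] - gr[1L]
    lp <- sapply(xi, function(x) plogis(gr - x, log.p = TRUE))
    l1p <- sapply(xi, function(x) plogis(-(gr - x), log.p = TRUE))
    obs <- !is.na(Y)
    y1 <- ifelse(obs & Y == 1, 1, 0)
    y0 <- ifelse(obs & Y == 0, 1, 0)
    L <- y1 %*% t(lp) + y0 %*% t(l1p)
    w <- dnorm(gr, mean, sd) * d
    v <- exp(L) %*% w
    if (any(v <= 0) || any(!is.finite(v)))
        return(-1e10)
    sum(log(v))
}
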