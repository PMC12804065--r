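test_that("Rasch response probability is the logistic of the ability gap", {
    expect_equal(raschProb(0, 0), 0.5)
    expect_equal(raschProb(1, 0), 0.73106, tolerance = 1e-5)
    expect_equal(raschProb(0, 1), 0.26894, tolerance = 1e-5)
    expect_equal(raschProb(2, 0.5), plogis(1.5))
})

test_that("marginal ML Rasch estimation matches a brute-force oracle on a tiny set", {
    set.seed(7)
    theta <- rnorm(60, 0, 1)
    xi <- c(-0.8, 0.1, 0.9)
    Y <- matrix(rbinom(180, 1, plogis(outer(theta, xi, "-"))), 60, 3)
    fit <- fitRaschMML(Y, nQuad = 301, gridBounds = c(-8, 8),
                       tol = 1e-12, parTol = 1e-9, maxit = 5000)
    expect_true(converged(fit))
    ## independent oracle: trapezoid-integrated marginal likelihood
    ## maximized by BFGS over (difficulties, log latent SD)
    opt <- optim(c(0, 0, 0, 0), function(p)
        -oracleMarginalLL(Y, p[1:3], 0, exp(p[4])),
        method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
    llAtFit <- oracleMarginalLL(Y, difficulty(fit), 0,
                                sqrt(fit@latentVar))
    expect_lt(abs(-opt$value - llAtFit), 1e-4)
    expect_lt(max(abs(opt$par[1:3] - difficulty(fit))), 1e-3)
})

test_that("Rasch difficulties are recovered from engaged data at scale", {
    dat <- cleanResponses(2000, seed = 5)
    fit <- suppressWarnings(fitRaschMML(dat$Y))
    trueXi <- rep(c(-1, -0.5, 0, 0.5, 1), each = 4)
    ## difficulties are identified up to location (the latent mean is
    ## fixed at 0, so the estimates absorb the sample mean of ability);
    ## recovery is judged on the centred parameters
    est <- difficulty(fit) - mean(difficulty(fit))
    expect_lt(mean(abs(est - (trueXi - mean(trueXi)))), 0.07)
    ## the variance of a 20-item variance estimate is itself sizeable
    expect_equal(fit@latentVar, 1, tolerance = 0.15)
})

test_that("items with identical difficulty estimate near zero symmetrically", {
    set.seed(8)
    theta <- rnorm(2000)
    Y <- matrix(rbinom(2000 * 10, 1, plogis(theta)), 2000, 10)
    fit <- fitRaschMML(Y)
    expect_lt(max(abs(difficulty(fit))), 0.15)
})

test_that("EM log-likelihood is nondecreasing for both fitters", {
    cond <- smallCondition(nPerGroup = 150)
    dat <- getFromNamespace("simulateConditionRaw", "rgpv")(cond, seed = 3)
    fit <- fitRaschMML(dat$Y)
    expect_true(all(diff(logLikTrace(fit)) > -1e-8))
    X <- data.frame(group = as.integer(dat$persons$group == "2"))
    lr <- fitLatentRegression(dat$Y, difficulty(fit), X)
    expect_true(all(diff(logLikTrace(lr)) > -1e-8))
})

test_that("degenerate items are excluded with a warning", {
    set.seed(9)
    Y <- matrix(rbinom(300, 1, 0.5), 100, 3)
    Y[, 2] <- 1
    expect_warning(fit <- fitRaschMML(Y), "without response variation")
    expect_true(is.na(difficulty(fit)[2]))
    expect_equal(fit@excludedItems, 2L)
    expect_false(anyNA(difficulty(fit)[c(1, 3)]))
})

test_that("effort-moderated filtering recodes exactly the flagged cells", {
    Y <- matrix(rbinom(60, 1, 0.5), 6, 10)
    allOn <- matrix(1L, 6, 10)
    expect_equal(unname(applyEmmFilter(Y, allOn))[, ], Y,
                 ignore_attr = TRUE)
    ## one fully disengaged person
    flags <- allOn; flags[3, ] <- 0L
    filt <- applyEmmFilter(Y, flags)
    expect_true(all(is.na(filt[3, ])))
    expect_equal(filt[-3, ], Y[-3, ], ignore_attr = TRUE)
    ## conservation: k flags -> k newly missing cells
    set.seed(10)
    flagsK <- matrix(rbinom(60, 1, 0.7), 6, 10)
    filtK <- applyEmmFilter(Y, flagsK)
    expect_equal(sum(is.na(filtK)) - sum(is.na(Y)), sum(flagsK == 0))
    expect_equal(attr(filtK, "nRecoded"), sum(flagsK == 0))
})

test_that("latent regression matches a brute-force oracle on a tiny set", {
    set.seed(4)
    th <- rnorm(40, 0.3, 1.2)
    xiFixed <- c(-1, 1)
    Y <- matrix(rbinom(80, 1, plogis(outer(th, xiFixed, "-"))), 40, 2)
    lr <- fitLatentRegression(Y, xiFixed, NULL, nQuad = 301,
                              gridBounds = c(-8, 8), tol = 0,
                              parTol = 1e-9, maxit = 50000)
    opt <- optim(c(0, 0), function(p)
        -oracleMarginalLL(Y, xiFixed, p[1], exp(p[2])),
        method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = 1e-14))
    expect_lt(abs(coef(lr)[["intercept"]] - opt$par[1]), 1e-3)
    expect_lt(abs(lr@residVar - exp(opt$par[2])^2), 1e-3)
})

test_that("latent regression recovers the generating population", {
    ## intercept-only model on standard-normal abilities
    dat <- cleanResponses(5000, gap = 0, seed = 6)
    rasch <- fitRaschMML(dat$Y)
    lr <- fitLatentRegression(dat$Y, difficulty(rasch))
    expect_equal(coef(lr)[["intercept"]], 0, tolerance = 0.06)
    expect_equal(lr@residVar, 1, tolerance = 0.1)
    ## with no covariates the model coincides with the Rasch population fit
    expect_equal(lr@residVar, rasch@latentVar, tolerance = 0.02)

    ## collinear covariates are rejected by name
    X <- data.frame(a = rnorm(5000))
    X$b <- 2 * X$a
    expect_error(fitLatentRegression(dat$Y, difficulty(rasch), X),
                 "collinear.*b")
})

test_that("plausible values reproduce the person posteriors", {
    cond <- smallCondition(nPerGroup = 40, rgr = 0.1)
    dat <- getFromNamespace("simulateConditionRaw", "rgpv")(cond, seed = 12)
    Y <- dat$Y
    Y[1, ] <- NA  # flat likelihood: prior draws
    rasch <- fitRaschMML(Y)
    X <- data.frame(group = as.integer(dat$persons$group == "2"))
    lr <- fitLatentRegression(Y, difficulty(rasch), X)
    pv <- drawPlausibleValues(lr, Y, X, nPV = 4000, seed = 13)
    draws <- pvMatrix(pv)

    ## person with no data draws from the prior
    priorMean <- coef(lr)[["intercept"]] + coef(lr)[["group"]] * X$group[1]
    priorSD <- sqrt(lr@residVar)
    expect_equal(mean(draws[, 1]), priorMean,
                 tolerance = 4 * priorSD / sqrt(4000))
    expect_equal(sd(draws[, 1]), priorSD, tolerance = 0.05)

    ## ensemble mean and variance match the quadrature posterior
    post <- eapAbility(lr, Y, X)
    expect_equal(unname(colMeans(draws)), post$eap, tolerance = 0.08)
    ## per-person draw SD = posterior SD (plus lattice jitter)
    delta <- lr@nodes[2] - lr@nodes[1]
    expect_equal(unname(apply(draws, 2, sd)),
                 sqrt(post$sd^2 + delta^2 / 12), tolerance = 0.05)
    ## shrinkage correction: PVs spread wider than point estimates
    expect_gt(var(as.vector(draws[1:25, ])), var(post$eap))

    ## determinism
    pv2 <- drawPlausibleValues(lr, Y, X, nPV = 5, seed = 99)
    pv3 <- drawPlausibleValues(lr, Y, X, nPV = 5, seed = 99)
    expect_identical(pvMatrix(pv2), pvMatrix(pv3))
    expect_error(drawPlausibleValues(lr, Y, X, nPV = 1, seed = 1),
                 "at least 2")
})

test_that("standard errors come from the observed information", {
    dat <- cleanResponses(800, gap = 1, seed = 14)
    rasch <- fitRaschMML(dat$Y)
    X <- data.frame(group = as.integer(dat$persons$group == "2"))
    lr <- fitLatentRegression(dat$Y, difficulty(rasch), X,
                              computeSE = TRUE)
    V <- vcov(lr)
    expect_equal(dim(V), c(3L, 3L))
    se <- sqrt(diag(V))
    expect_true(all(is.finite(se)))
    ## group-mean contrast SE should be near the two-sample analytic value
    expect_equal(se[["group"]], sqrt(4 * 1.25 / 800), tolerance = 0.35)
    lrNoSE <- fitLatentRegression(dat$Y, difficulty(rasch), X)
    expect_error(vcov(lrNoSE), "computeSE")
})
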