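test_that("logit conversion of rapid-guessing rates is exact", {
    expect_equal(rgrToMuPhi(0.5), 0)
    expect_equal(rgrToMuPhi(0.05), 2.9444, tolerance = 1e-4)
    expect_equal(rgrToMuPhi(0.15), 1.7346, tolerance = 1e-4)
    expect_error(rgrToMuPhi(0), "strictly inside")
    expect_error(rgrToMuPhi(1), "strictly inside")
    expect_error(rgrToMuPhi(-0.1), "strictly inside")
})

test_that("population conversion hits the target response-level rate", {
    ## realized rate = E[1 - expit(phi)] computed by direct integration
    for (r in c(0.025, 0.15)) {
        mu <- muPhiForRate(r, phiVar = 1.7)
        realized <- integrate(function(x) plogis(-x) * dnorm(x, mu, sqrt(1.7)),
                              -30, 30)$value
        expect_equal(realized, r, tolerance = 1e-6)
        ## location conversion underestimates mu for the same rate
        expect_gt(mu, muPhiForRate(r, conversion = "location"))
    }
    expect_equal(muPhiForRate(0.05, conversion = "location"),
                 qlogis(0.95))
})

test_that("design-cell factors map onto group parameters", {
    c1 <- makeCondition(0.5, 0.05, -0.05, nPerGroup = 1000,
                        Sigma = SIGMA, conditionId = 1)
    expect_equal(c1@muTheta, c(-0.25, 0.25))
    expect_equal(c1@rgr, c(0.075, 0.025))
    expect_equal(c1@trueD, 0.5)

    c12 <- makeCondition(1.0, 0.15, 0.05, nPerGroup = 1000,
                         Sigma = SIGMA, conditionId = 12)
    expect_equal(c12@muTheta, c(-0.5, 0.5))
    expect_equal(c12@rgr, c(0.125, 0.175))

    sym <- makeCondition(0.5, 0.15, 0, nPerGroup = 10, Sigma = SIGMA)
    expect_equal(sym@rgr, c(0.15, 0.15))
    expect_equal(sym@nPerGroup, c(10L, 10L))

    expect_error(makeCondition(0.5, 0.02, -0.05, Sigma = SIGMA),
                 "rapid-guessing rates")

    conds <- tableConditions(nPerGroup = 5, Sigma = SIGMA)
    expect_length(conds, 12L)
    expect_equal(conds[["condition12"]]@rgr, c(0.125, 0.175))
    expect_equal(conds[["condition1"]]@muTheta, c(-0.25, 0.25))
})

test_that("default person covariance is positive definite with the stated entries", {
    expect_equal(SIGMA[1, 1], 1.70)
    expect_equal(SIGMA[2, 2], 1.00)
    expect_equal(SIGMA[3, 3], 0.05)
    ## off-diagonals are correlations scaled by the variances
    expect_equal(SIGMA[1, 2] / sqrt(1.7), 0.35)
    expect_equal(SIGMA[2, 3] / sqrt(0.05), -0.20)
    expect_gt(min(eigen(SIGMA, symmetric = TRUE)$values), 0)

    ## covariance reading: indefinite as printed, repaired deterministically
    expect_gt(min(eigen(SIGMA_COV, symmetric = TRUE)$values), 0)
    expect_equal(SIGMA_COV[1, 2], 0.35)
    expect_gt(SIGMA_COV[2, 3], -0.20)   # moved toward zero
    ## repair leaves a PD matrix untouched
    expect_identical(repairSigma(SIGMA), SIGMA)
    bad <- SIGMA_COV; bad[2, 3] <- bad[3, 2] <- -0.20
    expect_error(makeCondition(0.5, 0.05, Sigma = bad, repair = FALSE),
                 "positive definite")
})

test_that("person draws follow the condition's group distributions", {
    ## degenerate covariance: everyone sits at the group mean vector
    eps <- diag(3) * 1e-12
    cond <- makeCondition(1.0, 0.05, 0, nPerGroup = 20, Sigma = eps,
                          repair = FALSE)
    p <- drawPersons(cond, seed = 1)
    expect_equal(nrow(p), 40L)
    for (g in 1:2) {
        pg <- p[p$group == g, ]
        expect_equal(unname(colMeans(pg[, c("phi", "theta", "tau")])),
                     c(cond@muPhi[g], cond@muTheta[g], 0),
                     tolerance = 1e-5)
        expect_lt(max(apply(pg[, c("phi", "theta", "tau")], 2, sd)), 1e-5)
    }

    ## determinism
    cond2 <- smallCondition()
    expect_identical(drawPersons(cond2, seed = 7),
                     drawPersons(cond2, seed = 7))

    ## law of large numbers: sample covariance approaches Sigma
    big <- makeCondition(0.5, 0.05, 0, nPerGroup = 25000, Sigma = SIGMA)
    pb <- drawPersons(big, seed = 3)
    g1 <- pb[pb$group == 1, c("phi", "theta", "tau")]
    Chat <- cov(g1)
    n <- nrow(g1)
    for (i in 1:3) for (j in 1:3) {
        se <- sqrt((SIGMA[i, j]^2 + SIGMA[i, i] * SIGMA[j, j]) / n)
        expect_lt(abs(Chat[i, j] - SIGMA[i, j]), 3 * se + 1e-12)
    }
})

test_that("response model matches the two-class generating distributions", {
    bank <- defaultItemBank()
    ## saturated engagement: all solution behaviour
    pSat <- data.frame(group = factor(rep(1:2, each = 25)),
                       phi = 20, theta = 0, tau = 0)
    reSat <- simulateResponses(pSat, bank, seed = 1)
    expect_true(all(engagementMatrix(reSat) == 1))

    ## forced rapid guessing: chance-level correctness, fast lognormal times
    nRG <- 6000
    pRG <- data.frame(group = factor(rep(1:2, each = nRG / 2)),
                      phi = -20, theta = rnorm(nRG), tau = 0)
    reRG <- simulateResponses(pRG, bank, seed = 2)
    E <- engagementMatrix(reRG)
    expect_true(all(E == 0))
    Y <- responseMatrix(reRG)
    nCells <- length(Y)
    expect_equal(mean(Y), 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / nCells))
    lt <- log(timeMatrix(reRG))
    expect_equal(mean(lt), 1.25, tolerance = 3 * 0.6 / sqrt(nCells))
    expect_equal(sd(lt), 0.60, tolerance = 0.01)
    ## guesses carry no ability information
    thetaMat <- matrix(pRG$theta, nRG, nItems(bank))
    expect_lt(abs(cor(as.vector(Y), as.vector(thetaMat))), 0.02)

    ## Rasch at matched difficulty: 50% correct
    pSB <- data.frame(group = factor(rep(1:2, each = 2500)),
                      phi = 20, theta = 0.5, tau = 0.2)
    bank1 <- ItemBank(difficulty = rep(0.5, 8), timeIntensity = rep(3.3, 8))
    reSB <- simulateResponses(pSB, bank1, seed = 3)
    expect_equal(mean(responseMatrix(reSB)), 0.5, tolerance = 0.01)
    ## solution-behaviour times: mean log time is intensity minus speed
    expect_equal(mean(log(timeMatrix(reSB))), 3.3 - 0.2, tolerance = 0.01)

    ## determinism of the full generator
    cond <- smallCondition()
    re1 <- simulateCondition(cond, seed = 11)
    re2 <- simulateCondition(cond, seed = 11)
    expect_identical(responseMatrix(re1), responseMatrix(re2))
    expect_identical(timeMatrix(re1), timeMatrix(re2))
})

test_that("realized rapid-guessing share decreases in the engagement mean", {
    bank <- defaultItemBank()
    shares <- sapply(c(-1, 0, 1, 2, 3), function(mu) {
        p <- data.frame(group = factor(rep(1:2, each = 1000)),
                        phi = rnorm(2000, mu, sqrt(1.7)),
                        theta = 0, tau = 0)
        mean(engagementMatrix(simulateResponses(p, bank, seed = 5)) == 0)
    })
    expect_true(all(diff(shares) < 0))
})

test_that("datasets round-trip through the delimited-text interface", {
    cond <- smallCondition(nPerGroup = 15)
    re <- simulateCondition(cond, seed = 4)
    dir <- withr::local_tempdir()
    writeResponseData(re, dir, prefix = "sim")
    back <- readResponseData(dir, prefix = "sim")
    expect_equal(responseMatrix(back), responseMatrix(re))
    expect_equal(timeMatrix(back), timeMatrix(re), tolerance = 1e-8)
    expect_equal(engagementMatrix(back), engagementMatrix(re))
    expect_equal(as.character(groupLabels(back)),
                 as.character(groupLabels(re)))
})

test_that("conditions load from a structured config file", {
    path <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c(
        "cellTwelve:",
        "  id: 12",
        "  nPerGroup: 25",
        "custom:",
        "  abilityGap: 0.8",
        "  overallRGR: 0.10",
        "  rgrDelta: 0.02",
        "  difficulty: [-1, 0, 1]",
        "  timeIntensity: [3.0, 3.3, 3.6]"), path)
    conds <- readConditionConfig(path)
    expect_named(conds, c("cellTwelve", "custom"))
    expect_equal(conds$cellTwelve@rgr, c(0.125, 0.175))
    expect_equal(conds$cellTwelve@nPerGroup, c(25L, 25L))
    expect_equal(conds$custom@trueD, 0.8)
    expect_equal(nItems(conds$custom@bank), 3L)
})
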