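test_that("fixed common-k thresholds apply one cutoff to every item", {
    thr <- fixedThresholds(20, k = 5)
    expect_length(thresholds(thr), 20L)
    expect_true(all(thresholds(thr) == 5))
    expect_equal(unname(thresholds(fixedThresholds(1, k = 3))), 3)
    expect_error(fixedThresholds(20, k = 0), "positive")
    expect_error(fixedThresholds(20, k = -1), "positive")
})

test_that("engagement flagging uses a strict inequality at the threshold", {
    thr <- fixedThresholds(3, k = 5)
    f <- flagEngagement(matrix(c(4.9, 5.0, 30), 1), thr)
    expect_equal(as.vector(f), c(0L, 1L, 1L))
    expect_error(flagEngagement(matrix(c(-1, 2, 3), 1), thr),
                 "strictly positive")
    ## missing times give missing flags
    fNA <- flagEngagement(matrix(c(NA, 6, 2), 1), thr)
    expect_equal(as.vector(fNA), c(NA_integer_, 1L, 0L))
})

test_that("raising thresholds can only turn engaged flags into guesses", {
    set.seed(42)
    times <- matrix(exp(rnorm(600, 2, 1)), 60, 10)
    f1 <- flagEngagement(times, fixedThresholds(10, k = 4))
    f2 <- flagEngagement(times, fixedThresholds(10, k = 7))
    expect_true(all(f2 <= f1))
    ## idempotent / deterministic
    expect_identical(f1, flagEngagement(times, fixedThresholds(10, k = 4)))
})

test_that("antimode thresholds find the density minimum between the two modes", {
    ## two-class lognormal mixture with a known analytic antimode
    mixDensity <- function(t)
        0.15 * dlnorm(t, 1.25, 0.6) + 0.85 * dlnorm(t, 3.3, 0.3)
    grid <- seq(5, 15, by = 0.001)
    analyticAntimode <- grid[which.min(mixDensity(grid))]
    set.seed(9)
    n <- 40000
    rg <- runif(n) < 0.15
    tt <- exp(rnorm(n, ifelse(rg, 1.25, 3.3), ifelse(rg, 0.6, 0.3)))
    thr <- visualThresholds(matrix(tt, ncol = 1), window = c(5, 15))
    expect_lt(abs(unname(thresholds(thr)[1]) - analyticAntimode), 1)
    expect_equal(thr@method, "visual")

    ## strictly increasing density on the window: minimum at the boundary
    set.seed(10)
    slow <- matrix(exp(rnorm(20000, 3.5, 0.3)), ncol = 1)
    thrSlow <- visualThresholds(slow, window = c(5, 15))
    expect_equal(unname(thresholds(thrSlow)[1]), 5, tolerance = 0.02)

    ## pooled items share one threshold
    set.seed(11)
    tm <- matrix(exp(rnorm(4000, 3.3, 0.3)), 1000, 4)
    thrP <- visualThresholds(tm, pooling = c("a", "a", "b", "b"))
    v <- thresholds(thrP)
    expect_equal(v[[1]], v[[2]])
    expect_equal(v[[3]], v[[4]])
})

test_that("condition-level antimode thresholds fall in the reported range", {
    ## one 5%-RG and one 15%-RG condition; thresholds by item parameter set
    for (cond in list(makeCondition(0.5, 0.05, -0.05, Sigma = SIGMA),
                      makeCondition(1.0, 0.15, 0.05, Sigma = SIGMA))) {
        thr <- conditionVisualThresholds(cond, seed = 21)
        v <- thresholds(thr)
        expect_length(unique(v), 5L)    # five (difficulty, intensity) pools
        expect_true(all(v >= 5 & v <= 14))
        ## the slowest item pool gets a clearly higher cutoff than the
        ## fastest (pool-level antimodes shift right with intensity)
        byPool <- tapply(v, thr@pooling, unique)
        beta <- tapply(timeIntensity(cond@bank), thr@pooling, unique)
        ord <- order(beta)
        expect_gt(byPool[ord[5]], byPool[ord[1]])
    }
})

test_that("response time effort summarises flags and dichotomizes at 0.9", {
    rte <- responseTimeEffort(matrix(rep(1, 20), 1))
    expect_equal(rte$rte, 1)
    expect_equal(rte$rteStar, 1L)
    ## exactly 0.9 counts as disengaged
    rte18 <- responseTimeEffort(matrix(c(rep(1, 18), 0, 0), 1))
    expect_equal(rte18$rte, 0.9)
    expect_equal(rte18$rteStar, 0L)
    rte19 <- responseTimeEffort(matrix(c(rep(1, 19), 0), 1))
    expect_equal(rte19$rte, 0.95)
    expect_equal(rte19$rteStar, 1L)
    ## missing flags drop out of numerator and denominator
    rteNA <- responseTimeEffort(matrix(c(1, 0, NA, NA), 1))
    expect_equal(rteNA$rte, 0.5)
    expect_equal(rteNA$nScorable, 2)
    ## person with nothing scorable is flagged missing
    rte0 <- responseTimeEffort(matrix(NA_integer_, 1, 4))
    expect_true(is.na(rte0$rte))
    ## item order is irrelevant
    f <- matrix(rbinom(40, 1, 0.8), 2, 20)
    expect_equal(responseTimeEffort(f)$rte,
                 responseTimeEffort(f[, 20:1])$rte)
})

test_that("classification diagnostics recover confusion-matrix rates", {
    truth <- matrix(rep(c(1, 0), c(6, 2)), 2, 4)
    d <- classificationDiagnostics(truth, truth)
    expect_equal(d$response$agreement, 1)
    expect_equal(d$response$sensitivity, 1)
    expect_equal(d$response$specificity, 1)

    ## 2x2 counts TP=90 FN=10 TN=70 FP=30
    tru <- matrix(rep(c(1, 0), c(100, 100)), 10, 20)
    est <- tru
    est[which(tru == 1)[1:10]] <- 0
    est[which(tru == 0)[1:30]] <- 1
    d2 <- classificationDiagnostics(est, tru)
    expect_equal(d2$response$sensitivity, 0.90)
    expect_equal(d2$response$specificity, 0.70)
    expect_equal(d2$response$agreement, 0.80)

    ## agreement identity holds to machine precision
    set.seed(13)
    tru3 <- matrix(rbinom(400, 1, 0.8), 20, 20)
    est3 <- matrix(rbinom(400, 1, 0.8), 20, 20)
    d3 <- classificationDiagnostics(est3, tru3)$response
    pE1 <- mean(tru3 == 1)
    expect_equal(d3$agreement,
                 d3$sensitivity * pE1 + d3$specificity * (1 - pE1))

    ## person level: RTE* scored against true RTE* (rates high enough
    ## that both engaged and disengaged persons occur)
    set.seed(14)
    tru5 <- matrix(rbinom(2000, 1, 0.96), 100, 20)
    est5 <- tru5; est5[sample(2000, 60)] <- 0L
    rte <- responseTimeEffort(est5)
    d4 <- classificationDiagnostics(est5, tru5, rte = rte)
    expect_true(all(unlist(d4$person[1:3]) >= 0 &
                    unlist(d4$person[1:3]) <= 1))
    expect_error(classificationDiagnostics(est3, NULL), "simulation-only")
})

test_that("thresholds round-trip through the two-column text format", {
    cond <- smallCondition()
    thr <- conditionVisualThresholds(cond, seed = 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeThresholds(thr, path)
    back <- readThresholds(path)
    expect_equal(thresholds(back), thresholds(thr), tolerance = 1e-12)
    expect_equal(back@method, "visual")
})
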