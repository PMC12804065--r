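#' Cohen's d with sampling variance
#'
#' Standardized mean difference (group 2 minus group 1) using the pooled
#' standard deviation with \code{n_g - 1} weights. The sampling variance
#' is the large-sample form
#' \code{(n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))}.
#'
#' @param values numeric vector (e.g. one plausible value set).
#' @param groups factor with two levels aligned with \code{values}.
#' @return list with elements \code{d} and \code{var}.
#' @examples
#' cohensD(c(0, 0, 1, 1, 1, 1, 2, 2), rep(c("1", "2"), each = 4))
#' @export
cohensD <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("'groups' must have exactly two levels")
    v1 <- values[groups == levels(groups)[1L]]
    v2 <- values[groups == levels(groups)[2L]]
    n1 <- length(v1); n2 <- length(v2)
    if (n1 < 2L || n2 < 2L)
        stop("both groups need at least two observations")
    sp2 <- ((n1 - 1) * var(v1) + (n2 - 1) * var(v2)) / (n1 + n2 - 2)
    if (sp2 <= 0)
        stop("pooled standard deviation is zero; d undefined")
    d <- (mean(v2) - mean(v1)) / sqrt(sp2)
    list(d = d,
         var = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
}

#' Group means and standard deviations with sampling variances
#'
#' Sample mean (variance \code{s^2/n}) and sample SD with its
#' large-sample variance \code{s^2 / (2 (n - 1))} for each group.
#'
#' @param values numeric vector.
#' @param groups factor with two levels.
#' @return data.frame with one row per group: \code{group}, \code{n},
#'   \code{mean}, \code{meanVar}, \code{sd}, \code{sdVar}.
#' @examples
#' groupMoments(1:10, rep(c("1", "2"), each = 5))
#' @export
groupMoments <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("'groups' must have exactly two levels")
    rows <- lapply(levels(groups), function(g) {
        v <- values[groups == g]
        n <- length(v)
        if (n < 2L)
            stop("group '", g, "' has fewer than two observations")
        s2 <- var(v)
        data.frame(group = g, n = n, mean = mean(v), meanVar = s2 / n,
                   sd = sqrt(s2), sdVar = s2 / (2 * (n - 1)))
    })
    do.call(rbind, rows)
}

#' Pool estimates across plausible value sets by Rubin's rules
#'
#' Point estimate: mean over the M sets. Within-imputation variance W:
#' mean of the per-set sampling variances. Between-imputation variance
#' B: sample variance (M - 1 denominator) of the per-set estimates.
#' Total variance T = W + (1 + 1/M) B. The 95 percent interval uses
#' normal quantiles on sqrt(T) by default; \code{smallSample = TRUE}
#' switches to the t interval with the classical multiple-imputation
#' degrees of freedom \code{(M - 1) (1 + W / ((1 + 1/M) B))^2}.
#'
#' @param estimates per-set point estimates (length M >= 2).
#' @param variances per-set sampling variances.
#' @param level confidence level.
#' @param smallSample use t quantiles with imputation df.
#' @return list with \code{estimate}, \code{W}, \code{B}, \code{T},
#'   \code{ciLower}, \code{ciUpper}, \code{M}.
#' @examples
#' rubinPool(c(1, 2), c(0.5, 0.5))
#' @export
rubinPool <- function(estimates, variances, level = 0.95,
                      smallSample = FALSE) {
    M <- length(estimates)
    if (M < 2L)
        stop("Rubin pooling requires at least 2 sets")
    if (length(variances) != M)
        stop("'variances' must match 'estimates' in length")
    if (any(variances < 0))
        stop("sampling variances must be nonnegative")
    point <- mean(estimates)
    W <- mean(variances)
    B <- var(estimates)
    Tvar <- W + (1 + 1 / M) * B
    alpha <- 1 - level
    q <- if (smallSample && B > 0) {
        df <- (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
        qt(1 - alpha / 2, df)
    } else {
        qnorm(1 - alpha / 2)
    }
    list(estimate = point, W = W, B = B, T = Tvar,
         ciLower = point - q * sqrt(Tvar),
         ciUpper = point + q * sqrt(Tvar), M = M)
}

#' Per-set estimands for a plausible value ensemble
#'
#' Computes Cohen's d, group means and group SDs (with their sampling
#' variances) for every plausible value set, then pools each estimand
#' with [rubinPool()].
#'
#' @param pv a [PlausibleValues-class] or sets x persons matrix.
#' @param groups factor with two levels, one entry per person.
#' @param smallSample passed to [rubinPool()].
#' @return data.frame with one row per estimand (\code{d}, \code{mu1},
#'   \code{mu2}, \code{sd1}, \code{sd2}): pooled estimate, W, B, T and
#'   interval bounds.
#' @examples
#' pv <- matrix(rnorm(200), 4)
#' pooledEstimands(pv, rep(c("1", "2"), each = 25))
#' @export
pooledEstimands <- function(pv, groups, smallSample = FALSE) {
    draws <- if (is(pv, "PlausibleValues")) pvMatrix(pv) else as.matrix(pv)
    groups <- factor(groups)
    if (nlevels(groups) != 2L)
        stop("'groups' must have exactly two levels")
    i1 <- groups == levels(groups)[1L]
    i2 <- !i1
    n1 <- sum(i1); n2 <- sum(i2)
    X1 <- draws[, i1, drop = FALSE]
    X2 <- draws[, i2, drop = FALSE]
    m1 <- rowMeans(X1); m2 <- rowMeans(X2)
    v1 <- (rowSums(X1^2) - n1 * m1^2) / (n1 - 1)
    v2 <- (rowSums(X2^2) - n2 * m2^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (any(sp2 <= 0))
        stop("pooled standard deviation is zero in a plausible value set")
    d <- (m2 - m1) / sqrt(sp2)
    est <- rbind(d = d, mu1 = m1, mu2 = m2,
                 sd1 = sqrt(v1), sd2 = sqrt(v2))
    vars <- rbind(d = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)),
                  mu1 = v1 / n1, mu2 = v2 / n2,
                  sd1 = v1 / (2 * (n1 - 1)), sd2 = v2 / (2 * (n2 - 1)))
    rows <- lapply(rownames(est), function(nm) {
        pooled <- rubinPool(est[nm, ], vars[nm, ],
                            smallSample = smallSample)
        data.frame(estimand = nm, estimate = pooled$estimate,
                   W = pooled$W, B = pooled$B, T = pooled$T,
                   ciLower = pooled$ciLower, ciUpper = pooled$ciUpper)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
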