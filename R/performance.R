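#' Monte Carlo performance measures for one estimator
#'
#' Computes bias, empirical SE, MSE and coverage with their Monte Carlo
#' standard errors (MCSEs) over converged replications:
#' bias = mean(est) - true, MCSE empSE/sqrt(nSim);
#' empSE = SD of est, MCSE empSE/sqrt(2 (nSim - 1));
#' MSE = mean((est - true)^2), MCSE sqrt(var((est - true)^2)/nSim);
#' coverage = proportion of intervals containing the truth, MCSE
#' sqrt(cov (1 - cov)/nSim).
#'
#' @param estimates per-replication pooled point estimates (converged
#'   replications only).
#' @param trueValue the estimand's true value.
#' @param ciLower,ciUpper per-replication interval bounds (optional; if
#'   absent coverage is NA).
#' @param nTotal total replications attempted, for the convergence rate
#'   (defaults to \code{length(estimates)}).
#' @return one-row data.frame with \code{nSim}, \code{convergenceRate},
#'   \code{bias}, \code{biasMCSE}, \code{empSE}, \code{empSEMCSE},
#'   \code{mse}, \code{mseMCSE}, \code{coverage}, \code{coverageMCSE}.
#' @examples
#' performanceSummary(c(0.9, 1.1), trueValue = 1)
#' @export
performanceSummary <- function(estimates, trueValue, ciLower = NULL,
                               ciUpper = NULL, nTotal = length(estimates)) {
    estimates <- estimates[!is.na(estimates)]
    nSim <- length(estimates)
    if (nSim < 2L)
        stop("at least 2 converged replications are required")
    err <- estimates - trueValue
    bias <- mean(err)
    empSE <- sd(estimates)
    mse <- mean(err^2)
    if (!is.null(ciLower)) {
        ok <- !is.na(ciLower) & !is.na(ciUpper)
        cover <- mean(ciLower[ok] <= trueValue & trueValue <= ciUpper[ok])
        coverMCSE <- sqrt(cover * (1 - cover) / sum(ok))
    } else {
        cover <- NA_real_
        coverMCSE <- NA_real_
    }
    data.frame(
        nSim = nSim,
        convergenceRate = nSim / nTotal,
        bias = bias,
        biasMCSE = empSE / sqrt(nSim),
        empSE = empSE,
        empSEMCSE = empSE / sqrt(2 * (nSim - 1)),
        mse = mse,
        mseMCSE = sqrt(var(err^2) / nSim),
        coverage = cover,
        coverageMCSE = coverMCSE)
}

#' Aggregate replication results into a performance table
#'
#' Takes the long per-replication table produced by [runReplication()] /
#' [runStudy()] (one row per replication x model x estimand) and returns
#' one row of performance measures per (condition, model, estimand).
#' Non-converged replications are excluded from the measures but counted
#' in the convergence rate.
#'
#' @param results data.frame with columns \code{condition}, \code{model},
#'   \code{estimand}, \code{replication}, \code{estimate},
#'   \code{ciLower}, \code{ciUpper}, \code{converged}.
#' @param trueValues data.frame with columns \code{condition},
#'   \code{estimand}, \code{trueValue}.
#' @return data.frame of performance rows.
#' @export
performanceTable <- function(results, trueValues) {
    keys <- unique(results[, c("condition", "model", "estimand")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
        sel <- results$condition == keys$condition[i] &
            results$model == keys$model[i] &
            results$estimand == keys$estimand[i]
        sub <- results[sel, ]
        tv <- trueValues$trueValue[
            trueValues$condition == keys$condition[i] &
            trueValues$estimand == keys$estimand[i]]
        if (length(tv) != 1L)
            stop("no unique true value for condition ", keys$condition[i],
                 ", estimand ", keys$estimand[i])
        ok <- sub$converged & !is.na(sub$estimate)
        perf <- performanceSummary(sub$estimate[ok], tv,
                                   ciLower = sub$ciLower[ok],
                                   ciUpper = sub$ciUpper[ok],
                                   nTotal = nrow(sub))
        cbind(keys[i, , drop = FALSE], trueValue = tv, perf,
              row.names = NULL)
    })
    do.call(rbind, rows)
}

#' Format a performance table in the conventional report layout
#'
#' Rows are conditions, columns the model x threshold variants, cells
#' \code{"measure (MCSE)"} -- the layout used to report absolute bias
#' and empirical SE per condition.
#'
#' @param perf data.frame from [performanceTable()].
#' @param measure \code{"bias"}, \code{"empSE"}, \code{"mse"} or
#'   \code{"coverage"}.
#' @param estimand which estimand to tabulate (default \code{"d"}).
#' @param digits digits for the point measure.
#' @return a character matrix (conditions x models).
#' @export
formatPerformanceTable <- function(perf, measure = c("bias", "empSE",
                                                     "mse", "coverage"),
                                   estimand = "d", digits = 3L) {
    measure <- match.arg(measure)
    mcseCol <- paste0(measure, "MCSE")
    perf <- perf[perf$estimand == estimand, ]
    conditions <- sort(unique(perf$condition))
    models <- unique(perf$model)
    out <- matrix("", length(conditions), length(models),
                  dimnames = list(paste("condition", conditions), models))
    for (i in seq_along(conditions)) {
        for (j in seq_along(models)) {
            row <- perf[perf$condition == conditions[i] &
                        perf$model == models[j], ]
            if (nrow(row) == 1L)
                out[i, j] <- sprintf(
                    paste0("%.", digits, "f (%.", digits, "f)"),
                    row[[measure]], row[[mcseCol]])
        }
    }
    out
}
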