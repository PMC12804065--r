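#' Item bank for the two-class response model
#'
#' Holds the item parameters of the generating model: Rasch difficulties
#' and lognormal time intensities under solution behaviour (SB), and the
#' chance success probability and lognormal time parameters under rapid
#' guessing (RG).
#'
#' @slot difficulty numeric, Rasch difficulty per item (logits).
#' @slot timeIntensity numeric, SB log-time mean per item (log-seconds).
#' @slot sbLogSD numeric(1), SB log-time standard deviation.
#' @slot guessProb numeric, RG success probability per item.
#' @slot rgLogMean numeric(1), RG log-time mean (log-seconds).
#' @slot rgLogSD numeric(1), RG log-time standard deviation.
#'
#' @seealso [ItemBank()], [defaultItemBank()]
#' @name ItemBank-class
#' @aliases ItemBank-class
#' @exportClass ItemBank
setClass("ItemBank",
    representation(
        difficulty = "numeric",
        timeIntensity = "numeric",
        sbLogSD = "numeric",
        guessProb = "numeric",
        rgLogMean = "numeric",
        rgLogSD = "numeric"
    )
)

setValidity("ItemBank", function(object) {
    msg <- character()
    J <- length(object@difficulty)
    if (J < 1L)
        msg <- c(msg, "item bank must contain at least one item")
    if (length(object@timeIntensity) != J)
        msg <- c(msg, "difficulty and timeIntensity lengths differ")
    if (length(object@guessProb) != J)
        msg <- c(msg, "guessProb must have one entry per item")
    if (any(!is.finite(object@difficulty)) ||
        any(!is.finite(object@timeIntensity)))
        msg <- c(msg, "item parameters must be finite")
    if (length(object@sbLogSD) != 1L || object@sbLogSD <= 0)
        msg <- c(msg, "sbLogSD must be a single positive number")
    if (length(object@rgLogSD) != 1L || object@rgLogSD <= 0)
        msg <- c(msg, "rgLogSD must be a single positive number")
    if (length(object@rgLogMean) != 1L || !is.finite(object@rgLogMean))
        msg <- c(msg, "rgLogMean must be a single finite number")
    if (any(object@guessProb <= 0) || any(object@guessProb >= 1))
        msg <- c(msg, "guessProb must lie strictly inside (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Simulation condition: one cell of the study design
#'
#' Describes one condition of the two-group simulation: group means of
#' ability and engagement (the latter converted from the nominal rapid
#' guessing rate), the shared person covariance, the per-group sample
#' size, the item bank, and the true values of the estimands.
#'
#' @slot conditionId integer(1), design cell id (NA for ad-hoc conditions).
#' @slot nPerGroup integer(2), persons per group.
#' @slot muTheta numeric(2), group ability means (logits).
#' @slot rgr numeric(2), nominal group rapid-guessing rates.
#' @slot muPhi numeric(2), group engagement means (logits).
#' @slot muTau numeric(1), speed mean (shared by both groups).
#' @slot Sigma 3x3 covariance of (engagement, ability, speed).
#' @slot bank the [ItemBank-class].
#' @slot trueD numeric(1), true standardized group difference.
#' @slot trueMu numeric(2), true group ability means.
#' @slot trueSD numeric(2), true group ability standard deviations.
#'
#' @seealso [makeCondition()], [tableConditions()]
#' @name SimulationCondition-class
#' @aliases SimulationCondition-class
#' @exportClass SimulationCondition
setClass("SimulationCondition",
    representation(
        conditionId = "integer",
        nPerGroup = "integer",
        muTheta = "numeric",
        rgr = "numeric",
        muPhi = "numeric",
        muTau = "numeric",
        Sigma = "matrix",
        bank = "ItemBank",
        trueD = "numeric",
        trueMu = "numeric",
        trueSD = "numeric"
    )
)

setValidity("SimulationCondition", function(object) {
    msg <- character()
    if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 1L))
        msg <- c(msg, "nPerGroup must give a positive size for both groups")
    for (nm in c("muTheta", "rgr", "muPhi", "trueMu", "trueSD"))
        if (length(slot(object, nm)) != 2L)
            msg <- c(msg, sprintf("%s must have one entry per group", nm))
    if (any(object@rgr < 0) || any(object@rgr >= 1))
        msg <- c(msg, "rapid guessing rates must lie in [0, 1)")
    S <- object@Sigma
    if (!is.matrix(S) || !identical(dim(S), c(3L, 3L)))
        msg <- c(msg, "Sigma must be a 3x3 matrix")
    else {
        if (max(abs(S - t(S))) > 1e-8)
            msg <- c(msg, "Sigma must be symmetric")
        else if (min(eigen(S, symmetric = TRUE,
                           only.values = TRUE)$values) <= 0)
            msg <- c(msg, "Sigma must be positive definite")
    }
    if (length(msg)) msg else TRUE
})

#' Container for responses, response times and engagement
#'
#' A [SummarizedExperiment::SummarizedExperiment] with items as rows and
#' persons as columns. Assays: \code{"responses"} (0/1/NA), \code{"times"}
#' (seconds, > 0 where observed) and, for simulated data, the latent
#' \code{"engagement"} class indicator (1 = solution behaviour, 0 = rapid
#' guess). \code{colData} carries at least the \code{group} factor and,
#' for simulated data, the person parameters \code{phi}, \code{theta},
#' \code{tau}; \code{rowData} carries the item bank columns.
#'
#' Matrix accessors return persons x items matrices, the orientation used
#' throughout the estimation functions.
#'
#' @seealso [ResponseExperiment()], [simulateResponses()]
#' @name ResponseExperiment-class
#' @aliases ResponseExperiment-class
#' @exportClass ResponseExperiment
setClass("ResponseExperiment", contains = "SummarizedExperiment")

setValidity("ResponseExperiment", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("responses", "times") %in% an))
        msg <- c(msg, "assays must include 'responses' and 'times'")
    else {
        y <- assay(object, "responses")
        tt <- assay(object, "times")
        if (!all(y %in% c(0, 1) | is.na(y)))
            msg <- c(msg, "responses must be 0, 1 or NA")
        if (any(tt <= 0, na.rm = TRUE))
            msg <- c(msg, "response times must be strictly positive")
        if ("engagement" %in% an) {
            e <- assay(object, "engagement")
            if (!all(e %in% c(0, 1) | is.na(e)))
                msg <- c(msg, "engagement must be 0, 1 or NA")
        }
    }
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
})

#' Response-time thresholds
#'
#' Per-item response-time cutoffs below which a response is flagged as a
#' rapid guess, together with the method that produced them.
#'
#' @slot thresholds named numeric, cutoff per item (seconds).
#' @slot method \code{"fixed"} (common-k) or \code{"visual"} (antimode).
#' @slot window numeric(2), search window in seconds (antimode method).
#' @slot pooling character, pooling key per item (items sharing a key
#'   share a threshold); empty for per-item thresholds.
#'
#' @seealso [fixedThresholds()], [visualThresholds()]
#' @name ThresholdSet-class
#' @aliases ThresholdSet-class
#' @exportClass ThresholdSet
setClass("ThresholdSet",
    representation(
        thresholds = "numeric",
        method = "character",
        window = "numeric",
        pooling = "character"
    )
)

setValidity("ThresholdSet", function(object) {
    msg <- character()
    if (any(object@thresholds <= 0))
        msg <- c(msg, "thresholds must be strictly positive")
    if (length(object@method) != 1L ||
        !object@method %in% c("fixed", "visual"))
        msg <- c(msg, "method must be 'fixed' or 'visual'")
    if (length(object@pooling) &&
        length(object@pooling) != length(object@thresholds))
        msg <- c(msg, "pooling must be empty or one key per item")
    if (length(msg)) msg else TRUE
})

#' Rasch fit by marginal maximum likelihood
#'
#' Result of [fitRaschMML()]: item difficulties estimated by EM over a
#' fixed quadrature grid with a normal latent population (mean fixed at 0
#' for identification, variance estimated).
#'
#' @slot difficulty numeric, estimated difficulty per item (NA for items
#'   excluded for lack of response variation).
#' @slot latentMean numeric(1), fixed at 0.
#' @slot latentVar numeric(1), estimated latent variance.
#' @slot logLik numeric(1), final marginal log-likelihood.
#' @slot logLikTrace numeric, per-iteration marginal log-likelihood.
#' @slot converged logical(1).
#' @slot iterations integer(1).
#' @slot excludedItems integer, column indices excluded from estimation.
#' @slot nodes numeric, quadrature grid.
#'
#' @name RaschFit-class
#' @aliases RaschFit-class
#' @exportClass RaschFit
setClass("RaschFit",
    representation(
        difficulty = "numeric",
        latentMean = "numeric",
        latentVar = "numeric",
        logLik = "numeric",
        logLikTrace = "numeric",
        converged = "logical",
        iterations = "integer",
        excludedItems = "integer",
        nodes = "numeric"
    )
)

#' Latent-regression fit with fixed difficulties
#'
#' Result of [fitLatentRegression()]: the background (conditioning) model
#' of plausible value estimation, a normal prior on ability regressed on
#' covariates, combined with a fixed-difficulty Rasch likelihood.
#'
#' @slot coefficients named numeric, intercept and regression weights.
#' @slot residVar numeric(1), residual prior variance of ability.
#' @slot difficulty numeric, fixed item difficulties used.
#' @slot covariates character, covariate names (may be empty).
#' @slot logLik numeric(1), final marginal log-likelihood.
#' @slot logLikTrace numeric, per-iteration marginal log-likelihood.
#' @slot converged logical(1).
#' @slot iterations integer(1).
#' @slot nodes numeric, quadrature grid.
#' @slot vcov matrix, large-sample covariance of (coefficients, residVar);
#'   0 x 0 unless standard errors were requested.
#'
#' @name LatentRegressionFit-class
#' @aliases LatentRegressionFit-class
#' @exportClass LatentRegressionFit
setClass("LatentRegressionFit",
    representation(
        coefficients = "numeric",
        residVar = "numeric",
        difficulty = "numeric",
        covariates = "character",
        logLik = "numeric",
        logLikTrace = "numeric",
        converged = "logical",
        iterations = "integer",
        nodes = "numeric",
        vcov = "matrix"
    )
)

#' Plausible value draws
#'
#' A set of M draws per person from the posterior of ability given the
#' item responses and the background model.
#'
#' @slot draws numeric matrix, sets x persons (logits).
#' @slot seed integer(1) or NA, seed used for the draws.
#'
#' @seealso [drawPlausibleValues()]
#' @name PlausibleValues-class
#' @aliases PlausibleValues-class
#' @exportClass PlausibleValues
setClass("PlausibleValues",
    representation(draws = "matrix", seed = "integer")
)

setValidity("PlausibleValues", function(object) {
    msg <- character()
    if (nrow(object@draws) < 2L)
        msg <- c(msg, "at least 2 plausible value sets are required")
    if (anyNA(object@draws))
        msg <- c(msg, "plausible values must not contain missing entries")
    if (length(msg)) msg else TRUE
})
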