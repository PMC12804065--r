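#' Draw person parameters for a condition
#'
#' For each group g, draws \code{nPerGroup[g]} persons from the
#' multivariate normal with mean (muPhi_g, muTheta_g, muTau) and the
#' condition's shared covariance.
#'
#' @param condition a [SimulationCondition-class].
#' @param seed integer seed for reproducibility (optional).
#' @return a data.frame with columns \code{group} (factor "1"/"2"),
#'   \code{phi}, \code{theta}, \code{tau}.
#' @examples
#' cond <- makeCondition(0.5, 0.05, nPerGroup = 5)
#' drawPersons(cond, seed = 1)
#' @export
drawPersons <- function(condition, seed = NULL) {
    stopifnot(is(condition, "SimulationCondition"))
    withSeed(seed, {
        perGroup <- lapply(1:2, function(g) {
            mu <- c(condition@muPhi[g], condition@muTheta[g],
                    condition@muTau)
            draws <- MASS::mvrnorm(condition@nPerGroup[g], mu = mu,
                                   Sigma = condition@Sigma)
            draws <- matrix(draws, ncol = 3L)
            data.frame(group = g, phi = draws[, 1L], theta = draws[, 2L],
                       tau = draws[, 3L])
        })
        out <- do.call(rbind, perGroup)
        out$group <- factor(out$group, levels = 1:2)
        rownames(out) <- sprintf("p%04d", seq_len(nrow(out)))
        out
    })
}

#' Construct a ResponseExperiment from persons x items matrices
#'
#' @param responses persons x items 0/1/NA matrix.
#' @param times persons x items matrix of response times in seconds.
#' @param group factor or vector of group labels, one per person.
#' @param engagement optional persons x items matrix of true engagement
#'   classes (1 = solution behaviour, 0 = rapid guess).
#' @param personData optional data.frame of additional per-person columns.
#' @param itemData optional data.frame of per-item columns.
#' @return a [ResponseExperiment-class].
#' @export
ResponseExperiment <- function(responses, times, group, engagement = NULL,
                               personData = NULL, itemData = NULL) {
    responses <- as.matrix(responses)
    times <- as.matrix(times)
    if (!identical(dim(responses), dim(times)))
        stop("responses and times must share dimensions")
    n <- nrow(responses)
    if (length(group) != n)
        stop("'group' must have one entry per person (row)")
    assays <- list(responses = t(responses), times = t(times))
    if (!is.null(engagement)) {
        engagement <- as.matrix(engagement)
        if (!identical(dim(engagement), dim(responses)))
            stop("engagement must share dimensions with responses")
        assays$engagement <- t(engagement)
    }
    cd <- DataFrame(group = factor(group))
    if (!is.null(personData))
        cd <- cbind(cd, DataFrame(personData))
    rd <- if (is.null(itemData)) NULL else DataFrame(itemData)
    se <- SummarizedExperiment(assays = assays, colData = cd,
                               rowData = rd)
    if (is.null(rownames(se)))
        rownames(se) <- sprintf("item%02d", seq_len(nrow(se)))
    if (is.null(colnames(se)))
        colnames(se) <- sprintf("p%04d", seq_len(ncol(se)))
    new("ResponseExperiment", se)
}

#' Simulate responses and response times
#'
#' For every person-item encounter the latent class is drawn as
#' Bernoulli(expit(phi_i)) (1 = solution behaviour). Under solution
#' behaviour the response follows the Rasch model
#' \code{P(correct) = expit(theta_i - difficulty_j)} and the log response
#' time is normal with mean \code{timeIntensity_j - tau_i} and SD
#' \code{sbLogSD}. Under rapid guessing the response is correct with the
#' item's chance probability and the log time is normal with the bank's
#' rapid-guessing mean and SD, independent of the person parameters.
#'
#' @param persons data.frame from [drawPersons()] (columns group, phi,
#'   theta, tau).
#' @param bank an [ItemBank-class].
#' @param seed integer seed (optional).
#' @return a [ResponseExperiment-class] with assays responses, times and
#'   engagement; person parameters in \code{colData}, item parameters in
#'   \code{rowData}.
#' @examples
#' cond <- makeCondition(0.5, 0.05, nPerGroup = 5)
#' re <- simulateResponses(drawPersons(cond, seed = 1), cond@bank, seed = 2)
#' responseMatrix(re)[1:3, 1:4]
#' @export
simulateResponses <- function(persons, bank, seed = NULL) {
    stopifnot(is(bank, "ItemBank"),
              all(c("group", "phi", "theta", "tau") %in% names(persons)))
    mats <- withSeed(seed, simulateMatrices(persons, bank))
    ResponseExperiment(
        responses = mats$Y, times = mats$T, group = persons$group,
        engagement = mats$E,
        personData = persons[, c("phi", "theta", "tau")],
        itemData = data.frame(
            difficulty = bank@difficulty,
            timeIntensity = bank@timeIntensity,
            guessProb = bank@guessProb,
            pool = itemPoolingKey(bank)))
}

## Matrix-level generator shared by the public constructor and the
## simulation loops (which avoid container-construction overhead).
## Uses the current RNG stream; callers control seeding.
simulateMatrices <- function(persons, bank) {
    n <- nrow(persons)
    J <- nItems(bank)
    pSB <- expit(persons$phi)
    E <- matrix(rbinom(n * J, 1L, rep(pSB, times = J)), n, J)
    pCorrect <- expit(outer(persons$theta, bank@difficulty, "-"))
    pGuess <- matrix(bank@guessProb, n, J, byrow = TRUE)
    Y <- matrix(rbinom(n * J, 1L, E * pCorrect + (1 - E) * pGuess), n, J)
    muLog <- outer(-persons$tau, bank@timeIntensity, "+")
    logT <- rnorm(n * J,
                  mean = E * muLog + (1 - E) * bank@rgLogMean,
                  sd = E * bank@sbLogSD + (1 - E) * bank@rgLogSD)
    Tmat <- matrix(exp(logT), n, J)
    itemIds <- sprintf("item%02d", seq_len(J))
    personIds <- rownames(persons)
    dimnames(Y) <- dimnames(Tmat) <- dimnames(E) <-
        list(personIds, itemIds)
    list(Y = Y, T = Tmat, E = E)
}

## Condition-level matrix generator mirroring simulateCondition's seed
## split, so both paths produce identical data for a given seed.
simulateConditionRaw <- function(condition, seed = NULL) {
    seeds <- deriveSeeds(seed, 2L)
    persons <- drawPersons(condition, seed = seeds[[1L]])
    mats <- withSeed(seeds[[2L]],
                     simulateMatrices(persons, condition@bank))
    c(list(persons = persons), mats)
}

#' Simulate one complete dataset for a condition
#'
#' Splits the master seed deterministically into a person-draw stream and
#' a response-draw stream, so that the same dataset can be regenerated in
#' isolation.
#'
#' @param condition a [SimulationCondition-class].
#' @param seed master integer seed (optional).
#' @return a [ResponseExperiment-class].
#' @examples
#' re <- simulateCondition(makeCondition(0.5, 0.05, nPerGroup = 10), seed = 7)
#' dim(re)
#' @export
simulateCondition <- function(condition, seed = NULL) {
    seeds <- deriveSeeds(seed, 2L)
    persons <- drawPersons(condition, seed = seeds[[1L]])
    simulateResponses(persons, condition@bank, seed = seeds[[2L]])
}

#' @rdname ResponseExperiment-class
#' @export
setMethod("responseMatrix", "ResponseExperiment",
          function(x) t(assay(x, "responses")))

#' @rdname ResponseExperiment-class
#' @export
setMethod("timeMatrix", "ResponseExperiment",
          function(x) t(assay(x, "times")))

#' @rdname ResponseExperiment-class
#' @export
setMethod("engagementMatrix", "ResponseExperiment", function(x) {
    if (!"engagement" %in% assayNames(x))
        return(NULL)
    t(assay(x, "engagement"))
})

#' @rdname ResponseExperiment-class
#' @export
setMethod("groupLabels", "ResponseExperiment",
          function(x) colData(x)$group)

#' Write a dataset as delimited text files
#'
#' Writes tab-separated matrices \code{<prefix>_responses.tsv},
#' \code{<prefix>_times.tsv}, \code{<prefix>_persons.tsv},
#' \code{<prefix>_items.tsv} and, when present,
#' \code{<prefix>_engagement.tsv} into \code{dir}. Missing responses are
#' written as the sentinel \code{NA}.
#'
#' @param x a [ResponseExperiment-class].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @seealso [readResponseData()]
#' @export
writeResponseData <- function(x, dir, prefix = "data") {
    stopifnot(is(x, "ResponseExperiment"))
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    path <- function(part) file.path(dir, paste0(prefix, "_", part, ".tsv"))
    wt <- function(obj, part) {
        write.table(obj, path(part), sep = "\t", quote = FALSE,
                    col.names = NA)
        path(part)
    }
    paths <- c(wt(responseMatrix(x), "responses"),
               wt(timeMatrix(x), "times"),
               wt(as.data.frame(colData(x)), "persons"),
               wt(as.data.frame(rowData(x)), "items"))
    if (!is.null(engagementMatrix(x)))
        paths <- c(paths, wt(engagementMatrix(x), "engagement"))
    invisible(paths)
}

#' Read a dataset written by writeResponseData
#'
#' @param dir directory containing the files.
#' @param prefix file name prefix used when writing.
#' @return a [ResponseExperiment-class].
#' @export
readResponseData <- function(dir, prefix = "data") {
    path <- function(part) file.path(dir, paste0(prefix, "_", part, ".tsv"))
    rd <- function(part) as.matrix(read.table(path(part), sep = "\t",
                                              header = TRUE, row.names = 1L,
                                              check.names = FALSE))
    persons <- read.table(path("persons"), sep = "\t", header = TRUE,
                          row.names = 1L, check.names = FALSE)
    items <- read.table(path("items"), sep = "\t", header = TRUE,
                        row.names = 1L, check.names = FALSE)
    engagement <- if (file.exists(path("engagement"))) rd("engagement")
                  else NULL
    extra <- setdiff(names(persons), "group")
    ResponseExperiment(
        responses = rd("responses"), times = rd("times"),
        group = persons$group, engagement = engagement,
        personData = if (length(extra)) persons[, extra, drop = FALSE]
                     else NULL,
        itemData = items)
}

#' @rdname ResponseExperiment-class
#' @param object a \code{ResponseExperiment}.
#' @export
setMethod("show", "ResponseExperiment", function(object) {
    callNextMethod()
    rg <- engagementMatrix(object)
    if (!is.null(rg))
        cat(sprintf("realized rapid-guessing rate: %.3f\n",
                    mean(rg == 0, na.rm = TRUE)))
})
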