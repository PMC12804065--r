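#' The seven canonical model variants
#'
#' One baseline model (no rapid-guessing handling) plus the person-level,
#' response-level and combined handling strategies, each under the fixed
#' and the visual threshold method. The grouping variable is a covariate
#' in every background model; person-level and combined models add the
#' dichotomized RTE; response-level and combined models recode flagged
#' responses as missing (effort-moderated scoring).
#'
#' @return data.frame with columns \code{name}, \code{level},
#'   \code{threshold}, \code{useRTE}, \code{filter}.
#' @examples
#' modelSpecs()
#' @export
modelSpecs <- function() {
    data.frame(
        name = c("baseline", "person_fixed", "person_visual",
                 "response_fixed", "response_visual",
                 "combined_fixed", "combined_visual"),
        level = c("baseline", "person", "person", "response", "response",
                  "combined", "combined"),
        threshold = c("none", "fixed", "visual", "fixed", "visual",
                      "fixed", "visual"),
        useRTE = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
        filter = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
        stringsAsFactors = FALSE)
}

#' Visual thresholds for a simulation condition
#'
#' Computes the antimode thresholds for a condition once, from a
#' dedicated calibration dataset, pooling items that share a
#' (difficulty, time-intensity) parameter set -- so a 20-item bank with
#' five parameter sets yields five distinct thresholds per condition.
#' The same thresholds are then shared by all replications of that
#' condition.
#'
#' @param condition a [SimulationCondition-class].
#' @param seed seed for the calibration dataset.
#' @param window,bw passed to [visualThresholds()].
#' @return a [ThresholdSet-class].
#' @export
conditionVisualThresholds <- function(condition, seed = NULL,
                                      window = c(5, 15), bw = "SJ") {
    dat <- simulateConditionRaw(condition, seed = seed)
    visualThresholds(dat$T, window = window,
                     pooling = itemPoolingKey(condition@bank), bw = bw)
}

## Fit all requested model variants on one dataset and pool estimands.
## Returns one row per (model, estimand); failures in one model are
## recorded as non-converged without affecting the others.
fitModelSuite <- function(Y, Tm, groups, specs, nPV, pvSeed,
                          fixed, visual, nQuad = 61L,
                          gridBounds = c(-6, 6)) {
    groups <- factor(groups)
    flags <- list(fixed = if (!is.null(fixed)) flagEngagement(Tm, fixed),
                  visual = if (!is.null(visual)) flagEngagement(Tm, visual))
    rte <- lapply(flags, function(f)
        if (is.null(f)) NULL else responseTimeEffort(f))
    groupDummy <- as.integer(groups == levels(groups)[2L])
    raschCache <- new.env(parent = emptyenv())
    step1 <- function(key, mat) {
        if (!exists(key, envir = raschCache, inherits = FALSE))
            assign(key, fitRaschMML(mat, nQuad = nQuad,
                                    gridBounds = gridBounds),
                   envir = raschCache)
        get(key, envir = raschCache, inherits = FALSE)
    }
    estimandNames <- c("d", "mu1", "mu2", "sd1", "sd2")
    rows <- lapply(seq_len(nrow(specs)), function(s) {
        spec <- specs[s, ]
        res <- tryCatch({
            Yuse <- if (spec$filter)
                applyEmmFilter(Y, flags[[spec$threshold]])
            else Y
            key <- if (spec$filter) paste0("filtered_", spec$threshold)
                   else "raw"
            rasch <- step1(key, Yuse)
            if (!rasch@converged)
                stop("step-1 Rasch model did not converge")
            X <- data.frame(group = groupDummy)
            if (spec$useRTE) {
                rteStar <- rte[[spec$threshold]]$rteStar
                if (anyNA(rteStar))
                    stop("missing RTE for some persons")
                if (var(rteStar) > 0)
                    X$rteStar <- rteStar
                else
                    message(sprintf(
                        "model %s: RTE* constant, covariate dropped",
                        spec$name))
            }
            fit <- fitLatentRegression(Yuse, rasch@difficulty, X,
                                       nQuad = nQuad,
                                       gridBounds = gridBounds)
            if (!fit@converged)
                stop("background model did not converge")
            pv <- drawPlausibleValues(fit, Yuse, X, nPV = nPV,
                                      seed = pvSeed)
            pooled <- pooledEstimands(pv, groups)
            cbind(model = spec$name, pooled, converged = TRUE,
                  stringsAsFactors = FALSE)
        }, error = function(e) {
            data.frame(model = spec$name, estimand = estimandNames,
                       estimate = NA_real_, W = NA_real_, B = NA_real_,
                       T = NA_real_, ciLower = NA_real_,
                       ciUpper = NA_real_, converged = FALSE,
                       error = conditionMessage(e))
        })
        if (is.null(res$error))
            res$error <- NA_character_
        res
    })
    do.call(rbind, rows)
}

#' Run one simulation replication
#'
#' Generates one dataset for the condition, computes both threshold sets
#' (the visual thresholds may be supplied precomputed, as in a full
#' study), and runs every requested model variant through the three-step
#' plausible value procedure: step-1 Rasch calibration (on the filtered
#' matrix for effort-moderated models, on the raw matrix otherwise),
#' step-2 latent regression with fixed difficulties, plausible value
#' drawing, per-set estimands and Rubin pooling. All models see the
#' identical dataset, and the plausible value seed is shared so that
#' models differing only in inert options coincide exactly.
#'
#' @param condition a [SimulationCondition-class].
#' @param specs model variants from [modelSpecs()].
#' @param nPV plausible value sets per model.
#' @param seed master seed for this replication.
#' @param visual optional precomputed [ThresholdSet-class]; computed
#'   from this replication's dataset when \code{NULL}.
#' @param fixedK fixed threshold in seconds.
#' @param nQuad,gridBounds quadrature settings.
#' @return data.frame with one row per (model, estimand): pooled
#'   estimate, Rubin variances, interval, convergence flag.
#' @examples
#' cond <- makeCondition(0.5, 0.05, nPerGroup = 60)
#' rep1 <- runReplication(cond, nPV = 2, seed = 1)
#' head(rep1)
#' @export
runReplication <- function(condition, specs = modelSpecs(), nPV = 25L,
                           seed = NULL, visual = NULL, fixedK = 5,
                           nQuad = 61L, gridBounds = c(-6, 6)) {
    seeds <- deriveSeeds(seed, 3L)
    dat <- simulateConditionRaw(condition, seed = seeds[[1L]])
    Y <- dat$Y
    Tm <- dat$T
    fixed <- fixedThresholds(colnames(Tm), k = fixedK)
    if (any(specs$threshold == "visual") && is.null(visual))
        visual <- visualThresholds(Tm,
                                   pooling = itemPoolingKey(condition@bank))
    out <- fitModelSuite(Y, Tm, dat$persons$group, specs, nPV = nPV,
                         pvSeed = seeds[[3L]], fixed = fixed,
                         visual = visual, nQuad = nQuad,
                         gridBounds = gridBounds)
    cbind(condition = condition@conditionId, out)
}

#' Study configuration
#'
#' @param conditions named list of [SimulationCondition-class] objects.
#' @param nSim replications per condition. The reference design uses
#'   1000; the default here (200) is a scaled-down setting and is
#'   flagged as such in the returned metadata.
#' @param nPV plausible value sets per model (reference design: 25).
#' @param seed master seed.
#' @param specs model variants.
#' @param outDir optional output directory; per-condition raw estimate
#'   files make a study resumable.
#' @param fixedK,nQuad,gridBounds estimation settings.
#' @return a list of class \code{"studyConfig"}.
#' @export
studyConfig <- function(conditions = tableConditions(), nSim = 200L,
                        nPV = 10L, seed = 1L, specs = modelSpecs(),
                        outDir = NULL, fixedK = 5, nQuad = 61L,
                        gridBounds = c(-6, 6)) {
    if (nSim < 2L || nPV < 2L)
        stop("nSim and nPV must both be at least 2")
    structure(list(conditions = conditions, nSim = as.integer(nSim),
                   nPV = as.integer(nPV), seed = as.integer(seed),
                   specs = specs, outDir = outDir, fixedK = fixedK,
                   nQuad = nQuad, gridBounds = gridBounds,
                   referenceScale = nSim >= 1000L && nPV >= 25L),
              class = "studyConfig")
}

#' True estimand values of a set of conditions
#'
#' @param conditions named list of [SimulationCondition-class] objects.
#' @return data.frame with columns \code{condition}, \code{estimand},
#'   \code{trueValue}.
#' @export
trueValuesTable <- function(conditions) {
    do.call(rbind, lapply(conditions, function(cond) {
        data.frame(condition = cond@conditionId,
                   estimand = c("d", "mu1", "mu2", "sd1", "sd2"),
                   trueValue = c(cond@trueD, cond@trueMu, cond@trueSD),
                   row.names = NULL)
    }))
}

#' Run a full simulation study
#'
#' For every condition: the visual thresholds are determined once from a
#' calibration dataset (mirroring a design in which one threshold per
#' item parameter set and condition is fixed for the whole study), then
#' \code{nSim} replications are run with deterministically derived
#' seeds, and the per-replication pooled estimates are aggregated into
#' ADEMP performance measures. With an \code{outDir}, raw per-condition
#' estimates are written as CSV and re-used on a rerun (resume).
#'
#' @param config a [studyConfig()].
#' @return list with \code{results} (per-replication long table),
#'   \code{performance} (from [performanceTable()]), \code{thresholds}
#'   (per-condition visual [ThresholdSet-class]s), \code{trueValues} and
#'   \code{config}.
#' @examples
#' cfg <- studyConfig(conditions = tableConditions(nPerGroup = 40)[1],
#'                    nSim = 2, nPV = 2, seed = 1)
#' res <- runStudy(cfg)
#' res$performance[res$performance$estimand == "d", ]
#' @export
runStudy <- function(config) {
    stopifnot(inherits(config, "studyConfig"))
    conditions <- config$conditions
    nCond <- length(conditions)
    condSeeds <- deriveSeeds(config$seed, nCond)
    outDir <- config$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    allThresholds <- vector("list", nCond)
    names(allThresholds) <- names(conditions)
    results <- vector("list", nCond)
    for (ci in seq_len(nCond)) {
        cond <- conditions[[ci]]
        repSeeds <- deriveSeeds(condSeeds[[ci]], config$nSim + 1L)
        visual <- conditionVisualThresholds(cond,
                                            seed = repSeeds[[config$nSim + 1L]])
        allThresholds[[ci]] <- visual
        rawPath <- if (!is.null(outDir))
            file.path(outDir, sprintf("estimates_condition%02d.csv",
                                      cond@conditionId))
        if (!is.null(rawPath) && file.exists(rawPath)) {
            results[[ci]] <- read.table(rawPath, sep = ",", header = TRUE,
                                        stringsAsFactors = FALSE)
            next
        }
        reps <- lapply(seq_len(config$nSim), function(r) {
            out <- runReplication(cond, specs = config$specs,
                                  nPV = config$nPV, seed = repSeeds[[r]],
                                  visual = visual, fixedK = config$fixedK,
                                  nQuad = config$nQuad,
                                  gridBounds = config$gridBounds)
            cbind(replication = r, out)
        })
        results[[ci]] <- do.call(rbind, reps)
        if (!is.null(rawPath))
            write.table(results[[ci]], rawPath, sep = ",",
                        row.names = FALSE, quote = TRUE)
    }
    results <- do.call(rbind, c(results, list(make.row.names = FALSE)))
    trueVals <- trueValuesTable(conditions)
    perf <- performanceTable(results, trueVals)
    if (!is.null(outDir)) {
        write.table(perf, file.path(outDir, "performance.csv"), sep = ",",
                    row.names = FALSE, quote = TRUE)
        for (nm in names(allThresholds))
            writeThresholds(allThresholds[[nm]],
                            file.path(outDir,
                                      paste0("thresholds_", nm, ".tsv")))
        meta <- list(nSim = config$nSim, nPV = config$nPV,
                     seed = config$seed,
                     referenceScale = config$referenceScale,
                     note = if (config$referenceScale)
                         "reference-scale settings"
                     else
                         "scaled-down settings; not the reference design scale")
        yaml::write_yaml(meta, file.path(outDir, "metadata.yaml"))
    }
    list(results = results, performance = perf,
         thresholds = allThresholds, trueValues = trueVals,
         config = config)
}

#' Threshold classification study
#'
#' Generation + classification only (no model fitting): for each
#' condition the visual thresholds are calibrated once, then response
#' flags under both threshold methods are scored against the true
#' engagement classes over \code{nRep} replications, accumulating the
#' confusion counts.
#'
#' @param conditions named list of [SimulationCondition-class] objects.
#' @param nRep replications per condition.
#' @param seed master seed.
#' @param fixedK fixed threshold in seconds.
#' @return data.frame with one row per (condition, method): pooled
#'   \code{agreement}, \code{sensitivity}, \code{specificity} and counts.
#' @examples
#' conds <- tableConditions(nPerGroup = 100)[1]
#' thresholdDiagnosticsStudy(conds, nRep = 3, seed = 1)
#' @export
thresholdDiagnosticsStudy <- function(conditions, nRep = 500L, seed = 1L,
                                      fixedK = 5) {
    condSeeds <- deriveSeeds(seed, length(conditions))
    rows <- lapply(seq_along(conditions), function(ci) {
        cond <- conditions[[ci]]
        repSeeds <- deriveSeeds(condSeeds[[ci]], nRep + 1L)
        visual <- conditionVisualThresholds(cond,
                                            seed = repSeeds[[nRep + 1L]])
        fixed <- fixedThresholds(nItems(cond@bank), k = fixedK)
        counts <- list(fixed = c(tp = 0, fn = 0, tn = 0, fp = 0),
                       visual = c(tp = 0, fn = 0, tn = 0, fp = 0))
        for (r in seq_len(nRep)) {
            dat <- simulateConditionRaw(cond, seed = repSeeds[[r]])
            Tm <- dat$T
            E <- dat$E
            for (method in c("fixed", "visual")) {
                thr <- if (method == "fixed") fixed else visual
                f <- flagEngagement(Tm, thr)
                counts[[method]] <- counts[[method]] +
                    c(tp = sum(f == 1 & E == 1),
                      fn = sum(f == 0 & E == 1),
                      tn = sum(f == 0 & E == 0),
                      fp = sum(f == 1 & E == 0))
            }
        }
        do.call(rbind, lapply(c("fixed", "visual"), function(method) {
            ct <- counts[[method]]
            data.frame(condition = cond@conditionId, method = method,
                       agreement = (ct[["tp"]] + ct[["tn"]]) / sum(ct),
                       sensitivity = ct[["tp"]] / (ct[["tp"]] + ct[["fn"]]),
                       specificity = ct[["tn"]] / (ct[["tn"]] + ct[["fp"]]),
                       nResponses = sum(ct))
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Apply the seven model variants to observed data
#'
#' Real-data mode: takes user-supplied response and response-time
#' matrices plus a grouping variable, computes both threshold sets, and
#' reports the Rubin-pooled estimands with intervals for every model
#' variant. No truth-based diagnostics are computed.
#'
#' @param responses persons x items 0/1/NA matrix.
#' @param times persons x items matrix of response times in seconds.
#' @param groups factor with two levels, one entry per person.
#' @param specs model variants from [modelSpecs()].
#' @param nPV plausible value sets.
#' @param seed seed for the plausible value draws.
#' @param fixedK fixed threshold in seconds.
#' @param visual optional precomputed visual [ThresholdSet-class];
#'   computed from \code{times} (per item) when \code{NULL}.
#' @param window antimode search window in seconds.
#' @param pooling optional pooling keys for the visual thresholds.
#' @param nQuad,gridBounds quadrature settings.
#' @return data.frame with one row per (model, estimand).
#' @export
analyzeResponses <- function(responses, times, groups,
                             specs = modelSpecs(), nPV = 25L, seed = NULL,
                             fixedK = 5, visual = NULL, window = c(5, 15),
                             pooling = NULL, nQuad = 61L,
                             gridBounds = c(-6, 6)) {
    Y <- as.matrix(responses)
    Tm <- as.matrix(times)
    if (!identical(dim(Y), dim(Tm)))
        stop("responses and times must share dimensions")
    if (is.null(colnames(Tm)))
        colnames(Tm) <- colnames(Y) %||%
            sprintf("item%02d", seq_len(ncol(Tm)))
    fixed <- fixedThresholds(colnames(Tm), k = fixedK)
    if (is.null(visual) && any(specs$threshold == "visual"))
        visual <- visualThresholds(Tm, window = window, pooling = pooling)
    fitModelSuite(Y, Tm, groups, specs, nPV = nPV, pvSeed = seed,
                  fixed = fixed, visual = visual, nQuad = nQuad,
                  gridBounds = gridBounds)
}
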