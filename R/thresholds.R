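#' Fixed (common-k) response-time thresholds
#'
#' One shared cutoff for every item, the common-k method. The
#' conventional default is 5 seconds.
#'
#' @param itemIds item names, or a single integer giving the item count.
#' @param k threshold in seconds (> 0).
#' @return a [ThresholdSet-class].
#' @examples
#' fixedThresholds(20)
#' @export
fixedThresholds <- function(itemIds, k = 5) {
    if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
        stop("'k' must be a single positive number of seconds")
    if (is.numeric(itemIds) && length(itemIds) == 1L)
        itemIds <- sprintf("item%02d", seq_len(itemIds))
    new("ThresholdSet",
        thresholds = setNames(rep(k, length(itemIds)), itemIds),
        method = "fixed", window = c(NA_real_, NA_real_),
        pooling = character())
}

#' Antimode (visual-inspection) response-time thresholds
#'
#' Automates the visual-inspection rule: under mixed rapid-guessing and
#' solution behaviour the response-time distribution is bimodal, and the
#' threshold is placed at the local minimum (antimode) between the fast
#' and slow modes. A kernel density on the seconds scale (bandwidth by
#' the Sheather-Jones plug-in rule) is evaluated on a fine grid inside
#' the search window and its minimum is returned; ties are broken toward
#' the smallest time. Items sharing a pooling key are pooled to a common
#' threshold. If a pool has no observed times the window's lower bound is
#' used with a warning.
#'
#' @param times persons x items matrix of response times (seconds).
#' @param window numeric(2), search window in seconds.
#' @param pooling optional character of pooling keys, one per item;
#'   \code{NULL} gives per-item thresholds.
#' @param bw kernel bandwidth selector passed to [stats::density()].
#' @param gridStep spacing of the evaluation grid in seconds.
#' @return a [ThresholdSet-class].
#' @examples
#' set.seed(1)
#' tt <- cbind(exp(rnorm(500, 1.25, 0.6)), exp(rnorm(500, 3.3, 0.3)))
#' visualThresholds(tt, pooling = c("a", "a"))
#' @export
visualThresholds <- function(times, window = c(5, 15), pooling = NULL,
                             bw = "SJ", gridStep = 0.01) {
    times <- as.matrix(times)
    if (any(times <= 0, na.rm = TRUE))
        stop("response times must be strictly positive")
    if (length(window) != 2L || window[1L] <= 0 || diff(window) <= 0)
        stop("'window' must be increasing positive bounds in seconds")
    J <- ncol(times)
    itemIds <- colnames(times)
    if (is.null(itemIds))
        itemIds <- sprintf("item%02d", seq_len(J))
    if (is.null(pooling))
        pooling <- itemIds
    if (length(pooling) != J)
        stop("'pooling' must supply one key per item")
    nGrid <- max(16L, ceiling(diff(window) / gridStep) + 1L)
    rho <- numeric(J)
    for (key in unique(pooling)) {
        idx <- which(pooling == key)
        x <- as.vector(times[, idx])
        x <- x[!is.na(x)]
        if (!length(x)) {
            warning(sprintf(
                "no observed response times for pool '%s'; using window lower bound",
                key))
            rho[idx] <- window[1L]
            next
        }
        dens <- tryCatch(
            density(x, bw = bw, from = window[1L], to = window[2L],
                    n = nGrid),
            error = function(e)
                density(x, bw = "nrd0", from = window[1L], to = window[2L],
                        n = nGrid))
        rho[idx] <- dens$x[which.min(dens$y)]
    }
    new("ThresholdSet",
        thresholds = setNames(rho, itemIds),
        method = "visual", window = as.numeric(window),
        pooling = as.character(pooling))
}

#' @rdname ThresholdSet-class
#' @export
setMethod("thresholds", "ThresholdSet", function(x) x@thresholds)

#' @rdname ThresholdSet-class
#' @export
setMethod("nItems", "ThresholdSet", function(x) length(x@thresholds))

#' @rdname ThresholdSet-class
#' @param object a \code{ThresholdSet}.
#' @export
setMethod("show", "ThresholdSet", function(object) {
    cat(sprintf("ThresholdSet (%s) for %d items\n", object@method,
                nItems(object)))
    cat(sprintf("  range: %.2f .. %.2f seconds\n",
                min(object@thresholds), max(object@thresholds)))
    if (length(object@pooling))
        cat(sprintf("  pools: %d\n", length(unique(object@pooling))))
})

#' Export / import thresholds as delimited text
#'
#' Two tab-separated columns: item id and threshold in seconds.
#'
#' @param x a [ThresholdSet-class].
#' @param path file path.
#' @return \code{writeThresholds} invisibly returns \code{path};
#'   \code{readThresholds} returns a [ThresholdSet-class] (method tag as
#'   recorded in the file's header comment, defaulting to "fixed").
#' @export
writeThresholds <- function(x, path) {
    stopifnot(is(x, "ThresholdSet"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# method: %s", x@method), con)
    write.table(data.frame(item = names(x@thresholds),
                           threshold = unname(x@thresholds)),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
    first <- readLines(path, n = 1L)
    method <- if (grepl("^# method: ", first))
        sub("^# method: ", "", first) else "fixed"
    tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
    new("ThresholdSet",
        thresholds = setNames(tab$threshold, tab$item),
        method = method, window = c(NA_real_, NA_real_),
        pooling = character())
}

#' Flag engagement of each response against thresholds
#'
#' A response is flagged as a rapid guess (flag 0) when its time is
#' strictly below the item threshold; times at or above the threshold
#' are engaged (flag 1). Missing times yield missing flags.
#'
#' @param times persons x items matrix of response times (seconds).
#' @param thr a [ThresholdSet-class] (or numeric vector of per-item
#'   thresholds).
#' @return persons x items 0/1/NA matrix of engagement flags.
#' @examples
#' flagEngagement(matrix(c(4.9, 5, 30), 1), fixedThresholds(3, k = 5))
#' @export
flagEngagement <- function(times, thr) {
    times <- as.matrix(times)
    rho <- if (is(thr, "ThresholdSet")) thresholds(thr) else thr
    if (length(rho) != ncol(times))
        stop("number of thresholds must match number of items")
    if (any(times <= 0, na.rm = TRUE))
        stop("response times must be strictly positive")
    flags <- 0L + (times >= matrix(rho, nrow(times), ncol(times),
                                   byrow = TRUE))
    dimnames(flags) <- dimnames(times)
    flags
}

#' Response time effort (RTE) per person
#'
#' RTE is the proportion of a person's scorable responses flagged as
#' engaged; it is dichotomized at 0.9 (engaged only when strictly more
#' than 90 percent of responses show solution behaviour, so RTE = 0.9
#' maps to 0). Responses with missing flags are excluded from both the
#' numerator and the denominator.
#'
#' @param flags persons x items 0/1/NA matrix from [flagEngagement()].
#' @param minItems minimum number of scorable items per person; persons
#'   below it get missing RTE.
#' @return a data.frame with columns \code{rte}, \code{rteStar},
#'   \code{nScorable}.
#' @examples
#' responseTimeEffort(matrix(c(rep(1, 18), 0, 0), 1))
#' @export
responseTimeEffort <- function(flags, minItems = 1L) {
    flags <- as.matrix(flags)
    nScorable <- rowSums(!is.na(flags))
    rte <- rowSums(flags == 1L, na.rm = TRUE) / nScorable
    rte[nScorable < minItems] <- NA_real_
    rteStar <- ifelse(is.na(rte), NA_integer_, as.integer(rte > 0.9))
    data.frame(rte = rte, rteStar = rteStar, nScorable = nScorable,
               row.names = rownames(flags))
}

#' Classification diagnostics against true engagement
#'
#' Confusion-matrix rates of the threshold classification against the
#' simulated engagement classes, at the response level and, optionally,
#' at the person level (RTE* against true RTE* computed from the true
#' engagement matrix with the same 0.9 rule). Engaged (class 1) is the
#' positive class: sensitivity is the proportion of truly engaged
#' responses flagged engaged; specificity is the proportion of true
#' rapid guesses flagged as rapid guesses.
#'
#' @param flags persons x items 0/1/NA matrix of estimated flags.
#' @param truth persons x items matrix of true engagement (simulation
#'   only); an error if absent.
#' @param rte optional data.frame from [responseTimeEffort()] for the
#'   person-level diagnostics.
#' @return a list with elements \code{response} and (if \code{rte} was
#'   given) \code{person}, each containing \code{agreement},
#'   \code{sensitivity}, \code{specificity} and the underlying counts.
#' @examples
#' truth <- matrix(c(1, 1, 0, 0), 2)
#' classificationDiagnostics(truth, truth)$response
#' @export
classificationDiagnostics <- function(flags, truth, rte = NULL) {
    if (is.null(truth))
        stop("true engagement is required; diagnostics are simulation-only")
    flags <- as.matrix(flags)
    truth <- as.matrix(truth)
    if (!identical(dim(flags), dim(truth)))
        stop("flags and truth must share dimensions")
    rates <- function(est, tru) {
        ok <- !is.na(est) & !is.na(tru)
        est <- est[ok]; tru <- tru[ok]
        counts <- c(tp = sum(est == 1 & tru == 1),
                    fn = sum(est == 0 & tru == 1),
                    tn = sum(est == 0 & tru == 0),
                    fp = sum(est == 1 & tru == 0))
        list(agreement = (counts[["tp"]] + counts[["tn"]]) / sum(counts),
             sensitivity = counts[["tp"]] /
                 (counts[["tp"]] + counts[["fn"]]),
             specificity = counts[["tn"]] /
                 (counts[["tn"]] + counts[["fp"]]),
             counts = counts)
    }
    out <- list(response = rates(flags, truth))
    if (!is.null(rte)) {
        trueRte <- responseTimeEffort(truth)
        out$person <- rates(rte$rteStar, trueRte$rteStar)
    }
    out
}
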