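#' Construct an item bank
#'
#' @param difficulty numeric, Rasch difficulty per item (logits).
#' @param timeIntensity numeric, solution-behaviour log-time mean per item
#'   (log-seconds).
#' @param sbLogSD solution-behaviour log-time SD.
#' @param guessProb rapid-guessing success probability, recycled across
#'   items if scalar.
#' @param rgLogMean rapid-guessing log-time mean (log-seconds).
#' @param rgLogSD rapid-guessing log-time SD.
#' @return an [ItemBank-class] object.
#'
#' @examples
#' bank <- ItemBank(difficulty = c(-1, 0, 1), timeIntensity = c(3, 3.3, 3.6))
#' nItems(bank)
#' @export
ItemBank <- function(difficulty, timeIntensity, sbLogSD = 0.30,
                     guessProb = 0.25, rgLogMean = 1.25, rgLogSD = 0.60) {
    J <- length(difficulty)
    guessProb <- rep_len(as.numeric(guessProb), J)
    new("ItemBank",
        difficulty = as.numeric(difficulty),
        timeIntensity = as.numeric(timeIntensity),
        sbLogSD = as.numeric(sbLogSD),
        guessProb = guessProb,
        rgLogMean = as.numeric(rgLogMean),
        rgLogSD = as.numeric(rgLogSD))
}

#' Default 20-item bank
#'
#' The crossed bank used throughout the simulation study: difficulties
#' \{-1, -0.5, 0, 0.5, 1\} logits and time intensities \{2.9, 3.1, 3.3,
#' 3.5, 3.7\} log-seconds (average solution-behaviour response times of
#' roughly 15 to 40 seconds), each value replicated four times so that
#' five (difficulty, intensity) parameter sets of four items each make up
#' 20 items. Rapid guesses succeed with probability 0.25 (four-option
#' multiple choice) and have lognormal times with mean 1.25 log-seconds
#' (about 3.5 s) and SD 0.60.
#'
#' @return an [ItemBank-class] with 20 items.
#' @examples
#' defaultItemBank()
#' @export
defaultItemBank <- function() {
    xi <- c(-1.0, -0.5, 0.0, 0.5, 1.0)
    beta <- c(2.9, 3.1, 3.3, 3.5, 3.7)
    ItemBank(difficulty = rep(xi, each = 4L),
             timeIntensity = rep(beta, each = 4L))
}

#' @rdname ItemBank-class
#' @export
setMethod("nItems", "ItemBank", function(x) length(x@difficulty))

#' @rdname ItemBank-class
#' @export
setMethod("difficulty", "ItemBank", function(x) x@difficulty)

#' @rdname ItemBank-class
#' @export
setMethod("timeIntensity", "ItemBank", function(x) x@timeIntensity)

#' @rdname ItemBank-class
#' @param object an \code{ItemBank}.
#' @export
setMethod("show", "ItemBank", function(object) {
    cat(sprintf("ItemBank with %d items\n", nItems(object)))
    cat("  difficulty range: ",
        paste(range(object@difficulty), collapse = " .. "), " logits\n",
        sep = "")
    cat("  time intensity range: ",
        paste(range(object@timeIntensity), collapse = " .. "),
        " log-seconds (SB log-time SD ", object@sbLogSD, ")\n", sep = "")
    cat(sprintf("  RG: success prob %s, log-time %.2f (SD %.2f)\n",
                paste(unique(object@guessProb), collapse = "/"),
                object@rgLogMean, object@rgLogSD))
})

## Pooling key: items sharing a (difficulty, timeIntensity) parameter set.
itemPoolingKey <- function(bank) {
    paste0("d", bank@difficulty, "_b", bank@timeIntensity)
}
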