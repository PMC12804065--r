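## Internal helpers: seeded evaluation and deterministic seed derivation.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so seeded package functions do not
#' disturb the global random stream. A \code{NULL} seed evaluates the
#' expression under the current stream.
#'
#' @param seed integer scalar or \code{NULL}.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number or NULL")
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed)
        oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hasSeed)
            assign(".Random.seed", oldSeed, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    expr
}

## Derive n child seeds from a master seed. Deterministic, stays below
## 2^31 so the values remain valid R integers.
deriveSeeds <- function(seed, n, salt = 0L) {
    if (is.null(seed))
        return(rep(list(NULL), n))
    withSeed(seed + salt, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

## Stable logistic helpers used across modules.
expit <- function(x) plogis(x)

stopifnotScalarProb <- function(x, name, open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single number", name))
    if (open && (x <= 0 || x >= 1))
        stop(sprintf("'%s' must lie strictly inside (0, 1), got %g", name, x))
    if (!open && (x < 0 || x >= 1))
        stop(sprintf("'%s' must lie in [0, 1), got %g", name, x))
    invisible(x)
}

## log(sum(exp(x))) along rows of a matrix, guarding against underflow.
rowLogSumExp <- function(x) {
    m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
    m + log(rowSums(exp(x - m)))
}

## Row-wise cumulative sums via one BLAS multiply.
rowCumsum <- function(x) {
    u <- matrix(0, ncol(x), ncol(x))
    u[upper.tri(u, diag = TRUE)] <- 1
    x %*% u
}
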