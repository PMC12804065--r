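#' Convert a rapid-guessing rate to the group engagement mean
#'
#' The generating model draws a person engagement parameter phi on the
#' logit scale; the nominal group rapid-guessing rate RGR is converted to
#' the group mean of phi through \code{1 - RGR = expit(muPhi)}, i.e.
#' \code{muPhi = logit(1 - RGR)}.
#'
#' @param rgr rapid-guessing rate, strictly inside (0, 1).
#' @return the group engagement mean on the logit scale.
#' @examples
#' rgrToMuPhi(0.05)  # 2.944
#' rgrToMuPhi(0.5)   # 0
#' @export
rgrToMuPhi <- function(rgr) {
    if (!is.numeric(rgr) || anyNA(rgr))
        stop("'rgr' must be numeric without NA")
    if (any(rgr <= 0) || any(rgr >= 1))
        stop("'rgr' must lie strictly inside (0, 1)")
    qlogis(1 - rgr)
}

#' Person covariance matrix of the generating model
#'
#' Covariance of (engagement phi, ability theta, speed tau). Variances
#' are 1.70 (phi), 1.00 (theta, so that a mean gap of 0.5 is a 0.5 SD
#' gap) and 0.05 (tau). The association entries \{.35, -.20, -.20\}
#' admit two readings:
#' \describe{
#'   \item{\code{"correlation"} (default)}{the entries are correlations
#'     r(phi,theta) = .35, r(phi,tau) = r(theta,tau) = -.20, scaled by
#'     the variances. This matrix is positive definite as is.}
#'   \item{\code{"covariance"}}{the entries are covariances. That matrix
#'     is indefinite, so cov(theta, tau) is moved from -.20 to the
#'     nearest value with minimum eigenvalue \code{minEigen} (a
#'     deterministic root find, see [repairSigma()]; the result implies
#'     corr(theta, tau) of about -0.89).}
#' }
#' The correlation reading is the default because the covariance reading
#' is not a valid covariance matrix and implies an implausibly strong
#' ability-speed association.
#'
#' @param reading \code{"correlation"} or \code{"covariance"}.
#' @param minEigen smallest admissible eigenvalue for the repair used by
#'   the covariance reading.
#' @return a symmetric positive-definite 3x3 matrix with dimnames
#'   \code{c("phi", "theta", "tau")}.
#' @examples
#' defaultSigma()
#' suppressMessages(defaultSigma("covariance"))
#' @export
defaultSigma <- function(reading = c("correlation", "covariance"),
                         minEigen = 1e-6) {
    reading <- match.arg(reading)
    nm <- c("phi", "theta", "tau")
    if (reading == "correlation") {
        R <- matrix(c(1, 0.35, -0.20,
                      0.35, 1, -0.20,
                      -0.20, -0.20, 1), nrow = 3L)
        s <- sqrt(c(1.70, 1.00, 0.05))
        S <- diag(s) %*% R %*% diag(s)
        dimnames(S) <- list(nm, nm)
        return(S)
    }
    S <- matrix(c(1.70, 0.35, -0.20,
                  0.35, 1.00, -0.20,
                  -0.20, -0.20, 0.05),
                nrow = 3L, dimnames = list(nm, nm))
    repairSigma(S, minEigen = minEigen)
}

#' Engagement mean for a target rapid-guessing rate
#'
#' Converts a group rapid-guessing rate to the group mean of the latent
#' engagement parameter phi. Two conversions are provided:
#' \describe{
#'   \item{\code{"response"} (default)}{solves
#'     \code{E[expit(phi)] = 1 - rgr} with \code{phi ~ N(mu, phiVar)},
#'     so the generated responses exhibit the requested response-level
#'     rate in expectation.}
#'   \item{\code{"location"}}{the closed form \code{qlogis(1 - rgr)}
#'     (see [rgrToMuPhi()]), which places the rate at the distribution's
#'     location; because expit is concave above 0.5, the realized
#'     response-level rate then exceeds \code{rgr} when phi varies.}
#' }
#' \code{rgr = 0} disables rapid guessing (largest finite logit).
#'
#' @param rgr target rapid-guessing rate in [0, 1).
#' @param phiVar variance of phi (ignored for \code{"location"}).
#' @param conversion \code{"response"} or \code{"location"}.
#' @return the engagement mean on the logit scale.
#' @examples
#' muPhiForRate(0.05, phiVar = 1.7)             # about 4.43
#' muPhiForRate(0.05, conversion = "location")  # 2.944
#' @export
muPhiForRate <- function(rgr, phiVar = 1.70,
                         conversion = c("response", "location")) {
    conversion <- match.arg(conversion)
    if (length(rgr) > 1L)
        return(vapply(rgr, muPhiForRate, numeric(1L), phiVar = phiVar,
                      conversion = conversion))
    if (rgr == 0)
        return(qlogis(1 - 1e-12))
    stopifnotScalarProb(rgr, "rgr")
    if (conversion == "location")
        return(qlogis(1 - rgr))
    sdPhi <- sqrt(phiVar)
    realized <- function(mu)
        stats::integrate(function(x) plogis(-x) * dnorm(x, mu, sdPhi),
                         mu - 10 * sdPhi, mu + 10 * sdPhi)$value
    uniroot(function(mu) realized(mu) - rgr,
            lower = qlogis(1 - rgr), upper = qlogis(1 - rgr) + 10,
            extendInt = "yes", tol = 1e-10)$root
}

#' Repair an indefinite person covariance matrix
#'
#' If \code{Sigma} already has minimum eigenvalue at least
#' \code{minEigen} it is returned unchanged. Otherwise only the
#' (theta, tau) covariance is moved toward zero until the minimum
#' eigenvalue equals \code{minEigen}, keeping every other entry at its
#' requested value; the adjustment is reported via a message.
#'
#' @param Sigma symmetric 3x3 covariance matrix.
#' @param minEigen smallest admissible eigenvalue.
#' @return a positive-definite matrix.
#' @export
repairSigma <- function(Sigma, minEigen = 1e-6) {
    if (!is.matrix(Sigma) || !identical(dim(Sigma), c(3L, 3L)))
        stop("'Sigma' must be a 3x3 matrix")
    if (max(abs(Sigma - t(Sigma))) > 1e-8)
        stop("'Sigma' must be symmetric")
    minEig <- function(S)
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (minEig(Sigma) >= minEigen)
        return(Sigma)
    c0 <- Sigma[2L, 3L]
    f <- function(c23) {
        S <- Sigma
        S[2L, 3L] <- S[3L, 2L] <- c23
        minEig(S) - minEigen
    }
    if (f(0) < 0)
        stop("Sigma cannot be repaired by adjusting cov(theta, tau) alone")
    root <- uniroot(f, lower = min(c0, 0), upper = max(c0, 0),
                    tol = 1e-12)$root
    S <- Sigma
    S[2L, 3L] <- S[3L, 2L] <- root
    message(sprintf(
        "repairSigma: cov(theta, tau) moved from %.4f to %.4f for positive definiteness",
        c0, root))
    S
}

#' Build a simulation condition
#'
#' Defines one cell of the two-group design from its three factors: the
#' true standardized ability gap, the overall nominal rapid-guessing rate
#' and the (signed) between-group difference in rapid-guessing rates.
#' Group ability means are \code{-gap/2} and \code{+gap/2}; group RG
#' rates are \code{overallRGR -/+ rgrDelta/2} for groups 1 and 2, and are
#' converted to engagement means with [rgrToMuPhi()]. \code{rgr = 0}
#' (rapid guessing disabled) is accepted: the engagement mean is set to
#' the largest finite logit so that effectively every response is
#' solution behaviour.
#'
#' @param abilityGap true group difference in ability SD units.
#' @param overallRGR overall nominal rapid-guessing rate.
#' @param rgrDelta signed difference (group 2 minus group 1) in RG rates.
#' @param nPerGroup persons per group (recycled to length 2).
#' @param bank an [ItemBank-class].
#' @param Sigma 3x3 person covariance; repaired via [repairSigma()] when
#'   \code{repair = TRUE}, otherwise an indefinite matrix is an error.
#' @param conditionId optional design cell id.
#' @param repair logical, whether to repair an indefinite \code{Sigma}.
#' @param rgrConversion how group RG rates map to engagement means, see
#'   [muPhiForRate()].
#' @return a [SimulationCondition-class].
#' @examples
#' cond1 <- makeCondition(0.5, 0.05, -0.05, nPerGroup = 1000, conditionId = 1)
#' cond1
#' @export
makeCondition <- function(abilityGap, overallRGR, rgrDelta = 0,
                          nPerGroup = 1000L, bank = defaultItemBank(),
                          Sigma = defaultSigma(), conditionId = NA_integer_,
                          repair = TRUE,
                          rgrConversion = c("response", "location")) {
    rgrConversion <- match.arg(rgrConversion)
    rgr <- c(overallRGR - rgrDelta / 2, overallRGR + rgrDelta / 2)
    if (any(rgr < 0) || any(rgr >= 1))
        stop("group rapid-guessing rates must lie in [0, 1); got ",
             paste(signif(rgr, 4), collapse = ", "))
    if (repair)
        Sigma <- repairSigma(Sigma)
    muPhi <- muPhiForRate(rgr, phiVar = Sigma[1L, 1L],
                          conversion = rgrConversion)
    thetaSD <- sqrt(Sigma[2L, 2L])
    new("SimulationCondition",
        conditionId = as.integer(conditionId),
        nPerGroup = rep_len(as.integer(nPerGroup), 2L),
        muTheta = c(-abilityGap / 2, abilityGap / 2),
        rgr = rgr,
        muPhi = muPhi,
        muTau = 0,
        Sigma = Sigma,
        bank = bank,
        trueD = abilityGap,
        trueMu = c(-abilityGap / 2, abilityGap / 2),
        trueSD = rep(thetaSD, 2L))
}

#' The twelve conditions of the study design
#'
#' The full 2 (overall RG rate: 5\% vs 15\%) x 2 (ability gap: 0.5 vs
#' 1.0 SD) x 3 (RG-rate difference: -5, 0, +5 points) crossed design,
#' with the canonical condition numbering (1-6 gap 0.5, 7-12 gap 1.0;
#' within each gap, overall rate 5\% then 15\%; within each rate,
#' delta -5\%, 0\%, +5\%).
#'
#' @param nPerGroup persons per group (default 1000).
#' @param bank item bank shared by all conditions.
#' @param Sigma person covariance shared by all conditions.
#' @param rgrConversion how group RG rates map to engagement means, see
#'   [muPhiForRate()].
#' @return a named list of 12 [SimulationCondition-class] objects.
#' @examples
#' conds <- tableConditions(nPerGroup = 50)
#' conds[["condition12"]]
#' @export
tableConditions <- function(nPerGroup = 1000L, bank = defaultItemBank(),
                            Sigma = defaultSigma(),
                            rgrConversion = c("response", "location")) {
    rgrConversion <- match.arg(rgrConversion)
    grid <- expand.grid(delta = c(-0.05, 0, 0.05),
                        overall = c(0.05, 0.15),
                        gap = c(0.5, 1.0))
    Sigma <- repairSigma(Sigma)
    conds <- lapply(seq_len(nrow(grid)), function(i) {
        makeCondition(grid$gap[i], grid$overall[i], grid$delta[i],
                      nPerGroup = nPerGroup, bank = bank, Sigma = Sigma,
                      conditionId = i, repair = FALSE,
                      rgrConversion = rgrConversion)
    })
    names(conds) <- paste0("condition", seq_len(nrow(grid)))
    conds
}

#' Load simulation conditions from a YAML config file
#'
#' The file maps condition names to either a canonical design cell id
#' (field \code{id} in 1..12) or the explicit factors \code{abilityGap},
#' \code{overallRGR}, \code{rgrDelta}. Optional override fields:
#' \code{nPerGroup}, \code{Sigma} (3x3, row-major list), and item bank
#' fields (\code{difficulty}, \code{timeIntensity}, \code{sbLogSD},
#' \code{guessProb}, \code{rgLogMean}, \code{rgLogSD}).
#'
#' @param path path to a YAML file.
#' @return a named list of [SimulationCondition-class] objects.
#' @export
readConditionConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    canonical <- NULL
    lapply(cfg, function(entry) {
        nPer <- entry$nPerGroup %||% 1000L
        Sigma <- if (!is.null(entry$Sigma))
            matrix(unlist(entry$Sigma), 3L, 3L, byrow = TRUE)
        else defaultSigma()
        bank <- if (!is.null(entry$difficulty))
            ItemBank(difficulty = unlist(entry$difficulty),
                     timeIntensity = unlist(entry$timeIntensity),
                     sbLogSD = entry$sbLogSD %||% 0.30,
                     guessProb = entry$guessProb %||% 0.25,
                     rgLogMean = entry$rgLogMean %||% 1.25,
                     rgLogSD = entry$rgLogSD %||% 0.60)
        else defaultItemBank()
        if (!is.null(entry$id)) {
            id <- as.integer(entry$id)
            if (id < 1L || id > 12L)
                stop("canonical condition id must be in 1..12, got ", id)
            grid <- expand.grid(delta = c(-0.05, 0, 0.05),
                                overall = c(0.05, 0.15),
                                gap = c(0.5, 1.0))
            makeCondition(grid$gap[id], grid$overall[id], grid$delta[id],
                          nPerGroup = nPer, bank = bank, Sigma = Sigma,
                          conditionId = id)
        } else {
            makeCondition(entry$abilityGap, entry$overallRGR,
                          entry$rgrDelta %||% 0, nPerGroup = nPer,
                          bank = bank, Sigma = Sigma)
        }
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname SimulationCondition-class
#' @param object a \code{SimulationCondition}.
#' @export
setMethod("show", "SimulationCondition", function(object) {
    id <- if (is.na(object@conditionId)) "ad hoc"
          else paste("design cell", object@conditionId)
    cat(sprintf("SimulationCondition (%s)\n", id))
    cat(sprintf("  N per group: %s\n",
                paste(object@nPerGroup, collapse = ", ")))
    cat(sprintf("  ability means: %+.2f / %+.2f (true d = %.2f)\n",
                object@muTheta[1L], object@muTheta[2L], object@trueD))
    cat(sprintf("  nominal RG rates: %.1f%% / %.1f%% (muPhi %.3f / %.3f)\n",
                100 * object@rgr[1L], 100 * object@rgr[2L],
                object@muPhi[1L], object@muPhi[2L]))
    cat(sprintf("  items: %d\n", nItems(object@bank)))
})
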