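#' Construct a causal-effect object
#'
#' Wraps an externally estimated causal effect (e.g. from any
#' Mendelian-randomization method) for use in the correction step.
#'
#' @param tau point estimate of the causal effect of the exposure on the
#'   outcome.
#' @param se optional standard error.
#' @param scale `"observed"` (default) or `"liability"`.
#' @param source provenance label, `"external"` (default) or `"greml_vp"`.
#' @return A [CausalEffect].
#' @export
causalEffect <- function(tau, se = NA_real_, scale = "observed",
                         source = "external") {
    new("CausalEffect", tau = tau, seTau = se, scale = scale, source = source)
}

#' Estimate the causal effect from vertical-pleiotropy variance components
#'
#' On a GRM built from vertical-pleiotropy SNPs the exposure and outcome
#' effects are independent by construction, so the fitted genetic
#' covariance satisfies `cov(g2, beta2) = tau * var(beta2)` and
#' `tau = cov(g2, beta2) / var(beta2)`.  The standard error follows from
#' the delta method on the ratio using the components' sampling
#' covariance: with `f = cg / vb`, the gradient is
#' `(1 / vb, -cg / vb^2)` over `(cg, vb)`.
#'
#' @param vpComponents a bivariate [VarComp] fitted on the
#'   vertical-pleiotropy SNP set (see [estimateVPComponents]).
#' @return A [CausalEffect] with `source = "greml_vp"`.
#' @export
estimateTau <- function(vpComponents) {
    stopifnot(is(vpComponents, "VarComp"))
    if (vpComponents@scope != "bivariate")
        stop("a bivariate fit is required")
    est <- vcEstimates(vpComponents)
    vb <- est[["vgC"]]
    cg <- est[["cg"]]
    if (!is.finite(vb) || vb <= 0)
        stop("var(beta2) estimate is not positive; the vertical-pleiotropy ",
             "SNP set carries no usable exposure signal")
    tau <- cg / vb
    Om <- omegaBlock(vpComponents, c("cg", "vgC"))
    se <- NA_real_
    if (all(is.finite(Om))) {
        g <- c(1 / vb, -cg / vb^2)
        v <- drop(g %*% Om %*% g)
        se <- if (v >= 0) sqrt(v) else NA_real_
    }
    causalEffect(tau, se, scale = vpComponents@scale, source = "greml_vp")
}

#' @rdname pleiodecomp-accessors
#' @export
setMethod("tauValue", "CausalEffect", function(x) x@tau)

#' @rdname pleiodecomp-accessors
#' @export
setMethod("tauSE", "CausalEffect", function(x) x@seTau)

#' @rdname pleiodecomp-accessors
#' @export
setMethod("tauScale", "CausalEffect", function(x) x@scale)

setMethod("show", "CausalEffect", function(object) {
    cat(sprintf("CausalEffect: tau = %.5g (se %s), %s scale, source %s\n",
                object@tau,
                if (is.na(object@seTau)) "NA" else sprintf("%.5g", object@seTau),
                object@scale, object@source))
})

#' Bias corrections for vertical pleiotropy
#'
#' Pure formulas removing the vertical-pleiotropy contribution from the
#' mis-specified bivariate model's estimates:
#' \describe{
#'   \item{`correctGencov(covGB, varB, tau)`}{genetic covariance attributed
#'     to horizontal pleiotropy, `cov(alpha, beta) = cov(g, beta) - tau * var(beta)`.}
#'   \item{`correctGenvar(varG, varB, covGB, tau)`}{corrected genetic
#'     variance `var(alpha) = var(g) - tau^2 var(beta) - 2 tau [cov(g, beta) - tau var(beta)]`.}
#'   \item{`correctedH2(varA, varY)`}{heritability `var(alpha) / var(y)`
#'     (with a standardized outcome, `var(y) = 1`).}
#'   \item{`correctedRg(varG, varB, covGB, tau)`}{corrected genetic
#'     correlation; `NA` with attribute `defined = FALSE` when the
#'     corrected genetic variance is not positive (complete-mediation
#'     regime).}
#' }
#' At `tau = 0` every correction is the identity.
#'
#' @param covGB genetic covariance `cov(g, beta)` from the standard
#'   bivariate fit.
#' @param varG,varB genetic variances of outcome (`var(g)`) and exposure
#'   (`var(beta)`).
#' @param tau causal effect.
#' @param varA corrected genetic variance. @param varY phenotypic variance
#'   of the outcome.
#' @return Numeric scalar (see details for `correctedRg`).
#' @export
correctGencov <- function(covGB, varB, tau) covGB - tau * varB

#' @rdname correctGencov
#' @export
correctGenvar <- function(varG, varB, covGB, tau)
    varG - tau^2 * varB - 2 * tau * (covGB - tau * varB)

#' @rdname correctGencov
#' @export
correctedH2 <- function(varA, varY = 1) {
    if (varY <= 0) stop("varY must be positive")
    varA / varY
}

#' @rdname correctGencov
#' @export
correctedRg <- function(varG, varB, covGB, tau) {
    covAB <- correctGencov(covGB, varB, tau)
    varA <- correctGenvar(varG, varB, covGB, tau)
    if (varA <= 1e-8 || varB <= 0)
        return(structure(NA_real_, defined = FALSE))
    structure(covAB / sqrt(varA * varB), defined = TRUE)
}

#' Delta-method standard errors of the corrected parameters
#'
#' Each corrected parameter is a smooth function `f` of the fitted variance
#' components, so its standard error is `sqrt(g' Omega g)` with `g` the
#' gradient of `f` and `Omega` the components' sampling covariance, taking
#' the causal effect as estimated without error:
#' \describe{
#'   \item{`seGencov(Omega2, tau)`}{2x2 `Omega` over
#'     `(cov(g,beta), var(beta))`; gradient `(1, -tau)`.}
#'   \item{`seGenvar(Omega3, tau)`}{3x3 `Omega` over
#'     `(var(g), var(beta), cov(g,beta))`; gradient `(1, tau^2, -2 tau)`.}
#'   \item{`seRg(Omega3, varG, varB, covGB, tau)`}{same 3x3 `Omega`;
#'     analytic gradient of the corrected-correlation composite.}
#' }
#'
#' @param Omega2,Omega3 symmetric sampling-covariance blocks (see above
#'   for the component order).
#' @inheritParams correctGencov
#' @return Standard error (numeric scalar).
#' @export
seGencov <- function(Omega2, tau) {
    stopifnot(identical(dim(Omega2), c(2L, 2L)))
    g <- c(1, -tau)
    v <- drop(g %*% Omega2 %*% g)
    if (is.na(v)) return(NA_real_)
    if (v < 0) stop("negative delta-method variance: invalid Omega")
    sqrt(v)
}

#' @rdname seGencov
#' @export
seGenvar <- function(Omega3, tau) {
    stopifnot(identical(dim(Omega3), c(3L, 3L)))
    g <- c(1, tau^2, -2 * tau)
    v <- drop(g %*% Omega3 %*% g)
    if (is.na(v)) return(NA_real_)
    if (v < 0) stop("negative delta-method variance: invalid Omega")
    sqrt(v)
}

## gradient of the corrected genetic correlation in (varG, varB, covGB)
.rgGradient <- function(varG, varB, covGB, tau) {
    A <- covGB - tau * varB            # corrected covariance
    V <- varG - tau^2 * varB - 2 * tau * A  # corrected variance
    S <- sqrt(V * varB)
    dG <- -A * varB / (2 * S^3)
    dB <- -tau / S - A / (2 * S^3) * (tau^2 * varB + V)
    dC <- 1 / S + A * tau * varB / S^3
    c(dG, dB, dC)
}

#' @rdname seGencov
#' @export
seRg <- function(Omega3, varG, varB, covGB, tau) {
    stopifnot(identical(dim(Omega3), c(3L, 3L)))
    varA <- correctGenvar(varG, varB, covGB, tau)
    if (varA <= 1e-8 || varB <= 0)
        stop("corrected genetic variance is not positive; ",
             "the corrected correlation (and its se) is undefined")
    g <- .rgGradient(varG, varB, covGB, tau)
    v <- drop(g %*% Omega3 %*% g)
    if (is.na(v)) return(NA_real_)
    if (v < 0) stop("negative delta-method variance: invalid Omega")
    sqrt(v)
}

## partial derivatives of the corrected quantities with respect to tau,
## used by the optional extended delta method
.tauDerivs <- function(varG, varB, covGB, tau) {
    A <- covGB - tau * varB
    V <- varG - tau^2 * varB - 2 * tau * A
    dV <- 2 * tau * varB - 2 * covGB
    S <- sqrt(V * varB)
    c(covAB = -varB,
      varA = dV,
      rg = if (V > 1e-8) -varB / S - A / (2 * S^3) * varB * dV else NA_real_)
}

## shared assembly used by the individual-level and summary paths
.assembleCorrected <- function(varG, varB, covGB, Omega3, tau, varY = 1,
                               seTau = NA_real_) {
    covAB <- correctGencov(covGB, varB, tau)
    varA <- correctGenvar(varG, varB, covGB, tau)
    rg <- correctedRg(varG, varB, covGB, tau)
    defined <- isTRUE(attr(rg, "defined"))
    ## clamp a numerically-zero corrected variance for h2 reporting only;
    ## clearly negative estimates pass through (and flag rg undefined)
    h2 <- correctedH2(if (varA > -1e-8 && varA <= 0) 0 else varA, varY)
    seC <- seGencov(Omega3[c("covGB", "varB"), c("covGB", "varB")], tau)
    seV <- seGenvar(Omega3[c("varG", "varB", "covGB"),
                           c("varG", "varB", "covGB")], tau)
    seR <- if (defined)
        seRg(Omega3[c("varG", "varB", "covGB"), c("varG", "varB", "covGB")],
             varG, varB, covGB, tau) else NA_real_
    if (!is.na(seTau)) {
        ## extended delta method: add the (independent) tau contribution
        dtau <- .tauDerivs(varG, varB, covGB, tau)
        seC <- sqrt(seC^2 + (dtau[["covAB"]] * seTau)^2)
        seV <- sqrt(seV^2 + (dtau[["varA"]] * seTau)^2)
        if (defined) seR <- sqrt(seR^2 + (dtau[["rg"]] * seTau)^2)
    }
    ## uncorrected counterparts (tau = 0 gradients)
    uncRg <- if (varG > 0 && varB > 0) covGB / sqrt(varG * varB) else NA_real_
    seUncC <- sqrt(Omega3["covGB", "covGB"])
    seUncV <- sqrt(Omega3["varG", "varG"])
    seUncR <- if (!is.na(uncRg) && varG > 1e-8) {
        g <- .rgGradient(varG, varB, covGB, 0)
        v <- drop(g %*% Omega3[c("varG", "varB", "covGB"),
                               c("varG", "varB", "covGB")] %*% g)
        if (!is.na(v) && v >= 0) sqrt(v) else NA_real_
    } else NA_real_
    list(
        corrected = c(covAB = covAB, varA = varA, h2 = h2,
                      rg = as.numeric(rg)),
        se = c(covAB = seC, varA = seV, h2 = seV / varY, rg = seR),
        uncorrected = c(covGB = covGB, varG = varG, h2 = varG / varY,
                        rg = uncRg, se.covGB = seUncC, se.varG = seUncV,
                        se.h2 = seUncV / varY, se.rg = seUncR),
        rgDefined = defined)
}

#' Correct bivariate GREML estimates for vertical pleiotropy
#'
#' Applies the full correction pipeline to a bivariate variance-component
#' fit: corrected genetic covariance, genetic variance, heritability and
#' genetic correlation, each with a delta-method standard error taking the
#' causal effect as estimated without error.  The 2x2 and 3x3 sampling
#' covariance blocks are sub-selected from the fit's full 6x6 inverse
#' average-information matrix.  With `tau = 0` the output equals the input
#' estimates (and standard errors) exactly.
#'
#' When the corrected genetic variance falls in `(-1e-8, 0]` it is clamped
#' to zero for heritability reporting and the corrected correlation is
#' flagged undefined rather than imaginary (the complete-mediation regime
#' sits exactly on this boundary).
#'
#' @param varcomp a bivariate [VarComp] from genome-wide SNPs.
#' @param causalEffect a [CausalEffect] on the same scale as the
#'   components.
#' @param varY phenotypic variance of the outcome (1 for a standardized
#'   trait).
#' @param propagateTauSE logical; when `TRUE`, the causal effect's own
#'   standard error is additionally propagated through an extended
#'   gradient (treating the tau estimate as independent of the
#'   components).  Off by default: the published correction treats tau
#'   as error-free, and in practice the positive correlation between the
#'   tau and covariance estimates makes the error-free form well
#'   calibrated while the extended form is conservative.
#' @return A [CorrectedParams].
#' @export
hvpCorrect <- function(varcomp, causalEffect, varY = 1,
                       propagateTauSE = FALSE) {
    stopifnot(is(varcomp, "VarComp"), is(causalEffect, "CausalEffect"))
    if (varcomp@scope != "bivariate")
        stop("a bivariate fit is required")
    if (varcomp@scale != causalEffect@scale)
        stop("scale mismatch: components are on the ", varcomp@scale,
             " scale but tau is on the ", causalEffect@scale, " scale")
    if (propagateTauSE && is.na(tauSE(causalEffect)))
        stop("propagateTauSE = TRUE requires a causal effect with a ",
             "standard error")
    est <- vcEstimates(varcomp)
    Om <- omegaBlock(varcomp, c("vgY", "vgC", "cg"))
    dimnames(Om) <- list(c("varG", "varB", "covGB"),
                         c("varG", "varB", "covGB"))
    parts <- .assembleCorrected(est[["vgY"]], est[["vgC"]], est[["cg"]],
                                Om, tauValue(causalEffect), varY,
                                seTau = if (propagateTauSE)
                                    tauSE(causalEffect) else NA_real_)
    new("CorrectedParams", corrected = parts$corrected, se = parts$se,
        uncorrected = parts$uncorrected, rgDefined = parts$rgDefined,
        tauUsed = causalEffect, scale = varcomp@scale, seMethod = "delta")
}

#' @rdname pleiodecomp-accessors
#' @export
setMethod("correctedEstimates", "CorrectedParams", function(x) x@corrected)

#' @rdname pleiodecomp-accessors
#' @export
setMethod("correctedSE", "CorrectedParams", function(x) x@se)

setMethod("show", "CorrectedParams", function(object) {
    cat(sprintf("CorrectedParams (%s scale, %s se): tau = %.4g [%s]\n",
                object@scale, object@seMethod, tauValue(object@tauUsed),
                object@tauUsed@source))
    unc <- object@uncorrected
    tab <- data.frame(
        uncorrected = unc[c("covGB", "varG", "h2", "rg")],
        se.unc = unc[c("se.covGB", "se.varG", "se.h2", "se.rg")],
        corrected = object@corrected,
        se.corr = object@se,
        row.names = c("gen. covariance", "gen. variance", "heritability",
                      "gen. correlation"))
    print(round(tab, 5))
    if (!object@rgDefined)
        cat("  corrected genetic correlation undefined ",
            "(corrected genetic variance <= 0)\n", sep = "")
})

#' Write a corrected-parameter report
#'
#' Human-readable text table plus a machine-readable JSON sidecar
#' (`<prefix>.json`) with estimates, standard errors, Wald z p-values and
#' the causal-effect provenance.
#'
#' @param x a [CorrectedParams].
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
writeCorrected <- function(x, prefix) {
    stopifnot(is(x, "CorrectedParams"))
    paths <- paste0(prefix, c(".txt", ".json"))
    unc <- x@uncorrected
    wald <- function(est, se) 2 * pnorm(-abs(est / se))
    rows <- c("covAB", "varA", "h2", "rg")
    urows <- c("covGB", "varG", "h2", "rg")
    tab <- data.frame(
        parameter = c("genetic covariance", "genetic variance",
                      "heritability", "genetic correlation"),
        uncorrected = unname(unc[urows]),
        se_uncorrected = unname(unc[paste0("se.", urows)]),
        corrected = unname(x@corrected[rows]),
        se_corrected = unname(x@se[rows]))
    tab$p_corrected <- wald(tab$corrected, tab$se_corrected)
    con <- file(paths[1L], "w")
    writeLines(c(
        sprintf("scale: %s", x@scale),
        sprintf("se method: %s", x@seMethod),
        sprintf("tau: %.6g (se %s, source %s, %s scale)",
                tauValue(x@tauUsed),
                format(tauSE(x@tauUsed)), x@tauUsed@source,
                tauScale(x@tauUsed)),
        sprintf("corrected rg defined: %s", x@rgDefined), ""), con)
    utils::write.table(format(tab, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    jsonlite::write_json(list(
        scale = x@scale, seMethod = x@seMethod,
        tau = list(value = tauValue(x@tauUsed), se = tauSE(x@tauUsed),
                   source = x@tauUsed@source, scale = tauScale(x@tauUsed)),
        rgDefined = x@rgDefined,
        corrected = as.list(x@corrected), se = as.list(x@se),
        uncorrected = as.list(unc)),
        paths[2L], auto_unbox = TRUE, digits = NA, na = "null")
    invisible(paths)
}
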