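#' Prevalence context for a binary trait
#'
#' For population prevalence `k`, computes the liability threshold
#' `t = -qnorm(k)` and the standard-normal density height `z = dnorm(t)`,
#' the two quantities driving all observed/liability transformations.
#' Sample prevalence is taken to equal population prevalence (no
#' ascertainment correction).
#'
#' @param k prevalence in (0,1).
#' @param label optional trait label.
#' @return A [PrevalenceContext].
#' @examples
#' prevalenceContext(0.5)  # t = 0, z = 0.3989
#' @export
prevalenceContext <- function(k, label = "") {
    if (length(k) != 1L || !is.finite(k) || k <= 0 || k >= 1)
        stop("prevalence k must lie in (0,1)")
    t <- -qnorm(k)
    new("PrevalenceContext", k = k, t = t, z = dnorm(t), label = label)
}

setMethod("show", "PrevalenceContext", function(object) {
    cat(sprintf("PrevalenceContext%s: k = %.4g, t = %.5g, z = %.5g\n",
                if (nzchar(object@label)) paste0(" (", object@label, ")")
                else "", object@k, object@t, object@z))
})

## per-trait factor: z^2 / (k (1-k)) maps liability -> observed for
## proportion-of-variance parameters; a quantitative trait contributes 1
.ctxFactor <- function(ctx) {
    if (is.null(ctx)) return(1)
    stopifnot(is(ctx, "PrevalenceContext"))
    ctx@z^2 / (ctx@k * (1 - ctx@k))
}

.ctxZ <- function(ctx) {
    if (is.null(ctx)) return(1)
    stopifnot(is(ctx, "PrevalenceContext"))
    ctx@z
}

#' Observed/liability scale transformations
#'
#' Transformations between the observed (0/1) and liability scales for
#' every parameter of the model.  With `z` the density at the threshold
#' and `k` the prevalence:
#' \describe{
#'   \item{heritability, R2}{`x_obs = x_liab * z^2 / (k (1-k))`.}
#'   \item{genetic covariance}{`cov_obs = cov_liab * z_y * z_c`.}
#'   \item{genetic variance}{`var_obs = z_y^2 * var_liab`.}
#'   \item{causal effect}{`tau_obs = tau_liab * (z_y / z_c) * sqrt(var(c) / var(y))`
#'     with observed-scale phenotypic variances (for a 0/1 trait,
#'     `k (1-k)`).}
#' }
#' A quantitative trait passes `NULL` for its context and contributes a
#' factor of one, so mixed binary/quantitative pairs transform only the
#' binary member.  Every `*ObsToLiab` function composes with its
#' `*LiabToObs` inverse to the identity, and the genetic correlation is
#' invariant under the transformation.
#'
#' @param h2Obs,h2Liab,r2Obs,r2Liab,covObs,covLiab,varObs,varLiab,tauObs,tauLiab
#'   the value to transform.
#' @param ctx,ctxY,ctxC [PrevalenceContext] of the (binary) trait(s);
#'   `NULL` for a quantitative trait.
#' @param varC,varY observed-scale phenotypic variances of exposure and
#'   outcome used by the causal-effect transform.
#' @return Transformed numeric scalar.
#' @name liability-transforms
NULL

#' @rdname liability-transforms
#' @export
h2ObsToLiab <- function(h2Obs, ctx) h2Obs / .ctxFactor(ctx)

#' @rdname liability-transforms
#' @export
h2LiabToObs <- function(h2Liab, ctx) h2Liab * .ctxFactor(ctx)

#' @rdname liability-transforms
#' @export
r2ObsToLiab <- function(r2Obs, ctx) r2Obs / .ctxFactor(ctx)

#' @rdname liability-transforms
#' @export
r2LiabToObs <- function(r2Liab, ctx) r2Liab * .ctxFactor(ctx)

#' @rdname liability-transforms
#' @export
gencovObsToLiab <- function(covObs, ctxY = NULL, ctxC = NULL)
    covObs / (.ctxZ(ctxY) * .ctxZ(ctxC))

#' @rdname liability-transforms
#' @export
gencovLiabToObs <- function(covLiab, ctxY = NULL, ctxC = NULL)
    covLiab * .ctxZ(ctxY) * .ctxZ(ctxC)

#' @rdname liability-transforms
#' @export
genvarObsToLiab <- function(varObs, ctxY = NULL) varObs / .ctxZ(ctxY)^2

#' @rdname liability-transforms
#' @export
genvarLiabToObs <- function(varLiab, ctxY = NULL) varLiab * .ctxZ(ctxY)^2

#' @rdname liability-transforms
#' @export
tauObsToLiab <- function(tauObs, ctxY = NULL, ctxC = NULL, varC = 1,
                         varY = 1) {
    if (varC <= 0 || varY <= 0) stop("phenotypic variances must be positive")
    tauObs * .ctxZ(ctxC) / .ctxZ(ctxY) * sqrt(varY / varC)
}

#' @rdname liability-transforms
#' @export
tauLiabToObs <- function(tauLiab, ctxY = NULL, ctxC = NULL, varC = 1,
                         varY = 1) {
    if (varC <= 0 || varY <= 0) stop("phenotypic variances must be positive")
    tauLiab * .ctxZ(ctxY) / .ctxZ(ctxC) * sqrt(varC / varY)
}

#' Transform a bivariate fit's genetic components to the liability scale
#'
#' Rescales the genetic components (`vgY`, `vgC`, `cg`) of an
#' observed-scale bivariate [VarComp] to the liability scale
#' (`var(g)` divided by `z^2`, the covariance by `z_y * z_c`), with the
#' sampling covariance transformed by the same linear map.  Residual
#' components are artefacts of the linear model on 0/1 data and have no
#' liability counterpart; they are carried through unchanged and the
#' result is flagged `"residuals_on_observed_scale"`.  The correction step
#' only consumes the genetic block.
#'
#' @param vc an observed-scale bivariate [VarComp] fitted on 0/1 traits.
#' @param ctxY,ctxC [PrevalenceContext] for the binary trait(s); `NULL`
#'   for a quantitative member.
#' @return A liability-scale [VarComp].
#' @export
liabilityVarComp <- function(vc, ctxY = NULL, ctxC = NULL) {
    stopifnot(is(vc, "VarComp"))
    if (vc@scope != "bivariate") stop("a bivariate fit is required")
    if (vc@scale != "observed") stop("components are already on the ",
                                     vc@scale, " scale")
    zy <- .ctxZ(ctxY); zc <- .ctxZ(ctxC)
    fac <- c(vgY = 1 / zy^2, vgC = 1 / zc^2, cg = 1 / (zy * zc),
             veY = 1, veC = 1, ce = 1)
    est <- vcEstimates(vc) * fac
    Om <- samplingCov(vc) * outer(fac, fac)
    new("VarComp", scope = vc@scope, estimates = est, Omega = Om,
        loglik = vc@loglik, nUsed = vc@nUsed, iterations = vc@iterations,
        converged = vc@converged,
        flags = union(vc@flags, "residuals_on_observed_scale"),
        scale = "liability")
}
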