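#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats qnorm dnorm rnorm rbinom var cov sd complete.cases pnorm quantile setNames
NULL

.isPSD <- function(M, tol = 1e-8) {
    if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

#' Generative truth for one simulation scenario
#'
#' A `ScenarioConfig` holds everything needed to simulate a bivariate cohort
#' under the pleiotropy decomposition model: the 2x2 genetic
#' variance-covariance blocks for the horizontal-pleiotropy SNP set
#' (`G1`, effects alpha1/beta1) and the vertical-pleiotropy SNP set
#' (`G2`, effects alpha2/beta2), the residual block `R` for (e, eps), the
#' causal effect `tau` of the exposure on the outcome, SNP counts, allele
#' frequency and optional prevalences for dichotomization.
#'
#' The residual variance of the outcome, `R[1,1]`, is always computed by the
#' balancing formula
#' `var(e) = 1 - var(alpha) - tau^2 * var(c) - 2 tau (cov(alpha,beta) + cov(e,eps))`
#' with `var(c) = var(beta) + var(eps)`, so the phenotypic variance of the
#' outcome equals one.
#'
#' @slot scenarioId integer, 1 to 5.
#' @slot n integer, number of individuals.
#' @slot mHP,mVP integer SNP counts for the horizontal- and
#'   vertical-pleiotropy sets (the VP set is split half exposure / half
#'   outcome).
#' @slot maf allele frequency in (0, 0.5].
#' @slot tau numeric causal effect of the exposure on the outcome.
#' @slot G1,G2 2x2 genetic variance-covariance blocks.
#' @slot R 2x2 residual block with the computed `var(e)` in `[1,1]`.
#' @slot kY,kC optional prevalences in (0,1) for binary copies of the
#'   outcome / exposure (`NA_real_` when the trait stays quantitative).
#' @export
setClass("ScenarioConfig",
    representation(
        scenarioId = "integer", n = "integer", mHP = "integer",
        mVP = "integer", maf = "numeric", tau = "numeric",
        G1 = "matrix", G2 = "matrix", R = "matrix",
        kY = "numeric", kC = "numeric"
    )
)

setValidity("ScenarioConfig", function(object) {
    msg <- character()
    if (!object@scenarioId %in% 1:5) msg <- c(msg, "scenarioId must be in 1..5")
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (object@mHP < 1L || object@mVP < 2L)
        msg <- c(msg, "SNP counts must be positive (mVP >= 2)")
    if (object@mVP %% 2L != 0L) msg <- c(msg, "mVP must be even (half exposure, half outcome)")
    if (!(object@maf > 0 && object@maf <= 0.5)) msg <- c(msg, "maf must be in (0, 0.5]")
    if (!is.finite(object@tau)) msg <- c(msg, "tau must be finite")
    if (!.isPSD(object@G1)) msg <- c(msg, "G1 must be symmetric positive semi-definite")
    if (!.isPSD(object@G2)) msg <- c(msg, "G2 must be symmetric positive semi-definite")
    if (object@R[1L, 1L] <= 0)
        msg <- c(msg, sprintf(
            "balancing residual variance var(e) = %.4f is not positive; tau is too large for this scenario",
            object@R[1L, 1L]))
    for (k in c(object@kY, object@kC))
        if (!is.na(k) && !(k > 0 && k < 1)) msg <- c(msg, "prevalences must lie in (0,1)")
    if (length(msg)) msg else TRUE
})

#' Simulated bivariate cohort
#'
#' A `PleioCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' one `"dosage"` assay (SNPs in rows, individuals in columns).  `rowData`
#' carries the SNP-set label (`"hp"`, `"vp_exposure"`, `"vp_outcome"`);
#' `colData` carries the latent genetic values (`alpha1`, `alpha2`, `beta1`,
#' `beta2`), the residuals (`e`, `eps`), the phenotypes (`y`, `c`) and, when
#' prevalences were set, their binary copies (`yBin`, `cBin`).  The
#' generating [ScenarioConfig] is stored in `metadata(x)$config`.
#'
#' @export
setClass("PleioCohort", contains = "SummarizedExperiment")

setValidity("PleioCohort", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    if (!"set" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData column 'set' is required")
    need <- c("alpha1", "alpha2", "beta1", "beta2", "e", "eps", "y", "c")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss)) msg <- c(msg, paste("missing colData columns:",
                                          paste(miss, collapse = ", ")))
    cfg <- S4Vectors::metadata(object)$config
    if (!is(cfg, "ScenarioConfig")) msg <- c(msg, "metadata(x)$config must be a ScenarioConfig")
    if (length(msg)) msg else TRUE
})

#' Variance-component estimates with sampling covariance
#'
#' Holds univariate (`vg`, `ve`) or bivariate
#' (`vgY`, `vgC`, `cg`, `veY`, `veC`, `ce`) REML estimates together with the
#' inverse average-information matrix `Omega` (their approximate sampling
#' covariance), the restricted log-likelihood, and convergence diagnostics.
#' In the mis-specified bivariate model the components correspond to
#' var(g), var(beta) and cov(g, beta) plus the residual block.
#'
#' @slot scope `"univariate"` or `"bivariate"`.
#' @slot estimates named numeric vector of variance components.
#' @slot Omega sampling covariance matrix of the estimates (dimnames match
#'   `estimates`).
#' @slot loglik restricted log-likelihood at convergence (constant terms
#'   dropped).
#' @slot nUsed number of individuals used.
#' @slot iterations accepted REML iterations.
#' @slot converged logical convergence flag.
#' @slot flags character vector of diagnostic flags (e.g.
#'   `"singular_information"`, `"boundary"`).
#' @slot scale `"observed"` or `"liability"`.
#' @export
setClass("VarComp",
    representation(
        scope = "character", estimates = "numeric", Omega = "matrix",
        loglik = "numeric", nUsed = "integer", iterations = "integer",
        converged = "logical", flags = "character", scale = "character"
    )
)

setValidity("VarComp", function(object) {
    msg <- character()
    if (!object@scope %in% c("univariate", "bivariate"))
        msg <- c(msg, "scope must be 'univariate' or 'bivariate'")
    p <- if (object@scope == "univariate") 2L else 6L
    if (length(object@estimates) != p)
        msg <- c(msg, sprintf("expected %d components", p))
    if (!identical(dim(object@Omega), c(p, p)))
        msg <- c(msg, "Omega dimension must match the components")
    ## an all-NA Omega marks a singular information matrix and is allowed
    if (!anyNA(object@Omega)) {
        if (!isSymmetric(unname(object@Omega), tol = 1e-6))
            msg <- c(msg, "Omega must be symmetric")
        if (any(diag(object@Omega) < -1e-10))
            msg <- c(msg, "Omega diagonal must be >= 0")
    }
    if (!object@scale %in% c("observed", "liability"))
        msg <- c(msg, "scale must be 'observed' or 'liability'")
    if (length(msg)) msg else TRUE
})

#' Causal-effect estimate
#'
#' The causal effect `tau` of the exposure on the outcome, either estimated
#' internally by GREML on a vertical-pleiotropy SNP set
#' ([estimateTau]) or supplied externally from any Mendelian-randomization
#' method.
#'
#' @slot tau numeric estimate.
#' @slot seTau standard error (may be `NA_real_` for an external point value).
#' @slot scale `"observed"` or `"liability"`.
#' @slot source `"greml_vp"` or `"external"`.
#' @export
setClass("CausalEffect",
    representation(tau = "numeric", seTau = "numeric", scale = "character",
                   source = "character")
)

setValidity("CausalEffect", function(object) {
    msg <- character()
    if (!is.finite(object@tau)) msg <- c(msg, "tau must be finite")
    if (!is.na(object@seTau) && object@seTau < 0) msg <- c(msg, "seTau must be >= 0")
    if (!object@scale %in% c("observed", "liability"))
        msg <- c(msg, "scale must be 'observed' or 'liability'")
    if (!object@source %in% c("greml_vp", "external"))
        msg <- c(msg, "source must be 'greml_vp' or 'external'")
    if (length(msg)) msg else TRUE
})

#' Corrected genetic parameters
#'
#' Output of [hvpCorrect] / [correctSummary]: the genetic covariance,
#' genetic variance, heritability and genetic correlation attributed to
#' horizontal pleiotropy (vertical-pleiotropy bias removed), each with a
#' delta-method (or jackknife) standard error, alongside the uncorrected
#' inputs.
#'
#' @slot corrected named numeric: `covAB`, `varA`, `h2`, `rg`.
#' @slot se named numeric standard errors for the same four quantities.
#' @slot uncorrected named numeric: the input `covGB`, `varG`, `h2`, `rg`
#'   and their standard errors (`se.` prefix).
#' @slot rgDefined logical; `FALSE` when the corrected genetic variance is
#'   not positive so the corrected correlation is undefined (complete
#'   mediation regime).
#' @slot tauUsed the [CausalEffect] consumed.
#' @slot scale `"observed"` or `"liability"`.
#' @slot seMethod `"delta"` or `"jackknife"`.
#' @export
setClass("CorrectedParams",
    representation(
        corrected = "numeric", se = "numeric", uncorrected = "numeric",
        rgDefined = "logical", tauUsed = "CausalEffect", scale = "character",
        seMethod = "character"
    )
)

#' Prevalence context for liability transforms
#'
#' For a binary trait with population prevalence `k`, the liability
#' threshold is `t = -qnorm(k)` and `z = dnorm(t)` is the standard-normal
#' density height at the threshold.  These two numbers drive every
#' observed/liability transformation.
#'
#' @slot k prevalence in (0,1).
#' @slot t liability threshold.
#' @slot z normal density at the threshold.
#' @slot label trait label (informational).
#' @export
setClass("PrevalenceContext",
    representation(k = "numeric", t = "numeric", z = "numeric",
                   label = "character")
)

setValidity("PrevalenceContext", function(object) {
    msg <- character()
    if (!(object@k > 0 && object@k < 1)) msg <- c(msg, "k must lie in (0,1)")
    if (abs(object@t - (-qnorm(object@k))) > 1e-8) msg <- c(msg, "t must equal -qnorm(k)")
    if (abs(object@z - dnorm(object@t)) > 1e-8) msg <- c(msg, "z must equal dnorm(t)")
    if (length(msg)) msg else TRUE
})

#' Summary-level (LDSC-style) estimates
#'
#' The triple (var(g), var(beta), cov(g,beta)) from a summary-statistics
#' front end such as LD score regression, with uncertainty carried either
#' as a 3x3 sampling covariance `Omega` or as per-block delete-one
#' jackknife estimates of the triple.
#'
#' @slot vgY,vgC,cg point estimates of var(g), var(beta), cov(g, beta).
#' @slot Omega 3x3 sampling covariance (0x0 matrix when absent).
#' @slot blocks B x 3 matrix of delete-one-block estimates, columns
#'   (vgY, vgC, cg) (0x0 when absent).
#' @export
setClass("SummaryEstimates",
    representation(vgY = "numeric", vgC = "numeric", cg = "numeric",
                   Omega = "matrix", blocks = "matrix")
)

setValidity("SummaryEstimates", function(object) {
    msg <- character()
    hasO <- length(object@Omega) > 0L
    hasB <- length(object@blocks) > 0L
    if (!hasO && !hasB)
        msg <- c(msg, "either Omega or jackknife blocks must be supplied")
    if (hasO) {
        if (!identical(dim(object@Omega), c(3L, 3L)))
            msg <- c(msg, "Omega must be 3x3")
        else if (!isSymmetric(unname(object@Omega), tol = 1e-6))
            msg <- c(msg, "Omega must be symmetric")
    }
    if (hasB) {
        if (ncol(object@blocks) != 3L) msg <- c(msg, "blocks must have 3 columns")
        if (nrow(object@blocks) < 2L) msg <- c(msg, "at least 2 jackknife blocks required")
    }
    if (length(msg)) msg else TRUE
})
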