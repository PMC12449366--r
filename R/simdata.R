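## Scenario library: genetic blocks for the horizontal-pleiotropy (HP) SNP
## set (alpha1, beta1) and the vertical-pleiotropy (VP) set (alpha2, beta2).
## Scenarios 1 and 4 are printed as a single genetic block with zero
## covariance; the split across the two SNP sets is even (all aggregate
## moments and the VP-set tau estimator are invariant to the split).
.scenarioBlocks <- list(
    `1` = list(G1 = diag(c(0.25, 0.25)),
               G2 = diag(c(0.25, 0.25)), ce = 0),
    `2` = list(G1 = matrix(c(0.35, 0.25, 0.25, 0.26), 2L),
               G2 = diag(c(0.15, 0.24)), ce = 0),
    `3` = list(G1 = matrix(c(0.35, 0.25, 0.25, 0.26), 2L),
               G2 = diag(c(0.15, 0.24)), ce = 0.1),
    `4` = list(G1 = diag(c(0, 0.25)),
               G2 = diag(c(0, 0.25)), ce = 0),
    `5` = list(G1 = matrix(c(0.5, 0.25, 0.25, 0.26), 2L),
               G2 = diag(c(0, 0.24)), ce = 0)
)

#' Build the generative configuration for one simulation scenario
#'
#' Returns the exact variance-covariance structure of one of the five
#' validation scenarios:
#' \enumerate{
#'   \item vertical pleiotropy only (total genetic block `diag(0.5, 0.5)`,
#'     no genetic or residual covariance);
#'   \item vertical plus horizontal pleiotropy
#'     (`G1 = [[0.35, 0.25], [0.25, 0.26]]`, `G2 = diag(0.15, 0.24)`);
#'   \item scenario 2 plus residual covariance `cov(e, eps) = 0.1`;
#'   \item complete mediation: no direct genetic effect on the outcome
#'     (`var(alpha) = 0`, `var(beta) = 0.5`);
#'   \item horizontal pleiotropy only for the outcome-specific SNPs
#'     (`G1 = [[0.5, 0.25], [0.25, 0.26]]`, `G2 = diag(0, 0.24)`).
#' }
#' `var(eps) = 0.5` throughout, and `var(e)` is computed by the balancing
#' formula `1 - var(alpha) - tau^2 - 2 tau (cov(alpha,beta) + cov(e,eps))`
#' (the `tau^2` term carries the unit phenotypic variance of the exposure),
#' which keeps `var(y) = 1`.
#'
#' @param scenario integer 1..5.
#' @param tau causal effect of the exposure on the outcome; may be negative.
#'   Values making the balancing `var(e)` non-positive are rejected.
#' @param n number of individuals (default 10000).
#' @param mHP,mVP SNP counts for the two sets (defaults 1000 each; the VP
#'   set is split half exposure / half outcome).
#' @param maf allele frequency in (0, 0.5], default 0.2.
#' @param kY,kC optional prevalences for binary copies of the outcome /
#'   exposure.
#' @return A [ScenarioConfig].
#' @examples
#' cfg <- makeScenario(2, tau = 0.4, n = 2000)
#' residualBlock(cfg)[1, 1]  # balancing var(e) = 0.14
#' @export
makeScenario <- function(scenario, tau, n = 10000L, mHP = 1000L, mVP = 1000L,
                         maf = 0.2, kY = NA_real_, kC = NA_real_) {
    scenario <- as.integer(scenario)
    if (length(scenario) != 1L || is.na(scenario) || !scenario %in% 1:5)
        stop("unknown scenario id: must be an integer in 1..5")
    if (!is.finite(tau)) stop("tau must be finite")
    b <- .scenarioBlocks[[as.character(scenario)]]
    varEps <- 0.5
    varA <- b$G1[1L, 1L] + b$G2[1L, 1L]
    varB <- b$G1[2L, 2L] + b$G2[2L, 2L]
    covAB <- b$G1[1L, 2L] + b$G2[1L, 2L]
    varC <- varB + varEps
    varE <- 1 - varA - tau^2 * varC - 2 * tau * (covAB + b$ce)
    R <- matrix(c(varE, b$ce, b$ce, varEps), 2L,
                dimnames = list(c("e", "eps"), c("e", "eps")))
    new("ScenarioConfig", scenarioId = scenario, n = as.integer(n),
        mHP = as.integer(mHP), mVP = as.integer(mVP), maf = maf, tau = tau,
        G1 = b$G1, G2 = b$G2, R = R, kY = kY, kC = kC)
}

#' @describeIn makeScenario the residual 2x2 block (e, eps) of a config.
#' @param x a [ScenarioConfig].
#' @export
residualBlock <- function(x) x@R

#' @describeIn makeScenario the HP-set and VP-set genetic blocks as a list.
#' @export
geneticBlocks <- function(x) list(G1 = x@G1, G2 = x@G2)

#' Population parameters implied by a scenario configuration
#'
#' Forward-composes the generative truth into the quantities the
#' mis-specified bivariate model estimates: the biased genetic variance
#' `var(g) = var(alpha) + tau^2 var(beta) + 2 tau cov(alpha, beta)` and
#' covariance `cov(g, beta) = cov(alpha, beta) + tau var(beta)`, alongside
#' the horizontal-pleiotropy targets `var(alpha)`, `cov(alpha, beta)`,
#' heritability and genetic correlation.  `rg` is `NA` when
#' `var(alpha) = 0` (complete mediation).
#'
#' @param config a [ScenarioConfig].
#' @return Named numeric vector.
#' @export
impliedParams <- function(config) {
    stopifnot(is(config, "ScenarioConfig"))
    tau <- config@tau
    varA <- config@G1[1L, 1L] + config@G2[1L, 1L]
    varB <- config@G1[2L, 2L] + config@G2[2L, 2L]
    covAB <- config@G1[1L, 2L] + config@G2[1L, 2L]
    varG <- varA + tau^2 * varB + 2 * tau * covAB
    covGB <- covAB + tau * varB
    varC <- varB + config@R[2L, 2L]
    c(tau = tau, varA = varA, varB = varB, covAB = covAB,
      varE = config@R[1L, 1L], varEps = config@R[2L, 2L],
      ce = config@R[1L, 2L], varY = 1, varC = varC,
      varG = varG, covGB = covGB,
      h2Y = varA, h2C = varB / varC,
      rg = if (varA > 0) covAB / sqrt(varA * varB) else NA_real_,
      covYC = covAB + config@R[1L, 2L] + tau * varC)
}

#' Simulate a genotype dosage matrix
#'
#' Independent SNPs with dosages drawn from Binomial(2, maf), one column
#' per SNP.
#'
#' @param n individuals. @param m SNPs. @param maf allele frequency in
#'   (0, 0.5].
#' @param seed optional integer seed for reproducible draws.
#' @return Integer matrix, `n` x `m`.
#' @export
simulateGenotypes <- function(n, m, maf, seed = NULL) {
    if (length(maf) != 1L || !is.finite(maf) || maf <= 0 || maf > 0.5)
        stop("maf must lie in (0, 0.5]")
    if (n < 1L || m < 1L) stop("n and m must be >= 1")
    if (!is.null(seed)) set.seed(as.integer(seed))
    matrix(rbinom(n * m, 2L, maf), nrow = n, ncol = m)
}

## standardize dosages by the generating allele frequency
.stdDosage <- function(X, maf) (X - 2 * maf) / sqrt(2 * maf * (1 - maf))

## PSD matrix square root (chol fails on the singular scenario blocks)
.psdSqrt <- function(M) {
    ed <- eigen(M, symmetric = TRUE)
    ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
}

#' Dichotomize a quantitative trait at a prevalence threshold
#'
#' Liability-threshold dichotomization: the trait is standardized and
#' individuals whose value exceeds the upper-`k` standard-normal quantile
#' (`-qnorm(k)`) are scored 1, the rest 0, so the sample prevalence is
#' approximately `k`.
#'
#' @param values numeric vector (approximately standardized liabilities).
#' @param k target prevalence in (0,1).
#' @return Integer 0/1 vector.
#' @export
dichotomize <- function(values, k) {
    if (length(k) != 1L || !is.finite(k) || k <= 0 || k >= 1)
        stop("prevalence k must lie in (0,1)")
    s <- sd(values)
    if (!is.finite(s) || s == 0)
        stop("cannot dichotomize a constant trait")
    z <- (values - mean(values)) / s
    as.integer(z > -qnorm(k))
}

#' Simulate a cohort under the pleiotropy decomposition model
#'
#' Draws genotypes for the HP and VP SNP sets, per-SNP effects (HP effects
#' bivariate normal with covariance `G1 / mHP` on standardized dosages; VP
#' exposure and outcome effects independent with variances
#' `G2[2,2] / (mVP/2)` and `G2[1,1] / (mVP/2)`), bivariate-normal residuals
#' with block `R`, and assembles the phenotypes
#' `c = beta1 + beta2 + eps` and `y = c * tau + alpha1 + alpha2 + e`.
#' Binary copies are added when the config carries prevalences.
#'
#' The RNG is split into fixed-order sub-streams (genotypes, effects,
#' residuals), so supplying previously drawn `genotypes` reproduces the
#' same effects and residuals as a full draw under the same seed.
#'
#' @param config a [ScenarioConfig].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param genotypes optional list `(hp, vpExposure, vpOutcome)` of dosage
#'   matrices to reuse (e.g. across replicates that condition on one
#'   genotype sample).
#' @return A [PleioCohort].
#' @export
simulateCohort <- function(config, seed = NULL, genotypes = NULL) {
    stopifnot(is(config, "ScenarioConfig"))
    validObject(config)
    if (!is.null(seed)) set.seed(as.integer(seed))
    subseed <- sample.int(.Machine$integer.max - 1L, 3L)
    n <- config@n; mHP <- config@mHP; mH <- config@mVP %/% 2L
    maf <- config@maf

    if (is.null(genotypes)) {
        set.seed(subseed[1L])
        genotypes <- list(
            hp = simulateGenotypes(n, mHP, maf),
            vpExposure = simulateGenotypes(n, mH, maf),
            vpOutcome = simulateGenotypes(n, mH, maf))
    } else {
        stopifnot(all(c("hp", "vpExposure", "vpOutcome") %in% names(genotypes)))
        if (nrow(genotypes$hp) != n)
            stop("reused genotypes have ", nrow(genotypes$hp),
                 " individuals but the config asks for ", n)
    }

    set.seed(subseed[2L])
    effHP <- matrix(rnorm(2L * mHP), mHP, 2L) %*% .psdSqrt(config@G1 / mHP)
    effB2 <- rnorm(mH, sd = sqrt(config@G2[2L, 2L] / mH))
    effA2 <- rnorm(mH, sd = sqrt(config@G2[1L, 1L] / mH))

    Zhp <- .stdDosage(genotypes$hp, maf)
    alpha1 <- drop(Zhp %*% effHP[, 1L])
    beta1 <- drop(Zhp %*% effHP[, 2L])
    beta2 <- drop(.stdDosage(genotypes$vpExposure, maf) %*% effB2)
    alpha2 <- drop(.stdDosage(genotypes$vpOutcome, maf) %*% effA2)

    set.seed(subseed[3L])
    res <- matrix(rnorm(2L * n), n, 2L) %*% .psdSqrt(config@R)
    e <- res[, 1L]; eps <- res[, 2L]

    cc <- beta1 + beta2 + eps
    y <- cc * config@tau + alpha1 + alpha2 + e

    cd <- S4Vectors::DataFrame(alpha1 = alpha1, alpha2 = alpha2,
                               beta1 = beta1, beta2 = beta2,
                               e = e, eps = eps, y = y, c = cc)
    if (!is.na(config@kY)) cd$yBin <- dichotomize(y, config@kY)
    if (!is.na(config@kC)) cd$cBin <- dichotomize(cc, config@kC)

    dosage <- t(cbind(genotypes$hp, genotypes$vpExposure, genotypes$vpOutcome))
    set <- rep(c("hp", "vp_exposure", "vp_outcome"), c(mHP, mH, mH))
    rownames(dosage) <- paste0("snp_", set, "_",
                               c(seq_len(mHP), seq_len(mH), seq_len(mH)))
    colnames(dosage) <- sprintf("ind%05d", seq_len(n))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowData = S4Vectors::DataFrame(set = set),
        colData = cd,
        metadata = list(config = config))
    new("PleioCohort", se)
}

#' @rdname pleiodecomp-accessors
#' @export
setMethod("scenarioConfig", "PleioCohort",
          function(x) S4Vectors::metadata(x)$config)

#' @rdname pleiodecomp-accessors
#' @export
setMethod("phenotypes", "PleioCohort", function(x, ...) {
    cd <- SummarizedExperiment::colData(x)
    keep <- intersect(c("y", "c", "yBin", "cBin"), colnames(cd))
    data.frame(FID = colnames(x), IID = colnames(x),
               as.data.frame(cd[, keep, drop = FALSE]))
})

#' @rdname pleiodecomp-accessors
#' @param set for `dosages()`: `"all"`, `"hp"`, `"vp"` (both VP halves),
#'   `"vp_exposure"` or `"vp_outcome"`.
#' @export
setMethod("dosages", "PleioCohort", function(x, set = "all", ...) {
    set <- match.arg(set, c("all", "hp", "vp", "vp_exposure", "vp_outcome"))
    lab <- SummarizedExperiment::rowData(x)$set
    keep <- switch(set,
        all = rep(TRUE, length(lab)),
        vp = lab %in% c("vp_exposure", "vp_outcome"),
        lab == set)
    t(SummarizedExperiment::assay(x, "dosage")[keep, , drop = FALSE])
})

#' @describeIn simulateCohort realized per-individual genetic values.
#' @param cohort a [PleioCohort].
#' @export
geneticValues <- function(cohort) {
    stopifnot(is(cohort, "PleioCohort"))
    as.data.frame(SummarizedExperiment::colData(cohort)[,
        c("alpha1", "alpha2", "beta1", "beta2", "e", "eps")])
}

setMethod("show", "ScenarioConfig", function(object) {
    cat(sprintf("ScenarioConfig: scenario %d, n = %d, tau = %g\n",
                object@scenarioId, object@n, object@tau))
    cat(sprintf("  SNPs: %d HP + %d VP (maf %.2f)\n",
                object@mHP, object@mVP, object@maf))
    cat(sprintf("  G1 = [%.2f %.2f; %.2f %.2f], G2 = [%.2f %.2f; %.2f %.2f]\n",
                object@G1[1], object@G1[3], object@G1[2], object@G1[4],
                object@G2[1], object@G2[3], object@G2[2], object@G2[4]))
    cat(sprintf("  residuals: var(e) = %.4f, var(eps) = %.2f, cov(e,eps) = %.2f\n",
                object@R[1, 1], object@R[2, 2], object@R[1, 2]))
    if (!is.na(object@kY) || !is.na(object@kC))
        cat(sprintf("  prevalences: kY = %s, kC = %s\n",
                    format(object@kY), format(object@kC)))
})

setMethod("show", "PleioCohort", function(object) {
    cfg <- scenarioConfig(object)
    cat(sprintf("PleioCohort: %d individuals, %d SNPs (scenario %d, tau = %g)\n",
                ncol(object), nrow(object), cfg@scenarioId, cfg@tau))
    tab <- table(SummarizedExperiment::rowData(object)$set)
    cat("  SNP sets:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    ph <- phenotypes(object)
    cat(sprintf("  var(y) = %.3f, var(c) = %.3f, cov(y,c) = %.3f\n",
                var(ph$y), var(ph$c), cov(ph$y, ph$c)))
})

#' Write a simulated cohort to plain-text files
#'
#' Emits `<prefix>.raw.tsv` (PLINK .raw-style dosages: FID IID then one
#' column per SNP), `<prefix>.phen.tsv` (FID IID and the phenotype
#' columns) and `<prefix>.truth.json` (the generating configuration).
#'
#' @param cohort a [PleioCohort].
#' @param prefix output path prefix.
#' @param overwrite logical; refuse to clobber existing files by default.
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, prefix, overwrite = FALSE) {
    stopifnot(is(cohort, "PleioCohort"))
    paths <- paste0(prefix, c(".raw.tsv", ".phen.tsv", ".truth.json"))
    if (!overwrite && any(file.exists(paths)))
        stop("output files exist; use overwrite = TRUE")
    ph <- phenotypes(cohort)
    geno <- dosages(cohort, "all")
    raw <- data.frame(FID = ph$FID, IID = ph$IID, geno, check.names = FALSE)
    utils::write.table(raw, paths[1L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ph, paths[2L], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfg <- scenarioConfig(cohort)
    jsonlite::write_json(list(
        scenario = cfg@scenarioId, n = cfg@n, mHP = cfg@mHP, mVP = cfg@mVP,
        maf = cfg@maf, tau = cfg@tau, G1 = cfg@G1, G2 = cfg@G2, R = cfg@R,
        kY = cfg@kY, kC = cfg@kC, implied = as.list(impliedParams(cfg))),
        paths[3L], auto_unbox = TRUE, digits = NA, na = "null")
    invisible(paths)
}
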