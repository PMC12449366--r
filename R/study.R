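#' Run a simulation study for one scenario and causal-effect value
#'
#' Simulates replicate cohorts under a scenario, and for each replicate
#' (i) fits the standard bivariate model by GREML on a genome-wide GRM
#' (all HP and VP SNPs), (ii) estimates the causal effect from a GRM built
#' on the vertical-pleiotropy SNP set only, and (iii) applies the
#' vertical-pleiotropy corrections with delta-method standard errors.
#'
#' By default the replicates condition on a single genotype sample:
#' genotypes (and therefore the two GRM eigendecompositions) are drawn
#' once and only SNP effects and residuals are redrawn per replicate.
#' REML inference is conditional on the realized relatedness, so this
#' matches the estimand of the reported standard errors while making the
#' study orders of magnitude cheaper; set `reuseGenotypes = FALSE` to
#' redraw genotypes every replicate.
#'
#' @param scenario scenario id 1..5.
#' @param tau causal effect.
#' @param n individuals per cohort.
#' @param reps number of replicates.
#' @param seed integer seed governing the whole study.
#' @param mHP,mVP,maf forwarded to [makeScenario].
#' @param reuseGenotypes logical (see details).
#' @param constrain passed to the REML fits.
#' @return data.frame with one row per replicate: the causal-effect
#'   estimate and its standard error, the uncorrected components
#'   (`vgY`, `vgC`, `cg`) with their reported standard errors and the
#'   uncorrected heritability/correlation, the
#'   corrected values (`covAB`, `varA`, `h2`, `rg`) with their standard
#'   errors, the `rgDefined` and `converged` flags.  The generating
#'   [ScenarioConfig] and its [impliedParams] are attached as attributes
#'   `"config"` and `"truth"`.
#' @export
runScenarioStudy <- function(scenario, tau, n = 2000L, reps = 50L, seed = 1L,
                             mHP = 1000L, mVP = 1000L, maf = 0.2,
                             reuseGenotypes = TRUE,
                             constrain = "none") {
    cfg <- makeScenario(scenario, tau, n = n, mHP = mHP, mVP = mVP, maf = maf)
    set.seed(as.integer(seed))
    repSeeds <- sample.int(.Machine$integer.max - 1L, reps)

    geno <- NULL; edGW <- NULL; edVP <- NULL
    if (reuseGenotypes) {
        geno <- list(hp = simulateGenotypes(n, mHP, maf),
                     vpExposure = simulateGenotypes(n, mVP %/% 2L, maf),
                     vpOutcome = simulateGenotypes(n, mVP %/% 2L, maf))
        edGW <- grmEigen(computeGRM(do.call(cbind, geno)))
        edVP <- grmEigen(computeGRM(cbind(geno$vpExposure, geno$vpOutcome)))
    }

    rows <- vector("list", reps)
    for (r in seq_len(reps)) {
        cohort <- simulateCohort(cfg, seed = repSeeds[r], genotypes = geno)
        ph <- phenotypes(cohort)
        if (is.null(edGW)) {
            eGW <- grmEigen(computeGRM(dosages(cohort, "all")))
            eVP <- grmEigen(computeGRM(dosages(cohort, "vp")))
        } else {
            eGW <- edGW; eVP <- edVP
        }
        fitGW <- fitBivariateREML(NULL, ph$y, ph$c, eigenGRM = eGW,
                                  constrain = constrain)
        fitVP <- estimateVPComponents(NULL, ph$y, ph$c, eigenGRM = eVP,
                                      constrain = constrain)
        tauHat <- estimateTau(fitVP)
        corr <- hvpCorrect(fitGW, tauHat)
        est <- vcEstimates(fitGW)
        seEst <- sqrt(pmax(diag(samplingCov(fitGW)), 0))
        unc <- corr@uncorrected
        rows[[r]] <- data.frame(
            rep = r, tauHat = tauValue(tauHat), seTauHat = tauSE(tauHat),
            vgY = est[["vgY"]], vgC = est[["vgC"]], cg = est[["cg"]],
            seVgY = seEst[["vgY"]], seVgC = seEst[["vgC"]],
            seCg = seEst[["cg"]],
            h2Unc = unc[["h2"]], rgUnc = unc[["rg"]],
            covAB = corr@corrected[["covAB"]],
            varA = corr@corrected[["varA"]],
            h2 = corr@corrected[["h2"]], rg = corr@corrected[["rg"]],
            seH2 = corr@se[["h2"]], seRg = corr@se[["rg"]],
            seCovAB = corr@se[["covAB"]],
            rgDefined = corr@rgDefined,
            converged = isConverged(fitGW) && isConverged(fitVP))
    }
    out <- do.call(rbind, rows)
    attr(out, "config") <- cfg
    attr(out, "truth") <- impliedParams(cfg)
    out
}

#' Summarize a scenario study
#'
#' Means, empirical standard deviations and standard errors of the mean
#' for the key quantities of a [runScenarioStudy] result, plus the
#' empirical coverage of the delta-method 95\% confidence interval for the
#' corrected genetic correlation against the generating value.
#'
#' @param study result of [runScenarioStudy].
#' @param level confidence level for the coverage computation.
#' @return Named list: `truth`, `mean` / `sd` / `seMean` vectors over
#'   (tauHat, h2Unc, rgUnc, h2, rg), `rgCoverage` (proportion of CIs
#'   containing the generating correlation, `NA` when that correlation is
#'   undefined) and `meanSeRg` (average reported standard error).
#' @export
summarizeStudy <- function(study, level = 0.95) {
    truth <- attr(study, "truth")
    cols <- c("tauHat", "h2Unc", "rgUnc", "h2", "rg")
    mean_ <- vapply(cols, function(k) mean(study[[k]], na.rm = TRUE), 0)
    sd_ <- vapply(cols, function(k) sd(study[[k]], na.rm = TRUE), 0)
    nOK <- vapply(cols, function(k) sum(!is.na(study[[k]])), 0L)
    zc <- qnorm(1 - (1 - level) / 2)
    cover <- NA_real_
    if (!is.na(truth[["rg"]])) {
        ok <- !is.na(study$rg) & !is.na(study$seRg)
        cover <- mean(abs(study$rg[ok] - truth[["rg"]]) <=
                          zc * study$seRg[ok])
    }
    list(truth = truth, mean = mean_, sd = sd_, seMean = sd_ / sqrt(nOK),
         rgCoverage = cover, meanSeRg = mean(study$seRg, na.rm = TRUE))
}
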