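## Shared fixtures, built once per test run.  The REML fits are the
## expensive part (GRM + eigendecomposition at n = 2000), so cohorts and
## fits used by several test files are cached here.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
    if (is.null(.fixtureCache[[name]]))
        assign(name, force(expr), envir = .fixtureCache)
    .fixtureCache[[name]]
}

## scenario-2 cohort at tau = 0.4 with genome-wide and VP-set fits
fixtureS2 <- function() fixture("s2", {
    cfg <- makeScenario(2, 0.4, n = 2000)
    cohort <- simulateCohort(cfg, seed = 101)
    ph <- phenotypes(cohort)
    edGW <- grmEigen(computeGRM(dosages(cohort, "all")))
    edVP <- grmEigen(computeGRM(dosages(cohort, "vp")))
    list(cfg = cfg, cohort = cohort, ph = ph, edGW = edGW, edVP = edVP,
         fitGW = fitBivariateREML(NULL, ph$y, ph$c, eigenGRM = edGW),
         fitVP = estimateVPComponents(NULL, ph$y, ph$c, eigenGRM = edVP))
})

## scenario-2 cohort at tau = 0 (no vertical pleiotropy, h2 = 0.5) with a
## binary copy of the outcome at prevalence 0.3
fixtureNull <- function() fixture("null", {
    cfg <- makeScenario(2, 0, n = 2000, kY = 0.3)
    cohort <- simulateCohort(cfg, seed = 202)
    ph <- phenotypes(cohort)
    edGW <- grmEigen(computeGRM(dosages(cohort, "all")))
    list(cfg = cfg, cohort = cohort, ph = ph, edGW = edGW,
         fitY = fitUnivariateREML(NULL, ph$y, eigenGRM = edGW),
         fitYBin = fitUnivariateREML(NULL, ph$yBin, eigenGRM = edGW))
})

## scenario-2 replicate study at tau = 0.4 (50 replicates, n = 2000):
## shared between the GREML calibration properties and the recovery
## criteria
fixtureStudyS2 <- function() fixture("studyS2",
    runScenarioStudy(2, 0.4, n = 2000, reps = 50, seed = 2024))

## wrap a component triple + sampling covariance as a bivariate fit
vcFromTriple <- function(vgY, vgC, cg, Omega3 = diag(3) * 1e-4,
                         scale = "observed") {
    est <- c(vgY = vgY, vgC = vgC, cg = cg, veY = 0.3, veC = 0.3, ce = 0)
    Om <- diag(6) * 1e-4
    Om[1:3, 1:3] <- Omega3
    dimnames(Om) <- list(names(est), names(est))
    new("VarComp", scope = "bivariate", estimates = est, Omega = Om,
        loglik = 0, nUsed = 1000L, iterations = 5L, converged = TRUE,
        flags = character(), scale = scale)
}

## standardized dosages for building phenotypes directly in tests
.stdDosageForTest <- function(X, maf) (X - 2 * maf) / sqrt(2 * maf * (1 - maf))

## random symmetric positive semi-definite matrix
randomPSD <- function(p) {
    M <- matrix(rnorm(p * p), p)
    crossprod(M) / p + diag(p) * 1e-3
}

## central finite-difference gradient
fdGradient <- function(f, x, h = 1e-5) {
    vapply(seq_along(x), function(j) {
        hp <- hm <- x
        hp[j] <- x[j] + h
        hm[j] <- x[j] - h
        (f(hp) - f(hm)) / (2 * h)
    }, 0)
}
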