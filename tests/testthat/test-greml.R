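test_that("GRM construction standardizes dosages and drops monomorphic SNPs", {
    set.seed(8)
    X <- simulateGenotypes(300, 400, 0.25)
    X[, 1] <- 0                       # monomorphic
    X <- rbind(X, X[1, ])             # duplicate of individual 1
    A <- computeGRM(X)
    expect_identical(attr(A, "nSnps"), 399L)
    expect_lt(abs(mean(diag(A)) - 1), 0.05)
    offd <- A[upper.tri(A)]
    expect_lt(abs(mean(offd)), 0.01)
    ## identical genotypes: relationship equals the mean of the diagonals
    n <- nrow(A)
    expect_equal(A[1, n], (A[1, 1] + A[n, n]) / 2, tolerance = 1e-12)
    expect_error(computeGRM(matrix(2, 10, 3)), "monomorphic")
})

test_that("univariate REML recovers heritability and the null", {
    nl <- fixtureNull()           # tau = 0, h2 = 0.5, n = 2000
    est <- vcEstimates(nl$fitY)
    se <- sqrt(diag(samplingCov(nl$fitY)))
    h2 <- est[["vg"]] / sum(est)
    expect_true(isConverged(nl$fitY))
    expect_lt(abs(est[["vg"]] - 0.5), 3 * se[["vg"]])
    expect_lt(abs(h2 - 0.5), 0.1)
    ## pure noise on the same GRM
    set.seed(44)
    fit0 <- fitUnivariateREML(NULL, rnorm(2000), eigenGRM = nl$edGW)
    expect_lt(abs(vcEstimates(fit0)[["vg"]]),
              3 * sqrt(samplingCov(fit0)["vg", "vg"]))
})

test_that("an identity GRM leaves the components unidentifiable", {
    set.seed(13)
    fit <- fitUnivariateREML(diag(200), rnorm(200))
    expect_false(isConverged(fit))
    expect_true("singular_information" %in% fit@flags)
})

test_that("bivariate REML recovers the mis-specified model components", {
    s2 <- fixtureS2()
    est <- vcEstimates(s2$fitGW)
    se <- sqrt(diag(samplingCov(s2$fitGW)))
    ## forward-composed truth: var(g) = 0.78, var(beta) = 0.5, cov = 0.45
    expect_true(isConverged(s2$fitGW))
    expect_lt(abs(est[["vgY"]] - 0.78), 3 * se[["vgY"]])
    expect_lt(abs(est[["vgC"]] - 0.50), 3 * se[["vgC"]])
    expect_lt(abs(est[["cg"]] - 0.45), 3 * se[["cg"]])
    expect_true(isSymmetric(samplingCov(s2$fitGW), tol = 1e-8))
    expect_true(all(diag(samplingCov(s2$fitGW)) > 0))
})

test_that("VP-set components give cov(g2, beta2) = tau * var(beta2)", {
    s2 <- fixtureS2()
    est <- vcEstimates(s2$fitVP)
    se <- sqrt(diag(samplingCov(s2$fitVP)))
    expect_lt(abs(est[["cg"]] - 0.4 * 0.24), 3 * se[["cg"]])
    expect_lt(abs(est[["vgC"]] - 0.24), 3 * se[["vgC"]])
})

test_that("independent traits show no genetic covariance", {
    s1 <- runScenarioStudy(1, 0, n = 1000, reps = 3, seed = 5,
                           mHP = 400, mVP = 400)
    ## scenario 1 at tau = 0: no shared genetics, no causation
    expect_lt(max(abs(s1$cg)), 0.15)
    expect_lt(abs(mean(s1$rgUnc)), 0.25)
})

test_that("restricted log-likelihood never decreases across iterations", {
    set.seed(21)
    X <- simulateGenotypes(400, 300, 0.2)
    A <- computeGRM(X)
    ed <- grmEigen(A)
    g <- drop(.stdDosageForTest(X, 0.2) %*% rnorm(300, sd = sqrt(0.4 / 300)))
    y <- g + rnorm(400, sd = sqrt(0.6))
    c2 <- 0.5 * g + rnorm(400, sd = sqrt(0.8))
    lls <- vapply(c(1, 2, 4, 6, 10, 50), function(mx)
        fitBivariateREML(NULL, y, c2, eigenGRM = ed, maxit = mx)@loglik, 0)
    expect_true(all(diff(lls) >= -1e-8))
})

test_that("duplicated traits are flagged as degenerate", {
    set.seed(31)
    X <- simulateGenotypes(300, 200, 0.2)
    ed <- grmEigen(computeGRM(X))
    g <- drop(.stdDosageForTest(X, 0.2) %*% rnorm(200, sd = sqrt(0.5 / 200)))
    y <- g + rnorm(300, sd = sqrt(0.5))
    ## an exact duplicate leaves the six components unidentifiable
    fit0 <- fitBivariateREML(NULL, y, y, eigenGRM = ed)
    expect_true("singular_information" %in% fit0@flags)
    expect_false(isConverged(fit0))
    ## a near-duplicate drives both correlations to the boundary
    fit <- fitBivariateREML(NULL, y, y + rnorm(300, sd = 0.05),
                            eigenGRM = ed)
    est <- vcEstimates(fit)
    rg <- est[["cg"]] / sqrt(est[["vgY"]] * est[["vgC"]])
    re <- est[["ce"]] / sqrt(est[["veY"]] * est[["veC"]])
    expect_gt(rg, 0.99)
    expect_gt(re, 0.99)
    expect_true("boundary" %in% fit@flags)
})

test_that("boxed constraint keeps components in the admissible region", {
    set.seed(61)
    ## null traits: unconstrained estimates may go negative, boxed may not
    nl <- fixtureNull()
    fit <- fitBivariateREML(NULL, rnorm(2000), rnorm(2000),
                            eigenGRM = nl$edGW, constrain = "boxed")
    est <- vcEstimates(fit)
    expect_true(all(est[c("vgY", "vgC", "veY", "veC")] >= 0))
    expect_lte(abs(est[["cg"]]), sqrt(est[["vgY"]] * est[["vgC"]]) + 1e-8)
})

test_that("REML estimates and reported uncertainty are calibrated over replicates", {
    st <- fixtureStudyS2()      # scenario 2, tau = 0.4, 50 reps, n = 2000
    truth <- attr(st, "truth")
    expect_true(all(st$converged))
    for (k in c("vgY", "vgC", "cg")) {
        tk <- c(vgY = "varG", vgC = "varB", cg = "covGB")[[k]]
        se <- sd(st[[k]]) / sqrt(nrow(st))
        expect_lt(abs(mean(st[[k]]) - truth[[tk]]), 3 * se)
        ## mean reported (average-information) se vs the replicate spread
        sek <- paste0("se", toupper(substr(k, 1, 1)), substr(k, 2, 10))
        expect_lt(abs(mean(st[[sek]]) - sd(st[[k]])) / sd(st[[k]]), 0.2)
    }
})

test_that("phenotype/GRM dimension mismatches are rejected", {
    nl <- fixtureNull()
    expect_error(fitUnivariateREML(NULL, rnorm(100), eigenGRM = nl$edGW),
                 "does not match")
    expect_error(fitUnivariateREML(diag(50), rnorm(40)), "does not match")
    expect_error(fitUnivariateREML(diag(10), rnorm(10)), "complete cases")
})
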