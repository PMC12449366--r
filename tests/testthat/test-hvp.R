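test_that("the correction formulas invert the forward composition", {
    expect_equal(correctGencov(0.45, 0.5, 0.4), 0.25)
    expect_equal(correctGencov(0.2, 0.5, 0.4), 0)
    expect_equal(correctGencov(0.37, 0.5, 0), 0.37)
    expect_equal(correctGenvar(0.78, 0.5, 0.45, 0.4), 0.5)
    expect_equal(correctGenvar(0.62, 0.5, 0.3, 0), 0.62)
    expect_equal(correctedH2(0.5, 1), 0.5)
    expect_equal(correctedH2(0, 1), 0)
    expect_equal(correctedH2(0.3, 2), 0.15)
    expect_error(correctedH2(0.3, 0), "positive")
    rg <- correctedRg(0.78, 0.5, 0.45, 0.4)
    expect_equal(as.numeric(rg), 0.5)
    expect_true(attr(rg, "defined"))
})

test_that("composition consistency holds to machine precision, including negative tau", {
    set.seed(90)
    for (i in 1:200) {
        varA <- runif(1, 0.05, 0.8)
        varB <- runif(1, 0.05, 0.8)
        covAB <- runif(1, -0.9, 0.9) * sqrt(varA * varB)
        tau <- runif(1, -0.5, 0.5)
        varG <- varA + tau^2 * varB + 2 * tau * covAB
        covGB <- covAB + tau * varB
        expect_equal(correctGencov(covGB, varB, tau), covAB,
                     tolerance = 1e-12)
        expect_equal(correctGenvar(varG, varB, covGB, tau), varA,
                     tolerance = 1e-12)
        expect_equal(as.numeric(correctedRg(varG, varB, covGB, tau)),
                     covAB / sqrt(varA * varB), tolerance = 1e-12)
    }
})

test_that("scenario truths collapse to zero under their own correction", {
    for (tau in seq(0, 0.4, by = 0.1)) {
        ## complete mediation: var(alpha) = cov(alpha,beta) = 0
        varG <- tau^2 * 0.5
        covGB <- tau * 0.5
        expect_equal(correctGenvar(varG, 0.5, covGB, tau), 0,
                     tolerance = 1e-12)
        ## vertical pleiotropy only: cov(alpha,beta) = 0 so corrected
        ## correlation is 0
        varG1 <- 0.5 + tau^2 * 0.5
        rg <- correctedRg(varG1, 0.5, tau * 0.5, tau)
        expect_equal(as.numeric(rg), 0, tolerance = 1e-12)
    }
})

test_that("delta-method standard errors match direct quadratic forms", {
    expect_equal(seGencov(diag(c(9e-4, 4e-4)), 0.4),
                 sqrt(9e-4 + 0.16 * 4e-4))
    expect_equal(seGencov(diag(c(9e-4, 4e-4)), 0), sqrt(9e-4))
    expect_equal(seGenvar(diag(3), 0.4), sqrt(1 + 0.4^4 + 4 * 0.16))
    expect_equal(seGenvar(diag(c(2e-3, 1e-3, 3e-3)), 0), sqrt(2e-3))
    ## with gradient (1, -tau), perfectly correlated components at matched
    ## scale shrink the se below sqrt(Omega11) for positive tau
    Om <- matrix(c(1e-4, 1e-4, 1e-4, 1e-4), 2)
    expect_lt(seGencov(Om, 0.4), sqrt(1e-4))
    ## an indefinite Omega with a negative quadratic form is rejected
    expect_error(seGencov(matrix(c(1, 2, 2, 1), 2) * 1e-4, 1), "negative")
})

test_that("all delta-method gradients agree with central finite differences", {
    set.seed(17)
    for (i in 1:50) {
        varA <- runif(1, 0.1, 0.7)
        varB <- runif(1, 0.1, 0.7)
        covAB <- runif(1, -0.8, 0.8) * sqrt(varA * varB)
        tau <- runif(1, -0.4, 0.4)
        x <- c(varA + tau^2 * varB + 2 * tau * covAB,  # varG
               varB, covAB + tau * varB)               # varB, covGB
        ## corrected correlation gradient via basis-vector Omegas
        fRg <- function(v) as.numeric(correctedRg(v[1], v[2], v[3], tau))
        fd <- fdGradient(fRg, x, h = 1e-6)
        for (j in 1:3) {
            Ej <- matrix(0, 3, 3); Ej[j, j] <- 1
            expect_lt(abs(seRg(Ej, x[1], x[2], x[3], tau) - abs(fd[j])),
                      1e-8)
        }
        ## full quadratic form on a random PSD Omega
        Om <- randomPSD(3) * 1e-3
        expect_equal(seRg(Om, x[1], x[2], x[3], tau)^2,
                     drop(fd %*% Om %*% fd), tolerance = 1e-6)
        fVar <- function(v) correctGenvar(v[1], v[2], v[3], tau)
        fdv <- fdGradient(fVar, x)
        expect_equal(seGenvar(Om, tau)^2, drop(fdv %*% Om %*% fdv),
                     tolerance = 1e-8)
        fCov <- function(v) correctGencov(v[1], v[2], tau)
        fdc <- fdGradient(fCov, x[c(3, 2)])
        Om2 <- Om[c(3, 2), c(3, 2)]
        expect_equal(seGencov(Om2, tau)^2, drop(fdc %*% Om2 %*% fdc),
                     tolerance = 1e-8)
    }
})

test_that("tau estimation divides the VP-set covariance by the exposure variance", {
    vc <- vcFromTriple(0.2, 0.24, 0.096)
    th <- estimateTau(vc)
    expect_equal(tauValue(th), 0.4)
    expect_identical(th@source, "greml_vp")
    expect_equal(tauValue(estimateTau(vcFromTriple(0.2, 0.3, 0))), 0)
    ## delta-method se of the ratio: g = (1/vb, -cg/vb^2) over (cg, vgC)
    Om <- samplingCov(vc)[c("cg", "vgC"), c("cg", "vgC")]
    g <- c(1 / 0.24, -0.096 / 0.24^2)
    expect_equal(tauSE(th), sqrt(drop(g %*% Om %*% g)))
    bad <- vcFromTriple(0.2, -0.01, 0.05)
    expect_error(estimateTau(bad), "not positive")
})

test_that("tau = 0 correction is the identity on estimates and standard errors", {
    s2 <- fixtureS2()
    corr <- hvpCorrect(s2$fitGW, causalEffect(0))
    est <- vcEstimates(s2$fitGW)
    se <- sqrt(diag(samplingCov(s2$fitGW)))
    expect_equal(corr@corrected[["covAB"]], est[["cg"]])
    expect_equal(corr@corrected[["varA"]], est[["vgY"]])
    expect_equal(corr@corrected[["h2"]], est[["vgY"]])
    expect_equal(corr@corrected[["rg"]],
                 est[["cg"]] / sqrt(est[["vgY"]] * est[["vgC"]]))
    expect_equal(corr@se[["covAB"]], se[["cg"]])
    expect_equal(corr@se[["varA"]], se[["vgY"]])
    expect_equal(corr@corrected, corr@uncorrected[c("covGB", "varG", "h2", "rg")],
                 ignore_attr = TRUE)
    expect_equal(corr@se[["rg"]], corr@uncorrected[["se.rg"]])
})

test_that("the assembled correction recovers scenario-2 truth from a fitted cohort", {
    s2 <- fixtureS2()
    th <- estimateTau(s2$fitVP)
    expect_lt(abs(tauValue(th) - 0.4), 3 * tauSE(th))
    corr <- hvpCorrect(s2$fitGW, th)
    expect_true(corr@rgDefined)
    expect_lt(abs(corr@corrected[["rg"]] - 0.5), 3 * corr@se[["rg"]])
    expect_lt(abs(corr@corrected[["h2"]] - 0.5), 3 * corr@se[["h2"]])
    expect_lt(abs(corr@corrected[["covAB"]] - 0.25), 3 * corr@se[["covAB"]])
})

test_that("complete mediation flags the corrected correlation undefined", {
    ## population-level scenario-4 components at tau = 0.3
    vc <- vcFromTriple(0.3^2 * 0.5, 0.5, 0.3 * 0.5)
    corr <- hvpCorrect(vc, causalEffect(0.3))
    expect_false(corr@rgDefined)
    expect_true(is.na(corr@corrected[["rg"]]))
    expect_equal(corr@corrected[["varA"]], 0, tolerance = 1e-12)
    expect_equal(corr@corrected[["h2"]], 0, tolerance = 1e-12)
    expect_error(seRg(diag(3), 0.3^2 * 0.5, 0.5, 0.3 * 0.5, 0.3),
                 "undefined")
})

test_that("optional tau-uncertainty propagation widens the standard errors", {
    vc <- vcFromTriple(0.78, 0.5, 0.45, Omega3 = randomPSD(3) * 1e-3)
    base <- hvpCorrect(vc, causalEffect(0.4, se = 0.07))
    ext <- hvpCorrect(vc, causalEffect(0.4, se = 0.07),
                      propagateTauSE = TRUE)
    expect_equal(ext@corrected, base@corrected)
    for (k in c("covAB", "varA", "h2", "rg"))
        expect_gte(ext@se[[k]], base@se[[k]])
    ## independent-tau quadrature for the linear covariance correction
    expect_equal(ext@se[["covAB"]],
                 sqrt(base@se[["covAB"]]^2 + (0.5 * 0.07)^2))
    expect_error(hvpCorrect(vc, causalEffect(0.4), propagateTauSE = TRUE),
                 "standard error")
})

test_that("scale mismatches between tau and components are rejected", {
    vc <- vcFromTriple(0.5, 0.5, 0.2)
    expect_error(hvpCorrect(vc, causalEffect(0.2, scale = "liability")),
                 "scale mismatch")
})

test_that("corrected reports serialize with provenance", {
    s2 <- fixtureS2()
    corr <- hvpCorrect(s2$fitGW, estimateTau(s2$fitVP))
    pre <- file.path(withr::local_tempdir(), "rep")
    paths <- writeCorrected(corr, pre)
    expect_true(all(file.exists(paths)))
    js <- jsonlite::read_json(paths[2])
    expect_equal(js$corrected$rg, corr@corrected[["rg"]], tolerance = 1e-12)
    expect_identical(js$tau$source, "greml_vp")
    txt <- readLines(paths[1])
    expect_true(any(grepl("genetic correlation", txt)))
})
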