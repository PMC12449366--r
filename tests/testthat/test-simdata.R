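test_that("scenario configurations reproduce the published blocks and balancing variance", {
    cfg2 <- makeScenario(2, 0.4, n = 100)
    blocks <- geneticBlocks(cfg2)
    expect_equal(blocks$G1, matrix(c(0.35, 0.25, 0.25, 0.26), 2))
    expect_equal(blocks$G2, diag(c(0.15, 0.24)))
    ## var(e) = 1 - var(alpha) - tau^2 * var(c) - 2 tau cov(alpha,beta)
    ## with var(c) = 1, so 1 - 0.5 - 0.16 - 0.2
    expect_equal(residualBlock(cfg2)[1, 1], 0.14)
    expect_equal(residualBlock(cfg2)[2, 2], 0.5)

    cfg1 <- makeScenario(1, 0, n = 100)
    expect_equal(residualBlock(cfg1)[1, 1], 0.5)
    expect_equal(sum(vapply(geneticBlocks(cfg1), function(g) g[1, 1], 0)), 0.5)
    expect_equal(impliedParams(cfg1)[["h2Y"]], 0.5)

    cfg4 <- makeScenario(4, 0.3, n = 100)
    expect_equal(impliedParams(cfg4)[["varA"]], 0)
    expect_equal(residualBlock(cfg4)[1, 1], 1 - 0.09)

    cfg3 <- makeScenario(3, 0.2, n = 100)
    expect_equal(residualBlock(cfg3)[1, 2], 0.1)
    ## extra -2 tau cov(e,eps) term in the balancing formula
    expect_equal(residualBlock(cfg3)[1, 1],
                 1 - 0.5 - 0.04 - 2 * 0.2 * 0.25 - 2 * 0.2 * 0.1)

    cfg5 <- makeScenario(5, 0.1, n = 100)
    expect_equal(geneticBlocks(cfg5)$G1[1, 1], 0.5)
    expect_equal(geneticBlocks(cfg5)$G2[1, 1], 0)

    expect_error(makeScenario(6, 0.1), "scenario")
    ## tau large enough to exhaust the outcome's residual variance
    expect_error(makeScenario(1, 1.5, n = 100), "not positive")
})

test_that("implied mis-specified-model parameters forward-compose the truth", {
    ip <- impliedParams(makeScenario(2, 0.4, n = 100))
    expect_equal(ip[["varG"]], 0.5 + 0.16 * 0.5 + 0.8 * 0.25)
    expect_equal(ip[["covGB"]], 0.25 + 0.4 * 0.5)
    expect_equal(ip[["rg"]], 0.5)
    expect_equal(ip[["covYC"]], 0.25 + 0 + 0.4 * 1)
    expect_true(is.na(impliedParams(makeScenario(4, 0.2, n = 100))[["rg"]]))
})

test_that("genotype simulation is reproducible with correct allele frequency", {
    X1 <- simulateGenotypes(500, 200, 0.2, seed = 9)
    X2 <- simulateGenotypes(500, 200, 0.2, seed = 9)
    expect_identical(X1, X2)
    expect_true(all(X1 %in% 0:2))
    ## column means ~ 2 * maf; mean over 200 columns has se ~ 0.0025
    expect_lt(abs(mean(colMeans(X1)) - 0.4), 3 * sqrt(2 * 0.2 * 0.8 / 1e5))
    expect_error(simulateGenotypes(10, 10, 0), "maf")
    expect_error(simulateGenotypes(10, 10, 0.7), "maf")
})

test_that("simulated cohorts satisfy the structural identities exactly", {
    s2 <- fixtureS2()
    gv <- geneticValues(s2$cohort)
    ph <- s2$ph
    ## y = c tau + alpha1 + alpha2 + e and c = beta1 + beta2 + eps
    expect_equal(ph$c, gv$beta1 + gv$beta2 + gv$eps, tolerance = 1e-12)
    expect_equal(ph$y, ph$c * 0.4 + gv$alpha1 + gv$alpha2 + gv$e,
                 tolerance = 1e-12)
    expect_equal(var(ph$y), 1, tolerance = 0.1)
    ## alpha2 and beta2 sit on disjoint SNP sets: independent by construction
    expect_lt(abs(cov(gv$alpha2, gv$beta2)), 3 * sqrt(0.15 * 0.24 / 2000))
    expect_identical(dim(dosages(s2$cohort, "hp")), c(2000L, 1000L))
    expect_identical(dim(dosages(s2$cohort, "vp_exposure")), c(2000L, 500L))
})

test_that("cohort moments match the generating blocks across replicates", {
    ## redraw effects and residuals over a fixed genotype sample; aggregate
    ## genetic moments must match the config blocks within Monte-Carlo error
    cfg <- makeScenario(2, 0.4, n = 4000, mHP = 600, mVP = 600)
    geno <- list(hp = simulateGenotypes(4000, 600, 0.2, seed = 31),
                 vpExposure = simulateGenotypes(4000, 300, 0.2, seed = 32),
                 vpOutcome = simulateGenotypes(4000, 300, 0.2, seed = 33))
    reps <- 120
    set.seed(77)
    seeds <- sample.int(1e8, reps)
    mom <- t(vapply(seeds, function(s) {
        co <- simulateCohort(cfg, seed = s, genotypes = geno)
        gv <- geneticValues(co)
        ph <- phenotypes(co)
        a <- gv$alpha1 + gv$alpha2
        b <- gv$beta1 + gv$beta2
        c(varA = var(a), varB = var(b), covAB = cov(a, b),
          varY = var(ph$y), covYC = cov(ph$y, ph$c))
    }, numeric(5)))
    truth <- impliedParams(cfg)
    for (k in colnames(mom)) {
        se <- sd(mom[, k]) / sqrt(reps)
        expect_lt(abs(mean(mom[, k]) - truth[[k]]), 3 * se + 1e-3)
    }
})

test_that("scenario 4 outcome genetics flow only through the exposure", {
    cfg <- makeScenario(4, 0.3, n = 3000)
    co <- simulateCohort(cfg, seed = 55)
    gv <- geneticValues(co)
    expect_equal(var(gv$alpha1 + gv$alpha2), 0, tolerance = 1e-20)
    ph <- phenotypes(co)
    ## all genetic covariance of y with c comes from tau * var(beta)
    b <- gv$beta1 + gv$beta2
    expect_lt(abs(cov(ph$y, b) - 0.3 * var(b)), 3 * 0.6 / sqrt(3000))
})

test_that("dichotomization hits the target prevalence at the normal threshold", {
    set.seed(12)
    x <- rnorm(10000)
    half <- dichotomize(x, 0.5)
    expect_lt(abs(mean(half) - 0.5), 3 * sqrt(0.25 / 1e4) + 0.01)
    fifth <- dichotomize(x, 0.2)
    expect_lt(abs(mean(fifth) - 0.2), 3 * sqrt(0.16 / 1e4) + 0.01)
    ## cases are the upper tail
    expect_true(min(x[fifth == 1]) > max(x[fifth == 0]))
    expect_error(dichotomize(x, 0), "k must lie")
    expect_error(dichotomize(x, 1.2), "k must lie")
    expect_error(dichotomize(rep(1, 50), 0.3), "constant")
})

test_that("binary copies appear when prevalences are configured", {
    nl <- fixtureNull()
    expect_true("yBin" %in% colnames(phenotypes(nl$cohort)))
    expect_lt(abs(mean(nl$ph$yBin) - 0.3), 0.03)
    expect_false("cBin" %in% colnames(phenotypes(nl$cohort)))
})

test_that("cohort files round-trip through the plain-text writers", {
    cfg <- makeScenario(1, 0.2, n = 60, mHP = 30, mVP = 20)
    co <- simulateCohort(cfg, seed = 5)
    pre <- file.path(withr::local_tempdir(), "coh")
    paths <- writeCohort(co, pre)
    expect_true(all(file.exists(paths)))
    expect_error(writeCohort(co, pre), "overwrite")
    ph <- readPhenotypes(paths[2])
    expect_equal(ph$y, phenotypes(co)$y, tolerance = 1e-6)
    raw <- utils::read.table(paths[1], header = TRUE, check.names = FALSE)
    expect_identical(nrow(raw), 60L)
    expect_identical(ncol(raw), 2L + 50L)
    truth <- jsonlite::read_json(paths[3])
    expect_equal(truth$tau, 0.2)
    ## determinism: same seed reproduces the same cohort
    co2 <- simulateCohort(cfg, seed = 5)
    expect_identical(phenotypes(co2)$y, phenotypes(co)$y)
})
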