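#' Compute a genetic relationship matrix from dosages
#'
#' Standard GRM: dosages are centered by twice the sample allele frequency
#' and scaled by `sqrt(2 p (1-p))` per SNP, then `A = Z Z' / m`.
#' Monomorphic SNPs carry no relationship information and are dropped from
#' `m`.
#'
#' @param dosages numeric matrix, individuals x SNPs (0/1/2 dosages).
#' @return Symmetric n x n matrix with attribute `"nSnps"` (SNPs used) and
#'   the dosage rownames as dimnames.
#' @export
computeGRM <- function(dosages) {
    if (!is.matrix(dosages) || ncol(dosages) < 1L)
        stop("dosages must be an n x m matrix with m >= 1")
    p <- colMeans(dosages) / 2
    poly <- p > 0 & p < 1
    if (!any(poly)) stop("all SNPs are monomorphic")
    X <- dosages[, poly, drop = FALSE]
    p <- p[poly]
    Z <- sweep(X, 2L, 2 * p, "-")
    Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
    A <- tcrossprod(Z) / ncol(Z)
    dimnames(A) <- list(rownames(dosages), rownames(dosages))
    attr(A, "nSnps") <- ncol(Z)
    A
}

#' Precompute the eigendecomposition of a GRM
#'
#' REML on a single relationship matrix only needs the GRM through its
#' eigenvalues and the rotation of phenotypes onto its eigenvectors, so the
#' decomposition can be shared across traits and simulation replicates that
#' condition on the same genotypes.
#'
#' @param grm symmetric n x n relationship matrix.
#' @return Object of class `"GRMEigen"`: eigenvalues `values`, eigenvectors
#'   `vectors`, `u` (rotated intercept) and `n`.
#' @export
grmEigen <- function(grm) {
    ed <- eigen(grm, symmetric = TRUE)
    structure(list(values = ed$values, vectors = ed$vectors,
                   u = drop(crossprod(ed$vectors, rep(1, nrow(grm)))),
                   n = nrow(grm)),
              class = "GRMEigen")
}

## ---- bivariate AI-REML engine --------------------------------------------
## Model (trait-major): [y; c] = (I2 (x) X) b + [gy; gc] + [ey; ec] with
## cov(g) = G0 (x) A and cov(e) = R0 (x) I.  After rotating by the
## eigenvectors of A the 2n x 2n system factors into n independent 2 x 2
## blocks V_i = d_i G0 + R0, so every REML quantity is O(n) per iteration.
## Components ordered (vgY, vgC, cg, veY, veC, ce); dV_i for component k is
## s_i E_k with s_i = d_i (genetic) or 1 (residual) and E one of
## E11, E22, E12 + E21.

.biv.kind <- data.frame(
    name = c("vgY", "vgC", "cg", "veY", "veC", "ce"),
    e = c("11", "22", "12", "11", "22", "12"),
    genetic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

.bivAux <- function(theta, d, u, Yr, Xr) {
    V11 <- theta[1L] * d + theta[4L]
    V22 <- theta[2L] * d + theta[5L]
    V12 <- theta[3L] * d + theta[6L]
    det <- V11 * V22 - V12^2
    if (any(V11 <= 0) || any(det <= 0)) return(NULL)
    W11 <- V22 / det; W22 <- V11 / det; W12 <- -V12 / det
    q <- ncol(Xr)
    ## C = sum_i W_i (x) x_i x_i'  (2q x 2q, trait-major blocks)
    blk <- function(w) crossprod(Xr, w * Xr)
    C <- rbind(cbind(blk(W11), blk(W12)), cbind(blk(W12), blk(W22)))
    Cc <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Cc)) return(NULL)
    logdetC <- 2 * sum(log(diag(Cc)))
    Wy1 <- W11 * Yr[, 1L] + W12 * Yr[, 2L]
    Wy2 <- W12 * Yr[, 1L] + W22 * Yr[, 2L]
    tvec <- c(crossprod(Xr, Wy1), crossprod(Xr, Wy2))
    bhat <- backsolve(Cc, forwardsolve(t(Cc), tvec))
    r1 <- Yr[, 1L] - drop(Xr %*% bhat[seq_len(q)])
    r2 <- Yr[, 2L] - drop(Xr %*% bhat[q + seq_len(q)])
    p1 <- W11 * r1 + W12 * r2
    p2 <- W12 * r1 + W22 * r2
    yPy <- sum(Yr[, 1L] * p1 + Yr[, 2L] * p2)
    ll <- -0.5 * (sum(log(det)) + logdetC + yPy)
    list(ll = ll, W11 = W11, W22 = W22, W12 = W12, det = det, Cc = Cc,
         p1 = p1, p2 = p2)
}

## apply P to an n x 2 matrix given aux quantities
.bivApplyP <- function(w1, w2, aux, Xr) {
    q <- ncol(Xr)
    Ww1 <- aux$W11 * w1 + aux$W12 * w2
    Ww2 <- aux$W12 * w1 + aux$W22 * w2
    tvec <- c(crossprod(Xr, Ww1), crossprod(Xr, Ww2))
    b <- backsolve(aux$Cc, forwardsolve(t(aux$Cc), tvec))
    r1 <- w1 - drop(Xr %*% b[seq_len(q)])
    r2 <- w2 - drop(Xr %*% b[q + seq_len(q)])
    cbind(aux$W11 * r1 + aux$W12 * r2, aux$W12 * r1 + aux$W22 * r2)
}

.bivDeriv <- function(theta, d, u, Yr, Xr, aux) {
    n <- length(d); q <- ncol(Xr)
    Cinv <- chol2inv(aux$Cc)
    W11 <- aux$W11; W22 <- aux$W22; W12 <- aux$W12
    p1 <- aux$p1; p2 <- aux$p2
    grad <- numeric(6L); ypvpy <- numeric(6L)
    Wmat <- matrix(0, 2L * n, 6L)   # columns: dV_k P y, stacked (trait-major)
    for (k in seq_len(6L)) {
        s <- if (.biv.kind$genetic[k]) d else rep(1, n)
        e <- .biv.kind$e[k]
        if (e == "11") { w1 <- s * p1; w2 <- numeric(n) }
        else if (e == "22") { w1 <- numeric(n); w2 <- s * p2 }
        else { w1 <- s * p2; w2 <- s * p1 }
        Wmat[, k] <- c(w1, w2)
        ypvpy[k] <- sum(p1 * w1 + p2 * w2)
        ## tr(P dV) = sum s tr(W E) - tr(Cinv sum s (W E W) (x) x x')
        if (e == "11") {
            t1 <- sum(s * W11)
            m11 <- s * W11^2; m12 <- s * W11 * W12; m22 <- s * W12^2
        } else if (e == "22") {
            t1 <- sum(s * W22)
            m11 <- s * W12^2; m12 <- s * W12 * W22; m22 <- s * W22^2
        } else {
            t1 <- 2 * sum(s * W12)
            m11 <- 2 * s * W11 * W12
            m12 <- s * (W11 * W22 + W12^2)
            m22 <- 2 * s * W12 * W22
        }
        blk <- function(w) crossprod(Xr, w * Xr)
        M <- rbind(cbind(blk(m11), blk(m12)), cbind(blk(m12), blk(m22)))
        trP <- t1 - sum(Cinv * M)
        grad[k] <- -0.5 * (trP - ypvpy[k])
    }
    Qmat <- matrix(0, 2L * n, 6L)
    for (k in seq_len(6L)) {
        pq <- .bivApplyP(Wmat[seq_len(n), k], Wmat[n + seq_len(n), k],
                         aux, Xr)
        Qmat[, k] <- c(pq[, 1L], pq[, 2L])
    }
    AI <- 0.5 * crossprod(Wmat, Qmat)
    AI <- (AI + t(AI)) / 2
    list(grad = grad, AI = AI, ypvpy = ypvpy)
}

.bivClamp <- function(theta, varP) {
    eps <- 1e-8 * max(varP, 1e-8)
    theta[c(1L, 2L, 4L, 5L)] <- pmax(theta[c(1L, 2L, 4L, 5L)], eps)
    gmax <- sqrt(theta[1L] * theta[2L]) * (1 - 1e-6)
    theta[3L] <- max(min(theta[3L], gmax), -gmax)
    rmax <- sqrt(theta[4L] * theta[5L]) * (1 - 1e-6)
    theta[6L] <- max(min(theta[6L], rmax), -rmax)
    theta
}

.fitBivEngine <- function(ed, y, c, X, constrain, maxit, tol, emIterations) {
    n <- ed$n
    Yr <- crossprod(ed$vectors, cbind(y, c))
    Xr <- crossprod(ed$vectors, X)
    d <- ed$values
    varP <- c(var(y), var(c))
    cp <- cov(y, c)
    theta <- c(0.5 * varP[1L], 0.5 * varP[2L], 0.5 * cp,
               0.5 * varP[1L], 0.5 * varP[2L], 0.5 * cp)
    if (constrain == "boxed") theta <- .bivClamp(theta, max(varP))
    ## shrink the covariance starts until the implied blocks are PD
    aux <- NULL
    for (shrink in c(1, 0.7, 0.5, 0.25, 0.1, 0)) {
        cand <- theta
        cand[c(3L, 6L)] <- theta[c(3L, 6L)] * shrink
        aux <- .bivAux(cand, d, ed$u, Yr, Xr)
        if (!is.null(aux)) { theta <- cand; break }
    }
    if (is.null(aux)) stop("could not find a feasible starting point")
    flags <- character()
    conv <- FALSE
    it <- 0L
    der <- NULL
    for (it in seq_len(maxit)) {
        der <- .bivDeriv(theta, d, ed$u, Yr, Xr, aux)
        if (it <= emIterations) {
            ## elementwise EM-style warm-up step
            step <- theta^2 * (2 * der$grad) / (2 * n)
        } else {
            step <- tryCatch(solve(der$AI, der$grad), error = function(e) NULL)
            if (is.null(step)) {
                flags <- union(flags, "singular_information")
                break
            }
        }
        accepted <- FALSE
        fac <- 1
        for (h in seq_len(30L)) {
            cand <- theta + fac * step
            if (constrain == "boxed") cand <- .bivClamp(cand, max(varP))
            auxNew <- .bivAux(cand, d, ed$u, Yr, Xr)
            if (!is.null(auxNew) && auxNew$ll >= aux$ll - 1e-10) {
                accepted <- TRUE
                break
            }
            fac <- fac / 2
        }
        if (!accepted) break
        dll <- auxNew$ll - aux$ll
        dth <- max(abs(cand - theta))
        theta <- cand
        aux <- auxNew
        if (it > emIterations && dll < tol && dth < tol) {
            conv <- TRUE
            break
        }
    }
    der <- .bivDeriv(theta, d, ed$u, Yr, Xr, aux)
    Omega <- tryCatch(solve(der$AI), error = function(e) NULL)
    if (is.null(Omega) || any(diag(Omega) < 0)) {
        Omega <- matrix(NA_real_, 6L, 6L)
        flags <- union(flags, "singular_information")
        conv <- FALSE
    }
    if (abs(theta[3L]) >= sqrt(max(theta[1L] * theta[2L], 0)) * (1 - 1e-4) ||
        theta[1L] <= 1e-6 * max(varP) || theta[2L] <= 1e-6 * max(varP))
        flags <- union(flags, "boundary")
    nm <- .biv.kind$name
    names(theta) <- nm
    dimnames(Omega) <- list(nm, nm)
    new("VarComp", scope = "bivariate", estimates = theta, Omega = Omega,
        loglik = aux$ll, nUsed = as.integer(n), iterations = it,
        converged = conv, flags = flags, scale = "observed")
}

## ---- univariate engine (same machinery, scalar blocks) -------------------

.uniAux <- function(theta, d, Yr, Xr) {
    V <- theta[1L] * d + theta[2L]
    if (any(V <= 0)) return(NULL)
    W <- 1 / V
    C <- crossprod(Xr, W * Xr)
    Cc <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Cc)) return(NULL)
    bhat <- backsolve(Cc, forwardsolve(t(Cc), crossprod(Xr, W * Yr)))
    r <- Yr - drop(Xr %*% bhat)
    p <- W * r
    ll <- -0.5 * (sum(log(V)) + 2 * sum(log(diag(Cc))) + sum(Yr * p))
    list(ll = ll, W = W, Cc = Cc, p = p)
}

.uniApplyP <- function(w, aux, Xr) {
    b <- backsolve(aux$Cc, forwardsolve(t(aux$Cc), crossprod(Xr, aux$W * w)))
    aux$W * (w - drop(Xr %*% b))
}

.uniDeriv <- function(theta, d, Yr, Xr, aux) {
    n <- length(d)
    Cinv <- chol2inv(aux$Cc)
    grad <- numeric(2L)
    Wmat <- matrix(0, n, 2L)
    for (k in 1:2) {
        s <- if (k == 1L) d else rep(1, n)
        w <- s * aux$p
        Wmat[, k] <- w
        ypvpy <- sum(aux$p * w)
        M <- crossprod(Xr, (s * aux$W^2) * Xr)
        trP <- sum(s * aux$W) - sum(Cinv * M)
        grad[k] <- -0.5 * (trP - ypvpy)
    }
    Qmat <- cbind(.uniApplyP(Wmat[, 1L], aux, Xr),
                  .uniApplyP(Wmat[, 2L], aux, Xr))
    AI <- 0.5 * crossprod(Wmat, Qmat)
    list(grad = grad, AI = (AI + t(AI)) / 2)
}

.fitUniEngine <- function(ed, y, X, constrain, maxit, tol, emIterations) {
    n <- ed$n
    Yr <- drop(crossprod(ed$vectors, y))
    Xr <- crossprod(ed$vectors, X)
    d <- ed$values
    vp <- var(y)
    theta <- c(0.5 * vp, 0.5 * vp)
    aux <- .uniAux(theta, d, Yr, Xr)
    flags <- character(); conv <- FALSE; it <- 0L
    for (it in seq_len(maxit)) {
        der <- .uniDeriv(theta, d, Yr, Xr, aux)
        if (it <= emIterations) {
            step <- theta^2 * (2 * der$grad) / n
        } else {
            step <- tryCatch(solve(der$AI, der$grad), error = function(e) NULL)
            if (is.null(step)) {
                flags <- union(flags, "singular_information")
                break
            }
        }
        accepted <- FALSE; fac <- 1
        for (h in seq_len(30L)) {
            cand <- theta + fac * step
            if (constrain == "boxed") cand <- pmax(cand, 1e-8 * vp)
            auxNew <- .uniAux(cand, d, Yr, Xr)
            if (!is.null(auxNew) && auxNew$ll >= aux$ll - 1e-10) {
                accepted <- TRUE; break
            }
            fac <- fac / 2
        }
        if (!accepted) break
        dll <- auxNew$ll - aux$ll
        dth <- max(abs(cand - theta))
        theta <- cand; aux <- auxNew
        if (it > emIterations && dll < tol && dth < tol) { conv <- TRUE; break }
    }
    der <- .uniDeriv(theta, d, Yr, Xr, aux)
    Omega <- tryCatch(solve(der$AI), error = function(e) NULL)
    if (is.null(Omega) || any(diag(Omega) < 0)) {
        Omega <- matrix(NA_real_, 2L, 2L)
        flags <- union(flags, "singular_information")
        conv <- FALSE
    }
    names(theta) <- c("vg", "ve")
    dimnames(Omega) <- list(names(theta), names(theta))
    new("VarComp", scope = "univariate", estimates = theta, Omega = Omega,
        loglik = aux$ll, nUsed = as.integer(n), iterations = it,
        converged = conv, flags = flags, scale = "observed")
}

.prepGRMInput <- function(grm, eigenGRM, traits, covariates) {
    X <- if (is.null(covariates)) matrix(1, nrow(traits), 1L) else
        cbind(1, as.matrix(covariates))
    cc <- complete.cases(traits) & complete.cases(X)
    if (sum(cc) < 30L) stop("fewer than 30 complete cases")
    if (!all(cc)) {
        if (!is.null(eigenGRM))
            stop("a precomputed eigendecomposition cannot be subset; ",
                 "drop incomplete cases first")
        grm <- grm[cc, cc, drop = FALSE]
        traits <- traits[cc, , drop = FALSE]
        X <- X[cc, , drop = FALSE]
    }
    if (is.null(eigenGRM)) {
        if (is.null(grm)) stop("either grm or eigenGRM must be supplied")
        if (nrow(grm) != nrow(traits))
            stop("GRM dimension (", nrow(grm),
                 ") does not match phenotype length (", nrow(traits), ")")
        eigenGRM <- grmEigen(grm)
    } else if (eigenGRM$n != nrow(traits)) {
        stop("eigenGRM dimension (", eigenGRM$n,
             ") does not match phenotype length (", nrow(traits), ")")
    }
    list(ed = eigenGRM, traits = traits, X = X)
}

#' Univariate GREML: single-trait variance components by AI-REML
#'
#' Maximizes the restricted likelihood of `y = X b + g + e` with
#' `cov(g) = vg * A`, using a few EM-style warm-up iterations followed by
#' average-information updates with step-halving (the restricted
#' log-likelihood never decreases across accepted iterations).  The
#' sampling covariance of the estimates is the inverse average-information
#' matrix at convergence.
#'
#' @param grm symmetric relationship matrix (ignored when `eigenGRM`
#'   given).
#' @param y numeric phenotype vector (missing values dropped).
#' @param covariates optional numeric covariate matrix; an intercept is
#'   always included.
#' @param constrain `"none"` (components may go slightly negative;
#'   default, because downstream bias corrections are linear in the
#'   components) or `"boxed"` (variances kept non-negative, correlations
#'   inside the admissible box).
#' @param maxit,tol iteration cap and convergence tolerance on both the
#'   log-likelihood change and the component changes.
#' @param emIterations number of EM warm-up iterations before switching to
#'   average-information updates.
#' @param eigenGRM optional [grmEigen] result to reuse.
#' @return A [VarComp] with components `(vg, ve)`.
#' @export
fitUnivariateREML <- function(grm, y, covariates = NULL, constrain = c("none", "boxed"),
                              maxit = 100L, tol = 1e-6, emIterations = 3L,
                              eigenGRM = NULL) {
    constrain <- match.arg(constrain)
    pr <- .prepGRMInput(grm, eigenGRM, cbind(y = y), covariates)
    .fitUniEngine(pr$ed, pr$traits[, 1L], pr$X, constrain, maxit, tol,
                  emIterations)
}

#' Bivariate GREML: two-trait variance components by AI-REML
#'
#' Fits the standard bivariate mixed model (no causal path) with genetic
#' covariance structure `G0 (x) A` and residual `R0 (x) I`.  Under
#' vertical pleiotropy its genetic components are the biased quantities
#' `var(g)`, `var(beta)` and `cov(g, beta)` that the correction step
#' ([hvpCorrect]) consumes, together with their full 6 x 6 sampling
#' covariance from the inverse average-information matrix.  The GRM enters
#' only through its eigendecomposition, which can be precomputed with
#' [grmEigen] and reused across fits.
#'
#' @inheritParams fitUnivariateREML
#' @param y,c outcome and exposure phenotype vectors (pairwise complete
#'   cases used).
#' @return A [VarComp] with components `(vgY, vgC, cg, veY, veC, ce)`.
#' @export
fitBivariateREML <- function(grm, y, c, covariates = NULL,
                             constrain = c("none", "boxed"),
                             maxit = 100L, tol = 1e-6, emIterations = 3L,
                             eigenGRM = NULL) {
    constrain <- match.arg(constrain)
    pr <- .prepGRMInput(grm, eigenGRM, cbind(y = y, c = c), covariates)
    .fitBivEngine(pr$ed, pr$traits[, 1L], pr$traits[, 2L], pr$X, constrain,
                  maxit, tol, emIterations)
}

#' Variance components on the vertical-pleiotropy SNP set
#'
#' Bivariate GREML on a GRM built from the SNPs classified as
#' vertical-pleiotropy variants.  Because the exposure and outcome effects
#' of that set are independent by construction, the fitted genetic
#' covariance equals `tau * var(beta2)`, which [estimateTau] turns into a
#' causal-effect estimate.
#'
#' @inheritParams fitBivariateREML
#' @param grmVP relationship matrix from the vertical-pleiotropy SNP set.
#' @return A [VarComp] (bivariate).
#' @export
estimateVPComponents <- function(grmVP, y, c, ..., eigenGRM = NULL) {
    fitBivariateREML(grmVP, y, c, ..., eigenGRM = eigenGRM)
}

## ---- VarComp accessors ----------------------------------------------------

#' @rdname pleiodecomp-accessors
#' @export
setMethod("vcEstimates", "VarComp", function(x) x@estimates)

#' @rdname pleiodecomp-accessors
#' @export
setMethod("samplingCov", "VarComp", function(x) x@Omega)

#' @rdname pleiodecomp-accessors
#' @param which character vector of component names selecting a sub-block
#'   of the sampling covariance, e.g. `c("vgY", "vgC", "cg")` for the 3x3
#'   block of the variance correction or `c("cg", "vgC")` for the 2x2
#'   block of the covariance correction.
#' @export
setMethod("omegaBlock", "VarComp", function(x, which) {
    miss <- setdiff(which, names(x@estimates))
    if (length(miss)) stop("unknown components: ", paste(miss, collapse = ", "))
    x@Omega[which, which, drop = FALSE]
})

#' @rdname pleiodecomp-accessors
#' @export
setMethod("isConverged", "VarComp", function(x) x@converged)

setMethod("show", "VarComp", function(object) {
    cat(sprintf("VarComp (%s GREML, %s scale): n = %d, loglik = %.4f\n",
                object@scope, object@scale, object@nUsed, object@loglik))
    se <- sqrt(pmax(diag(object@Omega), 0))
    tab <- data.frame(estimate = object@estimates, se = se)
    print(round(tab, 5))
    cat(sprintf("  converged: %s after %d iterations%s\n", object@converged,
                object@iterations,
                if (length(object@flags))
                    paste0(" [", paste(object@flags, collapse = ", "), "]")
                else ""))
})
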