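#' Construct summary-level estimates
#'
#' Wraps the genetic-component triple from a summary-statistics front end
#' (e.g. LD score regression) for the correction step.  Uncertainty comes
#' either from a 3x3 sampling covariance or from per-block delete-one
#' jackknife estimates of the triple (LDSC convention: 200 genome blocks).
#'
#' @param vgY,vgC,cg point estimates of var(g), var(beta) and
#'   cov(g, beta), on the unit-phenotypic-variance scale (so `vgY` and
#'   `vgC` are the heritabilities).
#' @param Omega optional 3x3 sampling covariance, component order
#'   (vgY, vgC, cg).
#' @param blocks optional B x 3 matrix of delete-one-block estimates,
#'   columns (vgY, vgC, cg).
#' @return A [SummaryEstimates].
#' @export
summaryEstimates <- function(vgY, vgC, cg, Omega = NULL, blocks = NULL) {
    if (!is.null(blocks)) {
        blocks <- as.matrix(blocks)
        colnames(blocks) <- c("vgY", "vgC", "cg")
    }
    if (!is.null(Omega)) {
        Omega <- as.matrix(Omega)
        dimnames(Omega) <- list(c("vgY", "vgC", "cg"), c("vgY", "vgC", "cg"))
    }
    new("SummaryEstimates", vgY = vgY, vgC = vgC, cg = cg,
        Omega = if (is.null(Omega)) matrix(numeric(), 0L, 0L) else Omega,
        blocks = if (is.null(blocks)) matrix(numeric(), 0L, 0L) else blocks)
}

setMethod("show", "SummaryEstimates", function(object) {
    cat(sprintf("SummaryEstimates: var(g) = %.4g, var(beta) = %.4g, cov(g,beta) = %.4g\n",
                object@vgY, object@vgC, object@cg))
    if (length(object@Omega)) cat("  uncertainty: 3x3 sampling covariance\n")
    if (length(object@blocks))
        cat(sprintf("  uncertainty: %d jackknife blocks\n", nrow(object@blocks)))
})

## delete-one-block jackknife standard error of a statistic already
## computed on each delete-one sample
.jackknifeSE <- function(thetaBlocks) {
    B <- length(thetaBlocks)
    m <- mean(thetaBlocks)
    sqrt((B - 1) / B * sum((thetaBlocks - m)^2))
}

#' Correct summary-level estimates for vertical pleiotropy
#'
#' Applies exactly the same corrections as [hvpCorrect] to a summary-level
#' triple (var(g), var(beta), cov(g, beta)).  Standard errors come from
#' the supplied sampling covariance when present; otherwise each corrected
#' quantity is jackknifed directly over the delete-one-block estimates of
#' the triple (equal block weights).
#'
#' @param summary a [SummaryEstimates].
#' @param causalEffect a [CausalEffect].
#' @param varY phenotypic variance of the outcome (1 by convention for
#'   summary data).
#' @return A [CorrectedParams].
#' @export
correctSummary <- function(summary, causalEffect, varY = 1) {
    stopifnot(is(summary, "SummaryEstimates"),
              is(causalEffect, "CausalEffect"))
    validObject(summary)
    tau <- tauValue(causalEffect)
    hasOmega <- length(summary@Omega) > 0L
    Om <- if (hasOmega) summary@Omega else {
        ## jackknife covariance of the triple doubles as Omega for the
        ## uncorrected-se columns
        B <- nrow(summary@blocks)
        ctr <- sweep(summary@blocks, 2L, colMeans(summary@blocks))
        (B - 1) / B * crossprod(ctr)
    }
    dimnames(Om) <- list(c("varG", "varB", "covGB"),
                         c("varG", "varB", "covGB"))
    parts <- .assembleCorrected(summary@vgY, summary@vgC, summary@cg, Om,
                                tau, varY)
    seMethod <- "delta"
    if (!hasOmega) {
        b <- summary@blocks
        covB <- correctGencov(b[, "cg"], b[, "vgC"], tau)
        varB <- correctGenvar(b[, "vgY"], b[, "vgC"], b[, "cg"], tau)
        rgB <- covB / sqrt(pmax(varB, 1e-12) * pmax(b[, "vgC"], 1e-12))
        parts$se <- c(covAB = .jackknifeSE(covB),
                      varA = .jackknifeSE(varB),
                      h2 = .jackknifeSE(varB / varY),
                      rg = if (parts$rgDefined && all(varB > 0))
                          .jackknifeSE(rgB) else NA_real_)
        seMethod <- "jackknife"
    }
    new("CorrectedParams", corrected = parts$corrected, se = parts$se,
        uncorrected = parts$uncorrected, rgDefined = parts$rgDefined,
        tauUsed = causalEffect, scale = tauScale(causalEffect),
        seMethod = seMethod)
}

#' Read / write summary-level estimates
#'
#' Plain-text key-value dialect that can be assembled by hand from an LDSC
#' log: lines `h2_y`, `h2_c`, `gencov` (required) and optionally `se_h2_y`,
#' `se_h2_c`, `se_gencov` (used for a diagonal sampling covariance when no
#' block file is given), separated from their values by whitespace.  An
#' optional companion CSV (`blocksPath`) holds the delete-one-block
#' estimates with columns `h2_y, h2_c, gencov`.
#'
#' @param path key-value file path.
#' @param blocksPath optional CSV of per-block estimates.
#' @return A [SummaryEstimates].
#' @export
readSummary <- function(path, blocksPath = NULL) {
    raw <- readLines(path)
    raw <- raw[nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")]
    parts <- strsplit(trimws(raw), "[ \t:]+")
    kv <- setNames(vapply(parts, function(p) as.numeric(p[2L]), 0),
                   vapply(parts, `[`, "", 1L))
    need <- c("h2_y", "h2_c", "gencov")
    miss <- setdiff(need, names(kv))
    if (length(miss))
        stop("missing required keys in ", path, ": ",
             paste(miss, collapse = ", "))
    blocks <- NULL
    Omega <- NULL
    if (!is.null(blocksPath)) {
        tab <- utils::read.csv(blocksPath)
        if (!all(c("h2_y", "h2_c", "gencov") %in% colnames(tab)))
            stop("block file must have columns h2_y, h2_c, gencov")
        blocks <- as.matrix(tab[, c("h2_y", "h2_c", "gencov")])
    } else if (all(c("se_h2_y", "se_h2_c", "se_gencov") %in% names(kv))) {
        Omega <- diag(c(kv[["se_h2_y"]], kv[["se_h2_c"]],
                        kv[["se_gencov"]])^2)
    }
    summaryEstimates(kv[["h2_y"]], kv[["h2_c"]], kv[["gencov"]],
                     Omega = Omega, blocks = blocks)
}

#' @rdname readSummary
#' @param summary a [SummaryEstimates] to write.
#' @param prefix output path prefix (`<prefix>.sumstats.txt` and, when
#'   blocks are present, `<prefix>.blocks.csv`).
#' @export
writeSummary <- function(summary, prefix) {
    stopifnot(is(summary, "SummaryEstimates"))
    path <- paste0(prefix, ".sumstats.txt")
    lines <- c(sprintf("h2_y\t%.10g", summary@vgY),
               sprintf("h2_c\t%.10g", summary@vgC),
               sprintf("gencov\t%.10g", summary@cg))
    if (length(summary@Omega))
        lines <- c(lines,
                   sprintf("se_h2_y\t%.10g", sqrt(summary@Omega[1L, 1L])),
                   sprintf("se_h2_c\t%.10g", sqrt(summary@Omega[2L, 2L])),
                   sprintf("se_gencov\t%.10g", sqrt(summary@Omega[3L, 3L])))
    writeLines(lines, path)
    paths <- path
    if (length(summary@blocks)) {
        bp <- paste0(prefix, ".blocks.csv")
        tab <- as.data.frame(summary@blocks)
        colnames(tab) <- c("h2_y", "h2_c", "gencov")
        utils::write.csv(tab, bp, row.names = FALSE)
        paths <- c(paths, bp)
    }
    invisible(paths)
}
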