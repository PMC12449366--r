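#' Write a genetic relationship matrix in GCTA binary triplet format
#'
#' Emits `<prefix>.grm.bin` (lower triangle including the diagonal,
#' row-major, 4-byte little-endian floats), `<prefix>.grm.N.bin` (per-pair
#' SNP counts, same layout) and `<prefix>.grm.id` (two-column FID/IID
#' table), the dialect used by GCTA and related GREML tools.
#'
#' @param grm square symmetric numeric matrix.
#' @param ids data.frame with columns FID and IID (or a character vector
#'   used for both), one row per individual.
#' @param nSnps SNP count per pair; a scalar is recycled.
#' @param prefix output path prefix.
#' @return Invisibly, the three paths written.
#' @export
writeGRM <- function(grm, ids, nSnps, prefix) {
    if (!is.matrix(grm) || nrow(grm) != ncol(grm))
        stop("grm must be a square matrix")
    if (!isSymmetric(unname(grm), tol = 1e-6))
        stop("grm must be symmetric")
    n <- nrow(grm)
    if (is.character(ids)) ids <- data.frame(FID = ids, IID = ids)
    if (nrow(ids) != n)
        stop("ids length (", nrow(ids), ") does not match GRM dimension (", n, ")")
    ## GCTA layout: columns 1..i within row i (lower triangle, row-major)
    idx <- sequence(seq_len(n))
    row <- rep(seq_len(n), seq_len(n))
    tri <- grm[cbind(row, idx)]
    nvec <- rep_len(as.numeric(nSnps), length(tri))
    paths <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
    con <- file(paths[1L], "wb")
    writeBin(as.numeric(tri), con, size = 4L, endian = "little")
    close(con)
    con <- file(paths[2L], "wb")
    writeBin(nvec, con, size = 4L, endian = "little")
    close(con)
    utils::write.table(ids[, c("FID", "IID")], paths[3L], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(paths)
}

#' Read a GCTA binary-triplet genetic relationship matrix
#'
#' @param prefix path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triplet.
#' @return List with `grm` (full symmetric matrix, ids as dimnames),
#'   `ids` (data.frame FID/IID) and `nSnps` (per-pair counts, lower
#'   triangle row-major).
#' @export
readGRM <- function(prefix) {
    paths <- paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id"))
    for (p in paths[c(1L, 3L)])
        if (!file.exists(p)) stop("missing GRM file: ", p)
    ids <- utils::read.table(paths[3L], header = FALSE,
                             col.names = c("FID", "IID"),
                             colClasses = "character")
    key <- paste(ids$FID, ids$IID)
    if (anyDuplicated(key)) stop("duplicate FID+IID in ", paths[3L])
    n <- nrow(ids)
    ntri <- n * (n + 1L) / 2L
    sz <- file.info(paths[1L])$size
    if (sz != 4L * ntri)
        stop("truncated GRM: ", paths[1L], " holds ", sz / 4L,
             " values but n(n+1)/2 = ", ntri)
    con <- file(paths[1L], "rb")
    tri <- readBin(con, "numeric", n = ntri, size = 4L, endian = "little")
    close(con)
    nSnps <- rep(NA_real_, ntri)
    if (file.exists(paths[2L])) {
        con <- file(paths[2L], "rb")
        nSnps <- readBin(con, "numeric", n = ntri, size = 4L,
                         endian = "little")
        close(con)
        if (length(nSnps) != ntri)
            stop("truncated GRM: ", paths[2L], " does not match n(n+1)/2")
    }
    A <- matrix(0, n, n)
    row <- rep(seq_len(n), seq_len(n))
    col <- sequence(seq_len(n))
    A[cbind(row, col)] <- tri
    A[cbind(col, row)] <- tri
    dimnames(A) <- list(key, key)
    list(grm = A, ids = ids, nSnps = nSnps)
}

#' Read a phenotype table (PLINK phenotype-file dialect)
#'
#' Whitespace- or tab-separated file with FID and IID followed by trait
#' columns; `NA` marks missing values.  Columns whose non-missing values
#' are all in {0, 1} are flagged binary.
#'
#' @param path file path.
#' @param traitColumns optional character vector selecting trait columns
#'   (default: all non-id columns).
#' @return data.frame with FID, IID and numeric trait columns; attribute
#'   `"binary"` names the traits detected as 0/1.
#' @export
readPhenotypes <- function(path, traitColumns = NULL) {
    tab <- utils::read.table(path, header = TRUE, na.strings = "NA",
                             check.names = FALSE, colClasses = NA,
                             stringsAsFactors = FALSE)
    if (!all(c("FID", "IID") %in% colnames(tab)))
        stop("phenotype file must have FID and IID columns")
    key <- paste(tab$FID, tab$IID)
    if (anyDuplicated(key))
        stop("duplicate individual (FID+IID) in ", path)
    traits <- if (is.null(traitColumns))
        setdiff(colnames(tab), c("FID", "IID")) else traitColumns
    miss <- setdiff(traits, colnames(tab))
    if (length(miss)) stop("trait columns not found: ",
                           paste(miss, collapse = ", "))
    for (tr in traits) {
        v <- tab[[tr]]
        if (!is.numeric(v)) {
            suppressWarnings(num <- as.numeric(v))
            if (any(!is.na(v) & is.na(num)))
                stop("non-numeric values in trait column '", tr, "'")
            tab[[tr]] <- num
        }
    }
    out <- tab[, c("FID", "IID", traits), drop = FALSE]
    binary <- traits[vapply(traits, function(tr) {
        v <- out[[tr]][!is.na(out[[tr]])]
        length(v) > 0L && all(v %in% c(0, 1))
    }, logical(1L))]
    attr(out, "binary") <- binary
    out
}

#' Write / read a variance-component report
#'
#' The report is a `.hsq`-style key-value text file (component estimates
#' with standard errors, restricted log-likelihood, sample size,
#' convergence flags, scale) plus `<prefix>.omega.csv`, the full sampling
#' covariance matrix as a labeled CSV.  `readVarComp()` reconstructs the
#' [VarComp] from the pair.
#'
#' @param vc a [VarComp].
#' @param prefix output path prefix.
#' @return `writeVarComp()`: invisibly, the paths written;
#'   `readVarComp()`: a [VarComp].
#' @export
writeVarComp <- function(vc, prefix) {
    stopifnot(is(vc, "VarComp"))
    paths <- paste0(prefix, c(".hsq", ".omega.csv"))
    est <- vcEstimates(vc)
    se <- sqrt(pmax(diag(samplingCov(vc)), 0))
    lines <- c(
        paste0("scope\t", vc@scope),
        paste0("scale\t", vc@scale),
        sprintf("%s\t%.10g\t%.10g", names(est), est, se),
        sprintf("loglik\t%.10g", vc@loglik),
        sprintf("n\t%d", vc@nUsed),
        sprintf("iterations\t%d", vc@iterations),
        paste0("converged\t", vc@converged),
        paste0("flags\t", paste(vc@flags, collapse = ",")))
    writeLines(lines, paths[1L])
    utils::write.csv(samplingCov(vc), paths[2L])
    invisible(paths)
}

#' @rdname writeVarComp
#' @param prefix path prefix of the `.hsq` / `.omega.csv` pair.
#' @export
readVarComp <- function(prefix) {
    paths <- paste0(prefix, c(".hsq", ".omega.csv"))
    for (p in paths) if (!file.exists(p)) stop("missing report file: ", p)
    raw <- strsplit(readLines(paths[1L]), "\t", fixed = TRUE)
    kv <- setNames(lapply(raw, `[`, -1L), vapply(raw, `[`, "", 1L))
    scope <- kv$scope[1L]
    comp <- if (scope == "univariate") c("vg", "ve") else
        c("vgY", "vgC", "cg", "veY", "veC", "ce")
    est <- vapply(comp, function(k) as.numeric(kv[[k]][1L]), 0)
    om <- as.matrix(utils::read.csv(paths[2L], row.names = 1L))
    dimnames(om) <- list(comp, comp)
    flags <- kv$flags[1L]
    flags <- if (is.na(flags) || flags == "") character() else
        strsplit(flags, ",", fixed = TRUE)[[1L]]
    new("VarComp", scope = scope, estimates = est, Omega = om,
        loglik = as.numeric(kv$loglik[1L]), nUsed = as.integer(kv$n[1L]),
        iterations = as.integer(kv$iterations[1L]),
        converged = as.logical(kv$converged[1L]), flags = flags,
        scale = kv$scale[1L])
}
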