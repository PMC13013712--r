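#' TMM normalization factors
#'
#' Per-sample trimmed-mean-of-M-values factors (Robinson & Oshlack), computed
#' with edgeR's canonical implementation: M-values doubly trimmed (30% on M,
#' 5% on A), weights equal to the inverse asymptotic binomial variance, genes
#' zero in either sample excluded, and factors rescaled so their geometric
#' mean is 1. The reference sample defaults to the one whose 75th-percentile
#' count fraction is closest to the mean.
#'
#' @param x a [ViCountSet-class] with at least two samples.
#' @param refSample optional sample ID to use as the TMM reference.
#' @return named numeric vector of normalization factors (geometric mean 1).
#' @seealso [applyTMM()] to store the factors in the object.
#' @export
tmmFactors <- function(x, refSample = NULL) {
    stopifnot(is(x, "ViCountSet"))
    if (ncol(x) < 2L) stop("TMM needs at least two samples")
    cts <- countsMatrix(x)
    if (any(colSums(cts) == 0)) stop("sample with all-zero counts")
    refCol <- if (!is.null(refSample)) match(refSample, colnames(cts)) else NULL
    if (!is.null(refCol) && is.na(refCol)) stop("refSample not found")
    f <- edgeR::calcNormFactors(cts, lib.size = libSizes(x), method = "TMM",
                                refColumn = refCol)
    setNames(as.numeric(f), colnames(cts))
}

#' Compute and store TMM factors
#'
#' @param x a [ViCountSet-class].
#' @param refSample optional reference sample ID.
#' @return `x` with `norm_factor` replaced by TMM factors.
#' @export
applyTMM <- function(x, refSample = NULL) {
    normFactors(x) <- tmmFactors(x, refSample)
    x
}

#' Filter lowly expressed genes
#'
#' Retains genes with CPM above `cpmThreshold` in at least
#' `ceiling(minFraction * n_samples)` samples. CPM is computed on raw
#' library sizes (pre-TMM, no prior count), matching the convention of the
#' edgeR workflow this mirrors.
#'
#' @param x a [ViCountSet-class].
#' @param cpmThreshold CPM cutoff (default 1).
#' @param minFraction minimum fraction of samples above the cutoff
#'   (default 0.10).
#' @return the filtered [ViCountSet-class] (library sizes unchanged).
#' @export
filterGenes <- function(x, cpmThreshold = 1, minFraction = 0.10) {
    stopifnot(cpmThreshold > 0, minFraction > 0)
    cpm <- t(t(countsMatrix(x)) / libSizes(x)) * 1e6
    nmin <- ceiling(minFraction * ncol(x))
    keep <- rowSums(cpm > cpmThreshold) >= nmin
    if (!any(keep)) warning("no genes survive the expression filter")
    x[keep, ]
}

#' Log2 counts per million
#'
#' `logCPM = log2((count + prior) / (lib_size * norm_factor + 2 * prior) * 1e6)`,
#' with the normalization factors first rescaled to geometric mean 1 (the
#' TMM product convention), which makes downstream z-scores invariant to a
#' global rescaling of the factors.
#'
#' @param x a [ViCountSet-class]; TMM factors are used if present
#'   (default factors of 1 otherwise).
#' @param priorCount prior count added to avoid log of zero (default 0.5).
#' @return numeric matrix of logCPM values with attributes `prior_count`
#'   and `lib_size_eff` (effective library sizes).
#' @export
logCPM <- function(x, priorCount = 0.5) {
    stopifnot(is(x, "ViCountSet"), priorCount > 0)
    nf <- normFactors(x)
    nf <- nf / exp(mean(log(nf)))   # product convention: geometric mean 1
    eff <- libSizes(x) * nf
    out <- log2(t((t(countsMatrix(x)) + priorCount) /
                  (eff + 2 * priorCount)) * 1e6)
    attr(out, "prior_count") <- priorCount
    attr(out, "lib_size_eff") <- eff
    out
}

#' Per-gene z-scores across samples
#'
#' Standardizes each gene (row) to mean 0, sd 1 (denominator n - 1).
#' Constant genes are set to all-zero with a warning.
#'
#' @param m numeric matrix, genes x samples (e.g. from [logCPM()]).
#' @return matrix of the same shape with standardized rows.
#' @export
zscoreByGene <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 2L) stop("z-scoring needs at least two samples")
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    flat <- s == 0 | !is.finite(s)
    if (any(flat)) {
        warning(sum(flat), " constant gene(s) set to zero z-scores")
        s[flat] <- 1
    }
    z <- (m - mu) / s
    z[flat, ] <- 0
    z
}

## ---- readers / writers -----------------------------------------------------

#' Read / write counts as TSV (genes in rows, header = sample IDs)
#'
#' @param path file path.
#' @param meta optional per-sample metadata data.frame passed to
#'   [ViCountSet()].
#' @return `readCountsTsv` returns a [ViCountSet-class]; the writers return
#'   the path invisibly.
#' @export
readCountsTsv <- function(path, meta = NULL) {
    df <- read.delim(path, row.names = 1L, check.names = FALSE)
    ViCountSet(as.matrix(df), meta = meta)
}

#' @rdname readCountsTsv
#' @param x a [ViCountSet-class].
#' @export
writeCountsTsv <- function(x, path) {
    df <- data.frame(gene_id = rownames(x), countsMatrix(x),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write counts as MatrixMarket with gene/sample sidecars
#'
#' The `.mtx` file holds the sparse gene x sample counts; `genes.txt` and
#' `samples.txt` in the same directory hold the row and column IDs, one per
#' line.
#'
#' @param dir directory containing `counts.mtx`, `genes.txt`, `samples.txt`.
#' @param meta optional per-sample metadata.
#' @return `readCountsMtx` returns a [ViCountSet-class].
#' @export
readCountsMtx <- function(dir, meta = NULL) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    rownames(m) <- readLines(file.path(dir, "genes.txt"))
    colnames(m) <- readLines(file.path(dir, "samples.txt"))
    ViCountSet(m, meta = meta)
}

#' @rdname readCountsMtx
#' @param x a [ViCountSet-class].
#' @export
writeCountsMtx <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(countsMatrix(x), sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(rownames(x), file.path(dir, "genes.txt"))
    writeLines(colnames(x), file.path(dir, "samples.txt"))
    invisible(dir)
}

#' Read / write per-sample metadata TSV
#'
#' Required columns: `sample_id`, `grade`, `vi`, `batch`, `tumor_id`,
#' `region_id`.
#'
#' @param path file path.
#' @return `readSampleMeta` returns a data.frame.
#' @export
readSampleMeta <- function(path) {
    df <- read.delim(path, check.names = FALSE,
                     colClasses = c(sample_id = "character"))
    need <- c("sample_id", "grade", "vi", "batch", "tumor_id", "region_id")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("missing metadata columns: ",
                           paste(miss, collapse = ", "))
    df
}

#' @rdname readSampleMeta
#' @param meta data.frame of sample metadata.
#' @export
writeSampleMeta <- function(meta, path) {
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path file path; each GMT line is `name<TAB>description<TAB>genes...`.
#' @return `readGmt` returns a named list of character vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, "", 1L)
    sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param description description field written per set (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
        "")
    writeLines(lines, path)
    invisible(path)
}
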