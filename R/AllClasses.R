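#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats median quantile rnorm rbeta rnbinom rpois runif sd var
#'   p.adjust plogis qbeta qlogis model.matrix hclust cutree dist cor cor.test
#'   wilcox.test ks.test pchisq setNames complete.cases aggregate
#' @importFrom utils read.delim write.table head
NULL

#' Gene-by-sample count container for the VI pipeline
#'
#' `ViCountSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `counts` assay of non-negative integers and two mandatory per-sample
#' columns in `colData`: `lib_size` (positive library sizes, defaulting to
#' column sums) and `norm_factor` (TMM normalization factors, defaulting
#' to 1). Cohort metadata used downstream (`grade`, `vi`, `batch`,
#' `tumor_id`, `region_id`) lives in `colData` as well.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @export
setClass("ViCountSet", contains = "SummarizedExperiment")

setValidity("ViCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene IDs")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("lib_size", "norm_factor") %in% colnames(cd)))
        msg <- c(msg, "colData must contain lib_size and norm_factor")
    else {
        if (any(cd$lib_size <= 0)) msg <- c(msg, "lib_size must be positive")
        if (any(cd$norm_factor <= 0))
            msg <- c(msg, "norm_factor must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ViCountSet
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns; dimnames required (unique gene and sample IDs).
#' @param meta optional `data.frame` of per-sample covariates (e.g. `grade`,
#'   `vi`, `batch`, `tumor_id`, `region_id`), rows matching `colnames(counts)`.
#' @param libSizes per-sample library sizes; defaults to column sums.
#' @param normFactors per-sample normalization factors; defaults to 1.
#' @return A [ViCountSet-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' vcs <- ViCountSet(m)
#' libSizes(vcs)
#' @export
ViCountSet <- function(counts, meta = NULL, libSizes = NULL,
                       normFactors = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have gene and sample dimnames")
    if (is.null(libSizes)) libSizes <- colSums(counts)
    if (is.null(normFactors)) normFactors <- rep(1, ncol(counts))
    cd <- S4Vectors::DataFrame(lib_size = as.numeric(libSizes),
                               norm_factor = as.numeric(normFactors),
                               row.names = colnames(counts))
    if (!is.null(meta)) {
        meta <- as.data.frame(meta)
        if (!is.null(meta$sample_id)) {
            rownames(meta) <- meta$sample_id
            meta$sample_id <- NULL
        }
        meta <- meta[colnames(counts), , drop = FALSE]
        cd <- cbind(cd, S4Vectors::DataFrame(meta))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("ViCountSet", se)
}

#' Signature of co-expressed differentially expressed gene clusters
#'
#' Holds the DE table of significant genes, the gene-to-cluster assignment
#' (Ward2 hierarchical clustering of per-gene z-score profiles), the chosen
#' number of clusters and per-cluster direction of change in VI tumors, plus
#' the consensus-clustering diagnostics used to choose k.
#'
#' @slot genes character, member gene IDs (the FDR-significant set).
#' @slot cluster named integer, cluster label in 1..k per gene.
#' @slot k integer, number of clusters.
#' @slot direction character per cluster, "up" or "down" in VI.
#' @slot deTable data.frame, per-gene DE statistics for the members.
#' @slot consensus list, per-k area under the consensus CDF and delta-areas.
#' @export
setClass("GeneClusterSignature",
    representation(genes = "character", cluster = "integer", k = "integer",
                   direction = "character", deTable = "data.frame",
                   consensus = "list"))

setValidity("GeneClusterSignature", function(object) {
    msg <- character()
    if (!setequal(names(object@cluster), object@genes))
        msg <- c(msg, "cluster labels must cover exactly the member genes")
    if (length(object@k) != 1L || object@k < 1L)
        msg <- c(msg, "k must be a single positive integer")
    else if (!all(object@cluster %in% seq_len(object@k)))
        msg <- c(msg, "cluster labels must lie in 1..k")
    if (length(object@direction) &&
        !all(object@direction %in% c("up", "down")))
        msg <- c(msg, "direction must be 'up' or 'down'")
    if (length(msg)) msg else TRUE
})

#' Ridge binomial-logit VI predictor
#'
#' A fitted compact predictor: the selected gene panel, per-gene
#' standardization parameters estimated on the training cohort, ridge
#' coefficients on the standardized scale, intercept, penalty, and the
#' Youden-point decision cutoff on the probability scale.
#'
#' @slot genes character, panel gene IDs (default panel size 48).
#' @slot center,scale named numeric, per-gene training mean / sd of logCPM.
#' @slot coef named numeric, coefficients on the standardized scale.
#' @slot intercept numeric scalar.
#' @slot lambda numeric, ridge penalty (>= 0).
#' @slot cutoff numeric in \[0, 1\], Youden-point probability cutoff.
#' @slot seed integer, training seed (provenance).
#' @export
setClass("PredictorModel",
    representation(genes = "character", center = "numeric", scale = "numeric",
                   coef = "numeric", intercept = "numeric", lambda = "numeric",
                   cutoff = "numeric", seed = "integer"))

setValidity("PredictorModel", function(object) {
    msg <- character()
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate panel genes")
    for (sl in c("center", "scale", "coef")) {
        v <- slot(object, sl)
        if (!identical(names(v), object@genes))
            msg <- c(msg, sprintf("%s must be named by the panel genes", sl))
    }
    if (any(object@scale <= 0)) msg <- c(msg, "per-gene sd must be > 0")
    if (length(object@lambda) != 1L || object@lambda < 0)
        msg <- c(msg, "lambda must be a single value >= 0")
    if (length(msg)) msg else TRUE
})

#' Confusion counts at a prespecified cutoff
#'
#' @slot tp,fn,tn,fp non-negative integer counts.
#' @export
setClass("DxCounts",
    representation(tp = "integer", fn = "integer", tn = "integer",
                   fp = "integer"))

setValidity("DxCounts", function(object) {
    v <- c(object@tp, object@fn, object@tn, object@fp)
    if (length(v) != 4L || any(v < 0L)) "counts must be non-negative integers"
    else TRUE
})

#' @rdname DxCounts-class
#' @param tp,fn,tn,fp non-negative integers: true/false positives/negatives.
#' @return A `DxCounts` object.
#' @examples
#' DxCounts(10, 2, 11, 1)
#' @export
DxCounts <- function(tp, fn, tn, fp) {
    new("DxCounts", tp = as.integer(tp), fn = as.integer(fn),
        tn = as.integer(tn), fp = as.integer(fp))
}

#' Beta posteriors for sensitivity and specificity
#'
#' Under uniform Beta(1, 1) priors the posteriors are
#' sensitivity ~ Beta(1 + TP, 1 + FN) and specificity ~ Beta(1 + TN, 1 + FP).
#'
#' @slot alphaSens,betaSens numeric, sensitivity posterior parameters.
#' @slot alphaSpec,betaSpec numeric, specificity posterior parameters.
#' @export
setClass("DxPosterior",
    representation(alphaSens = "numeric", betaSens = "numeric",
                   alphaSpec = "numeric", betaSpec = "numeric"))

setValidity("DxPosterior", function(object) {
    v <- c(object@alphaSens, object@betaSens, object@alphaSpec,
           object@betaSpec)
    if (any(v <= 0)) "Beta parameters must be positive" else TRUE
})

setMethod("show", "ViCountSet", function(object) {
    cat(sprintf("ViCountSet: %d genes x %d samples\n",
                nrow(object), ncol(object)))
    callNextMethod()
})

setMethod("show", "GeneClusterSignature", function(object) {
    sizes <- tabulate(object@cluster, nbins = object@k)
    cat(sprintf("GeneClusterSignature: %d genes in %d clusters\n",
                length(object@genes), object@k))
    for (i in seq_len(object@k))
        cat(sprintf("  cluster %d: %d genes (%s in VI)\n", i, sizes[i],
                    object@direction[i]))
    invisible(object)
})

setMethod("show", "PredictorModel", function(object) {
    cat(sprintf(
        "PredictorModel: %d genes, lambda = %.4g, Youden cutoff = %.4f\n",
        length(object@genes), object@lambda, object@cutoff))
    cat(sprintf("  %d positive / %d negative coefficients\n",
                sum(object@coef > 0), sum(object@coef < 0)))
    invisible(object)
})

setMethod("show", "DxCounts", function(object) {
    cat(sprintf("DxCounts: TP=%d FN=%d TN=%d FP=%d (sens %.3f, spec %.3f)\n",
                object@tp, object@fn, object@tn, object@fp,
                object@tp / max(1L, object@tp + object@fn),
                object@tn / max(1L, object@tn + object@fp)))
    invisible(object)
})

setMethod("show", "DxPosterior", function(object) {
    cat(sprintf(
        "DxPosterior: sens ~ Beta(%g, %g), spec ~ Beta(%g, %g)\n",
        object@alphaSens, object@betaSens, object@alphaSpec,
        object@betaSpec))
    invisible(object)
})
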