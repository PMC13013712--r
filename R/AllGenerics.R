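#' Library sizes of a count set
#' @param x a [ViCountSet-class].
#' @return numeric vector of per-sample library sizes.
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname libSizes
#' @export
setMethod("libSizes", "ViCountSet", function(x)
    setNames(SummarizedExperiment::colData(x)$lib_size, colnames(x)))

#' Normalization factors of a count set
#' @param x a [ViCountSet-class].
#' @param value replacement numeric vector, one positive factor per sample.
#' @return numeric vector of per-sample TMM factors.
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' @rdname normFactors
#' @export
setMethod("normFactors", "ViCountSet", function(x)
    setNames(SummarizedExperiment::colData(x)$norm_factor, colnames(x)))

#' @rdname normFactors
#' @export
setGeneric("normFactors<-",
           function(x, value) standardGeneric("normFactors<-"))

#' @rdname normFactors
#' @export
setMethod("normFactors<-", "ViCountSet", function(x, value) {
    stopifnot(length(value) == ncol(x), all(value > 0))
    SummarizedExperiment::colData(x)$norm_factor <- as.numeric(value)
    validObject(x)
    x
})

#' Raw counts of a count set
#' @param x a [ViCountSet-class].
#' @return integer matrix, genes x samples.
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' @rdname countsMatrix
#' @export
setMethod("countsMatrix", "ViCountSet", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' Member genes of a signature or predictor
#' @param x a [GeneClusterSignature-class] or [PredictorModel-class].
#' @return character vector of gene IDs.
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname signatureGenes
#' @export
setMethod("signatureGenes", "GeneClusterSignature", function(x) x@genes)

#' @rdname signatureGenes
#' @export
setMethod("signatureGenes", "PredictorModel", function(x) x@genes)

#' Gene-to-cluster assignment of a signature
#' @param x a [GeneClusterSignature-class].
#' @return named integer vector of cluster labels.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "GeneClusterSignature", function(x) x@cluster)

#' Per-cluster direction of change in VI tumors
#' @param x a [GeneClusterSignature-class].
#' @return character vector, "up"/"down" per cluster.
#' @export
setGeneric("clusterDirections",
           function(x) standardGeneric("clusterDirections"))

#' @rdname clusterDirections
#' @export
setMethod("clusterDirections", "GeneClusterSignature", function(x)
    x@direction)

#' Gene sets of a signature, one per cluster
#' @param x a [GeneClusterSignature-class].
#' @return named list of character vectors (cluster_1 .. cluster_k).
#' @export
setGeneric("clusterGeneSets", function(x) standardGeneric("clusterGeneSets"))

#' @rdname clusterGeneSets
#' @export
setMethod("clusterGeneSets", "GeneClusterSignature", function(x) {
    sets <- split(names(x@cluster), x@cluster)
    names(sets) <- paste0("cluster_", names(sets))
    sets
})
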