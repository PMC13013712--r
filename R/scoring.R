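#' Mean z-score signature score
#'
#' Per-sample mean of the per-gene z-scores over a gene set - the simple
#' cluster score used to summarize each co-expression cluster per tumor.
#'
#' @param z numeric matrix, genes x samples (from [zscoreByGene()]).
#' @param geneSet character vector of gene IDs; genes absent from `z` are
#'   dropped with a warning.
#' @return data.frame: `unit_id`, `score` (one row per sample).
#' @export
meanZscoreScore <- function(z, geneSet) {
    present <- intersect(geneSet, rownames(z))
    if (length(present) == 0L) stop("no gene of the set is in the matrix")
    if (length(present) < length(geneSet))
        warning(length(geneSet) - length(present),
                " set gene(s) absent from the matrix; dropped")
    sc <- colMeans(z[present, , drop = FALSE])
    data.frame(unit_id = colnames(z), score = as.numeric(sc),
               stringsAsFactors = FALSE)
}

#' Log-normalize spot counts
#'
#' `log1p(count / colsum * scale)` per spot, the simple log-normalization
#' applied to individual spatial samples before module scoring.
#'
#' @param counts gene x unit count matrix.
#' @param scaleFactor depth scale (default 1e4).
#' @return gene x unit matrix of log-normalized values.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
    log1p(t(t(counts) / colSums(counts)) * scaleFactor)
}

#' Control-bin module score
#'
#' AddModuleScore-style scoring: genes are binned into `nBins`
#' equal-frequency bins of average expression across units (ties to the
#' lower bin); for each set gene, `nCtrl` control genes are sampled with
#' replacement from its bin; the score per unit is the mean expression of
#' the set genes minus the mean expression of the pooled control draws.
#'
#' @param expr numeric matrix, genes x units, log-normalized expression.
#' @param geneSet character vector of gene IDs (absent genes dropped with a
#'   warning; empty intersection is an error).
#' @param nBins number of average-expression bins (default 24; capped at
#'   the number of genes).
#' @param nCtrl control genes sampled per set gene (default 100).
#' @param seed integer seed for the control draws.
#' @return data.frame: `unit_id`, `score`.
#' @export
moduleScore <- function(expr, geneSet, nBins = 24, nCtrl = 100, seed = 1L) {
    expr <- as.matrix(expr)
    present <- intersect(geneSet, rownames(expr))
    if (length(present) == 0L) stop("no gene of the set is in the matrix")
    if (length(present) < length(geneSet))
        warning(length(geneSet) - length(present),
                " set gene(s) absent; dropped")
    nBins <- min(nBins, nrow(expr))
    avg <- rowMeans(expr)
    # equal-frequency bins; tied averages share the min rank -> lower bin
    r <- rank(avg, ties.method = "min")
    bin <- ceiling(r * nBins / nrow(expr))
    names(bin) <- rownames(expr)
    set.seed(seed)
    ctrl <- unlist(lapply(present, function(g) {
        pool <- names(bin)[bin == bin[[g]]]
        pool[sample.int(length(pool), nCtrl, replace = TRUE)]
    }))
    setScore <- colMeans(expr[present, , drop = FALSE])
    ctrlScore <- colMeans(expr[ctrl, , drop = FALSE])
    data.frame(unit_id = colnames(expr),
               score = as.numeric(setScore - ctrlScore),
               stringsAsFactors = FALSE)
}

#' Up-minus-down predictor spot score
#'
#' Module score of the VI-increased predictor genes minus the module score
#' of the VI-decreased predictor genes, per unit. Both scores use the same
#' seed, so swapping the sets negates the result exactly.
#'
#' @param expr numeric matrix, genes x units.
#' @param upSet,downSet character vectors of gene IDs.
#' @inheritParams moduleScore
#' @return data.frame: `unit_id`, `score`.
#' @export
predictorSpotScore <- function(expr, upSet, downSet, nBins = 24,
                               nCtrl = 100, seed = 1L) {
    up <- moduleScore(expr, upSet, nBins = nBins, nCtrl = nCtrl, seed = seed)
    dn <- moduleScore(expr, downSet, nBins = nBins, nCtrl = nCtrl,
                      seed = seed)
    data.frame(unit_id = up$unit_id, score = up$score - dn$score,
               stringsAsFactors = FALSE)
}

#' Write a score table as TSV
#'
#' @param scores data.frame with `unit_id` and `score`.
#' @param path output path.
#' @param name score name written in the `score_name` column.
#' @return the path, invisibly.
#' @export
writeScoresTsv <- function(scores, path, name = "score") {
    out <- data.frame(unit_id = scores$unit_id, score_name = name,
                      value = scores$score)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
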