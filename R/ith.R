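#' Sample matched intra- and inter-tumor region pairs
#'
#' Down-samples every tumor to two regions (one intra-tumor pair per tumor)
#' and draws an equal number of inter-tumor pairs, each built from one
#' random region of each of two distinct tumors (tumors drawn without
#' replacement within a draw, with replacement across draws). Tumors with a
#' single region are excluded with a warning.
#'
#' @param scores data.frame with columns `tumor_id`, `region_id`, `score`
#'   (as produced by [generateMultiregionCohort()]).
#' @param seed integer seed.
#' @return data.frame: `tumor_id` (intra) or `tumor_a`/`tumor_b` (inter,
#'   joined with ";"), `region_a`, `region_b`, `score_a`, `score_b`,
#'   `pair_type` ("intra"/"inter").
#' @export
sampleRegionPairs <- function(scores, seed = 1L) {
    set.seed(seed)
    byTumor <- split(scores, scores$tumor_id)
    nReg <- vapply(byTumor, nrow, 0L)
    if (any(nReg < 2L)) {
        warning(sum(nReg < 2L), " tumor(s) with a single region excluded")
        byTumor <- byTumor[nReg >= 2L]
    }
    if (length(byTumor) < 2L) stop("need at least two multi-region tumors")
    intra <- do.call(rbind, lapply(byTumor, function(df) {
        i <- sample.int(nrow(df), 2L)
        data.frame(tumor_id = df$tumor_id[1L],
                   region_a = df$region_id[i[1L]],
                   region_b = df$region_id[i[2L]],
                   score_a = df$score[i[1L]], score_b = df$score[i[2L]],
                   pair_type = "intra", stringsAsFactors = FALSE)
    }))
    tumors <- names(byTumor)
    inter <- do.call(rbind, lapply(seq_along(tumors), function(d) {
        tt <- sample(tumors, 2L)           # without replacement in a draw
        a <- byTumor[[tt[1L]]]; b <- byTumor[[tt[2L]]]
        ia <- sample.int(nrow(a), 1L); ib <- sample.int(nrow(b), 1L)
        data.frame(tumor_id = paste(tt, collapse = ";"),
                   region_a = a$region_id[ia], region_b = b$region_id[ib],
                   score_a = a$score[ia], score_b = b$score[ib],
                   pair_type = "inter", stringsAsFactors = FALSE)
    }))
    out <- rbind(intra, inter)
    rownames(out) <- NULL
    out
}

#' Intra- versus inter-tumor heterogeneity test
#'
#' Compares the absolute score difference of matched within-tumor region
#' pairs against between-tumor pairs with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param pairs data.frame from [sampleRegionPairs()].
#' @return list: `medianIntra`, `medianInter`, `pvalue`.
#' @export
intraInterTest <- function(pairs) {
    d <- abs(pairs$score_a - pairs$score_b)
    intra <- d[pairs$pair_type == "intra"]
    inter <- d[pairs$pair_type == "inter"]
    if (!length(intra) || !length(inter))
        stop("both pair types must be present")
    p <- if (length(unique(c(intra, inter))) == 1L) 1
         else suppressWarnings(wilcox.test(intra, inter,
                                           exact = FALSE)$p.value)
    list(medianIntra = median(intra), medianInter = median(inter),
         pvalue = p)
}

#' Spearman correlation of matched region pairs
#'
#' @param pairs data.frame from [sampleRegionPairs()]; only intra pairs are
#'   used (>= 3 required).
#' @return list: `rho`, `pvalue` (t-approximation).
#' @export
regionPairCorrelation <- function(pairs) {
    intra <- pairs[pairs$pair_type == "intra", , drop = FALSE]
    if (nrow(intra) < 3L) stop("need at least 3 intra-tumor pairs")
    if (sd(intra$score_a) == 0 || sd(intra$score_b) == 0)
        stop("constant scores: correlation undefined")
    ct <- suppressWarnings(cor.test(intra$score_a, intra$score_b,
                                    method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), pvalue = ct$p.value)
}

#' Pre-ranked gene set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Genes are ordered by decreasing ranking value; the running sum gains
#' `|value|^weightP` (normalized over the set) at set genes and loses
#' `1 / (N - |set|)` elsewhere. ES is the extremum of the running sum; the
#' null is built by drawing random sets of the same size, NES divides ES by
#' the mean |null ES| of the same sign, and the two-sided p-value is the
#' permutation fraction with `|null| >= |ES|`.
#'
#' @param values named numeric vector of per-gene ranking values.
#' @param geneSet character vector, a strict nonempty subset of
#'   `names(values)`.
#' @param weightP enrichment weight exponent (default 1).
#' @param nPerm permutations (default 1000).
#' @param seed integer seed.
#' @return list: `ES`, `NES`, `pvalue`.
#' @export
prerankedGsea <- function(values, geneSet, weightP = 1, nPerm = 1000,
                          seed = 1L) {
    if (all(values == 0)) stop("all ranking values are zero")
    geneSet <- unique(geneSet)
    if (!length(geneSet) || !all(geneSet %in% names(values)))
        stop("geneSet must be a nonempty subset of the ranked universe")
    if (length(geneSet) >= length(values))
        stop("geneSet must be a strict subset")
    ord <- order(values, decreasing = TRUE)
    v <- values[ord]
    isHit <- names(v) %in% geneSet
    es <- gseaES(v, isHit, weightP)
    set.seed(seed)
    m <- length(geneSet); N <- length(v)
    null <- vapply(seq_len(nPerm), function(b) {
        hit <- logical(N)
        hit[sample.int(N, m)] <- TRUE
        gseaES(v, hit, weightP)
    }, 0)
    sameSign <- null[sign(null) == sign(es)]
    nes <- if (length(sameSign)) es / mean(abs(sameSign)) else NA_real_
    p <- (1 + sum(abs(null) >= abs(es))) / (1 + nPerm)
    list(ES = es, NES = nes, pvalue = p)
}

# Running-sum enrichment score for one hit indicator.
gseaES <- function(v, isHit, weightP) {
    w <- abs(v)^weightP
    hitSum <- sum(w[isHit])
    if (hitSum == 0) {                       # all-zero hit weights: uniform
        inc <- ifelse(isHit, 1 / sum(isHit), 0)
    } else {
        inc <- ifelse(isHit, w / hitSum, 0)
    }
    dec <- ifelse(isHit, 0, 1 / sum(!isHit))
    run <- cumsum(inc - dec)
    run[which.max(abs(run))]
}
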