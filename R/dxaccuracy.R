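#' Confusion counts at a prespecified cutoff
#'
#' Units are called positive iff `score > cutoff` (strict inequality; a
#' score exactly at the cutoff is called negative).
#'
#' @param scores numeric predictor scores.
#' @param labels binary 0/1 truth labels.
#' @param cutoff decision cutoff (e.g. the Youden point of the training
#'   cohort); `-Inf` calls everything positive.
#' @return a [DxCounts-class].
#' @export
confusionCounts <- function(scores, labels, cutoff) {
    stopifnot(!is.na(cutoff), all(labels %in% c(0, 1)))
    pos <- scores > cutoff
    DxCounts(tp = sum(pos & labels == 1), fn = sum(!pos & labels == 1),
             tn = sum(!pos & labels == 0), fp = sum(pos & labels == 0))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' `lo = qbeta(alpha/2; k, n-k+1)` (0 when k = 0) and
#' `hi = qbeta(1-alpha/2; k+1, n-k)` (1 when k = n).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return named numeric c(lo, hi).
#' @export
clopperPearson <- function(k, n, level = 0.95) {
    if (n < 1 || k < 0 || k > n) stop("require 0 <= k <= n, n >= 1")
    alpha <- 1 - level
    lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
    c(lo = lo, hi = hi)
}

#' Beta posteriors for sensitivity and specificity
#'
#' Under uniform Beta(1, 1) priors: sensitivity ~ Beta(1 + TP, 1 + FN),
#' specificity ~ Beta(1 + TN, 1 + FP).
#'
#' @param counts a [DxCounts-class].
#' @return a [DxPosterior-class].
#' @export
betaPosteriors <- function(counts) {
    stopifnot(is(counts, "DxCounts"))
    new("DxPosterior",
        alphaSens = 1 + counts@tp, betaSens = 1 + counts@fn,
        alphaSpec = 1 + counts@tn, betaSpec = 1 + counts@fp)
}

#' Monte-Carlo projection of PPV and NPV across prevalence
#'
#' Draws paired (sensitivity, specificity) samples from the Beta
#' posteriors and applies Bayes' theorem per draw and prevalence:
#' `PPV = se p / (se p + (1 - sp)(1 - p))`,
#' `NPV = sp (1 - p) / ((1 - se) p + sp (1 - p))`.
#' Summaries are the median and the 2.5th/97.5th linear-interpolation
#' (type-7) percentiles of the draws. The same draws are reused across
#' prevalences, so PPV is nondecreasing and NPV nonincreasing in
#' prevalence draw by draw.
#'
#' @param post a [DxPosterior-class].
#' @param prevalences assumed disease prevalences in (0, 1)
#'   (default c(0.15, 0.20, 0.25, 0.30, 0.35)).
#' @param nDraws Monte-Carlo draws (default 10000, minimum 1000).
#' @param seed integer seed.
#' @return data.frame with one row per prevalence: `prevalence`,
#'   `ppv_median`, `ppv_lo`, `ppv_hi`, `npv_median`, `npv_lo`, `npv_hi`;
#'   the raw draws are attached as attribute `draws` (list with `sens`,
#'   `spec`).
#' @export
projectPpvNpv <- function(post, prevalences = c(0.15, 0.20, 0.25, 0.30, 0.35),
                          nDraws = 10000, seed = 1L) {
    stopifnot(is(post, "DxPosterior"), nDraws >= 1000)
    if (any(prevalences <= 0 | prevalences >= 1))
        stop("prevalences must lie strictly inside (0, 1)")
    set.seed(seed)
    se <- rbeta(nDraws, post@alphaSens, post@betaSens)
    sp <- rbeta(nDraws, post@alphaSpec, post@betaSpec)
    rows <- lapply(prevalences, function(p) {
        ppv <- se * p / (se * p + (1 - sp) * (1 - p))
        npv <- sp * (1 - p) / ((1 - se) * p + sp * (1 - p))
        data.frame(prevalence = p,
                   ppv_median = median(ppv),
                   ppv_lo = unname(quantile(ppv, 0.025)),
                   ppv_hi = unname(quantile(ppv, 0.975)),
                   npv_median = median(npv),
                   npv_lo = unname(quantile(npv, 0.025)),
                   npv_hi = unname(quantile(npv, 0.975)))
    })
    out <- do.call(rbind, rows)
    attr(out, "draws") <- list(sens = se, spec = sp)
    out
}
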