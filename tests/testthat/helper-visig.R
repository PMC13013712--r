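# Shared fixtures and small independent oracles, built in code.

# small deterministic count matrix with dimnames
makeToyCounts <- function(nGenes = 20, nSamples = 6, seed = 1) {
    set.seed(seed)
    m <- matrix(rnbinom(nGenes * nSamples, mu = 100, size = 5),
                nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%02d", seq_len(nSamples))))
    m
}

# default synthetic cohort, filtered and TMM-normalized, cached per session
defaultCohort <- local({
    cache <- NULL
    function(seed = 11) {
        if (is.null(cache)) {
            sim <- generateBulkCohort(cohortConfig(seed = seed))
            vcs <- applyTMM(filterGenes(sim$counts))
            cache <<- list(sim = sim, vcs = vcs)
        }
        cache
    }
})

# adjusted Rand index (independent implementation for recovery checks)
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    expected <- ai * bj / choose(n, 2)
    maxidx <- (ai + bj) / 2
    (sumij - expected) / (maxidx - expected)
}

# brute-force TMM factor for one sample against a reference column,
# straight from the published formula (doubly trimmed weighted mean of
# M-values); independent of edgeR
bruteTmmPair <- function(obs, ref, libO, libR, trimM = 0.3, trimA = 0.05) {
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    M <- log2((obs / libO) / (ref / libR))
    A <- 0.5 * log2((obs / libO) * (ref / libR))
    w <- (libO - obs) / (libO * obs) + (libR - ref) / (libR * ref)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    k2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum((M / w)[k2]) / sum((1 / w)[k2]))
}

# exhaustive-pair AUROC oracle (ties count one half)
pairCountAuroc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}
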