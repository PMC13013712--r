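test_that("BH adjustment matches the hand-computed step-up", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(c(0.01, NA, 0.02)),
                 c(p.adjust(c(0.01, 0.02), "BH")[1], NA,
                   p.adjust(c(0.01, 0.02), "BH")[2]))
    expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("signed ranking statistic and tie-break ordering behave", {
    de <- data.frame(gene = c("a", "b", "c", "d"),
                     logFC = c(-1, 0.5, 1.5, 2),
                     pvalue = c(0.01, 0.05, 0.05, 1))
    s <- signedRankStat(de)
    expect_equal(unname(s["a"]), -2)
    expect_equal(unname(s["d"]), 0)
    # identical p and sign: larger |logFC| first among positives
    de2 <- data.frame(gene = c("x", "y"), logFC = c(0.5, 1.5),
                      pvalue = c(0.05, 0.05))
    expect_equal(rankedGeneList(de2), c("y", "x"))
})

test_that("Ward2 clustering separates blobs and handles boundary k", {
    set.seed(4)
    z <- rbind(matrix(rnorm(50, 5), 10, 5), matrix(rnorm(50, -5), 10, 5))
    rownames(z) <- paste0("g", 1:20)
    cl <- ward2Cluster(z, 2)
    expect_equal(length(unique(cl[1:10])), 1)
    expect_equal(length(unique(cl[11:20])), 1)
    expect_false(cl[1] == cl[11])
    expect_equal(sort(unique(ward2Cluster(z, 20))), 1:20)
    expect_error(ward2Cluster(z, 21), "exceeds")
})

test_that("NB GLM LRT is calibrated and degenerates correctly", {
    # single-gene toy, identical group means -> LR near 0, p near 1
    m <- matrix(c(100, 100, 100, 100, 100, 100), 1, 6,
                dimnames = list("g1", paste0("s", 1:6)))
    meta <- data.frame(sample_id = paste0("s", 1:6),
                       grade = rep(c("LMP", "NST", "VI"), each = 2),
                       vi = rep(c(0, 0, 1), each = 2))
    vcs <- ViCountSet(m, meta = meta, libSizes = rep(1e5, 6))
    de <- nbGlmLrt(vcs, dispersion = 0.1)
    expect_lt(de$LR, 1e-6)
    expect_gt(de$pvalue, 0.999)
})

test_that("NB LRT approaches the Poisson GLM LRT as dispersion vanishes", {
    set.seed(8)
    m <- makeToyCounts(25, 12, seed = 8)
    grade <- rep(c("LMP", "NST", "VI"), each = 4)
    meta <- data.frame(sample_id = colnames(m), grade = grade,
                       vi = as.integer(grade == "VI"))
    vcs <- ViCountSet(m, meta = meta)
    de <- nbGlmLrt(vcs, dispersion = 1e-6)
    design <- model.matrix(~factor(grade, levels = c("LMP", "NST", "VI")))
    off <- log(libSizes(vcs))
    for (i in seq_len(5)) {
        y <- countsMatrix(vcs)[i, ]
        full <- glm(y ~ design - 1 + offset(off), family = poisson())
        red <- glm(y ~ design[, 1:2] - 1 + offset(off), family = poisson())
        lrPois <- red$deviance - full$deviance
        if (lrPois > 0.1)
            expect_lt(abs(de$LR[i] - lrPois) / lrPois, 0.01)
    }
})

test_that("DE p-values are near-uniform under the generator's null", {
    sim <- generateBulkCohort(cohortConfig(seed = 21,
                                           clusterLog2fc = c(0, 0, 0, 0)))
    vcs <- applyTMM(filterGenes(sim$counts))
    de <- nbGlmLrt(vcs)
    expect_gte(nrow(de), 1500)
    frac <- mean(de$pvalue < 0.05, na.rm = TRUE)
    expect_lt(abs(frac - 0.05), 0.02)
    ks <- suppressWarnings(ks.test(de$pvalue, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
})

test_that("consensus matrices are valid and crisp for two clean clusters", {
    set.seed(6)
    z <- rbind(matrix(rnorm(80, 6), 16, 5), matrix(rnorm(80, -6), 16, 5))
    rownames(z) <- paste0("g", 1:32)
    cs <- consensusSelectK(z, kRange = 2:4, nSubsamples = 30, seed = 2)
    cm <- cs$consensus[["2"]]
    off <- cm[upper.tri(cm)]
    expect_true(all(off[!is.na(off)] %in% c(0, 1)))
    # at k = 2 the consensus reproduces blob membership exactly
    blob <- rep(1:2, each = 16)
    same <- outer(blob, blob, "==")[upper.tri(cm)]
    ok <- !is.na(off)
    expect_equal(off[ok], as.numeric(same)[ok])
    # structural validity on noise data
    zr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(paste0("r", 1:20), NULL))
    cr <- consensusSelectK(zr, kRange = 2:3, nSubsamples = 20, seed = 3)
    for (cm in cr$consensus) {
        expect_true(isSymmetric(unname(cm)))
        expect_true(all(diag(cm) == 1))
        expect_true(all(cm[!is.na(cm)] >= 0 & cm[!is.na(cm)] <= 1))
    }
})

test_that("consensus assignment is equivariant under gene permutation", {
    # with no subsampling randomness the consensus is deterministic, so
    # permuting input rows must permute the consensus identically
    set.seed(9)
    z <- rbind(matrix(rnorm(60, 3), 12, 5), matrix(rnorm(60, -3), 12, 5))
    rownames(z) <- paste0("g", 1:24)
    c1 <- consensusSelectK(z, kRange = 2:3, nSubsamples = 5,
                           itemFraction = 1, seed = 1)
    perm <- sample(24)
    c2 <- consensusSelectK(z[perm, ], kRange = 2:3, nSubsamples = 5,
                           itemFraction = 1, seed = 1)
    g <- rownames(z)
    expect_equal(c2$consensus[["2"]][g, g], c1$consensus[["2"]][g, g])
})

test_that("signature directions match the planted cluster signs", {
    d <- defaultCohort()
    de <- nbGlmLrt(d$vcs)
    z <- zscoreByGene(logCPM(d$vcs))
    sig <- buildSignature(de, z, k = 4)
    expect_equal(sig@k, 4L)
    # map each fitted cluster to the dominant planted cluster
    planted <- d$sim$truth$clusterGenes
    for (i in seq_len(4)) {
        genes <- names(clusterLabels(sig))[clusterLabels(sig) == i]
        ov <- vapply(planted, function(p) length(intersect(genes, p)), 0L)
        dominant <- which.max(ov)
        wanted <- if (dominant == 4L) "down" else "up"
        expect_equal(clusterDirections(sig)[i], wanted)
    }
    # export round-trips
    gmt <- withr::local_tempfile(fileext = ".gmt")
    writeSignatureGmt(sig, gmt)
    sets <- readGmt(gmt)
    expect_equal(lengths(sets), table(clusterLabels(sig)),
                 ignore_attr = TRUE)
})
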