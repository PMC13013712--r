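test_that("proportional selection apportions quotas by largest remainder", {
    # synthetic DE table + signature with the canonical cluster sizes
    sizes <- c(115, 37, 182, 140)
    genes <- sprintf("g%04d", seq_len(sum(sizes)))
    cl <- rep(1:4, sizes)
    de <- data.frame(gene = genes, logFC = ifelse(cl == 4, -1, 1),
                     pvalue = seq(1e-6, 1e-3, length.out = length(genes)))
    de$qvalue <- bhAdjust(de$pvalue)
    sig <- new("GeneClusterSignature", genes = genes,
               cluster = setNames(as.integer(cl), genes), k = 4L,
               direction = c("up", "up", "up", "down"),
               deTable = de, consensus = list())
    sel <- proportionalSelect(de, sig, nTotal = 48)
    expect_length(sel, 48)
    expect_equal(attr(sel, "quotas"), c(12L, 4L, 18L, 14L))
    # within-cluster picks are the smallest p-values
    c1 <- genes[cl == 1]
    expect_setequal(intersect(sel, c1), c1[1:12])
    # identity when nTotal equals the significant count
    selAll <- proportionalSelect(de, sig, nTotal = length(genes))
    expect_setequal(as.vector(selAll), genes)
})

test_that("ridge logit matches an independent numerical optimizer", {
    set.seed(21)
    X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- c(0, 0, 0, 1, 1, 1)
    lambda <- 1
    fit <- fitRidgeLogit(X, y, lambda)
    obj <- function(b) {
        eta <- b[1] + X %*% b[2:3]
        -mean(y * eta - log1p(exp(eta))) + lambda / 2 * sum(b[2:3]^2)
    }
    opt <- optim(c(0, 0, 0), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    expect_lt(max(abs(c(fit$intercept, fit$coef) - opt$par)), 1e-6)
})

test_that("ridge shrinkage is monotone and saturates at huge penalty", {
    set.seed(22)
    X <- matrix(rnorm(100), 20, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- rbinom(20, 1, plogis(X[, 1]))
    norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l)
        sqrt(sum(fitRidgeLogit(X, y, l)$coef^2)), 0)
    expect_true(all(diff(norms) <= 1e-8))
    big <- fitRidgeLogit(X, y, 1e6)
    expect_lt(sqrt(sum(big$coef^2)), 1e-3)
    expect_equal(unname(big$intercept), qlogis(mean(y)), tolerance = 1e-3)
})

test_that("ridge fit is invariant to duplicating every observation", {
    set.seed(23)
    X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("x", 1:4)))
    y <- rep(c(0, 1), 5)
    f1 <- fitRidgeLogit(X, y, 0.5)
    f2 <- fitRidgeLogit(rbind(X, X), c(y, y), 0.5)
    expect_equal(f1$coef, f2$coef, tolerance = 1e-7)
    expect_equal(f1$intercept, f2$intercept, tolerance = 1e-7)
})

test_that("inner CV returns the singleton penalty and favors finite ones", {
    set.seed(24)
    # correlated features whose joint signal is the difference: marginal
    # (fully shrunken) coefficients rank poorly, so extreme penalties lose
    x1 <- rnorm(80)
    x2 <- x1 + 0.3 * rnorm(80)
    X <- cbind(x1 = x1, x2 = x2)
    y <- rbinom(80, 1, plogis(6 * (x1 - x2)))
    expect_equal(as.numeric(innerCvLambda(X, y, lambdaGrid = 0.7, seed = 1)),
                 0.7)
    grid <- defaultLambdaGrid()
    for (s in 1:5) {
        lam <- as.numeric(innerCvLambda(X, y, lambdaGrid = grid, seed = s))
        expect_lt(lam, max(grid))
    }
})

test_that("AUROC equals exhaustive pair counting and flips with labels", {
    expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1), nBoot = 0)$auroc, 1)
    expect_equal(auroc(c(1, 3, 2, 4), c(0, 0, 1, 1), nBoot = 0)$auroc, 0.75)
    set.seed(25)
    for (r in 1:20) {
        n <- sample(4:8, 1)
        sc <- sample(1:5, n, replace = TRUE)   # ties included
        lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
        a <- auroc(sc, lab, nBoot = 0)$auroc
        expect_equal(a, pairCountAuroc(sc, lab))
        expect_equal(auroc(sc, 1 - lab, nBoot = 0)$auroc, 1 - a)
    }
    ci <- auroc(rnorm(40), rep(c(0, 1), 20), nBoot = 200, seed = 1)$ci
    expect_length(ci, 2)
    expect_true(ci[1] <= ci[2])
    expect_error(auroc(1:4, rep(1, 4)), "both classes")
})

test_that("Youden cutoff maximizes J with the documented tie rule", {
    # enumerated example: maximal J = 0.5 attained between 0.1 and 0.35,
    # and again above 0.4; tie rule picks the lower cutoff
    ct <- youdenCutoff(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
    expect_equal(attr(ct, "J"), 0.5)
    expect_gt(ct, 0.1); expect_lt(ct, 0.35)
    # perfect separation
    ct2 <- youdenCutoff(c(1, 2, 10, 11), c(0, 0, 1, 1))
    expect_equal(attr(ct2, "J"), 1)
    expect_gt(ct2, 2); expect_lt(ct2, 10)
    # all-identical scores: no discrimination
    ct3 <- youdenCutoff(rep(0.4, 6), c(0, 0, 0, 1, 1, 1))
    expect_equal(attr(ct3, "J"), 0)
})

test_that("predictor scores follow the logistic form and gene monotonicity", {
    genes <- paste0("g", 1:3)
    model <- new("PredictorModel", genes = genes,
                 center = setNames(c(1, 2, 3), genes),
                 scale = setNames(c(1, 1, 2), genes),
                 coef = setNames(c(0.5, -0.2, 0.1), genes),
                 intercept = -0.3, lambda = 1, cutoff = 0.5, seed = 1L)
    lcm <- matrix(c(1, 2, 3), 3, 2, dimnames = list(genes, c("a", "b")))
    sc <- predictScore(model, lcm)
    expect_equal(sc$score, rep(plogis(-0.3), 2))
    lcm2 <- lcm; lcm2["g1", "a"] <- 2   # positive coefficient: score rises
    expect_gt(predictScore(model, lcm2)$score[1], sc$score[1])
    expect_error(predictScore(model, lcm[1:2, ]), "absent")
    expect_warning(si <- predictScore(model, lcm[1:2, ],
                                      imputeMissing = TRUE), "imputed")
    expect_equal(si$score, rep(plogis(-0.3 + 0.5 * 0 - 0.2 * 0), 2))
})

test_that("model JSON serialization round-trips", {
    genes <- paste0("g", 1:4)
    model <- new("PredictorModel", genes = genes,
                 center = setNames(rnorm(4), genes),
                 scale = setNames(runif(4, 0.5, 2), genes),
                 coef = setNames(rnorm(4), genes),
                 intercept = 0.2, lambda = 3.5, cutoff = 0.41, seed = 9L)
    path <- withr::local_tempfile(fileext = ".json")
    writePredictorJson(model, path)
    back <- readPredictorJson(path)
    expect_equal(back@coef, model@coef, tolerance = 1e-12)
    expect_equal(back@cutoff, model@cutoff)
    expect_identical(back@genes, model@genes)
})

test_that("reference adjustment matches moments exactly and fixes cutoffs", {
    d <- defaultCohort()
    model <- suppressWarnings(trainFinal(d$vcs, predictorConfig(),
                                         seed = 7))
    expect_length(signatureGenes(model), 48)
    lcmD <- logCPM(d$vcs)
    # self-map is moment-identical
    self <- referenceAdjust(lcmD, lcmD)
    expect_equal(rowMeans(self), rowMeans(lcmD), tolerance = 1e-10)

    cfgV <- cohortConfig(seed = 31, nSamples = 60, batchShiftSd = 1)
    val <- generateBulkCohort(cfgV, truth = d$sim$truth)
    vv <- applyTMM(filterGenes(val$counts))
    lcmV <- logCPM(vv)
    adj <- suppressWarnings(referenceAdjust(lcmV, lcmD))
    shared <- rownames(adj)
    expect_lt(max(abs(rowMeans(adj) - rowMeans(lcmD[shared, ]))), 1e-10)
    expect_lt(max(abs(apply(adj, 1, sd) - apply(lcmD[shared, ], 1, sd))),
              1e-8)

    # a cohort-wide per-gene shift moves every linear score by the same
    # constant: ranks (AUROC) survive, fixed-cutoff calibration does not
    vi <- SummarizedExperiment::colData(vv)$vi
    sRaw <- suppressWarnings(predictScore(model, lcmV,
                                          imputeMissing = TRUE))
    sAdj <- suppressWarnings(predictScore(model, adj,
                                          imputeMissing = TRUE))
    aRaw <- auroc(sRaw$score, vi, nBoot = 0)$auroc
    aAdj <- auroc(sAdj$score, vi, nBoot = 0)$auroc
    expect_gt(aAdj, 0.85)
    expect_lt(abs(aAdj - aRaw), 0.1)
    jAt <- function(sc) {
        cc <- confusionCounts(sc, vi, model@cutoff)
        cc@tp / (cc@tp + cc@fn) + cc@tn / (cc@tn + cc@fp) - 1
    }
    expect_gt(jAt(sAdj$score), jAt(sRaw$score))
})

test_that("training is blind to held-out samples", {
    d <- defaultCohort()
    vcs <- d$vcs
    n <- ncol(vcs)
    trIdx <- which(seq_len(n) %% 10 < 7)   # ~70%, spanning all grades
    teIdx <- setdiff(seq_len(n), trIdx)
    lcm <- logCPM(vcs)
    cfg <- predictorConfig()
    t1 <- visig:::trainOnCohort(vcs[, trIdx], lcm[, trIdx], cfg, seed = 3)
    # corrupt labels of the held-out samples only
    vcs2 <- vcs
    cd <- SummarizedExperiment::colData(vcs2)
    cd$vi[teIdx] <- 1 - cd$vi[teIdx]
    cd$grade[teIdx] <- "VI"
    SummarizedExperiment::colData(vcs2) <- cd
    t2 <- visig:::trainOnCohort(vcs2[, trIdx], lcm[, trIdx], cfg, seed = 3)
    expect_identical(t1$panel, t2$panel)
    expect_equal(t1$fit$coef, t2$fit$coef)
})

test_that("final model is reproducible and self-consistent", {
    d <- defaultCohort()
    m1 <- suppressWarnings(trainFinal(d$vcs, predictorConfig(), seed = 7))
    m2 <- suppressWarnings(trainFinal(d$vcs, predictorConfig(), seed = 7))
    expect_equal(m1@coef, m2@coef)
    expect_equal(m1@cutoff, m2@cutoff)
    # stored cutoff reproduces on training scores
    sc <- predictScore(m1, logCPM(d$vcs))
    vi <- SummarizedExperiment::colData(d$vcs)$vi
    expect_equal(as.numeric(youdenCutoff(sc$score, vi)), m1@cutoff)
    # positive coefficients come from planted up-clusters, negative from
    # the down-cluster
    up <- unlist(d$sim$truth$clusterGenes[1:3])
    dn <- d$sim$truth$clusterGenes[[4]]
    co <- m1@coef
    expect_gte(mean(names(co)[co > 0] %in% up), 0.8)
    expect_gte(mean(names(co)[co < 0] %in% dn), 0.8)
})

test_that("KS rank enrichment flags a top-block subset and stays calibrated", {
    ranked <- sprintf("g%03d", 1:60)
    top <- ksRankEnrichment(ranked, ranked[1:5])
    expect_equal(top$D, 1)   # block at the very top vs complement
    expect_lt(top$pvalue, 0.01)
    set.seed(31)
    ps <- vapply(1:200, function(i)
        ksRankEnrichment(ranked, sample(ranked, 10))$pvalue, 0)
    expect_gt(mean(ps > 0.05), 0.8)   # mostly unremarkable under the null
    expect_error(ksRankEnrichment(ranked, ranked), "strict")
    expect_error(ksRankEnrichment(ranked, character(0)), "empty")
})
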