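test_that("spot filter applies the detection boundary exactly", {
    sp <- data.frame(spot_id = c("a", "b", "c"), x_um = 0, y_um = 0,
                     annotation = "normal", n_genes = c(249, 250, 400))
    kept <- filterSpots(sp)
    expect_setequal(kept$spot_id, c("b", "c"))
    expect_identical(filterSpots(kept), kept)
    expect_error(filterSpots(sp, minGenes = 1000), "no spot")
    # planted low-depth spots are exactly the casualties
    layout <- matrix("normal", 5, 5)
    cfg <- spotConfig(layout, regionMeans = list(normal = c(s = 0)),
                      lowDepthFraction = 0.2, seed = 3)
    spots <- generateSpotSample(cfg)$spots
    kept2 <- filterSpots(spots)
    expect_setequal(kept2$spot_id, spots$spot_id[spots$n_genes >= 250])
    expect_equal(nrow(spots) - nrow(kept2), 5)
})

test_that("pseudo-bulk sums are additive and track generating means", {
    layout <- matrix(rep(c("normal", "tumor"), each = 8), 4, 4)
    mu <- list(normal = c(g1 = 5, g2 = 50, g3 = 200),
               tumor = c(g1 = 5, g2 = 50, g3 = 200))
    cfg <- spotConfig(layout, regionMeans = mu, mode = "count", seed = 6)
    g <- generateSpotSample(cfg)
    pb <- pseudoBulk(g$counts)
    half1 <- pseudoBulk(g$counts, g$spots$spot_id[1:8])
    half2 <- pseudoBulk(g$counts, g$spots$spot_id[9:16])
    expect_equal(half1 + half2, pb)
    expect_equal(pseudoBulk(g$counts, g$spots$spot_id[1]),
                 g$counts[, 1])
    # Poisson count mode: pseudo-bulk ranks follow the generating means
    mu2 <- list(normal = setNames(2^seq(0, 7, length.out = 20),
                                  paste0("g", 1:20)))
    cfg2 <- spotConfig(matrix("normal", 6, 6), regionMeans = mu2,
                       mode = "count", seed = 7)
    g2 <- generateSpotSample(cfg2)
    rho <- cor(pseudoBulk(g2$counts), mu2$normal, method = "spearman")
    expect_gte(rho, 0.9)
})

test_that("spatially weighted correlation hits its analytic anchors", {
    layout <- matrix("normal", 7, 7)
    cfg <- spotConfig(layout, regionMeans = list(normal = c(a = 0, b = 0)),
                      noiseSd = 1, seed = 8)
    sp <- generateSpotSample(cfg)$spots
    sp$b <- sp$a
    r <- swCorrelation(sp, "a", "b")
    expect_equal(r$mean, 1, tolerance = 1e-12)
    sp$b <- -sp$a
    expect_equal(swCorrelation(sp, "a", "b")$mean, -1, tolerance = 1e-12)
    # infinite uniform bandwidth reduces to the global Spearman
    sp$b <- rnorm(nrow(sp))
    rInf <- swCorrelation(sp, "a", "b", bandwidth = Inf,
                          kernel = "uniform")
    expect_lt(abs(rInf$mean - cor(sp$a, sp$b, method = "spearman")), 1e-6)
    # monotone transforms leave the Spearman version unchanged
    sp2 <- sp
    sp2$a <- exp(sp$a); sp2$b <- sp$b^3 + 5 * sp$b
    r1 <- swCorrelation(sp, "a", "b", bandwidth = 3)
    r2 <- swCorrelation(sp2, "a", "b", bandwidth = 3)
    expect_equal(r1$local, r2$local, tolerance = 1e-12)
})

test_that("distance binning is geometric, inclusive, and rigid-motion safe", {
    sp <- data.frame(
        spot_id = c("f", "p", "q"),
        x_um = c(0, 600, 600), y_um = c(0, 800, 801),
        annotation = c("VI focus", "tumor", "tumor"))
    bins <- distanceBins(sp)
    expect_equal(bins, c("proximal", "proximal", "distal"))  # 1000 vs >1000
    # no focus: everything distal
    sp2 <- sp; sp2$annotation <- "tumor"
    expect_equal(distanceBins(sp2), rep("distal", 3))
    # rotation + translation invariance (no spot exactly on the boundary,
    # where floating-point rotation error could flip the call)
    sp3 <- sp; sp3$y_um[2] <- 799
    th <- 0.7
    rot <- sp3
    rot$x_um <- cos(th) * sp3$x_um - sin(th) * sp3$y_um + 500
    rot$y_um <- sin(th) * sp3$x_um + cos(th) * sp3$y_um - 200
    expect_equal(distanceBins(rot), distanceBins(sp3))
})

test_that("distal spots of a VI+ lattice outscore a VI- lattice", {
    # 300 genes with spread baselines so expression-matched control bins
    # mix set and non-set genes
    genes <- paste0("g", 1:300)
    set.seed(77)
    base <- setNames(sample(seq(1, 8, length.out = 300)), genes)
    up <- sample(genes, 10); dn <- sample(setdiff(genes, up), 10)
    # VI+ tumor with no invaded focus in the capture area: every spot is
    # distal, but the whole tissue shifts toward the invasive program
    mk <- function(hot, seed) {
        m <- base
        if (hot) m <- m + 1.5 * (genes %in% up) - 0.8 * (genes %in% dn)
        layout <- matrix("normal", 8, 8)
        g <- generateSpotSample(spotConfig(layout,
                                           regionMeans = list(normal = m),
                                           noiseSd = 0.3, seed = seed))
        g$spots
    }
    viPos <- mk(TRUE, 21)
    viNeg <- mk(FALSE, 22)
    exprPos <- t(as.matrix(viPos[, genes]))
    exprNeg <- t(as.matrix(viNeg[, genes]))
    colnames(exprPos) <- viPos$spot_id
    colnames(exprNeg) <- viNeg$spot_id
    sPos <- predictorSpotScore(exprPos, up, dn, seed = 1)
    sNeg <- predictorSpotScore(exprNeg, up, dn, seed = 1)
    distalPos <- sPos$score[distanceBins(viPos) == "distal"]
    expect_gt(length(distalPos), 0)
    expect_lt(wilcox.test(distalPos, sNeg$score,
                          alternative = "greater")$p.value, 0.05)
})

test_that("spot tables round-trip through TSV", {
    layout <- matrix(c("normal", "VI focus"), 2, 2)
    cfg <- spotConfig(layout,
                      regionMeans = list(normal = c(s = 0),
                                         `VI focus` = c(s = 1)),
                      seed = 2)
    sp <- generateSpotSample(cfg)$spots
    path <- withr::local_tempfile(fileext = ".tsv")
    writeSpotsTsv(sp, path)
    back <- readSpotsTsv(path)
    expect_equal(back$annotation, sp$annotation)
    expect_equal(back$s, sp$s, tolerance = 1e-10)
    expect_error(readSpotsTsv({
        p2 <- withr::local_tempfile(fileext = ".tsv")
        write.table(sp[, -1], p2, sep = "\t", row.names = FALSE)
        p2
    }), "missing spot columns")
})
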