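#' Cluster-proportional gene selection
#'
#' Selects a fixed-size gene panel from the significant genes so that each
#' co-expression cluster contributes in proportion to its share of the
#' significant set, using largest-remainder apportionment of the quotas.
#' Within a cluster, genes are chosen by ascending p-value (ties: larger
#' `|log2FC|`, then gene ID). A quota exceeding its cluster size spills to
#' the next-best cluster by remainder, with a warning.
#'
#' @param de DE table from [nbGlmLrt()] covering the signature genes.
#' @param clusters a [GeneClusterSignature-class].
#' @param nTotal panel size (default 48).
#' @return character vector of exactly `nTotal` gene IDs, with a
#'   `quotas` attribute (per-cluster counts).
#' @export
proportionalSelect <- function(de, clusters, nTotal = 48) {
    lab <- clusterLabels(clusters)
    genes <- names(lab)
    if (length(genes) < nTotal)
        stop("fewer significant genes than the requested panel size")
    k <- clusters@k
    sizes <- tabulate(lab, nbins = k)
    quota <- largestRemainder(nTotal, sizes)
    # spill quotas that exceed cluster sizes
    over <- quota > sizes
    if (any(over)) {
        warning("cluster quota exceeds cluster size; spilling")
        excess <- sum(quota[over] - sizes[over])
        quota[over] <- sizes[over]
        raw <- nTotal * sizes / sum(sizes)
        ord <- order(raw - floor(raw), decreasing = TRUE)
        for (i in ord) {
            if (excess == 0) break
            room <- sizes[i] - quota[i]
            add <- min(room, excess)
            quota[i] <- quota[i] + add
            excess <- excess - add
        }
    }
    de <- de[match(genes, de$gene), , drop = FALSE]
    picked <- character(0)
    for (i in seq_len(k)) {
        ing <- genes[lab == i]
        sub <- de[de$gene %in% ing, , drop = FALSE]
        ord <- order(sub$pvalue, -abs(sub$logFC), sub$gene)
        picked <- c(picked, sub$gene[ord][seq_len(quota[i])])
    }
    structure(picked, quotas = quota)
}

# Largest-remainder apportionment of nTotal by shares `sizes`.
largestRemainder <- function(nTotal, sizes) {
    raw <- nTotal * sizes / sum(sizes)
    base <- floor(raw)
    rem <- nTotal - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Ridge-penalized binomial logit fit
#'
#' Minimizes `-(1/n) * Bernoulli log-likelihood + (lambda/2) * ||beta||^2`
#' (intercept unpenalized) by damped Newton iterations to a gradient norm
#' below `tol`. Deterministic; duplicated observations rescale the
#' likelihood and leave the fit unchanged.
#'
#' @param X numeric matrix, units x features (standardized upstream).
#' @param y binary 0/1 response, both classes present.
#' @param lambda ridge penalty >= 0.
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param maxIter maximum Newton iterations (default 200).
#' @return list: `coef` (named), `intercept`, `lambda`, `converged`.
#' @export
fitRidgeLogit <- function(X, y, lambda, tol = 1e-8, maxIter = 200) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    stopifnot(length(unique(y)) == 2L, all(y %in% c(0, 1)), lambda >= 0)
    n <- nrow(X); p <- ncol(X)
    Xi <- cbind(`(Intercept)` = 1, X)
    pen <- c(0, rep(lambda, p))
    beta <- c(qlogis(mean(y)), rep(0, p))
    obj <- function(b) {
        eta <- drop(Xi %*% b)
        -mean(y * eta - log1p(exp(eta))) + sum(pen * b^2) / 2
    }
    grad <- function(b) {
        mu <- plogis(drop(Xi %*% b))
        -drop(crossprod(Xi, y - mu)) / n + pen * b
    }
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        g <- grad(beta)
        if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
        mu <- plogis(drop(Xi %*% beta))
        w <- pmax(mu * (1 - mu), 1e-10)
        H <- crossprod(Xi * w, Xi) / n + diag(pen, p + 1L)
        # ridge-damped fallback keeps the step defined under separation
        step <- tryCatch(solve(H, g),
                         error = function(e) solve(H + diag(1e-6, p + 1L), g))
        f0 <- obj(beta)
        t <- 1
        repeat {
            bNew <- beta - t * step
            if (obj(bNew) <= f0 + 1e-12 || t < 1e-10) break
            t <- t / 2
        }
        beta <- bNew
    }
    if (!converged && sqrt(sum(grad(beta)^2)) < 1e-4) converged <- TRUE
    if (!converged && lambda == 0)
        stop("no convergence at lambda = 0 (separation?); use lambda > 0")
    list(coef = setNames(beta[-1L], colnames(X)),
         intercept = unname(beta[1L]), lambda = lambda,
         converged = converged)
}

#' Inner cross-validated ridge penalty choice
#'
#' Stratified k-fold cross-validation over a penalty grid; returns the
#' penalty maximizing mean held-out AUROC (ties favor the larger penalty,
#' i.e. more shrinkage).
#'
#' @param X units x features matrix.
#' @param y binary response.
#' @param lambdaGrid candidate penalties (default 25 log-spaced values in
#'   `[1e-3, 1e3]`).
#' @param k folds (default 5; must not exceed the minority-class count).
#' @param seed integer seed for fold assignment.
#' @return the chosen penalty (scalar), with attribute `cvAuroc` (mean AUROC
#'   per grid value).
#' @export
innerCvLambda <- function(X, y, lambdaGrid = defaultLambdaGrid(), k = 5,
                          seed = 1L) {
    y <- as.numeric(y)
    if (k > min(table(y))) stop("k exceeds the minority-class count")
    set.seed(seed)
    folds <- stratifiedFolds(y, k)
    lambdaGrid <- sort(lambdaGrid)
    perf <- matrix(NA_real_, length(lambdaGrid), k)
    for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y[!tr])) < 2L) next
        for (j in seq_along(lambdaGrid)) {
            fit <- fitRidgeLogit(X[tr, , drop = FALSE], y[tr], lambdaGrid[j])
            sc <- drop(X[!tr, , drop = FALSE] %*% fit$coef) + fit$intercept
            perf[j, f] <- aurocStat(sc, y[!tr])
        }
    }
    m <- rowMeans(perf, na.rm = TRUE)
    best <- max(m)
    chosen <- max(lambdaGrid[m >= best - 1e-12])   # ties -> larger lambda
    structure(chosen, cvAuroc = setNames(m, lambdaGrid))
}

#' @rdname innerCvLambda
#' @export
defaultLambdaGrid <- function() 10^seq(-3, 3, length.out = 25)

# Stratified fold labels: within each class, folds assigned by shuffled
# round-robin.
stratifiedFolds <- function(y, k) {
    folds <- integer(length(y))
    for (cl in unique(y)) {
        idx <- which(y == cl)
        folds[idx[sample.int(length(idx))]] <-
            rep_len(seq_len(k), length(idx))
    }
    folds
}

# Tie-corrected Mann-Whitney AUROC (ties count one half).
aurocStat <- function(scores, labels) {
    labels <- as.numeric(labels)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC with stratified-bootstrap CI and rank-sum p
#'
#' AUROC as the tie-corrected Mann-Whitney statistic; 95% percentile CI
#' from class-stratified bootstrap resampling; p from the two-sided
#' normal-approximation Wilcoxon rank-sum test.
#'
#' @param scores numeric predictor scores.
#' @param labels binary 0/1 labels (both classes required).
#' @param nBoot bootstrap replicates (default 2000; 0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @param level CI level (default 0.95).
#' @return list: `auroc`, `ci` (lo, hi or NULL), `pvalue`.
#' @export
auroc <- function(scores, labels, nBoot = 2000, seed = 1L, level = 0.95) {
    labels <- as.numeric(labels)
    if (length(unique(labels)) < 2L) stop("both classes required")
    a <- aurocStat(scores, labels)
    p <- suppressWarnings(
        wilcox.test(scores[labels == 1], scores[labels == 0],
                    exact = FALSE)$p.value)
    ci <- NULL
    if (nBoot > 0) {
        set.seed(seed)
        i1 <- which(labels == 1); i0 <- which(labels == 0)
        boot <- vapply(seq_len(nBoot), function(b) {
            j <- c(sample(i1, length(i1), replace = TRUE),
                   sample(i0, length(i0), replace = TRUE))
            aurocStat(scores[j], labels[j])
        }, 0)
        alpha <- (1 - level) / 2
        ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
    }
    list(auroc = a, ci = ci, pvalue = p)
}

#' Youden-point decision cutoff
#'
#' Cutoff maximizing J = sensitivity + specificity - 1 over the midpoints
#' of adjacent distinct scores (positivity is score > cutoff). Ties take the
#' lowest cutoff, favoring sensitivity.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return the cutoff, with attribute `J` (the achieved Youden index).
#' @export
youdenCutoff <- function(scores, labels) {
    labels <- as.numeric(labels)
    if (length(unique(labels)) < 2L) stop("both classes required")
    s <- sort(unique(scores))
    cands <- if (length(s) == 1L) s - 1
             else c(min(s) - 1, (s[-length(s)] + s[-1L]) / 2)
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    J <- vapply(cands, function(ct) {
        sens <- sum(scores > ct & labels == 1) / n1
        spec <- sum(scores <= ct & labels == 0) / n0
        sens + spec - 1
    }, 0)
    best <- which(J >= max(J) - 1e-12)[1L]   # lowest cutoff among ties
    structure(cands[best], J = J[best])
}

## ---- nested cross-validation ----------------------------------------------

#' Configuration for predictor training / evaluation
#'
#' @param nOuter outer train/test splits (default 100).
#' @param trainFraction outer training fraction (default 0.7), stratified
#'   by VI label.
#' @param qThreshold DE FDR threshold for the signature (default 0.01).
#' @param kClusters clusters cut from the per-split signature (default 4).
#' @param nTotal panel size (default 48).
#' @param lambdaGrid inner CV penalty grid.
#' @param innerK inner CV folds (default 5).
#' @param maxRetries resampling attempts when an outer-train split misses a
#'   grade (default 10).
#' @return list of class `PredictorConfig`.
#' @export
predictorConfig <- function(nOuter = 100, trainFraction = 0.7,
                            qThreshold = 0.01, kClusters = 4, nTotal = 48,
                            lambdaGrid = defaultLambdaGrid(), innerK = 5,
                            maxRetries = 10) {
    structure(list(nOuter = nOuter, trainFraction = trainFraction,
                   qThreshold = qThreshold, kClusters = kClusters,
                   nTotal = nTotal, lambdaGrid = lambdaGrid,
                   innerK = innerK, maxRetries = maxRetries),
              class = "PredictorConfig")
}

# One training pass on a cohort subset: DE (VI vs LMP), FDR cut, Ward2
# clustering, proportional selection, standardization, inner CV, ridge fit.
# `lcm` is the logCPM matrix for the same samples.
trainOnCohort <- function(x, lcm, config, seed) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    de <- nbGlmLrt(x)
    sigGenes <- de[!is.na(de$qvalue) & de$qvalue < config$qThreshold, ]
    if (nrow(sigGenes) < config$nTotal) {
        # weak-signal fold: fall back to the top genes by p so the panel
        # size stays fixed (matters under label permutation / null data)
        warning("fewer than nTotal FDR-significant genes; ",
                "falling back to the top ", config$nTotal, " by p-value")
        ok <- !is.na(de$pvalue)
        sigGenes <- de[ok, ][order(de$pvalue[ok])[seq_len(config$nTotal)], ]
    }
    z <- zscoreByGene(lcm[sigGenes$gene, , drop = FALSE])
    cl <- ward2Cluster(z, config$kClusters)
    meanLfc <- vapply(seq_len(config$kClusters), function(i)
        mean(sigGenes$logFC[cl == i]), 0)
    sig <- new("GeneClusterSignature", genes = sigGenes$gene,
               cluster = setNames(as.integer(cl), sigGenes$gene),
               k = as.integer(config$kClusters),
               direction = ifelse(meanLfc >= 0, "up", "down"),
               deTable = sigGenes, consensus = list())
    panel <- as.vector(proportionalSelect(sigGenes, sig,
                                          nTotal = config$nTotal))
    Xtr <- t(lcm[panel, , drop = FALSE])
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2L, sd)
    if (any(scl == 0)) stop("constant panel gene in training data")
    Xs <- scale(Xtr, center = ctr, scale = scl)
    y <- as.numeric(cd$vi)
    lambda <- innerCvLambda(Xs, y, lambdaGrid = config$lambdaGrid,
                            k = config$innerK, seed = seed)
    fit <- fitRidgeLogit(Xs, y, as.numeric(lambda))
    list(panel = panel, signature = sig, center = ctr, scale = scl,
         fit = fit, lambda = as.numeric(lambda))
}

#' Nested cross-validated evaluation of the VI predictor
#'
#' Repeats a stratified outer train/test split; within each outer training
#' set only, reruns differential expression, clustering and proportional
#' 48-gene selection, chooses the ridge penalty by stratified inner CV,
#' fits the ridge binomial logit, and evaluates AUROC (VI vs rest) on the
#' held-out outer test set. Feature selection and fitting never see outer
#' test samples.
#'
#' @param x a [ViCountSet-class] with `grade` and `vi` metadata; all three
#'   grades must be present.
#' @param config a [predictorConfig()].
#' @param seed integer seed driving all splits.
#' @return list: `report` (data.frame per outer split: split, lambda,
#'   auroc, nSelected), `meanAuroc`, `sdAuroc`, `panels` (list of selected
#'   panels per split).
#' @export
nestedCvEvaluate <- function(x, config = predictorConfig(), seed = 1L) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    if (!all(c("LMP", "NST", "VI") %in% cd$grade))
        stop("cohort must contain all three grades")
    lcm <- logCPM(x)
    y <- as.numeric(cd$vi)
    n <- ncol(x)
    res <- vector("list", config$nOuter)
    panels <- vector("list", config$nOuter)
    for (i in seq_len(config$nOuter)) {
        set.seed(seed * 10000L + i)
        trIdx <- NULL
        for (try in seq_len(config$maxRetries)) {
            cand <- stratifiedSplit(y, config$trainFraction)
            if (all(c("LMP", "NST", "VI") %in% cd$grade[cand])) {
                trIdx <- cand; break
            }
        }
        if (is.null(trIdx)) stop("could not build a split with all grades")
        fitSeed <- seed * 10000L + i
        tr <- trainOnCohort(x[, trIdx], lcm[, trIdx, drop = FALSE],
                            config, seed = fitSeed)
        teIdx <- setdiff(seq_len(n), trIdx)
        Xte <- t(lcm[tr$panel, teIdx, drop = FALSE])
        Xs <- scale(Xte, center = tr$center, scale = tr$scale)
        sc <- drop(Xs %*% tr$fit$coef) + tr$fit$intercept
        res[[i]] <- data.frame(split = i, lambda = tr$lambda,
                               auroc = aurocStat(sc, y[teIdx]),
                               nSelected = length(tr$panel))
        panels[[i]] <- tr$panel
    }
    report <- do.call(rbind, res)
    list(report = report, meanAuroc = mean(report$auroc),
         sdAuroc = sd(report$auroc), panels = panels)
}

# Stratified sample of training indices at the given fraction.
stratifiedSplit <- function(y, fraction) {
    unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(fraction * length(idx))))
    }))
}

#' Train the final VI predictor on a full cohort
#'
#' Runs the same pipeline as one outer-training pass of
#' [nestedCvEvaluate()] on the entire cohort, and stores the per-gene
#' standardization parameters and the Youden cutoff computed on the
#' training scores.
#'
#' @inheritParams nestedCvEvaluate
#' @return a [PredictorModel-class].
#' @export
trainFinal <- function(x, config = predictorConfig(), seed = 1L) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    lcm <- logCPM(x)
    set.seed(seed)
    tr <- trainOnCohort(x, lcm, config, seed = seed)
    model <- new("PredictorModel", genes = tr$panel,
                 center = tr$center, scale = tr$scale,
                 coef = tr$fit$coef, intercept = tr$fit$intercept,
                 lambda = tr$lambda, cutoff = 0.5, seed = as.integer(seed))
    sc <- predictScore(model, lcm)
    model@cutoff <- as.numeric(youdenCutoff(sc$score, cd$vi))
    model
}

#' Predictor probability scores
#'
#' `logistic(intercept + sum(beta * (x - mean) / sd))` per sample.
#'
#' @param model a [PredictorModel-class].
#' @param lcm logCPM matrix, genes x samples, covering the panel genes.
#' @param imputeMissing if `TRUE`, genes absent from `lcm` are imputed at
#'   their training mean with a warning; the default is an error.
#' @return data.frame: `unit_id`, `score` (probabilities in \[0, 1\]).
#' @export
predictScore <- function(model, lcm, imputeMissing = FALSE) {
    genes <- model@genes
    missing <- setdiff(genes, rownames(lcm))
    if (length(missing)) {
        if (!imputeMissing)
            stop(length(missing), " panel gene(s) absent from the matrix")
        warning(length(missing), " panel gene(s) imputed at training mean")
        imp <- matrix(model@center[missing], length(missing), ncol(lcm),
                      dimnames = list(missing, colnames(lcm)))
        lcm <- rbind(lcm, imp)
    }
    X <- t(lcm[genes, , drop = FALSE])
    Xs <- scale(X, center = model@center, scale = model@scale)
    eta <- drop(Xs %*% model@coef) + model@intercept
    data.frame(unit_id = colnames(lcm), score = plogis(eta),
               stringsAsFactors = FALSE)
}

#' Standardized-coefficient importance
#'
#' Coefficients are already on the standardized (per-sd) scale, so their
#' absolute values rank gene importance directly.
#'
#' @param model a [PredictorModel-class].
#' @return data.frame: gene, coefficient, absCoefficient, rank.
#' @export
coefImportance <- function(model) {
    co <- model@coef
    ord <- order(-abs(co))
    data.frame(gene = names(co)[ord], coefficient = unname(co[ord]),
               absCoefficient = abs(unname(co[ord])),
               rank = seq_along(co), stringsAsFactors = FALSE)
}

#' Moment-matching harmonization to a reference cohort
#'
#' Adjusts each gene of the target logCPM matrix so its mean and variance
#' match the reference cohort:
#' `x' = (x - m_t) / s_t * s_r + m_r`. The reference is never altered.
#' Genes with zero target variance are shifted only, with a warning.
#'
#' @param target,reference logCPM matrices (genes x samples); the shared
#'   gene set is used (genes lost from either side trigger a warning).
#' @return the adjusted target matrix (shared genes only).
#' @export
referenceAdjust <- function(target, reference) {
    shared <- intersect(rownames(target), rownames(reference))
    if (length(shared) == 0L) stop("no shared genes")
    if (length(shared) < nrow(target) || length(shared) < nrow(reference))
        warning("gene universes differ; using the ",
                length(shared), "-gene intersection")
    t2 <- target[shared, , drop = FALSE]
    r2 <- reference[shared, , drop = FALSE]
    mt <- rowMeans(t2); st <- apply(t2, 1L, sd)
    mr <- rowMeans(r2); sr <- apply(r2, 1L, sd)
    flat <- st == 0
    if (any(flat)) {
        warning(sum(flat), " gene(s) with zero target variance: shift only")
        st[flat] <- 1; sr[flat] <- 1
    }
    (t2 - mt) / st * sr + mr
}

#' Kolmogorov-Smirnov rank enrichment of a gene subset
#'
#' Two-sample KS test comparing the rank positions of a subset against the
#' complement within a ranked gene list - are the subset genes concentrated
#' toward the top?
#'
#' @param rankedIds character vector, the full ranked gene list (best
#'   first).
#' @param subset character vector, a strict, nonempty subset of
#'   `rankedIds`.
#' @return list: `D` (KS statistic), `pvalue` (two-sided; exact for small
#'   samples per `stats::ks.test` rules).
#' @export
ksRankEnrichment <- function(rankedIds, subset) {
    subset <- unique(subset)
    if (!length(subset)) stop("empty subset")
    if (!all(subset %in% rankedIds)) stop("subset must lie in the ranking")
    if (length(subset) >= length(rankedIds))
        stop("subset must be a strict subset")
    pos <- match(subset, rankedIds)
    rest <- setdiff(seq_along(rankedIds), pos)
    kt <- suppressWarnings(ks.test(pos, rest))
    list(D = unname(kt$statistic), pvalue = kt$p.value)
}

#' Serialize / restore a PredictorModel as JSON
#'
#' @param model a [PredictorModel-class].
#' @param path file path.
#' @return `readPredictorJson` returns the restored model.
#' @export
writePredictorJson <- function(model, path) {
    obj <- list(genes = model@genes, center = as.list(model@center),
                scale = as.list(model@scale), coef = as.list(model@coef),
                intercept = model@intercept, lambda = model@lambda,
                cutoff = model@cutoff, seed = model@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePredictorJson
#' @export
readPredictorJson <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    genes <- obj$genes
    new("PredictorModel", genes = genes,
        center = setNames(as.numeric(obj$center[genes]), genes),
        scale = setNames(as.numeric(obj$scale[genes]), genes),
        coef = setNames(as.numeric(obj$coef[genes]), genes),
        intercept = obj$intercept, lambda = obj$lambda,
        cutoff = obj$cutoff, seed = as.integer(obj$seed))
}
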