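#' Configuration for the synthetic bulk cohort generator
#'
#' Defaults emulate the statistical structure of a stage I LUAD discovery
#' cohort graded LMP / NST / VI: about 100 tumors with 30% VI prevalence,
#' four planted co-expressed gene clusters of sizes 115, 37, 182 and 140
#' (three up-regulated in VI, one down-regulated), negative binomial counts
#' with a shared dispersion, log-normal library sizes, and a low-abundance
#' tail of genes that falls below the CPM expression filter.
#'
#' @param nSamples number of samples (>= 6, >= 2 per grade).
#' @param gradeFractions length-3 simplex over (LMP, NST, VI); VI default
#'   0.30.
#' @param nGenes total genes simulated.
#' @param clusterSizes sizes of the four planted clusters
#'   (default c(115, 37, 182, 140); sum 474).
#' @param clusterLog2fc signed VI-vs-LMP log2 fold changes per cluster;
#'   cluster 4 negative by default.
#' @param nstEffectScale NST effect as a fraction of the VI effect, in
#'   \[0, 1\] (default 0.5), producing the LMP < NST < VI gradient.
#' @param clusterCorSd sd of the per-cluster latent sample factor that makes
#'   each planted cluster an internally co-expressed block (log2 scale).
#' @param dispersion shared NB dispersion phi (Var = mu + phi mu^2).
#' @param libsizeLogMean,libsizeLogSd natural-log mean / sd of library sizes.
#' @param batchShiftSd sd of the per-gene additive log2-scale batch offset;
#'   0 (default) simulates a single batch, > 0 splits samples into two
#'   batches with the second shifted.
#' @param lowAbundanceFraction fraction of genes planted below the CPM
#'   filter threshold (default 0.05).
#' @param seed integer seed.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nSamples = 100,
                         gradeFractions = c(LMP = 0.30, NST = 0.40, VI = 0.30),
                         nGenes = 2000,
                         clusterSizes = c(115, 37, 182, 140),
                         clusterLog2fc = c(1.5, 2.0, 1.2, -1.5),
                         nstEffectScale = 0.5,
                         clusterCorSd = 0.8,
                         dispersion = 0.15,
                         libsizeLogMean = log(2e6),
                         libsizeLogSd = 0.3,
                         batchShiftSd = 0,
                         lowAbundanceFraction = 0.05,
                         seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples),
                gradeFractions = gradeFractions, nGenes = as.integer(nGenes),
                clusterSizes = as.integer(clusterSizes),
                clusterLog2fc = clusterLog2fc,
                nstEffectScale = nstEffectScale, clusterCorSd = clusterCorSd,
                dispersion = dispersion, libsizeLogMean = libsizeLogMean,
                libsizeLogSd = libsizeLogSd, batchShiftSd = batchShiftSd,
                lowAbundanceFraction = lowAbundanceFraction,
                seed = as.integer(seed))
    if (cfg$nSamples < 6L || cfg$nSamples != nSamples)
        stop("nSamples must be an integer >= 6")
    if (length(gradeFractions) != 3L ||
        abs(sum(gradeFractions) - 1) > 1e-8 || any(gradeFractions <= 0))
        stop("gradeFractions must be a positive 3-simplex")
    if (length(cfg$clusterSizes) != 4L || any(cfg$clusterSizes < 1L))
        stop("clusterSizes must be four integers >= 1")
    if (sum(cfg$clusterSizes) >= cfg$nGenes)
        stop("planted clusters must leave unplanted genes")
    if (length(clusterLog2fc) != 4L) stop("clusterLog2fc must have length 4")
    if (dispersion <= 0) stop("dispersion must be > 0")
    if (nstEffectScale < 0 || nstEffectScale > 1)
        stop("nstEffectScale must lie in [0, 1]")
    if (batchShiftSd < 0) stop("batchShiftSd must be >= 0")
    nper <- gradeAllocation(cfg$nSamples, gradeFractions)
    if (any(nper < 2L)) stop("each grade needs at least 2 samples")
    class(cfg) <- "CohortConfig"
    cfg
}

# Deterministic largest-remainder allocation of samples to grades.
gradeAllocation <- function(n, fractions) {
    raw <- n * fractions / sum(fractions)
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Generate a synthetic bulk RNA-seq cohort with a planted VI signature
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `baseline * lib_size * 2^(log2fc * grade_code + latent + batch)` and a
#' shared dispersion (Var = mu + phi mu^2). Grade codes are LMP = 0,
#' NST = `nstEffectScale`, VI = 1, so planted cluster genes change along the
#' LMP < NST < VI gradient; a per-cluster latent sample factor makes each
#' planted cluster a co-expressed block. Identical configurations reproduce
#' identical counts.
#'
#' @param config a [cohortConfig()].
#' @param truth optional truth list from a previous call; reuses the planted
#'   gene structure (cluster memberships, true effects, baseline
#'   abundances) so a validation cohort shares the discovery cohort's
#'   signature genes while drawing fresh samples.
#' @return list with elements `counts` (a [ViCountSet-class] carrying grade,
#'   vi, batch metadata) and `truth` (planted gene IDs per cluster, per-gene
#'   true log2FC, per-sample grade and batch).
#' @export
generateBulkCohort <- function(config, truth = NULL) {
    stopifnot(inherits(config, "CohortConfig"))
    set.seed(config$seed)
    nG <- config$nGenes; nS <- config$nSamples
    genes <- sprintf("g%04d", seq_len(nG))
    samples <- sprintf("s%03d", seq_len(nS))

    nper <- gradeAllocation(nS, config$gradeFractions)
    grade <- factor(rep(c("LMP", "NST", "VI"), nper),
                    levels = c("LMP", "NST", "VI"))
    gradeCode <- c(LMP = 0, NST = config$nstEffectScale, VI = 1)[as.character(grade)]

    if (is.null(truth)) {
        # planted clusters get shuffled gene IDs, mutually exclusive
        geneOrder <- sample.int(nG)
        clusterOf <- integer(nG)
        idx <- 1L
        for (k in 1:4) {
            clusterOf[geneOrder[idx:(idx + config$clusterSizes[k] - 1L)]] <- k
            idx <- idx + config$clusterSizes[k]
        }
        trueLfc <- ifelse(clusterOf > 0,
                          config$clusterLog2fc[pmax(clusterOf, 1L)], 0)

        # baseline abundances on the log2-CPM scale, rescaled to sum to 1e6
        # so realized library sizes match the nominal ones; a planted low
        # tail falls below the CPM > 1 filter
        baseLog2Cpm <- rnorm(nG, mean = 4, sd = 1.5)
        baseLog2Cpm <- baseLog2Cpm + log2(1e6 / sum(2^baseLog2Cpm))
        nLow <- round(config$lowAbundanceFraction * nG)
        if (nLow > 0) {
            low <- sample.int(nG, nLow)
            baseLog2Cpm[low] <- rnorm(nLow, mean = -2.5, sd = 0.5)
        }
    } else {
        if (length(truth$trueLog2fc) != nG)
            stop("truth does not match nGenes")
        clusterOf <- integer(nG)
        for (k in 1:4)
            clusterOf[match(truth$clusterGenes[[k]], genes)] <- k
        trueLfc <- unname(truth$trueLog2fc[genes])
        baseLog2Cpm <- unname(truth$baseLog2Cpm[genes])
    }

    libSize <- exp(rnorm(nS, config$libsizeLogMean, config$libsizeLogSd))

    # batchShiftSd > 0 shifts the whole cohort by one per-gene offset,
    # emulating a validation cohort measured in a different batch
    batch <- rep(1L, nS)
    batchShift <- matrix(0, nG, nS)
    if (config$batchShiftSd > 0) {
        batch <- rep(2L, nS)
        batchShift[] <- rnorm(nG, 0, config$batchShiftSd)
    }

    # per-cluster latent sample factor (co-expression within planted blocks)
    latent <- matrix(0, nG, nS)
    if (config$clusterCorSd > 0) {
        u <- matrix(rnorm(4 * nS, 0, config$clusterCorSd), 4, nS)
        planted <- clusterOf > 0
        latent[planted, ] <- u[clusterOf[planted], , drop = FALSE]
    }

    log2Mu <- outer(baseLog2Cpm, rep(1, nS)) +
        outer(trueLfc, gradeCode) + latent + batchShift
    mu <- 2^log2Mu / 1e6 * rep(libSize, each = nG)
    counts <- matrix(rnbinom(nG * nS, mu = mu, size = 1 / config$dispersion),
                     nG, nS, dimnames = list(genes, samples))

    meta <- data.frame(sample_id = samples, grade = as.character(grade),
                       vi = as.integer(grade == "VI"), batch = batch,
                       tumor_id = samples, region_id = "R1",
                       stringsAsFactors = FALSE)
    truth <- list(
        clusterGenes = lapply(1:4, function(k) genes[clusterOf == k]),
        trueLog2fc = setNames(trueLfc, genes),
        grade = setNames(as.character(grade), samples),
        batch = setNames(batch, samples),
        baseLog2Cpm = setNames(baseLog2Cpm, genes))
    list(counts = ViCountSet(counts, meta = meta, libSizes = colSums(counts)),
         truth = truth)
}

#' Generate multi-region tumor scores (tumor signal plus region noise)
#'
#' Each tumor gets a latent score drawn N(0, `tumorEffectSd`^2); each of its
#' regions observes the latent score plus independent N(0, `regionNoiseSd`^2)
#' noise. Emulates multi-region sampling where between-tumor variation
#' dominates within-tumor variation.
#'
#' @param nTumors number of tumors (>= 2).
#' @param regionsPerTumor regions per tumor (>= 2).
#' @param tumorEffectSd sd of the tumor-level latent score.
#' @param regionNoiseSd sd of the region-level noise.
#' @param seed integer seed.
#' @return list with `scores` (data.frame tumor_id, region_id, score) and
#'   `truth` (tumor latents and region noises).
#' @export
generateMultiregionCohort <- function(nTumors, regionsPerTumor = 2,
                                      tumorEffectSd = 1, regionNoiseSd = 0.2,
                                      seed = 1L) {
    stopifnot(nTumors >= 2, regionsPerTumor >= 2,
              tumorEffectSd >= 0, regionNoiseSd >= 0)
    set.seed(seed)
    tumors <- sprintf("T%03d", seq_len(nTumors))
    latent <- setNames(rnorm(nTumors, 0, tumorEffectSd), tumors)
    df <- expand.grid(region_id = sprintf("R%d", seq_len(regionsPerTumor)),
                      tumor_id = tumors, stringsAsFactors = FALSE)
    df <- df[, c("tumor_id", "region_id")]
    noise <- rnorm(nrow(df), 0, regionNoiseSd)
    df$score <- latent[df$tumor_id] + noise
    rownames(df) <- NULL
    list(scores = df, truth = list(latent = latent,
                                   noise = setNames(noise, paste(df$tumor_id,
                                                                 df$region_id))))
}

#' Configuration for the synthetic spot-lattice generator
#'
#' @param layout character matrix of annotation labels (one per lattice
#'   spot), rows x cols; e.g. "normal", "tumor", "desmoplastic stroma",
#'   "VI focus".
#' @param spacingUm center-to-center spot spacing in micrometers
#'   (default 100).
#' @param diameterUm spot diameter in micrometers (default 50).
#' @param regionMeans named list: label -> named numeric vector of score (or
#'   gene-mean) values for that region.
#' @param noiseSd sd of the Gaussian noise added to each spot value.
#' @param lowDepthFraction fraction of spots planted with < 250 detected
#'   genes (QC casualties; default 0).
#' @param mode "score" emits per-spot scores directly; "count" draws Poisson
#'   counts per gene with `regionMeans` as per-region mean expression.
#' @param seed integer seed.
#' @return a validated list of class `SpotConfig`.
#' @export
spotConfig <- function(layout, spacingUm = 100, diameterUm = 50,
                       regionMeans, noiseSd = 0.1, lowDepthFraction = 0,
                       mode = c("score", "count"), seed = 1L) {
    mode <- match.arg(mode)
    if (!is.matrix(layout) || !is.character(layout) || length(layout) == 0)
        stop("layout must be a non-empty character matrix of labels")
    if (spacingUm <= 0) stop("spacingUm must be > 0")
    labs <- unique(as.vector(layout))
    miss <- setdiff(labs, names(regionMeans))
    if (length(miss)) stop("regionMeans missing labels: ",
                           paste(miss, collapse = ", "))
    structure(list(layout = layout, spacingUm = spacingUm,
                   diameterUm = diameterUm, regionMeans = regionMeans,
                   noiseSd = noiseSd, lowDepthFraction = lowDepthFraction,
                   mode = mode, seed = as.integer(seed)),
              class = "SpotConfig")
}

#' Generate a synthetic spot lattice with annotated regions
#'
#' Spots sit on a regular lattice (coordinates in micrometers); each spot
#' carries one pathology annotation from the layout and score (or count)
#' values equal to its region mean plus Gaussian noise (Poisson sampling in
#' count mode).
#'
#' @param config a [spotConfig()].
#' @return list with `spots` (data.frame: spot_id, x_um, y_um, annotation,
#'   n_genes, one column per score) and, in count mode, `counts` (gene x
#'   spot matrix).
#' @export
generateSpotSample <- function(config) {
    stopifnot(inherits(config, "SpotConfig"))
    set.seed(config$seed)
    nr <- nrow(config$layout); nc <- ncol(config$layout)
    grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    spots <- data.frame(
        spot_id = sprintf("spot%04d", seq_len(nrow(grid))),
        x_um = (grid$col - 1) * config$spacingUm,
        y_um = (grid$row - 1) * config$spacingUm,
        annotation = config$layout[cbind(grid$row, grid$col)],
        stringsAsFactors = FALSE)
    n <- nrow(spots)
    spots$n_genes <- rep(1000L, n)
    if (config$lowDepthFraction > 0) {
        nLow <- round(config$lowDepthFraction * n)
        low <- sample.int(n, nLow)
        spots$n_genes[low] <- sample(50:249, nLow, replace = TRUE)
    }
    vars <- unique(unlist(lapply(config$regionMeans, names)))
    if (config$mode == "score") {
        for (v in vars) {
            mu <- vapply(spots$annotation, function(a) {
                m <- config$regionMeans[[a]]
                if (v %in% names(m)) m[[v]] else 0
            }, 0)
            spots[[v]] <- mu + rnorm(n, 0, config$noiseSd)
        }
        list(spots = spots)
    } else {
        mu <- vapply(config$regionMeans[spots$annotation],
                     function(m) m[vars], numeric(length(vars)))
        if (is.null(dim(mu))) mu <- matrix(mu, nrow = length(vars))
        counts <- matrix(rpois(length(mu), lambda = mu),
                         nrow = length(vars),
                         dimnames = list(vars, spots$spot_id))
        list(spots = spots, counts = counts)
    }
}

#' Generate paired biopsy / resection predictor scores
#'
#' Bivariate-normal latent scores with a specified correlation emulate the
#' attenuated agreement between a pre-surgical biopsy and the matched
#' resected tumor; binary VI labels are assigned by thresholding the
#' resection score at the `viFraction` empirical quantile (the diagnosis is
#' made on the resection).
#'
#' @param nPairs number of biopsy/resection pairs (>= 3).
#' @param targetCorrelation latent Pearson correlation, in \[-1, 1\].
#' @param viFraction fraction of pairs labeled VI-positive, in (0, 1).
#' @param seed integer seed.
#' @return data.frame: pair_id, biopsy_score, resection_score, vi (0/1).
#' @export
generateBiopsyPairs <- function(nPairs, targetCorrelation = 0.77,
                                viFraction = 0.5, seed = 1L) {
    stopifnot(nPairs >= 3, abs(targetCorrelation) <= 1)
    if (viFraction <= 0 || viFraction >= 1)
        stop("viFraction must lie in (0, 1)")
    set.seed(seed)
    z1 <- rnorm(nPairs)
    rho <- targetCorrelation
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nPairs)
    nPos <- round(viFraction * nPairs)
    vi <- as.integer(rank(-z2, ties.method = "first") <= nPos)
    data.frame(pair_id = sprintf("P%03d", seq_len(nPairs)),
               biopsy_score = z1, resection_score = z2, vi = vi,
               stringsAsFactors = FALSE)
}

#' Write synthetic truth tables as JSON
#'
#' @param truth truth list from a generator.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
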