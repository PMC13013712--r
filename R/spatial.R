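#' Spot quality filter
#'
#' Retains spots with at least `minGenes` detected genes.
#'
#' @param spots data.frame with columns `spot_id`, `x_um`, `y_um`,
#'   `annotation`, `n_genes` (and any score columns).
#' @param minGenes detection threshold (default 250).
#' @return the filtered data.frame.
#' @export
filterSpots <- function(spots, minGenes = 250) {
    if (is.null(spots$n_genes)) stop("spots need an n_genes column")
    keep <- spots$n_genes >= minGenes
    if (!any(keep)) stop("no spot passes the detection filter")
    spots[keep, , drop = FALSE]
}

#' Pseudo-bulk aggregation of spot counts
#'
#' Per-gene sum over the given spots.
#'
#' @param counts gene x spot count matrix.
#' @param spotIds optional spot IDs to aggregate (default: all columns).
#' @return named numeric vector of per-gene summed counts.
#' @export
pseudoBulk <- function(counts, spotIds = NULL) {
    if (!is.null(spotIds)) counts <- counts[, spotIds, drop = FALSE]
    rowSums(counts)
}

#' Spatially weighted local correlation of two score maps
#'
#' For the Spearman method both scores are globally rank-transformed first;
#' each spot then receives a kernel-weighted local Pearson correlation over
#' its neighbors within the bandwidth, and the sample summary is the mean
#' of the local coefficients. The bandwidth is expressed in lattice units
#' (multiples of the spot spacing).
#'
#' @param spots data.frame with `x_um`, `y_um` and the two score columns.
#' @param scoreA,scoreB names of the score columns.
#' @param bandwidth kernel bandwidth in lattice units (default 5); `Inf`
#'   includes all spots.
#' @param kernel "bisquare" (default), "gaussian" or "uniform".
#' @param method "spearman" (default) or "pearson".
#' @param spacingUm lattice spacing in micrometers; by default the smallest
#'   nonzero pairwise spot distance.
#' @return list: `local` (per-spot local correlation, NA where skipped),
#'   `mean` (sample mean over evaluable spots).
#' @export
swCorrelation <- function(spots, scoreA, scoreB, bandwidth = 5,
                          kernel = c("bisquare", "gaussian", "uniform"),
                          method = c("spearman", "pearson"),
                          spacingUm = NULL) {
    kernel <- match.arg(kernel)
    method <- match.arg(method)
    a <- spots[[scoreA]]; b <- spots[[scoreB]]
    if (is.null(a) || is.null(b)) stop("score column not found")
    if (method == "spearman") { a <- rank(a); b <- rank(b) }
    xy <- cbind(spots$x_um, spots$y_um)
    d <- as.matrix(dist(xy))
    if (is.null(spacingUm)) {
        pos <- d[d > 0]
        spacingUm <- if (length(pos)) min(pos) else 1
    }
    h <- bandwidth * spacingUm
    n <- nrow(spots)
    local <- rep(NA_real_, n)
    skipped <- 0L
    for (i in seq_len(n)) {
        if (is.finite(h)) {
            nb <- which(d[i, ] <= h)
            w <- switch(kernel,
                bisquare = (1 - (d[i, nb] / h)^2)^2,
                gaussian = exp(-0.5 * (d[i, nb] / h)^2),
                uniform = rep(1, length(nb)))
        } else {
            nb <- seq_len(n)
            w <- switch(kernel,
                bisquare = rep(1, n), gaussian = rep(1, n),
                uniform = rep(1, n))
        }
        if (length(nb) < 2L) { skipped <- skipped + 1L; next }
        local[i] <- weightedPearson(a[nb], b[nb], w)
        if (is.na(local[i])) skipped <- skipped + 1L
    }
    if (skipped > 0L)
        warning(skipped, " spot(s) skipped (too few neighbors or zero ",
                "local variance)")
    list(local = local, mean = mean(local, na.rm = TRUE))
}

# Weighted Pearson correlation; NA when either local variance is zero.
weightedPearson <- function(x, y, w) {
    w <- w / sum(w)
    mx <- sum(w * x); my <- sum(w * y)
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx <= 0 || vy <= 0) return(NA_real_)
    sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Distance binning around annotated invasion foci
#'
#' Spots carrying the focus label, or whose center lies within
#' `thresholdUm` of any focus-labeled spot center, are "proximal"
#' (boundary inclusive); all others are "distal". Samples without any
#' focus-labeled spot are entirely distal.
#'
#' @param spots data.frame with `x_um`, `y_um`, `annotation`.
#' @param focusLabel annotation marking invaded foci
#'   (default "VI focus").
#' @param thresholdUm distance threshold in micrometers (default 1000,
#'   i.e. 1 mm).
#' @return character vector ("proximal"/"distal"), one per spot.
#' @export
distanceBins <- function(spots, focusLabel = "VI focus",
                         thresholdUm = 1000) {
    stopifnot(all(is.finite(spots$x_um)), all(is.finite(spots$y_um)))
    isFocus <- spots$annotation == focusLabel
    if (!any(isFocus)) return(rep("distal", nrow(spots)))
    fx <- spots$x_um[isFocus]; fy <- spots$y_um[isFocus]
    minD <- vapply(seq_len(nrow(spots)), function(i)
        min(sqrt((spots$x_um[i] - fx)^2 + (spots$y_um[i] - fy)^2)), 0)
    ifelse(isFocus | minD <= thresholdUm, "proximal", "distal")
}

#' Read / write spot tables as TSV
#'
#' Required columns: `spot_id`, `x_um`, `y_um`, `annotation`; any further
#' columns (detection counts, scores) pass through.
#'
#' @param path file path.
#' @return `readSpotsTsv` returns a data.frame.
#' @export
readSpotsTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    need <- c("spot_id", "x_um", "y_um", "annotation")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("missing spot columns: ",
                           paste(miss, collapse = ", "))
    df
}

#' @rdname readSpotsTsv
#' @param spots data.frame of spots.
#' @export
writeSpotsTsv <- function(spots, path) {
    write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
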