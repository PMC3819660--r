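#' Construct trimming bounds
#'
#' @param mLower,mUpper fractional window on min-max-normalized M values.
#' @param aLower,aUpper fractional window on min-max-normalized A values.
#' @return a [TrimBounds-class].
#' @export
TrimBounds <- function(mLower = 0.3, mUpper = 1 - 0.3,
                       aLower = 0.2, aUpper = 1 - 0.2) {
    methods::new("TrimBounds", mLower = mLower, mUpper = mUpper,
                 aLower = aLower, aUpper = aUpper)
}

#' Build the reference profile from commonly expressed genes
#'
#' The common set G holds every scaffold with non-zero abundance in all n
#' samples.  Its reference abundance is the arithmetic mean over samples,
#' Y_g = sum_k Y[g, k] / n, and the reference total is N = sum_{g in G} Y_g.
#' The profile acts as a virtual reference sample for factor estimation.
#'
#' @param ab an [AbundanceMatrix-class] with >= 2 samples.
#' @return a [ReferenceProfile-class].
#' @export
buildReference <- function(ab) {
    stopifnot(methods::is(ab, "AbundanceMatrix"))
    if (ncol(ab) < 2)
        stop("reference profile needs at least 2 samples")
    Y <- abundance(ab)
    common <- rowSums(Y == 0) == 0
    if (!any(common))
        stop("no commonly expressed genes: G is empty")
    yRef <- rowMeans(Y[common, , drop = FALSE])
    methods::new("ReferenceProfile", genes = rownames(Y)[common],
                 abundance = yRef, total = sum(yRef),
                 nSamples = ncol(Y))
}

#' Compute M/A statistics of one sample against the reference
#'
#' Over the common set G:
#' M_g = log2((Y_gk / N_k) / (Y_g / N)),
#' A_g = 0.5 * log2((Y_gk / N_k) * (Y_g / N)).
#' Weights default to the approximate inverse-abundance form
#' w_g = 1/Y_gk + 1/Y_g; \code{exactWeights = TRUE} uses the binomial form
#' (N_k - Y_gk) / (N_k * Y_gk) + (N - Y_g) / (N * Y_g).
#'
#' @param ab an [AbundanceMatrix-class].
#' @param ref a [ReferenceProfile-class] built from \code{ab}.
#' @param sample sample ID or index.
#' @param exactWeights use the exact binomial weight form.
#' @return an [MAStatistics-class] with the attained extremes recorded.
#' @export
computeMA <- function(ab, ref, sample, exactWeights = FALSE) {
    stopifnot(methods::is(ab, "AbundanceMatrix"),
              methods::is(ref, "ReferenceProfile"))
    Y <- abundance(ab)
    if (is.numeric(sample)) sample <- colnames(Y)[sample]
    if (!sample %in% colnames(Y)) stop("unknown sample: ", sample)
    g <- ref@genes
    ygk <- Y[g, sample]
    if (any(ygk <= 0))
        stop("internal inconsistency: zero abundance inside G for sample ",
             sample)
    nk <- sampleTotals(ab)[sample]
    relK <- ygk / nk
    relR <- ref@abundance / ref@total
    M <- log2(relK / relR)
    A <- 0.5 * log2(relK * relR)
    w <- if (exactWeights)
        (nk - ygk) / (nk * ygk) +
            (ref@total - ref@abundance) / (ref@total * ref@abundance)
    else 1 / ygk + 1 / ref@abundance
    methods::new("MAStatistics", sample = sample, genes = g,
                 M = unname(M), A = unname(A), w = unname(w),
                 extremes = c(Mmin = min(M), Mmax = max(M),
                              Amin = min(A), Amax = max(A)))
}

#' Trim extreme genes on the MA plane
#'
#' M and A are min-max normalized per sample; a gene is kept when both
#' normalized statistics fall strictly inside their windows:
#' mLower < (M_g - Mmin)/(Mmax - Mmin) < mUpper and likewise for A.  When a
#' range is zero (all M equal, or all A equal) that criterion carries no
#' information and passes all genes.
#'
#' @param stats an [MAStatistics-class].
#' @param bounds a [TrimBounds-class].
#' @return character vector: the kept gene set G*.
#' @export
trimGenes <- function(stats, bounds = TrimBounds()) {
    stopifnot(methods::is(stats, "MAStatistics"),
              methods::is(bounds, "TrimBounds"))
    if (!length(stats@genes)) stop("MA statistics over an empty gene set")
    e <- stats@extremes
    keepM <- if (e["Mmax"] > e["Mmin"]) {
        m <- (stats@M - e["Mmin"]) / (e["Mmax"] - e["Mmin"])
        m > bounds@mLower & m < bounds@mUpper
    } else rep(TRUE, length(stats@M))
    keepA <- if (e["Amax"] > e["Amin"]) {
        a <- (stats@A - e["Amin"]) / (e["Amax"] - e["Amin"])
        a > bounds@aLower & a < bounds@aUpper
    } else rep(TRUE, length(stats@A))
    gStar <- stats@genes[keepM & keepA]
    if (!length(gStar))
        stop("trimming left no genes for sample ", stats@sample,
             "; widen the bounds")
    gStar
}

#' Weighted-mean normalization factor over the trimmed set
#'
#' log2 TMM = sum_{g in G*} w_g M_g / sum_{g in G*} w_g, and R = 2^logTMM.
#'
#' @param stats an [MAStatistics-class].
#' @param gStar the trimmed gene set from [trimGenes()].
#' @return list with elements \code{logTMM} and \code{R}.
#' @export
normalizationFactor <- function(stats, gStar) {
    stopifnot(methods::is(stats, "MAStatistics"), length(gStar) > 0)
    idx <- match(gStar, stats@genes)
    if (anyNA(idx)) stop("G* contains genes outside G")
    w <- stats@w[idx]
    if (sum(w) <= 0) stop("total weight is zero")
    logTMM <- sum(w * stats@M[idx]) / sum(w)
    list(logTMM = logTMM, R = 2^logTMM)
}

#' n-sample TMM normalization
#'
#' Full pipeline: build the reference profile from the genes expressed in
#' every sample, then per sample compute M/A statistics, trim extremes, and
#' take the weighted mean of M over the kept set.  The normalized output is
#' the per-million relative abundance divided by the sample factor:
#' (Y[g, k] / N_k) / R_k * 1e6 (the constant cancels in all ratios and
#' correlations).
#'
#' @param ab an [AbundanceMatrix-class].
#' @param bounds a [TrimBounds-class]; defaults to (0.3, 0.7) x (0.2, 0.8).
#' @param exactWeights use exact binomial weights (see [computeMA()]).
#' @return a [NormalizationResult-class] carrying factors, trimmed sets,
#'   per-sample MA statistics and the normalized matrix.
#' @examples
#' cts <- matrix(rpois(60, 50) + 2L, ncol = 3,
#'               dimnames = list(paste0("s", 1:20), c("A", "B", "C")))
#' sc <- ScaffoldCounts(cts, setNames(rep(500, 20), paste0("s", 1:20)))
#' res <- normalizeTMM(estimateAbundance(cleanCounts(sc)))
#' normFactors(res)
#' @export
normalizeTMM <- function(ab, bounds = TrimBounds(), exactWeights = FALSE) {
    stopifnot(methods::is(ab, "AbundanceMatrix"))
    ref <- buildReference(ab)
    samples <- colnames(ab)
    maStats <- trimmed <- stats::setNames(vector("list", length(samples)),
                                          samples)
    logTMM <- R <- stats::setNames(numeric(length(samples)), samples)
    for (k in samples) {
        st <- tryCatch(computeMA(ab, ref, k, exactWeights = exactWeights),
                       error = function(e)
                           stop("sample ", k, ": ", conditionMessage(e)))
        gs <- trimGenes(st, bounds)
        f <- normalizationFactor(st, gs)
        maStats[[k]] <- st
        trimmed[[k]] <- gs
        logTMM[k] <- f$logTMM
        R[k] <- f$R
    }
    Y <- abundance(ab)
    rel <- sweep(Y, 2L, sampleTotals(ab), "/")
    normalized <- sweep(rel, 2L, R, "/") * 1e6
    factors <- data.frame(sample = samples,
                          nG = length(ref@genes),
                          nGstar = lengths(trimmed),
                          logTMM = unname(logTMM), R = unname(R),
                          row.names = NULL)
    methods::new("NormalizationResult", reference = ref, factors = factors,
                 trimmedSets = trimmed, maStats = maStats, bounds = bounds,
                 normalized = normalized)
}

#' Write normalization outputs
#'
#' Writes the factors table and the normalized matrix as TSV, plus a JSON
#' audit record of the bounds and the per-sample M/A extremes.
#'
#' @param res a [NormalizationResult-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeNormalization <- function(res, dir) {
    stopifnot(methods::is(res, "NormalizationResult"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fFactors <- file.path(dir, "factors.tsv")
    fMatrix <- file.path(dir, "normalized.tsv")
    fAudit <- file.path(dir, "audit.json")
    utils::write.table(res@factors, fFactors, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    m <- data.frame(scaffold = rownames(res@normalized), res@normalized,
                    check.names = FALSE)
    utils::write.table(m, fMatrix, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    audit <- list(
        bounds = list(mLower = res@bounds@mLower, mUpper = res@bounds@mUpper,
                      aLower = res@bounds@aLower, aUpper = res@bounds@aUpper),
        nG = length(res@reference@genes),
        extremes = lapply(res@maStats, function(s) as.list(s@extremes)))
    jsonlite::write_json(audit, fAudit, auto_unbox = TRUE, digits = NA)
    invisible(c(fFactors, fMatrix, fAudit))
}
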