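# Independent direct-evaluation oracle for the normalization formulas.
# Deliberately written with explicit per-gene loops and no shared code with
# the package: it evaluates each printed formula one gene at a time.

oracleNormalize <- function(counts, lengths, mLower = 0.3, mUpper = 0.7,
                            aLower = 0.2, aUpper = 0.8,
                            exactWeights = FALSE) {
    counts[counts < 2] <- 0
    nGene <- nrow(counts); nSamp <- ncol(counts)
    totals <- numeric(nSamp)
    for (k in seq_len(nSamp)) totals[k] <- sum(counts[, k])
    Y <- matrix(0, nGene, nSamp, dimnames = dimnames(counts))
    for (g in seq_len(nGene)) for (k in seq_len(nSamp))
        Y[g, k] <- counts[g, k] / (lengths[g] * totals[k])
    N <- numeric(nSamp)
    for (k in seq_len(nSamp)) N[k] <- sum(Y[, k])
    inG <- logical(nGene)
    for (g in seq_len(nGene)) inG[g] <- all(Y[g, ] != 0)
    if (!any(inG)) stop("oracle: empty G")
    yRef <- numeric(nGene)
    for (g in which(inG)) yRef[g] <- sum(Y[g, ]) / nSamp
    nRef <- sum(yRef[inG])
    R <- logTMM <- numeric(nSamp)
    gStar <- vector("list", nSamp)
    for (k in seq_len(nSamp)) {
        gs <- which(inG)
        M <- A <- W <- numeric(length(gs))
        for (i in seq_along(gs)) {
            g <- gs[i]
            relK <- Y[g, k] / N[k]
            relR <- yRef[g] / nRef
            M[i] <- log2(relK / relR)
            A[i] <- 0.5 * log2(relK * relR)
            W[i] <- if (exactWeights)
                (N[k] - Y[g, k]) / (N[k] * Y[g, k]) +
                    (nRef - yRef[g]) / (nRef * yRef[g])
            else 1 / Y[g, k] + 1 / yRef[g]
        }
        mMin <- min(M); mMax <- max(M); aMin <- min(A); aMax <- max(A)
        keep <- logical(length(gs))
        for (i in seq_along(gs)) {
            okM <- if (mMax > mMin) {
                pos <- (M[i] - mMin) / (mMax - mMin)
                pos > mLower && pos < mUpper
            } else TRUE
            okA <- if (aMax > aMin) {
                pos <- (A[i] - aMin) / (aMax - aMin)
                pos > aLower && pos < aUpper
            } else TRUE
            keep[i] <- okM && okA
        }
        if (!any(keep)) stop("oracle: empty G* for sample ", k)
        num <- den <- 0
        for (i in which(keep)) {
            num <- num + W[i] * M[i]
            den <- den + W[i]
        }
        logTMM[k] <- num / den
        R[k] <- 2^logTMM[k]
        gStar[[k]] <- rownames(counts)[gs[keep]]
    }
    list(logTMM = logTMM, R = R, G = rownames(counts)[inG], gStar = gStar)
}

# well-behaved table: unimodal moderate noise, no extreme outliers
benignCountTable <- function(nGenes, nSamples) {
    cts <- matrix(as.integer(rpois(nGenes * nSamples, lambda = 400)) + 20L,
                  nGenes, nSamples,
                  dimnames = list(paste0("g", seq_len(nGenes)),
                                  paste0("s", seq_len(nSamples))))
    cts
}

# random small count table with guaranteed common genes
randomCountTable <- function(nGenes, nSamples) {
    cts <- matrix(rpois(nGenes * nSamples, lambda = 60) + 2L,
                  nGenes, nSamples,
                  dimnames = list(paste0("g", seq_len(nGenes)),
                                  paste0("s", seq_len(nSamples))))
    # sprinkle some zeros and low counts without emptying G
    idx <- sample(length(cts), size = floor(length(cts) / 5))
    cts[idx] <- sample(0:3, length(idx), replace = TRUE)
    cts[1:3, ] <- cts[1:3, ] + 10L  # keep G non-empty
    storage.mode(cts) <- "integer"
    cts
}

makeAbundance <- function(cts, lengths = NULL) {
    if (is.null(lengths))
        lengths <- stats::setNames(rep(1000L, nrow(cts)), rownames(cts))
    estimateAbundance(cleanCounts(ScaffoldCounts(cts, lengths)))
}
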