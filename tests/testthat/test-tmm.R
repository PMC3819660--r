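test_that("reference profile is the mean over samples of all-expressed genes", {
    Y <- matrix(c(0.4, 0.4, 10, 1,
                  0.6, 0,   20, 3,
                  0.5, 0.2, 30, 2), nrow = 4,
                dimnames = list(c("g1", "g2", "g3", "g4"),
                                c("s1", "s2", "s3")))
    cts <- matrix(2L, 4, 3, dimnames = dimnames(Y))
    ab <- makeAbundance(cts)
    # overwrite the assay to hold the prescribed abundances
    SummarizedExperiment::assay(ab, "abundance") <- Y
    SummarizedExperiment::colData(ab)$totalAbundance <- colSums(Y)
    ref <- buildReference(ab)
    expect_setequal(referenceGenes(ref), c("g1", "g3", "g4"))
    expect_equal(ref@abundance[["g1"]], mean(c(0.4, 0.6, 0.5)))
    expect_equal(ref@total, sum(ref@abundance))
    expect_equal(ref@nSamples, 3L)

    Y0 <- Y; Y0[, 2] <- 0
    SummarizedExperiment::assay(ab, "abundance") <- Y0
    SummarizedExperiment::colData(ab)$totalAbundance <- colSums(Y0)
    expect_error(buildReference(ab), "no commonly expressed")
})

test_that("M, A and weights follow the printed formulas", {
    # 6-gene table evaluated independently entry by entry
    set.seed(4)
    cts <- matrix(as.integer(rpois(12, 200)) + 2L, 6, 2,
                  dimnames = list(paste0("g", 1:6), c("k", "r")))
    len <- stats::setNames(c(300L, 500L, 800L, 1200L, 2000L, 650L),
                           rownames(cts))
    ab <- makeAbundance(cts, len)
    ref <- buildReference(ab)
    st <- computeMA(ab, ref, "k")
    Y <- abundance(ab)
    nk <- sum(Y[, "k"])
    yref <- rowMeans(Y)
    nref <- sum(yref)
    for (i in 1:6) {
        relK <- Y[i, "k"] / nk
        relR <- yref[i] / nref
        expect_equal(st@M[i], unname(log2(relK / relR)))
        expect_equal(st@A[i], unname(0.5 * log2(relK * relR)))
        expect_equal(st@w[i], unname(1 / Y[i, "k"] + 1 / yref[i]))
    }
    expect_equal(st@extremes[["Mmin"]], min(st@M))
    expect_equal(st@extremes[["Amax"]], max(st@A))

    stE <- computeMA(ab, ref, "k", exactWeights = TRUE)
    expect_equal(stE@w[1],
                 unname((nk - Y[1, "k"]) / (nk * Y[1, "k"]) +
                            (nref - yref[1]) / (nref * yref[1])))

    # identical relative abundance gives M = 0; 4x gives M = 2
    expect_equal(log2((4 * 0.01) / 0.01), 2)
    wEx <- 1 / 0.01 + 1 / 0.02
    expect_equal(wEx, 150)
})

test_that("min-max trimming keeps the strict central window", {
    st <- methods::new("MAStatistics", sample = "s",
                       genes = paste0("g", 0:10),
                       M = as.numeric(0:10), A = as.numeric(0:10),
                       w = rep(1, 11),
                       extremes = c(Mmin = 0, Mmax = 10, Amin = 0,
                                    Amax = 10))
    kept <- trimGenes(st, TrimBounds(0.3, 0.7, 0.2, 0.8))
    expect_identical(kept, paste0("g", 4:6))

    # boundary gene at exactly the lower fraction is excluded
    expect_false("g3" %in% kept)

    # degenerate ranges pass everything
    stFlat <- methods::new("MAStatistics", sample = "s",
                           genes = c("a", "b"), M = c(1, 1), A = c(2, 2),
                           w = c(1, 1),
                           extremes = c(Mmin = 1, Mmax = 1, Amin = 2,
                                        Amax = 2))
    expect_identical(trimGenes(stFlat, TrimBounds()), c("a", "b"))

    # all genes outside the window errors
    stBi <- methods::new("MAStatistics", sample = "s",
                         genes = c("a", "b"), M = c(0, 10), A = c(0, 10),
                         w = c(1, 1),
                         extremes = c(Mmin = 0, Mmax = 10, Amin = 0,
                                      Amax = 10))
    expect_error(trimGenes(stBi, TrimBounds()), "widen")
})

test_that("the factor is the weighted mean of M over G*", {
    st <- methods::new("MAStatistics", sample = "s", genes = c("a", "b"),
                       M = c(1, 3), A = c(0, 0), w = c(3, 1),
                       extremes = c(Mmin = 1, Mmax = 3, Amin = 0,
                                    Amax = 0))
    f <- normalizationFactor(st, c("a", "b"))
    expect_equal(f$logTMM, 1.5)
    expect_equal(f$R, 2^1.5)

    stConst <- methods::new("MAStatistics", sample = "s",
                            genes = c("a", "b"), M = c(1, 1), A = c(0, 0),
                            w = c(5, 0.1),
                            extremes = c(Mmin = 1, Mmax = 1, Amin = 0,
                                         Amax = 0))
    expect_equal(normalizationFactor(stConst, c("a", "b"))$R, 2)
    expect_error(normalizationFactor(st, c("a", "zzz")), "outside G")
})

test_that("pipeline matches the loop-based oracle on random tables", {
    set.seed(202)
    for (i in 1:25) {
        cts <- randomCountTable(sample(6:20, 1), sample(2:4, 1))
        len <- stats::setNames(sample(200:2000, nrow(cts)), rownames(cts))
        ok <- tryCatch({
            res <- normalizeTMM(makeAbundance(cts, len))
            TRUE
        }, error = function(e) FALSE)
        orc <- tryCatch(oracleNormalize(cts, len), error = function(e) NULL)
        if (!ok || is.null(orc)) {
            # both routes must agree on degeneracy too
            expect_true(!ok && is.null(orc))
            next
        }
        expect_equal(normFactors(res)$R, orc$R, tolerance = 1e-12)
        expect_equal(normFactors(res)$logTMM, orc$logTMM,
                     tolerance = 1e-12)
        expect_setequal(referenceGenes(res), orc$G)
    }
})

test_that("factor invariances: identity, per-sample scaling, row order", {
    set.seed(31)
    cts <- benignCountTable(15, 3)
    len <- stats::setNames(sample(300:1500, 15), rownames(cts))
    ab <- makeAbundance(cts, len)
    res <- normalizeTMM(ab)

    # per-sample rescaling of (cleaned) counts
    cts2 <- cts; cts2[, 2] <- cts2[, 2] * 13L
    res2 <- normalizeTMM(makeAbundance(cts2, len))
    expect_equal(normFactors(res2)$R, normFactors(res)$R)

    # gene-row permutation
    perm <- sample(nrow(cts))
    res3 <- normalizeTMM(makeAbundance(cts[perm, ], len[perm]))
    expect_equal(normFactors(res3)$R, normFactors(res)$R)

    # reported log2(R) equals the weighted mean over G* exactly
    for (k in seq_len(ncol(cts))) {
        st <- res@maStats[[k]]
        idx <- match(trimmedSets(res)[[k]], st@genes)
        expect_identical(normFactors(res)$logTMM[k],
                         sum(st@w[idx] * st@M[idx]) / sum(st@w[idx]))
        expect_true(all(trimmedSets(res)[[k]] %in% referenceGenes(res)))
    }
})

test_that("trimming ejects planted extreme genes from G* in the DE sample", {
    sim <- simulateOrganData(simulationSpec(
        nGenes = 500, nSamples = 3, seed = 9,
        librarySizes = c(1e6, 1e6, 1e6), deFraction = 0.05, deFold = 8,
        deSamples = 1, dropout = 0, dispersion = 0))
    res <- normalizeTMM(estimateAbundance(cleanCounts(sim$counts)))
    gStarDE <- trimmedSets(res)[["A"]]
    expect_length(intersect(gStarDE, sim$truth$deGenes), 0)
})

test_that("normalization outputs round-trip to disk", {
    set.seed(5)
    cts <- benignCountTable(10, 2)
    res <- normalizeTMM(makeAbundance(cts))
    dir <- tempfile()
    paths <- writeNormalization(res, dir)
    expect_true(all(file.exists(paths)))
    fac <- utils::read.delim(paths[1])
    expect_equal(fac$R, normFactors(res)$R)
    audit <- jsonlite::read_json(paths[3])
    expect_equal(audit$bounds$mLower, 0.3)
})
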