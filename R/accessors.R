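#' Scaffold lengths
#'
#' Lengths (nt) of the scaffolds in a [ScaffoldCounts-class] or
#' [AbundanceMatrix-class] object, named by scaffold ID.
#'
#' @param x a ScaffoldCounts or AbundanceMatrix.
#' @return named numeric vector of lengths.
#' @rdname scaffoldLengths
#' @export
setMethod("scaffoldLengths", "SummarizedExperiment", function(x) {
    len <- SummarizedExperiment::rowData(x)$scaffoldLength
    stats::setNames(as.numeric(len), rownames(x))
})

#' Abundance assay
#'
#' The Y matrix of an [AbundanceMatrix-class]: Y[g, k] =
#' count[g, k] / (length[g] * librarySize[k]).
#'
#' @param x an AbundanceMatrix.
#' @return numeric matrix (scaffolds x samples).
#' @rdname abundance
#' @export
setMethod("abundance", "AbundanceMatrix", function(x)
    SummarizedExperiment::assay(x, "abundance"))

#' Per-sample abundance totals
#'
#' N_k = sum over scaffolds of Y[g, k], named by sample.
#'
#' @param x an AbundanceMatrix.
#' @return named numeric vector.
#' @rdname sampleTotals
#' @export
setMethod("sampleTotals", "AbundanceMatrix", function(x)
    stats::setNames(SummarizedExperiment::colData(x)$totalAbundance,
                    colnames(x)))

#' Normalization factors
#'
#' The per-sample factors table of a [NormalizationResult-class]:
#' sample, |G|, |G*|, log2 TMM, and R = 2^logTMM.
#'
#' @param x a NormalizationResult.
#' @return data.frame with columns sample, nG, nGstar, logTMM, R.
#' @rdname normFactors
#' @export
setMethod("normFactors", "NormalizationResult", function(x) x@factors)

#' Normalized expression matrix
#'
#' Per-million relative abundance divided by the sample's factor R:
#' (Y[g, k] / N_k) / R_k * 1e6.
#'
#' @param x a NormalizationResult.
#' @return numeric matrix (scaffolds x samples).
#' @rdname normalizedExpression
#' @export
setMethod("normalizedExpression", "NormalizationResult",
          function(x) x@normalized)

#' Common gene set of a reference profile
#'
#' @param x a ReferenceProfile or NormalizationResult.
#' @return character vector of gene IDs in G.
#' @rdname referenceGenes
#' @export
setMethod("referenceGenes", "ReferenceProfile", function(x) x@genes)

#' @rdname referenceGenes
#' @export
setMethod("referenceGenes", "NormalizationResult",
          function(x) x@reference@genes)

#' Trimmed gene sets G* per sample
#'
#' @param x a NormalizationResult.
#' @return named list of character vectors.
#' @rdname trimmedSets
#' @export
setMethod("trimmedSets", "NormalizationResult", function(x) x@trimmedSets)

#' Subcellular class per scaffold
#'
#' @param x a PartitionResult.
#' @return named character vector with values "chloroplast",
#'   "mitochondrion" or "nucleus".
#' @rdname classification
#' @export
setMethod("classification", "PartitionResult", function(x) x@classification)

setMethod("show", "ScaffoldCounts", function(object) {
    cat("ScaffoldCounts:", nrow(object), "scaffolds x", ncol(object),
        "samples\n")
    cat("  library sizes:",
        paste(colSums(SummarizedExperiment::assay(object, "counts")),
              collapse = ", "), "\n")
})

setMethod("show", "AbundanceMatrix", function(object) {
    cat("AbundanceMatrix:", nrow(object), "scaffolds x", ncol(object),
        "samples\n")
    cat("  N_k:", paste(signif(sampleTotals(object), 4), collapse = ", "),
        "\n")
})

setMethod("show", "ReferenceProfile", function(object) {
    cat("ReferenceProfile over", object@nSamples, "samples\n")
    cat("  |G| =", length(object@genes), ", N =", signif(object@total, 6),
        "\n")
})

setMethod("show", "MAStatistics", function(object) {
    cat("MAStatistics for sample", object@sample, "over",
        length(object@genes), "genes\n")
    e <- object@extremes
    cat(sprintf("  M in [%.4g, %.4g], A in [%.4g, %.4g]\n",
                e["Mmin"], e["Mmax"], e["Amin"], e["Amax"]))
})

setMethod("show", "TrimBounds", function(object) {
    cat(sprintf("TrimBounds: M in (%.3g, %.3g), A in (%.3g, %.3g)\n",
                object@mLower, object@mUpper, object@aLower, object@aUpper))
})

setMethod("show", "NormalizationResult", function(object) {
    cat("NormalizationResult over", nrow(object@factors), "samples, |G| =",
        length(object@reference@genes), "\n")
    print(object@factors, row.names = FALSE)
})

setMethod("show", "PartitionResult", function(object) {
    cat("PartitionResult:",
        paste(names(table(object@classification)),
              table(object@classification), sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "PathwayGraph", function(object) {
    cat("PathwayGraph:", nrow(object@nodes), "nodes,", nrow(object@edges),
        "edges;", sum(lengths(object@scaffolds) > 0),
        "nodes with mapped scaffolds\n")
})

setMethod("show", "ClusterTree", function(object) {
    cat("ClusterTree over", length(object@tree$labels), object@axis,
        "( scaling:", object@scaling, ")\n")
})

setMethod("show", "SimulationSpec", function(object) {
    cat("SimulationSpec:", object@nGenes, "genes x", object@nSamples,
        "samples, seed", object@seed, "\n")
    cat(sprintf("  DE: %.1f%% at %g-fold in sample(s) %s; dropout %.2g\n",
                100 * object@deFraction, object@deFold,
                paste(object@deSamples, collapse = ","), object@dropout))
})
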