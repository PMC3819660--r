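#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setOldClass("hclust")

#' ScaffoldCounts: raw read counts per scaffold per sample
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"counts"}
#' assay of non-negative integer paired-end read counts (scaffolds x
#' samples) together with the scaffold lengths (nt) in
#' \code{rowData()$scaffoldLength}.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [ScaffoldCounts()], [cleanCounts()], [estimateAbundance()]
#' @exportClass ScaffoldCounts
setClass("ScaffoldCounts", contains = "SummarizedExperiment")

setValidity("ScaffoldCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (anyNA(cts))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(cts < 0)) {
                bad <- rownames(object)[which(rowSums(cts < 0) > 0)]
                msg <- c(msg, paste0("negative counts for scaffold(s): ",
                                     paste(utils::head(bad, 5), collapse = ", ")))
            }
            if (any(cts != floor(cts)))
                msg <- c(msg, "counts must be whole numbers")
        }
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!"scaffoldLength" %in% colnames(rd))
        msg <- c(msg, "rowData column 'scaffoldLength' is required")
    else {
        len <- rd$scaffoldLength
        if (anyNA(len) || any(len <= 0)) {
            bad <- rownames(object)[which(is.na(len) | len <= 0)]
            msg <- c(msg, paste0("missing or non-positive length for scaffold(s): ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
        }
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "scaffold IDs must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample IDs must be unique")
    if (length(msg)) msg else TRUE
})

#' AbundanceMatrix: length- and depth-scaled scaffold abundances
#'
#' A \linkS4class{SummarizedExperiment} with one \code{"abundance"} assay of
#' abundances Y (scaffolds x samples), where
#' Y[g, k] = count[g, k] / (length[g] * librarySize[k]).  Per-sample totals
#' N_k = sum_g Y[g, k] live in \code{colData()$totalAbundance}; the cleaned
#' per-sample read totals used as denominators are in
#' \code{colData()$librarySize}.
#'
#' @seealso [estimateAbundance()], [buildReference()], [normalizeTMM()]
#' @exportClass AbundanceMatrix
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("totalAbundance", "librarySize") %in% colnames(cd)))
        msg <- c(msg, "colData must carry 'totalAbundance' and 'librarySize'")
    if (!length(msg)) {
        Y <- SummarizedExperiment::assay(object, "abundance")
        if (any(Y < 0)) msg <- c(msg, "abundances must be non-negative")
        N <- cd$totalAbundance
        if (any(abs(colSums(Y) - N) > 1e-8 * pmax(N, 1e-300)))
            msg <- c(msg, "totalAbundance must equal column sums of Y")
    }
    if (length(msg)) msg else TRUE
})

#' ReferenceProfile: the virtual reference sample for TMM normalization
#'
#' Holds the common gene set G (scaffolds with non-zero abundance in every
#' sample), the mean abundance of each over the n samples, and the total.
#'
#' @slot genes character, the IDs in G.
#' @slot abundance named numeric, mean abundance per gene in G.
#' @slot total numeric(1), sum of the reference abundances.
#' @slot nSamples integer(1), number of samples the profile averages over.
#' @exportClass ReferenceProfile
setClass("ReferenceProfile",
         representation(genes = "character", abundance = "numeric",
                        total = "numeric", nSamples = "integer"))

setValidity("ReferenceProfile", function(object) {
    msg <- character()
    if (length(object@genes) != length(object@abundance))
        msg <- c(msg, "genes and abundance lengths differ")
    if (length(object@genes) && any(object@abundance <= 0))
        msg <- c(msg, "reference abundances must be positive on G")
    if (abs(object@total - sum(object@abundance)) >
        1e-8 * max(object@total, 1e-300))
        msg <- c(msg, "total must equal sum of reference abundances")
    if (length(msg)) msg else TRUE
})

#' MAStatistics: per-sample M/A values and weights over the common set
#'
#' For one sample k versus the reference profile: M (log2 ratio of relative
#' abundances), A (average log2 intensity), the precision weights w, and the
#' attained extremes of M and A used for min-max trimming.
#'
#' @slot sample character(1), sample ID.
#' @slot genes character, gene IDs (the common set G).
#' @slot M,A,w numeric vectors parallel to genes.
#' @slot extremes named numeric(4): Mmin, Mmax, Amin, Amax.
#' @exportClass MAStatistics
setClass("MAStatistics",
         representation(sample = "character", genes = "character",
                        M = "numeric", A = "numeric", w = "numeric",
                        extremes = "numeric"))

setValidity("MAStatistics", function(object) {
    msg <- character()
    n <- length(object@genes)
    if (length(object@M) != n || length(object@A) != n ||
        length(object@w) != n)
        msg <- c(msg, "M, A, w must be parallel to genes")
    if (n && any(object@w <= 0))
        msg <- c(msg, "weights must be positive")
    if (!all(c("Mmin", "Mmax", "Amin", "Amax") %in% names(object@extremes)))
        msg <- c(msg, "extremes must name Mmin, Mmax, Amin, Amax")
    if (length(msg)) msg else TRUE
})

#' TrimBounds: min-max trimming window on the MA plane
#'
#' Fractional bounds in [0, 1] applied to min-max-normalized M and A values;
#' a gene is kept when it falls strictly inside both windows.  Defaults are
#' the method's working values (0.3, 0.7) for M and (0.2, 0.8) for A.
#'
#' @slot mLower,mUpper,aLower,aUpper numeric(1) in [0, 1].
#' @exportClass TrimBounds
setClass("TrimBounds",
         representation(mLower = "numeric", mUpper = "numeric",
                        aLower = "numeric", aUpper = "numeric"))

setValidity("TrimBounds", function(object) {
    b <- c(object@mLower, object@mUpper, object@aLower, object@aUpper)
    msg <- character()
    if (any(b < 0 | b > 1)) msg <- c(msg, "bounds must lie in [0, 1]")
    if (object@mLower >= object@mUpper) msg <- c(msg, "mLower must be < mUpper")
    if (object@aLower >= object@aUpper) msg <- c(msg, "aLower must be < aUpper")
    if (length(msg)) msg else TRUE
})

#' NormalizationResult: factors and audit trail of TMM normalization
#'
#' @slot reference the [ReferenceProfile-class] used.
#' @slot factors data.frame with one row per sample: sample, nG, nGstar,
#'   logTMM, R.
#' @slot trimmedSets named list of kept gene sets G* per sample.
#' @slot maStats named list of [MAStatistics-class] per sample.
#' @slot bounds the [TrimBounds-class] applied.
#' @slot normalized matrix of normalized expression (per-million relative
#'   abundance divided by R).
#' @exportClass NormalizationResult
setClass("NormalizationResult",
         representation(reference = "ReferenceProfile", factors = "data.frame",
                        trimmedSets = "list", maStats = "list",
                        bounds = "TrimBounds", normalized = "matrix"))

#' PartitionResult: subcellular classification of scaffolds
#'
#' @slot classification named character: one of "chloroplast",
#'   "mitochondrion", "nucleus" per scaffold.
#' @slot summary data.frame of per-class per-sample scaffold counts and
#'   summed expression (when expression was supplied).
#' @slot conflicts data.frame of scaffolds passing both organelle filters.
#' @exportClass PartitionResult
setClass("PartitionResult",
         representation(classification = "character", summary = "data.frame",
                        conflicts = "data.frame"))

#' PathwayGraph: reaction topology with scaffold mappings
#'
#' @slot nodes data.frame with columns node_id, label (EC number or gene
#'   name).
#' @slot scaffolds named list (by node_id) of character vectors of mapped
#'   scaffold IDs (possibly empty).
#' @slot edges data.frame with columns from, to and optionally metabolite.
#' @exportClass PathwayGraph
setClass("PathwayGraph",
         representation(nodes = "data.frame", scaffolds = "list",
                        edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
    msg <- character()
    ids <- object@nodes$node_id
    if (anyDuplicated(ids)) msg <- c(msg, "node_id must be unique")
    if (!setequal(names(object@scaffolds), ids))
        msg <- c(msg, "scaffolds list must be named by node_id")
    if (nrow(object@edges)) {
        bad <- setdiff(c(object@edges$from, object@edges$to), ids)
        if (length(bad))
            msg <- c(msg, paste0("edges reference unknown node(s): ",
                                 paste(utils::head(bad, 5), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' ClusterTree: correlation-based agglomerative clustering result
#'
#' Wraps the merge tree from average-linkage (UPGMA) clustering on
#' 1 - Pearson correlation after row-max (maxtf) scaling.
#'
#' @slot tree the underlying \code{hclust} object.
#' @slot axis "genes" or "samples".
#' @slot scaling row-scaling mode used ("maxtf").
#' @exportClass ClusterTree
setClass("ClusterTree",
         representation(tree = "hclust", axis = "character",
                        scaling = "character"))

#' SimulationSpec: design of a synthetic organ-transcriptome data set
#'
#' @slot nGenes,nSamples integer scalars.
#' @slot seed integer(1) driving all randomness.
#' @slot librarySizes numeric, expected sequenced read total per sample.
#' @slot deFraction numeric(1), fraction of genes differentially expressed.
#' @slot deFold numeric(1), fold applied to DE genes in the DE samples.
#' @slot deSamples integer, indices of samples carrying the up-regulation.
#' @slot lengthRange integer(2), scaffold length range (nt).
#' @slot dispersion numeric(1), negative-binomial dispersion (1/size).
#' @slot dropout numeric(1), per-entry probability of forced zero.
#' @slot organelleFractions named numeric(2): chloroplast and mitochondrion
#'   fractions of scaffolds carrying planted alignment hits.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
         representation(nGenes = "integer", nSamples = "integer",
                        seed = "integer", librarySizes = "numeric",
                        deFraction = "numeric", deFold = "numeric",
                        deSamples = "integer", lengthRange = "integer",
                        dispersion = "numeric", dropout = "numeric",
                        organelleFractions = "numeric"))

setValidity("SimulationSpec", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
    if (length(object@librarySizes) != object@nSamples)
        msg <- c(msg, "librarySizes must have one entry per sample")
    if (any(object@librarySizes <= 0))
        msg <- c(msg, "librarySizes must be positive")
    if (object@deFraction < 0 || object@deFraction > 1)
        msg <- c(msg, "deFraction must lie in [0, 1]")
    if (object@deFold <= 0) msg <- c(msg, "deFold must be positive")
    if (length(object@deSamples) &&
        (any(object@deSamples < 1L) || any(object@deSamples > object@nSamples)))
        msg <- c(msg, "deSamples out of range")
    if (object@dropout < 0 || object@dropout > 1)
        msg <- c(msg, "dropout must lie in [0, 1]")
    if (any(object@organelleFractions < 0) ||
        sum(object@organelleFractions) > 1)
        msg <- c(msg, "organelle fractions must be in [0, 1] and sum to <= 1")
    if (object@lengthRange[1] < 1L ||
        object@lengthRange[2] < object@lengthRange[1])
        msg <- c(msg, "lengthRange must be increasing and positive")
    if (length(msg)) msg else TRUE
})
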