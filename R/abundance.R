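#' Construct a ScaffoldCounts object
#'
#' Bundles a raw read-count matrix with scaffold lengths.  Scaffolds present
#' in the count table but missing from the length table (or vice versa) are
#' an error by default; with \code{allowMissing = TRUE} they are dropped
#' with a warning, keeping the intersection in count-table order.
#'
#' @param counts integer matrix (scaffolds x samples) with rownames =
#'   scaffold IDs and colnames = sample IDs.
#' @param lengths named numeric vector of scaffold lengths (nt).
#' @param allowMissing drop rather than fail on scaffolds without a length
#'   (or lengths without a count row).
#' @return a [ScaffoldCounts-class].
#' @examples
#' cts <- matrix(c(10L, 20L, 40L), ncol = 1,
#'               dimnames = list(c("s1", "s2", "s3"), "petal"))
#' ScaffoldCounts(cts, c(s1 = 100, s2 = 200, s3 = 400))
#' @export
ScaffoldCounts <- function(counts, lengths, allowMissing = FALSE) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have scaffold rownames and sample colnames")
    if (is.null(names(lengths)))
        stop("lengths must be named by scaffold ID")
    missing <- setdiff(rownames(counts), names(lengths))
    if (length(missing)) {
        if (!allowMissing)
            stop("no length for scaffold(s): ",
                 paste(utils::head(missing, 10), collapse = ", "))
        warning(length(missing), " scaffold(s) without length dropped: ",
                paste(utils::head(missing, 5), collapse = ", "))
        counts <- counts[setdiff(rownames(counts), missing), , drop = FALSE]
    }
    lengths <- lengths[rownames(counts)]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(scaffoldLength = as.integer(lengths),
                                       row.names = rownames(counts)))
    methods::new("ScaffoldCounts", se)
}

#' Read a scaffold count table from TSV
#'
#' Expects a header row of sample IDs and a first column of scaffold IDs;
#' all cells integer.
#'
#' @param file path to the TSV.
#' @return integer matrix with dimnames.
#' @export
readCounts <- function(file) {
    df <- utils::read.delim(file, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
        stop("count table needs a scaffold ID column plus >= 1 sample")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
}

#' Read scaffold lengths from FASTA or a two-column TSV
#'
#' FASTA files (detected by extension .fa/.fasta/.fna or a leading '>') are
#' read with \pkg{Biostrings}; the length of each record is its sequence
#' length.  Otherwise the file is parsed as a two-column TSV of scaffold ID
#' and length.
#'
#' @param file path.
#' @return named numeric vector of lengths.
#' @export
readLengths <- function(file) {
    isFasta <- grepl("\\.(fa|fasta|fna)$", file, ignore.case = TRUE) ||
        startsWith(readLines(file, n = 1L), ">")
    if (isFasta) {
        seqs <- Biostrings::readDNAStringSet(file)
        ids <- sub("\\s.*$", "", names(seqs))
        return(stats::setNames(Biostrings::width(seqs), ids))
    }
    df <- utils::read.delim(file, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("length TSV needs two columns: ID, length")
    stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Zero out fortuitous low counts
#'
#' Read counts below 2 are considered fortuitous mapping artefacts and set
#' to zero; counts of 2 or more pass through unchanged.  Idempotent.
#'
#' @param x a [ScaffoldCounts-class].
#' @return a ScaffoldCounts with the same dimensions and lengths.
#' @export
cleanCounts <- function(x) {
    stopifnot(methods::is(x, "ScaffoldCounts"))
    methods::validObject(x)
    cts <- SummarizedExperiment::assay(x, "counts")
    cts[cts < 2L] <- 0L
    SummarizedExperiment::assay(x, "counts") <- cts
    x
}

#' Estimate scaffold abundances
#'
#' Computes Y[g, k] = count[g, k] / (length[g] * T_k), where T_k is the
#' total cleaned read count of sample k, and the per-sample abundance
#' totals N_k = sum_g Y[g, k].  Apply [cleanCounts()] first so that counts
#' below 2 do not contribute.
#'
#' @param x a cleaned [ScaffoldCounts-class].
#' @return an [AbundanceMatrix-class].
#' @examples
#' cts <- matrix(c(10L, 20L, 40L), ncol = 1,
#'               dimnames = list(c("s1", "s2", "s3"), "petal"))
#' sc <- ScaffoldCounts(cts, c(s1 = 100, s2 = 200, s3 = 400))
#' abundance(estimateAbundance(cleanCounts(sc)))
#' @export
estimateAbundance <- function(x) {
    stopifnot(methods::is(x, "ScaffoldCounts"))
    methods::validObject(x)
    cts <- SummarizedExperiment::assay(x, "counts")
    totals <- colSums(cts)
    if (any(totals == 0))
        stop("sample(s) with zero total count, abundance undefined: ",
             paste(colnames(cts)[totals == 0], collapse = ", "))
    len <- scaffoldLengths(x)
    Y <- sweep(cts / len, 2L, totals, "/")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = Y),
        rowData = SummarizedExperiment::rowData(x),
        colData = S4Vectors::DataFrame(totalAbundance = colSums(Y),
                                       librarySize = totals,
                                       row.names = colnames(cts)))
    methods::new("AbundanceMatrix", se)
}
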