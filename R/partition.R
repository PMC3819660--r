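blastColumns <- c("query_id", "subject_id", "identity", "aln_length",
                  "mismatches", "gap_opens", "q_start", "q_end",
                  "s_start", "s_end", "evalue", "bitscore")

#' Read a tabular BLAST hit file (outfmt 6)
#'
#' Twelve tab-separated columns: query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score.  Malformed rows abort with the line
#' number.
#'
#' @param file path to the hit table.
#' @return data.frame with the standard column names.
#' @export
readBlastHits <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
        return(stats::setNames(
            data.frame(matrix(nrow = 0, ncol = 12)), blastColumns))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 12L)
    if (length(bad))
        stop("malformed hit row (expected 12 columns) at line ", bad[1],
             " of ", file)
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- blastColumns
    num <- setdiff(blastColumns, c("query_id", "subject_id"))
    df[num] <- lapply(df[num], as.numeric)
    if (anyNA(df[num]))
        stop("non-numeric value in hit table ", file)
    df
}

bestHit <- function(hits) {
    # best hit per query: lowest e-value, then highest bitscore
    if (!nrow(hits)) return(hits)
    o <- order(hits$query_id, hits$evalue, -hits$bitscore)
    hits <- hits[o, , drop = FALSE]
    hits[!duplicated(hits$query_id), , drop = FALSE]
}

passesFilter <- function(hits, lengths, maxEvalue, minIdentity, minCoverage,
                         coverageBy = c("query", "subject")) {
    coverageBy <- match.arg(coverageBy)
    if (!nrow(hits)) return(character())
    denom <- if (coverageBy == "query") lengths[hits$query_id]
             else abs(hits$s_end - hits$s_start) + 1
    cov <- hits$aln_length / denom * 100
    ok <- hits$evalue <= maxEvalue & hits$identity >= minIdentity &
        cov >= minCoverage
    unique(hits$query_id[ok])
}

#' Classify scaffolds into chloroplast, mitochondrial and nuclear sets
#'
#' A scaffold longer than \code{minLen} nt is chloroplastic when any
#' chloroplast hit passes e-value <= 1e-5, identity >= 95\% and coverage >=
#' 80\% of the scaffold length; failing that, mitochondrial when any
#' mitochondrial hit passes e-value <= 1e-5, identity >= 80\% and coverage
#' >= 50\%.  Everything else — including scaffolds at or below the length
#' gate — is nuclear by exclusion.  Chloroplast takes precedence when a
#' scaffold passes both organelle filters; such conflicts are recorded.
#'
#' @param hitsCp,hitsMt data.frames of tabular hits against the chloroplast
#'   and mitochondrial reference genomes (see [readBlastHits()]).
#' @param lengths named numeric vector of scaffold lengths (nt), covering
#'   every scaffold to classify.
#' @param minLen length gate in nt (default 200, the sequencing library
#'   length); organelle calls require length strictly greater.
#' @param maxEvalue e-value ceiling for both organelles.
#' @param cpIdentity,cpCoverage chloroplast identity/coverage thresholds (%).
#' @param mtIdentity,mtCoverage mitochondrial thresholds (%).
#' @param coverageBy denominator of coverage: scaffold ("query", default)
#'   or subject alignment span.
#' @param expression optional expression matrix (scaffolds x samples; raw
#'   cleaned counts or normalized levels) for the per-class per-sample
#'   summary.
#' @return a [PartitionResult-class].
#' @export
classifyScaffolds <- function(hitsCp, hitsMt, lengths, minLen = 200,
                              maxEvalue = 1e-5,
                              cpIdentity = 95, cpCoverage = 80,
                              mtIdentity = 80, mtCoverage = 50,
                              coverageBy = c("query", "subject"),
                              expression = NULL) {
    coverageBy <- match.arg(coverageBy)
    if (is.null(names(lengths))) stop("lengths must be named by scaffold")
    unknown <- setdiff(unique(c(hitsCp$query_id, hitsMt$query_id)),
                       names(lengths))
    if (length(unknown))
        stop("hit(s) reference unknown scaffold(s): ",
             paste(utils::head(unknown, 10), collapse = ", "))
    cpBest <- bestHit(hitsCp)
    mtBest <- bestHit(hitsMt)
    cpPass <- passesFilter(cpBest, lengths, maxEvalue, cpIdentity,
                           cpCoverage, coverageBy)
    mtPass <- passesFilter(mtBest, lengths, maxEvalue, mtIdentity,
                           mtCoverage, coverageBy)
    longEnough <- names(lengths)[lengths > minLen]
    cpPass <- intersect(cpPass, longEnough)
    mtPass <- intersect(mtPass, longEnough)
    both <- intersect(cpPass, mtPass)
    cls <- stats::setNames(rep("nucleus", length(lengths)), names(lengths))
    cls[mtPass] <- "mitochondrion"
    cls[cpPass] <- "chloroplast"
    conflicts <- if (length(both)) {
        data.frame(scaffold = both,
                   chloroplast_hit = cpBest$subject_id[
                       match(both, cpBest$query_id)],
                   mitochondrion_hit = mtBest$subject_id[
                       match(both, mtBest$query_id)],
                   assigned = "chloroplast", stringsAsFactors = FALSE)
    } else data.frame(scaffold = character(), chloroplast_hit = character(),
                      mitochondrion_hit = character(),
                      assigned = character(), stringsAsFactors = FALSE)
    summary <- summarizePartition(cls, expression)
    methods::new("PartitionResult", classification = cls, summary = summary,
                 conflicts = conflicts)
}

summarizePartition <- function(cls, expression) {
    classes <- c("chloroplast", "mitochondrion", "nucleus")
    if (is.null(expression)) {
        tab <- table(factor(cls, levels = classes))
        return(data.frame(class = classes,
                          scaffolds = as.integer(tab),
                          stringsAsFactors = FALSE))
    }
    expression <- expression[intersect(rownames(expression), names(cls)), ,
                             drop = FALSE]
    out <- do.call(rbind, lapply(classes, function(cl) {
        rows <- names(cls)[cls == cl]
        sub <- expression[intersect(rownames(expression), rows), ,
                          drop = FALSE]
        data.frame(class = cl, sample = colnames(expression),
                   scaffolds = colSums(sub > 0),
                   expression = colSums(sub),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Shared and specific expressed-scaffold sets across groups
#'
#' Counts every intersection region (as in a Venn diagram) of the per-group
#' expressed-scaffold sets and the fraction of the union expressed in all
#' groups.
#'
#' @param sets named list (>= 2 entries) of character vectors of expressed
#'   scaffold IDs per group.
#' @return list with \code{regions} (data.frame: one row per membership
#'   pattern with the group flags and the region count), \code{union},
#'   \code{sharedAll}, and \code{sharedFraction} =
#'   |in all groups| / |in any group|.
#' @examples
#' sharedSets(list(petal = c("a", "b", "c"), sepal = c("b", "c"),
#'                 leaf = c("b", "c", "d")))$sharedFraction
#' @export
sharedSets <- function(sets) {
    if (length(sets) < 2) stop("need at least 2 groups")
    if (is.null(names(sets)))
        names(sets) <- paste0("group", seq_along(sets))
    union <- unique(unlist(sets))
    if (!length(union)) stop("union of expressed sets is empty")
    member <- vapply(sets, function(s) union %in% s,
                     logical(length(union)))
    member <- matrix(member, nrow = length(union),
                     dimnames = list(union, names(sets)))
    pattern <- apply(member, 1L, paste, collapse = "")
    pats <- do.call(expand.grid, rep(list(c(TRUE, FALSE)), length(sets)))
    names(pats) <- names(sets)
    pats <- pats[rowSums(pats) > 0, , drop = FALSE]
    key <- apply(pats, 1L, paste, collapse = "")
    counts <- as.integer(table(factor(pattern, levels = key)))
    regions <- cbind(pats, count = counts)
    rownames(regions) <- NULL
    allShared <- union[rowSums(member) == length(sets)]
    list(regions = regions, union = length(union),
         sharedAll = length(allShared),
         sharedFraction = length(allShared) / length(union))
}

#' Write partition outputs
#'
#' Per-scaffold class TSV and the per-class summary TSV.
#'
#' @param part a [PartitionResult-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writePartition <- function(part, dir) {
    stopifnot(methods::is(part, "PartitionResult"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fClass <- file.path(dir, "classes.tsv")
    fSummary <- file.path(dir, "class_summary.tsv")
    utils::write.table(
        data.frame(scaffold = names(part@classification),
                   class = unname(part@classification)),
        fClass, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(part@summary, fSummary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(fClass, fSummary))
}
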