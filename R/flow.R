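#' Construct a pathway graph
#'
#' @param nodes data.frame with columns \code{node_id}, \code{label} (EC
#'   number or gene name) and optionally \code{scaffold_ids} (comma-joined
#'   scaffold IDs; empty for unmapped nodes).
#' @param edges data.frame with columns \code{from}, \code{to} and
#'   optionally \code{metabolite}.
#' @param scaffolds alternative to the \code{scaffold_ids} column: named
#'   list of scaffold ID vectors per node.
#' @return a [PathwayGraph-class].
#' @export
PathwayGraph <- function(nodes, edges = data.frame(from = character(),
                                                   to = character()),
                         scaffolds = NULL) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    if (!all(c("node_id", "label") %in% names(nodes)))
        stop("nodes need columns node_id and label")
    if (is.null(scaffolds)) {
        raw <- if ("scaffold_ids" %in% names(nodes)) nodes$scaffold_ids
               else rep("", nrow(nodes))
        raw[is.na(raw)] <- ""
        scaffolds <- lapply(strsplit(raw, ","), function(v) {
            v <- trimws(v)
            v[nzchar(v)]
        })
        names(scaffolds) <- nodes$node_id
    }
    methods::new("PathwayGraph",
                 nodes = nodes[c("node_id", "label")],
                 scaffolds = scaffolds,
                 edges = as.data.frame(edges, stringsAsFactors = FALSE))
}

#' Read a pathway topology from node/edge TSV files
#'
#' Node TSV: node_id, label, comma-joined scaffold_ids (may be blank).
#' Edge TSV: from, to, and optionally metabolite.
#'
#' @param nodeFile,edgeFile paths.
#' @return a [PathwayGraph-class].
#' @export
readPathway <- function(nodeFile, edgeFile) {
    nodes <- utils::read.delim(nodeFile, stringsAsFactors = FALSE,
                               colClasses = "character")
    edges <- utils::read.delim(edgeFile, stringsAsFactors = FALSE,
                               colClasses = "character")
    PathwayGraph(nodes, edges)
}

#' Per-node expression levels
#'
#' A node's level in a sample is the sum of the normalized levels of its
#' mapped scaffolds.  Nodes with no resolvable scaffold are flagged absent;
#' scaffold IDs missing from the matrix are reported via a message and
#' ignored.
#'
#' @param graph a [PathwayGraph-class].
#' @param normalized expression matrix (scaffolds x samples).
#' @return list: \code{levels} (nodes x samples matrix), \code{absent}
#'   (logical per node), \code{unresolved} (character of unmatched
#'   scaffold IDs).
#' @export
nodeExpression <- function(graph, normalized) {
    stopifnot(methods::is(graph, "PathwayGraph"))
    ids <- graph@nodes$node_id
    unresolved <- setdiff(unlist(graph@scaffolds), rownames(normalized))
    if (length(unresolved))
        message("unresolved scaffold mapping(s): ",
                paste(utils::head(unresolved, 10), collapse = ", "))
    levels <- t(vapply(ids, function(id) {
        sc <- intersect(graph@scaffolds[[id]], rownames(normalized))
        if (!length(sc)) return(rep(0, ncol(normalized)))
        colSums(normalized[sc, , drop = FALSE])
    }, numeric(ncol(normalized))))
    colnames(levels) <- colnames(normalized)
    absent <- vapply(ids, function(id)
        length(intersect(graph@scaffolds[[id]], rownames(normalized))) == 0L,
        logical(1))
    list(levels = levels, absent = absent, unresolved = unresolved)
}

#' Fold-change class of one node
#'
#' Aggregates the target and reference sample levels (mean by default),
#' orients the fold so it is >= 1, and assigns the arrow tier by strict
#' thresholds: fold > 100 -> 3 (triple arrow), > 10 -> 2, > 2 -> 1, else
#' 0 with direction "approx" (within 2-fold).  A zero aggregate on one side
#' with a non-zero other side gives an infinite fold and tier 3.  The
#' highest-expressing sample (over all supplied levels, first on ties) is
#' recorded.
#'
#' @param targetLevels,refLevels named numeric vectors of per-sample levels.
#' @param aggregate "mean" (default) or "max".
#' @return list: \code{target_level}, \code{ref_level}, \code{fold},
#'   \code{direction} ("target_up", "ref_up" or "approx"), \code{tier}
#'   (0-3), \code{max_sample}, \code{absent}.
#' @export
foldClass <- function(targetLevels, refLevels,
                      aggregate = c("mean", "max")) {
    aggregate <- match.arg(aggregate)
    agg <- if (aggregate == "mean") mean else max
    t0 <- agg(targetLevels)
    r0 <- agg(refLevels)
    all_ <- c(targetLevels, refLevels)
    if (all(all_ == 0))
        return(list(target_level = 0, ref_level = 0, fold = NA_real_,
                    direction = NA_character_, tier = NA_integer_,
                    max_sample = NA_character_, absent = TRUE))
    maxSample <- names(all_)[which.max(all_)]
    if (t0 == 0 || r0 == 0) {
        return(list(target_level = t0, ref_level = r0, fold = Inf,
                    direction = if (t0 > 0) "target_up" else "ref_up",
                    tier = 3L, max_sample = maxSample, absent = FALSE))
    }
    fold <- max(t0, r0) / min(t0, r0)
    tier <- if (fold > 100) 3L else if (fold > 10) 2L else if (fold > 2) 1L
            else 0L
    direction <- if (tier == 0L) "approx"
                 else if (t0 > r0) "target_up" else "ref_up"
    list(target_level = t0, ref_level = r0, fold = fold,
         direction = direction, tier = tier, max_sample = maxSample,
         absent = FALSE)
}

#' Annotate a pathway with fold classes
#'
#' Composes [nodeExpression()] and [foldClass()] over every node: each gets
#' a direction, an arrow tier, and the highest-expressing sample.
#'
#' @param graph a [PathwayGraph-class].
#' @param normalized expression matrix (scaffolds x samples).
#' @param targetSamples,refSamples disjoint non-empty sample ID sets.
#' @param aggregate group aggregation, "mean" or "max".
#' @return data.frame with one row per node: node_id, label, target_level,
#'   ref_level, fold, direction, tier, max_sample, absent.
#' @export
annotatePathway <- function(graph, normalized, targetSamples, refSamples,
                            aggregate = c("mean", "max")) {
    aggregate <- match.arg(aggregate)
    samples <- colnames(normalized)
    unknown <- setdiff(c(targetSamples, refSamples), samples)
    if (length(unknown))
        stop("unknown sample ID(s): ", paste(unknown, collapse = ", "))
    if (!length(targetSamples) || !length(refSamples))
        stop("target and reference groups must be non-empty")
    if (length(intersect(targetSamples, refSamples)))
        stop("target and reference groups must be disjoint")
    ne <- nodeExpression(graph, normalized)
    rows <- lapply(seq_len(nrow(graph@nodes)), function(i) {
        lv <- ne$levels[i, ]
        fc <- foldClass(lv[targetSamples], lv[refSamples],
                        aggregate = aggregate)
        if (ne$absent[i]) {
            fc$absent <- TRUE
            fc$direction <- NA_character_
            fc$tier <- NA_integer_
            fc$max_sample <- NA_character_
            fc$fold <- NA_real_
        }
        data.frame(node_id = graph@nodes$node_id[i],
                   label = graph@nodes$label[i],
                   target_level = fc$target_level,
                   ref_level = fc$ref_level, fold = fc$fold,
                   direction = fc$direction, tier = fc$tier,
                   max_sample = fc$max_sample, absent = fc$absent,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

tierGlyph <- function(tier, absent) {
    ifelse(absent | is.na(tier), "(absent)",
           c("≈", "↑", "↑↑",
             "↑↑↑")[tier + 1L])
}

#' Write a pathway annotation as GraphViz DOT
#'
#' Nodes carry their label, the arrow glyph for the tier, and the
#' highest-expressing sample letter; direction maps to color (target up =
#' red, reference up = green).
#'
#' @param graph a [PathwayGraph-class].
#' @param annotation output of [annotatePathway()].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeFlowDot <- function(graph, annotation, file) {
    stopifnot(methods::is(graph, "PathwayGraph"))
    col <- ifelse(is.na(annotation$direction), "gray",
                  c(target_up = "red", ref_up = "green",
                    approx = "black")[annotation$direction])
    glyph <- tierGlyph(annotation$tier, annotation$absent)
    tag <- ifelse(is.na(annotation$max_sample), "",
                  paste0(" ", annotation$max_sample))
    lines <- c("digraph pathway {",
               "  node [shape=box];",
               sprintf("  \"%s\" [label=\"%s\\n%s%s\", color=%s];",
                       annotation$node_id, annotation$label, glyph, tag,
                       col))
    if (nrow(graph@edges)) {
        elab <- if ("metabolite" %in% names(graph@edges))
            sprintf(" [label=\"%s\"]", graph@edges$metabolite)
        else ""
        lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;",
                                  graph@edges$from, graph@edges$to, elab))
    }
    writeLines(c(lines, "}"), file, useBytes = TRUE)
    invisible(file)
}

#' Write a pathway annotation as TSV
#'
#' @param annotation output of [annotatePathway()].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeFlowTable <- function(annotation, file) {
    utils::write.table(annotation, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
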