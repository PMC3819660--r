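#' Construct a simulation design
#'
#' Defaults emulate a six-organ-sample study without replicates: a shared
#' majority of transcripts, a small organ-specific minority (dropout), one
#' sample carrying asymmetric up-regulation, unequal sequencing depths, and
#' small chloroplast/mitochondrial scaffold classes with planted alignment
#' hits.
#'
#' @param nGenes number of scaffolds.
#' @param nSamples number of samples (organs/stages).
#' @param seed integer seed controlling all randomness.
#' @param librarySizes expected sequenced read totals; recycled to
#'   \code{nSamples}.
#' @param deFraction fraction of genes differentially expressed.
#' @param deFold fold applied to DE genes in \code{deSamples}.
#' @param deSamples indices of samples carrying the up-regulation.
#' @param lengthRange scaffold length range (nt).
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param dropout per-entry probability that a non-DE gene is zeroed in a
#'   sample (organ-specific absence).
#' @param organelleFractions named numeric: fractions of scaffolds planted
#'   as chloroplast and mitochondrion.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nGenes = 2000, nSamples = 6, seed = 1,
                           librarySizes = 1e6 * c(1, 0.8, 1.2, 0.9,
                                                  1.1, 0.7),
                           deFraction = 0.05, deFold = 8, deSamples = 1,
                           lengthRange = c(250, 3000), dispersion = 0.1,
                           dropout = 0.05,
                           organelleFractions = c(chloroplast = 0.05,
                                                  mitochondrion = 0.03)) {
    librarySizes <- rep_len(librarySizes, nSamples)
    methods::new("SimulationSpec", nGenes = as.integer(nGenes),
                 nSamples = as.integer(nSamples), seed = as.integer(seed),
                 librarySizes = librarySizes,
                 deFraction = deFraction, deFold = deFold,
                 deSamples = as.integer(deSamples),
                 lengthRange = as.integer(lengthRange),
                 dispersion = dispersion, dropout = dropout,
                 organelleFractions = organelleFractions)
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Simulate a full synthetic data set with ground truth
#'
#' Draws counts from a negative-binomial model: the expected count of gene
#' g in sample k is proportional to librarySize_k * p_g * length_g *
#' fold_gk, with p_g log-normal base expression and fold_gk the planted
#' up-regulation.  Emits every input the toolkit consumes — count table,
#' lengths, organelle hit tables, a toy pathway — plus analytic ground
#' truth: the true normalization factors implied by the design (the
#' expected sample-vs-reference relative-abundance ratio of a non-DE gene,
#' which is identical for all non-DE genes), the true class per scaffold,
#' the DE gene set, and the true fold tier per pathway node.
#'
#' @param spec a [SimulationSpec-class].
#' @param dir optional directory; when given, all inputs are written as TSV
#'   (reproducibly byte-identical under the same spec).
#' @return list with elements \code{counts} ([ScaffoldCounts-class]),
#'   \code{hitsCp}, \code{hitsMt} (hit data.frames), \code{pathway}
#'   ([PathwayGraph-class]), \code{truth} (list: factors, classes, deGenes,
#'   nodeTiers), and \code{files} when \code{dir} was given.
#' @export
simulateOrganData <- function(spec, dir = NULL) {
    stopifnot(methods::is(spec, "SimulationSpec"))
    methods::validObject(spec)
    withSeed(spec@seed, {
        nG <- spec@nGenes; nS <- spec@nSamples
        genes <- sprintf("scaffold%05d", seq_len(nG))
        samples <- LETTERS[seq_len(nS)]
        len <- sample(seq(spec@lengthRange[1], spec@lengthRange[2]), nG,
                      replace = TRUE)
        names(len) <- genes
        p <- stats::rlnorm(nG, meanlog = 0, sdlog = 1.2)
        p <- p / sum(p)
        nDE <- round(spec@deFraction * nG)
        deGenes <- if (nDE > 0) sample(genes, nDE) else character()
        fold <- matrix(1, nG, nS, dimnames = list(genes, samples))
        fold[deGenes, spec@deSamples] <- spec@deFold

        mu <- vapply(seq_len(nS), function(k) {
            wt <- p * len * fold[, k]
            spec@librarySizes[k] * wt / sum(wt)
        }, numeric(nG))
        dimnames(mu) <- list(genes, samples)
        cts <- if (spec@dispersion > 0)
            matrix(stats::rnbinom(nG * nS, mu = mu,
                                  size = 1 / spec@dispersion), nG, nS)
        else matrix(stats::rpois(nG * nS, lambda = mu), nG, nS)
        dimnames(cts) <- dimnames(mu)
        if (spec@dropout > 0) {
            # organ-specific absence: only non-DE entries are candidates
            drop <- matrix(stats::runif(nG * nS) < spec@dropout, nG, nS)
            drop[genes %in% deGenes, ] <- FALSE
            cts[drop] <- 0L
        }
        storage.mode(cts) <- "integer"

        truthFactors <- trueFactors(p, len, fold)

        nCp <- round(spec@organelleFractions[["chloroplast"]] * nG)
        nMt <- round(spec@organelleFractions[["mitochondrion"]] * nG)
        organellePool <- setdiff(genes[len > 200], deGenes)
        cpGenes <- if (nCp) sample(organellePool, nCp) else character()
        mtGenes <- if (nMt) sample(setdiff(organellePool, cpGenes), nMt)
                   else character()
        classes <- stats::setNames(rep("nucleus", nG), genes)
        classes[cpGenes] <- "chloroplast"
        classes[mtGenes] <- "mitochondrion"
        hitsCp <- plantHits(cpGenes, len, subject = "cp_genome",
                            identity = c(96, 99.5), coverage = c(85, 98))
        hitsMt <- plantHits(mtGenes, len, subject = "mt_genome",
                            identity = c(82, 95), coverage = c(55, 90))
        # decoys strictly outside the thresholds stay nuclear
        decoyPool <- setdiff(genes[len > 200], c(cpGenes, mtGenes, deGenes))
        decoys <- sample(decoyPool, min(10L, length(decoyPool)))
        hitsCp <- rbind(hitsCp,
                        plantHits(decoys, len, subject = "cp_genome",
                                  identity = c(85, 94), coverage = c(30, 60)))
        hitsMt <- rbind(hitsMt,
                        plantHits(decoys, len, subject = "mt_genome",
                                  identity = c(60, 75), coverage = c(20, 40)))

        pathway <- toyPathway(genes, deGenes)
        rel <- vapply(seq_len(nS), function(k) {
            v <- p * fold[, k]; v / sum(v)
        }, numeric(nG))
        dimnames(rel) <- dimnames(mu)
        expectedNorm <- sweep(rel, 2L, truthFactors, "/") * 1e6
        nodeTiers <- trueNodeTiers(pathway, expectedNorm, spec@deSamples,
                                   samples)

        counts <- ScaffoldCounts(cts, len)
        truth <- list(factors = truthFactors, classes = classes,
                      deGenes = sort(deGenes), nodeTiers = nodeTiers)
        out <- list(counts = counts, hitsCp = hitsCp, hitsMt = hitsMt,
                    pathway = pathway, truth = truth)
        if (!is.null(dir)) out$files <- writeSimulation(out, cts, len, dir)
        out
    })
}

# Expected sample-vs-reference relative-abundance ratio of a non-DE gene;
# constant over non-DE genes, hence the factor TMM estimates.
trueFactors <- function(p, len, fold) {
    nS <- ncol(fold)
    D <- vapply(seq_len(nS), function(k) sum(p * len * fold[, k]),
                numeric(1))
    C <- vapply(seq_len(nS), function(k) sum(p * fold[, k]), numeric(1))
    # noiseless abundances Y_gk = p_g fold_gk / D_k
    Y <- vapply(seq_len(nS), function(k) p * fold[, k] / D[k],
                numeric(length(p)))
    yRef <- rowMeans(Y)
    nRef <- sum(yRef)
    g0 <- which(apply(fold == 1, 1L, all))[1]
    relRef <- yRef[g0] / nRef
    factors <- vapply(seq_len(nS), function(k)
        (Y[g0, k] / (C[k] / D[k])) / relRef, numeric(1))
    stats::setNames(factors, colnames(fold))
}

plantHits <- function(queries, len, subject, identity, coverage) {
    empty <- stats::setNames(data.frame(matrix(nrow = 0, ncol = 12)),
                             blastColumns)
    if (!length(queries)) return(empty)
    n <- length(queries)
    idn <- round(stats::runif(n, identity[1], identity[2]), 1)
    cov <- stats::runif(n, coverage[1], coverage[2])
    aln <- pmax(1L, as.integer(round(cov / 100 * len[queries])))
    sstart <- sample.int(100000L, n)
    data.frame(query_id = queries, subject_id = subject, identity = idn,
               aln_length = aln, mismatches = as.integer(
                   round(aln * (100 - idn) / 100)),
               gap_opens = 0L, q_start = 1L, q_end = aln,
               s_start = sstart, s_end = sstart + aln - 1L,
               evalue = 10^(-stats::runif(n, 20, 100)),
               bitscore = round(aln * 1.8), stringsAsFactors = FALSE)
}

toyPathway <- function(genes, deGenes, nNodes = 5) {
    nonDE <- setdiff(genes, deGenes)
    picks <- lapply(seq_len(nNodes), function(i) {
        if (i %% 2 == 0 && length(deGenes))
            sample(deGenes, min(2L, length(deGenes)))
        else sample(nonDE, 2L)
    })
    ids <- sprintf("n%02d", seq_len(nNodes))
    nodes <- data.frame(node_id = ids,
                        label = sprintf("EC 1.1.1.%d", seq_len(nNodes)),
                        stringsAsFactors = FALSE)
    edges <- data.frame(from = ids[-nNodes], to = ids[-1],
                        metabolite = sprintf("m%02d", seq_len(nNodes - 1)),
                        stringsAsFactors = FALSE)
    PathwayGraph(nodes, edges,
                 scaffolds = stats::setNames(picks, ids))
}

trueNodeTiers <- function(pathway, expectedNorm, deSamples, samples) {
    target <- samples[deSamples]
    ref <- setdiff(samples, target)
    ann <- annotatePathway(pathway, expectedNorm, target, ref)
    stats::setNames(ann$tier, ann$node_id)
}

writeSimulation <- function(sim, cts, len, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(counts = file.path(dir, "counts.tsv"),
               lengths = file.path(dir, "lengths.tsv"),
               hitsCp = file.path(dir, "hits_chloroplast.tsv"),
               hitsMt = file.path(dir, "hits_mitochondrion.tsv"),
               nodes = file.path(dir, "pathway_nodes.tsv"),
               edges = file.path(dir, "pathway_edges.tsv"),
               truth = file.path(dir, "truth.json"))
    utils::write.table(data.frame(scaffold = rownames(cts), cts,
                                  check.names = FALSE),
                       paths["counts"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(names(len), unname(len)),
                       paths["lengths"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeHits <- function(h, path)
        utils::write.table(h, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    writeHits(sim$hitsCp, paths["hitsCp"])
    writeHits(sim$hitsMt, paths["hitsMt"])
    nodes <- sim$pathway@nodes
    nodes$scaffold_ids <- vapply(sim$pathway@scaffolds[nodes$node_id],
                                 paste, character(1), collapse = ",")
    utils::write.table(nodes, paths["nodes"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sim$pathway@edges, paths["edges"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(factors = as.list(sim$truth$factors),
             deGenes = sim$truth$deGenes,
             classes = as.list(sim$truth$classes),
             nodeTiers = as.list(sim$truth$nodeTiers)),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    paths
}
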