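#' Pearson correlation over the commonly expressed genes
#'
#' Restricts two expression vectors to the genes non-zero in both, computes
#' the sample Pearson coefficient, and tests it either with the exact
#' t-statistic t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 df, or — for
#' very large n — the Fisher z-statistic z = atanh(r) * sqrt(n - 3) against
#' the standard normal.  Two-sided.
#'
#' @param x,y numeric vectors of equal length (expression levels over the
#'   same genes).
#' @param test "t" or "z".
#' @return list: \code{n} (common non-zero genes), \code{r},
#'   \code{statistic}, \code{p}, \code{test}.
#' @examples
#' correlateCommon(1:10, (1:10) * 2 + rnorm(10, sd = 0.1))
#' @export
correlateCommon <- function(x, y, test = c("t", "z")) {
    test <- match.arg(test)
    if (length(x) != length(y)) stop("vectors must have equal length")
    keep <- x != 0 & y != 0 & !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3) stop("fewer than 3 commonly expressed genes")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: zero variance in a vector")
    r <- stats::cor(x, y)
    if (test == "t") {
        stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
        p <- 2 * stats::pt(-abs(stat), df = n - 2)
    } else {
        if (n < 4) stop("z-test needs n >= 4")
        stat <- atanh(r) * sqrt(n - 3)
        p <- 2 * stats::pnorm(-abs(stat))
    }
    list(n = n, r = r, statistic = stat, p = min(p, 1), test = test)
}

#' One-sample Wilcoxon signed-rank test against a fixed value
#'
#' Tests whether a small sample is centered at \code{mu0}.  Zero
#' differences are dropped; the exact signed-rank distribution is used for
#' n <= 25 non-zero differences (absent ties) and the normal approximation
#' with continuity correction above.
#'
#' @param x numeric sample.
#' @param mu0 the hypothesized center.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list: \code{statistic} (V, sum of positive ranks), \code{p},
#'   \code{n} (non-zero differences), \code{exact}.
#' @export
wilcoxonRank <- function(x, mu0,
                         alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    d <- x[!is.na(x)] - mu0
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) stop("all differences are zero")
    if (n < 5) stop("need at least 5 non-zero differences, got ", n)
    exact <- n <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
        stats::wilcox.test(d, mu = 0, alternative = alternative,
                           exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
         exact = exact)
}

#' Correlation-based agglomerative clustering of expression profiles
#'
#' Rows (genes, or samples when \code{axis = "samples"}) are scaled by
#' their maximum (maxtf), pairwise similarity is the Pearson correlation,
#' distance is 1 - r, and trees are built by average linkage (UPGMA) —
#' deterministic for a given input order.
#'
#' @param mat normalized expression matrix (genes x samples).
#' @param axis cluster "genes" (rows) or "samples" (columns).
#' @return a [ClusterTree-class].
#' @export
clusterExpression <- function(mat, axis = c("genes", "samples")) {
    axis <- match.arg(axis)
    m <- if (axis == "samples") t(mat) else mat
    if (nrow(m) < 2) stop("need at least 2 ", axis)
    if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
    rowMax <- apply(m, 1L, max)
    if (any(rowMax <= 0))
        stop("all-zero row(s): ",
             paste(rownames(m)[rowMax <= 0], collapse = ", "))
    scaled <- m / rowMax
    sds <- apply(scaled, 1L, stats::sd)
    if (any(sds == 0))
        stop("constant row(s), correlation undefined: ",
             paste(rownames(m)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(scaled)))
    tree <- stats::hclust(d, method = "average")
    methods::new("ClusterTree", tree = tree, axis = axis, scaling = "maxtf")
}

#' Export a cluster tree as Newick
#'
#' Merge heights become branch lengths via \pkg{ape}.
#'
#' @param ct a [ClusterTree-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeNewick <- function(ct, file) {
    stopifnot(methods::is(ct, "ClusterTree"))
    phy <- ape::as.phylo(ct@tree)
    ape::write.tree(phy, file = file)
    invisible(file)
}
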