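#' Spearman rank correlation
#'
#' Midrank ties, two-sided p-value (asymptotic t approximation).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearmanAssoc <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need at least 3 observations")
    if (length(unique(x)) == 1 || length(unique(y)) == 1)
        stop("correlation undefined for a constant vector")
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Two-group Mann-Whitney comparison
#'
#' Two-sided. The exact null distribution is used when the smaller group has
#' at most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. Group
#' medians are reported alongside.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list of class \code{GroupComparison}: \code{n1}, \code{n2},
#'   \code{median1}, \code{median2}, \code{u_statistic}, \code{p_value}.
#' @export
mannWhitneyCompare <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
    hasTies <- anyDuplicated(c(a, b)) > 0
    useExact <- min(length(a), length(b)) <= 8 && !hasTies
    wt <- suppressWarnings(wilcox.test(a, b, exact = useExact,
                                       correct = !useExact))
    out <- list(n1 = length(a), n2 = length(b),
                median1 = median(a), median2 = median(b),
                u_statistic = unname(wt$statistic), p_value = wt$p.value)
    class(out) <- "GroupComparison"
    out
}

#' @export
print.GroupComparison <- function(x, ...) {
    cat(sprintf(
        "GroupComparison: n=(%d, %d), medians=(%.4g, %.4g), U=%.4g, p=%.4g\n",
        x$n1, x$n2, x$median1, x$median2, x$u_statistic, x$p_value))
    invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p by the hypergeometric distribution; the conditional
#' maximum-likelihood odds ratio is reported. A table with a zero margin
#' carries no information: p = 1 and the odds ratio is flagged undefined.
#'
#' @param tbl 2x2 matrix of non-negative integer counts.
#' @return list: \code{table}, \code{odds_ratio} (NA when undefined),
#'   \code{p_value}, \code{odds_defined}.
#' @export
fisherEnrichment <- function(tbl) {
    tbl <- as.matrix(tbl)
    if (!all(dim(tbl) == c(2, 2)) || any(tbl < 0) || any(tbl != round(tbl)))
        stop("need a 2x2 table of non-negative integer counts")
    storage.mode(tbl) <- "integer"
    if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
        return(list(table = tbl, odds_ratio = NA_real_, p_value = 1,
                    odds_defined = FALSE))
    ft <- fisher.test(tbl)
    list(table = tbl, odds_ratio = unname(ft$estimate),
         p_value = ft$p.value, odds_defined = TRUE)
}

#' Aggregate a long-format expression table into per-protein profiles
#'
#' Level is the median FPKM across tissues; breadth is the number of
#' tissues with nonzero FPKM.
#'
#' @param expr data.frame with columns \code{protein}, \code{tissue},
#'   \code{fpkm}.
#' @return data.frame: \code{protein}, \code{level}, \code{breadth}.
#' @export
expressionProfiles <- function(expr) {
    fp <- as.numeric(expr$fpkm)
    sp <- split(fp, expr$protein)
    prot <- names(sp)
    data.frame(protein = prot,
               level = vapply(sp, median, numeric(1)),
               breadth = vapply(sp, function(v) sum(v > 0), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression-matched subgroup via K-means
#'
#' Clusters the proteins of the two compared groups on log10(level + 1) and
#' selects, among the clusters whose within-cluster expression comparison
#' is non-significant (p > 0.05), the one maximizing the smaller group
#' count — an expression-matched stratum in which the dN contrast can be
#' re-tested free of the expression confound. Deterministic given the seed.
#'
#' @param groups named character vector: protein ID -> group label (exactly
#'   two labels).
#' @param expr expression profiles (from \code{\link{expressionProfiles}});
#'   every protein in \code{groups} must have a level.
#' @param dn dN table with columns \code{protein}, \code{dn}.
#' @param k number of clusters (>= 2), default 3.
#' @param seed RNG seed for the K-means initialisation.
#' @return list: \code{matched} (logical), \code{cluster} (selected cluster
#'   ID or NA), \code{proteins}, \code{expr_comparison},
#'   \code{dn_comparison} (GroupComparison or NULL), \code{cluster_sizes}.
#' @export
kmeansExpressionMatch <- function(groups, expr, dn, k = 3, seed = 1) {
    if (k < 2) stop("k must be at least 2")
    labs <- sort(unique(unname(groups)))
    if (length(labs) != 2) stop("groups must contain exactly two labels")
    prot <- names(groups)
    lev <- expr$level[match(prot, expr$protein)]
    if (anyNA(lev)) stop("missing expression level for some proteins")
    x <- log10(lev + 1)
    km <- withSeed(seed, kmeans(x, centers = k, nstart = 10))
    noMatch <- list(matched = FALSE, cluster = NA_integer_,
                    proteins = character(0), expr_comparison = NULL,
                    dn_comparison = NULL,
                    cluster_sizes = as.integer(km$size))
    best <- NULL; bestMin <- -1
    for (cl in seq_len(k)) {
        in_cl <- km$cluster == cl
        g1 <- prot[in_cl & groups == labs[1]]
        g2 <- prot[in_cl & groups == labs[2]]
        if (length(g1) < 2 || length(g2) < 2) next
        ec <- mannWhitneyCompare(lev[match(g1, prot)], lev[match(g2, prot)])
        if (ec$p_value > 0.05 && min(length(g1), length(g2)) > bestMin) {
            bestMin <- min(length(g1), length(g2))
            best <- list(cluster = cl, g1 = g1, g2 = g2, ec = ec)
        }
    }
    if (is.null(best)) return(noMatch)
    dnv <- dn$dn[match(c(best$g1, best$g2), dn$protein)]
    d1 <- dn$dn[match(best$g1, dn$protein)]
    d2 <- dn$dn[match(best$g2, dn$protein)]
    dc <- if (sum(!is.na(d1)) >= 2 && sum(!is.na(d2)) >= 2)
        mannWhitneyCompare(d1[!is.na(d1)], d2[!is.na(d2)]) else NULL
    list(matched = TRUE, cluster = best$cluster,
         proteins = c(best$g1, best$g2),
         expr_comparison = best$ec, dn_comparison = dc,
         cluster_sizes = as.integer(km$size))
}

#' Read an essential-gene list (one ID per line)
#'
#' @param path text file.
#' @return character vector of IDs.
#' @export
readEssentialGenes <- function(path) {
    x <- readLines(path)
    x <- trimws(x)
    x[x != "" & !startsWith(x, "#")]
}

#' Read a long-format expression table
#'
#' @param path TSV with columns \code{protein}, \code{tissue}, \code{fpkm}.
#' @return data.frame.
#' @export
readExpression <- function(path) {
    df <- readTsv(path, header = TRUE)
    df$fpkm <- as.numeric(df$fpkm)
    df
}

#' Read a protein domain interval table
#'
#' @param path TSV with columns \code{protein}, \code{start_aa},
#'   \code{end_aa} (1-based inclusive amino-acid coordinates).
#' @return data.frame.
#' @export
readDomains <- function(path) {
    df <- readTsv(path, header = TRUE)
    df$start_aa <- as.integer(df$start_aa)
    df$end_aa <- as.integer(df$end_aa)
    df
}
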