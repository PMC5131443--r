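#' Merge ID-mapped interaction records into one undirected simple network
#'
#' (A,B) and (B,A) collapse to a single edge, duplicates across sources are
#' removed, self-pairs are dropped. The node set is the set of endpoints of
#' the retained edges. Rebuilding from the resulting edge list is a no-op
#' (idempotent).
#'
#' @param records data.frame with columns \code{interactor_a},
#'   \code{interactor_b} (already ID-mapped). An empty record set yields an
#'   empty network.
#' @return a \linkS4class{PPINetwork}.
#' @export
buildNetwork <- function(records) {
    if (NROW(records) == 0) return(PPINetwork())
    PPINetwork(cbind(records$interactor_a, records$interactor_b))
}

#' Node degree
#'
#' @param net a \linkS4class{PPINetwork}.
#' @return named integer vector over all nodes (isolated nodes have 0);
#'   the degrees sum to twice the edge count.
#' @export
nodeDegree <- function(net) {
    n <- networkNodes(net)
    e <- networkEdges(net)
    idx <- c(match(e[, 1], n), match(e[, 2], n))
    deg <- tabulate(idx, nbins = length(n))
    names(deg) <- n
    deg
}

# adjacency in 0-based CSR form for the C++ kernel
.csrAdjacency <- function(net) {
    n <- networkNodes(net)
    e <- networkEdges(net)
    nv <- length(n)
    if (nrow(e) == 0)
        return(list(n = nv, adj = integer(0), ptr = integer(nv + 1)))
    i <- match(e[, 1], n)
    j <- match(e[, 2], n)
    from <- c(i, j); to <- c(j, i)
    o <- order(from, to)
    from <- from[o]; to <- to[o]
    ptr <- c(0L, cumsum(tabulate(from, nbins = nv)))
    list(n = nv, adj = as.integer(to - 1L), ptr = as.integer(ptr))
}

#' Betweenness centrality (Brandes accumulation)
#'
#' For each node v, the sum over unordered pairs (s,t), s != t != v, of the
#' fraction of shortest s-t paths passing through v. Undirected,
#' unnormalized, endpoints excluded; pairs in different components
#' contribute zero. Computed by Brandes' O(V·E) dependency accumulation in
#' compiled code.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @return named numeric vector over all nodes.
#' @export
nodeBetweenness <- function(net) {
    csr <- .csrAdjacency(net)
    bc <- brandes_betweenness(csr$n, csr$adj, csr$ptr)
    names(bc) <- networkNodes(net)
    bc
}

#' Degree and betweenness for every node
#'
#' @param net a \linkS4class{PPINetwork}.
#' @return data.frame with columns \code{protein}, \code{degree},
#'   \code{betweenness}.
#' @export
nodeMetrics <- function(net) {
    deg <- nodeDegree(net)
    btw <- nodeBetweenness(net)
    data.frame(protein = networkNodes(net), degree = unname(deg),
               betweenness = unname(btw), stringsAsFactors = FALSE)
}

#' Fit a power law to the degree distribution
#'
#' p(k), the fraction of nodes with degree k (k >= 1), is regressed on k on
#' log10-log10 axes by ordinary least squares over the degrees with p(k) >
#' 0. Raw (unbinned) frequencies are used. Requires at least three distinct
#' positive degree values.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @return list with \code{exponent} (slope, expected negative),
#'   \code{r_squared}, \code{points_used}.
#' @export
fitDegreePowerlaw <- function(net) {
    fitPowerlawFromDegrees(nodeDegree(net))
}

#' @rdname fitDegreePowerlaw
#' @param degrees integer vector of node degrees (the degree multiset).
#' @export
fitPowerlawFromDegrees <- function(degrees) {
    n <- length(degrees)
    if (n == 0) stop("empty degree vector")
    tab <- table(degrees[degrees >= 1])
    k <- as.numeric(names(tab))
    pk <- as.numeric(tab) / n
    if (length(k) < 3)
        stop("degree distribution has fewer than 3 distinct positive values")
    fit <- lm(log10(pk) ~ log10(k))
    # summary.lm warns on an essentially perfect fit; that case is valid here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    list(exponent = unname(coef(fit)[2]),
         r_squared = r2,
         points_used = length(k))
}

#' Induced subgraph on a node subset
#'
#' Keeps the edges with both endpoints in \code{keep}; the node set becomes
#' exactly \code{keep} (nodes that lose all edges remain as isolated nodes).
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param keep character vector of node IDs.
#' @return a \linkS4class{PPINetwork}.
#' @export
inducedSubgraph <- function(net, keep) {
    e <- networkEdges(net)
    sel <- e[, 1] %in% keep & e[, 2] %in% keep
    PPINetwork(e[sel, , drop = FALSE], nodes = keep)
}

# Subgraph from an edge subset (row indices into the canonical edge matrix);
# nodes that lose all their edges are removed.
.edgeSubgraph <- function(net, edgeIdx) {
    e <- networkEdges(net)[edgeIdx, , drop = FALSE]
    PPINetwork(e)
}
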