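#' Partition proteins into hub/bottleneck topological classes
#'
#' Hubs are the \code{floor(qHub * N)} nodes of highest degree (ties broken
#' by higher betweenness, then lexicographic protein ID); bottlenecks are
#' the \code{floor(qBottleneck * N)} nodes of highest betweenness (ties by
#' degree, then ID). Every protein receives exactly one of HB (hub and
#' bottleneck), HNB (hub only), NHB (bottleneck only), NHNB (neither). The
#' deterministic tie-break makes set sizes exact, which the permutation and
#' subsampling machinery relies on.
#'
#' @param metrics data.frame with columns \code{protein}, \code{degree},
#'   \code{betweenness} (as from \code{\link{nodeMetrics}}).
#' @param qHub,qBottleneck quantile cut-offs in (0, 0.5]; default 0.20, the
#'   "top 20 percent" convention.
#' @return a \linkS4class{ClassificationResult}.
#' @export
classifyNodes <- function(metrics, qHub = 0.2, qBottleneck = 0.2) {
    if (!(qHub > 0 && qHub <= 0.5) || !(qBottleneck > 0 && qBottleneck <= 0.5))
        stop("quantile cut-offs must lie in (0, 0.5]")
    N <- nrow(metrics)
    if (N < 2) stop("need at least 2 proteins to classify")
    nHub <- floor(qHub * N)
    nBot <- floor(qBottleneck * N)
    oH <- idOrder(-metrics$degree, -metrics$betweenness, metrics$protein)
    oB <- idOrder(-metrics$betweenness, -metrics$degree, metrics$protein)
    hubs <- metrics$protein[oH][seq_len(nHub)]
    bots <- metrics$protein[oB][seq_len(nBot)]
    isH <- metrics$protein %in% hubs
    isB <- metrics$protein %in% bots
    cls <- ifelse(isH & isB, "HB",
           ifelse(isH, "HNB", ifelse(isB, "NHB", "NHNB")))
    names(cls) <- metrics$protein
    methods::new("ClassificationResult", assignments = cls, qHub = qHub,
                 qBottleneck = qBottleneck, hubSet = hubs,
                 bottleneckSet = bots)
}

#' Class counts of a four-way partition
#'
#' @param result a \linkS4class{ClassificationResult}.
#' @return named integer vector (HB, HNB, NHB, NHNB) summing to N.
#' @export
classCounts <- function(result) {
    tab <- table(factor(classAssignments(result), levels = .TOPO_CLASSES))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
}

#' Sweep the hub/bottleneck cut-off and redo the HNB-vs-NHB comparison
#'
#' One row per cut-off q: classify at (q, q), compare dN of
#' hub-non-bottlenecks against non-hub-bottlenecks by the two-sided
#' Mann-Whitney test. A q that yields an empty HNB or NHB set gives a row
#' flagged undefined rather than an error.
#'
#' @param metrics node metrics data.frame.
#' @param dn dN table with columns \code{protein}, \code{dn} (as from
#'   \code{\link{computeDn}}).
#' @param qValues cut-off fractions, each in (0, 0.5]; default 5 to 40
#'   percent in 5-percent steps.
#' @return data.frame: \code{q}, \code{n_hnb}, \code{n_nhb},
#'   \code{median_hnb}, \code{median_nhb}, \code{p}, \code{undefined}.
#' @export
cutoffSweep <- function(metrics, dn, qValues = seq(0.05, 0.40, by = 0.05)) {
    if (length(qValues) == 0) stop("qValues must be non-empty")
    if (any(qValues <= 0 | qValues > 0.5))
        stop("every q must lie in (0, 0.5]")
    dnv <- dn$dn[match(metrics$protein, dn$protein)]
    rows <- lapply(qValues, function(q) {
        cl <- classifyNodes(metrics, q, q)
        a <- dnv[classAssignments(cl)[metrics$protein] == "HNB"]
        b <- dnv[classAssignments(cl)[metrics$protein] == "NHB"]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) == 0 || length(b) == 0) {
            data.frame(q = q, n_hnb = length(a), n_nhb = length(b),
                       median_hnb = NA_real_, median_nhb = NA_real_,
                       p = NA_real_, undefined = TRUE)
        } else {
            cmp <- mannWhitneyCompare(a, b)
            data.frame(q = q, n_hnb = length(a), n_nhb = length(b),
                       median_hnb = cmp$median1, median_nhb = cmp$median2,
                       p = cmp$p_value, undefined = FALSE)
        }
    })
    do.call(rbind, rows)
}
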