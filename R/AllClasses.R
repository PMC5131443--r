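#' PPINetwork: an undirected simple protein-protein interaction network
#'
#' Nodes are protein (transcript) IDs; edges are unordered ID pairs stored in
#' canonical form (smaller endpoint first, rows sorted). Self-loops and
#' duplicate edges are disallowed by the validity method. Isolated nodes are
#' permitted: the node set may be a superset of the edge endpoints.
#'
#' @slot nodes character vector of unique protein IDs.
#' @slot edges two-column character matrix of canonical edges.
#' @export
setClass("PPINetwork",
         representation(nodes = "character", edges = "matrix"))

setValidity("PPINetwork", function(object) {
    e <- object@edges
    msgs <- character(0)
    if (ncol(e) != 2 && !(nrow(e) == 0))
        msgs <- c(msgs, "edges must have two columns")
    if (nrow(e) > 0) {
        if (any(e[, 1] == e[, 2])) msgs <- c(msgs, "self-loops present")
        key <- paste(e[, 1], e[, 2], sep = "\r")
        if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edges present")
        if (!all(c(e) %in% object@nodes))
            msgs <- c(msgs, "edge endpoint missing from node set")
        if (any(e[, 1] > e[, 2]))
            msgs <- c(msgs, "edges not in canonical (sorted-endpoint) form")
    }
    if (anyDuplicated(object@nodes)) msgs <- c(msgs, "duplicate node IDs")
    if (length(msgs)) msgs else TRUE
})

#' Construct a PPINetwork from an edge table
#'
#' Edges are canonicalised (unordered), duplicates collapsed, self-pairs
#' removed. The node set defaults to the endpoints of the retained edges;
#' extra (isolated) nodes may be supplied.
#'
#' @param edges two-column character matrix or data.frame of endpoint pairs.
#' @param nodes optional character vector of node IDs to include even if
#'   edgeless.
#' @return a \linkS4class{PPINetwork}.
#' @export
PPINetwork <- function(edges = NULL, nodes = NULL) {
    if (is.null(edges) || NROW(edges) == 0) {
        e <- matrix(character(0), ncol = 2)
    } else {
        e <- as.matrix(edges)[, 1:2, drop = FALSE]
        mode(e) <- "character"
        a <- pmin(e[, 1], e[, 2])
        b <- pmax(e[, 1], e[, 2])
        keep <- a != b
        a <- a[keep]; b <- b[keep]
        key <- paste(a, b, sep = "\r")
        dup <- duplicated(key)
        a <- a[!dup]; b <- b[!dup]
        o <- idOrder(a, b)
        e <- cbind(a[o], b[o])
    }
    n <- unique(c(e[, 1], e[, 2], as.character(nodes %||% character(0))))
    n <- n[idOrder(n)]
    colnames(e) <- c("a", "b")
    methods::new("PPINetwork", nodes = n, edges = e)
}

#' @describeIn PPINetwork node IDs
#' @param net a PPINetwork.
#' @export
networkNodes <- function(net) net@nodes

#' @describeIn PPINetwork canonical edge matrix
#' @export
networkEdges <- function(net) net@edges

#' @describeIn PPINetwork number of nodes
#' @export
numNodes <- function(net) length(net@nodes)

#' @describeIn PPINetwork number of edges
#' @export
numEdges <- function(net) nrow(net@edges)

setMethod("show", "PPINetwork", function(object) {
    cat("PPINetwork with", numNodes(object), "nodes and",
        numEdges(object), "edges\n")
})

.TOPO_CLASSES <- c("HB", "HNB", "NHB", "NHNB")

#' ClassificationResult: the four-way hub/bottleneck partition
#'
#' @slot assignments named character vector, protein ID -> one of
#'   HB, HNB, NHB, NHNB.
#' @slot qHub,qBottleneck the quantile cut-offs used.
#' @slot hubSet,bottleneckSet the selected top sets.
#' @export
setClass("ClassificationResult",
         representation(assignments = "character", qHub = "numeric",
                        qBottleneck = "numeric", hubSet = "character",
                        bottleneckSet = "character"))

setValidity("ClassificationResult", function(object) {
    msgs <- character(0)
    if (!all(object@assignments %in% .TOPO_CLASSES))
        msgs <- c(msgs, "unknown topological class label")
    if (is.null(names(object@assignments)))
        msgs <- c(msgs, "assignments must be named by protein ID")
    hb <- intersect(object@hubSet, object@bottleneckSet)
    if (!setequal(names(object@assignments)[object@assignments == "HB"], hb))
        msgs <- c(msgs, "HB class does not equal hubSet ∩ bottleneckSet")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "ClassificationResult", function(object) {
    cts <- classCounts(object)
    cat(sprintf(
        "ClassificationResult (qHub=%.2f, qBottleneck=%.2f): %s\n",
        object@qHub, object@qBottleneck,
        paste(names(cts), cts, sep = "=", collapse = " ")))
})

#' @describeIn ClassificationResult named class vector
#' @param x a ClassificationResult.
#' @export
classAssignments <- function(x) x@assignments

#' @describeIn ClassificationResult proteins of one class
#' @param cls class label (HB, HNB, NHB or NHNB).
#' @export
proteinsOfClass <- function(x, cls) {
    cls <- match.arg(cls, .TOPO_CLASSES)
    names(x@assignments)[x@assignments == cls]
}

#' @describeIn ClassificationResult hub protein IDs
#' @export
hubSet <- function(x) x@hubSet

#' @describeIn ClassificationResult bottleneck protein IDs
#' @export
bottleneckSet <- function(x) x@bottleneckSet

#' PermutationTestResult: observed statistic vs an empirical null
#'
#' @slot observed observed statistic.
#' @slot nullValues the null replicate statistics.
#' @slot pValue literal estimator: fraction of null values strictly below
#'   the observed value.
#' @slot pSmoothed the (r+1)/(n+1) add-one estimator.
#' @slot nReplicates number of replicates.
#' @slot seed master seed.
#' @slot nResampled number of degenerate replicates that were redrawn.
#' @export
setClass("PermutationTestResult",
         representation(observed = "numeric", nullValues = "numeric",
                        pValue = "numeric", pSmoothed = "numeric",
                        nReplicates = "integer", seed = "integer",
                        nResampled = "integer"))

setValidity("PermutationTestResult", function(object) {
    msgs <- character(0)
    if (length(object@nullValues) != object@nReplicates)
        msgs <- c(msgs, "length(nullValues) != nReplicates")
    if (object@pValue < 0 || object@pValue > 1)
        msgs <- c(msgs, "pValue outside [0,1]")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "PermutationTestResult", function(object) {
    cat(sprintf(
        "PermutationTestResult: observed=%.4g, p=%.4g (smoothed %.4g), %d replicates\n",
        object@observed, object@pValue, object@pSmoothed, object@nReplicates))
})

#' @describeIn PermutationTestResult literal empirical p-value
#' @param x a PermutationTestResult.
#' @export
pValue <- function(x) x@pValue

#' @describeIn PermutationTestResult observed statistic
#' @export
observedStat <- function(x) x@observed

#' @describeIn PermutationTestResult null replicate values
#' @export
nullValues <- function(x) x@nullValues

#' SubsampleSummary: robustness of the HNB-vs-NHB contrast under subsampling
#'
#' @slot mode "nodes" or "edges".
#' @slot fraction subsampling fraction.
#' @slot nReps number of replicates.
#' @slot repRecords per-replicate data.frame (median1, median2, p, sign,
#'   defined).
#' @slot fullSign sign of the full-network median difference.
#' @slot signConsistency fraction of defined replicates preserving fullSign.
#' @slot seed master seed.
#' @export
setClass("SubsampleSummary",
         representation(mode = "character", fraction = "numeric",
                        nReps = "integer", repRecords = "data.frame",
                        fullSign = "numeric", signConsistency = "numeric",
                        seed = "integer"))

setValidity("SubsampleSummary", function(object) {
    msgs <- character(0)
    if (!object@mode %in% c("nodes", "edges"))
        msgs <- c(msgs, "mode must be 'nodes' or 'edges'")
    if (nrow(object@repRecords) != object@nReps)
        msgs <- c(msgs, "nReps != nrow(repRecords)")
    if (!is.na(object@signConsistency) &&
        (object@signConsistency < 0 || object@signConsistency > 1))
        msgs <- c(msgs, "signConsistency outside [0,1]")
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "SubsampleSummary", function(object) {
    cat(sprintf(
        "SubsampleSummary: %s mode, fraction=%.2f, %d reps, sign consistency %.3f\n",
        object@mode, object@fraction, object@nReps, object@signConsistency))
})

#' @describeIn SubsampleSummary fraction of replicates preserving the
#'   full-network sign
#' @param x a SubsampleSummary.
#' @export
signConsistency <- function(x) x@signConsistency

#' @describeIn SubsampleSummary per-replicate records
#' @export
repRecords <- function(x) x@repRecords
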