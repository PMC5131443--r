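# Per-protein counts of non-synonymous SNPs inside/outside domain
# intervals; set-level fractions are then two sums, which keeps the
# 10,000-replicate randomization cheap.
.domainSnpCounts <- function(domains, consequences) {
    ns <- consequences[consequences$kind == "nonsynonymous", , drop = FALSE]
    if (!"aa_pos" %in% names(ns))
        ns$aa_pos <- as.integer(ceiling(as.integer(ns$cds_pos) / 3))
    prot <- unique(c(ns$protein, domains$protein))
    total <- tabulate(factor(ns$protein, levels = prot), nbins = length(prot))
    inside <- integer(length(prot))
    if (nrow(ns) > 0 && nrow(domains) > 0) {
        dsp <- split(domains, domains$protein)
        vsp <- split(ns$aa_pos, factor(ns$protein, levels = prot))
        for (i in seq_along(prot)) {
            d <- dsp[[prot[i]]]
            if (is.null(d) || length(vsp[[i]]) == 0) next
            pos <- vsp[[i]]
            hit <- rep(FALSE, length(pos))
            for (j in seq_len(nrow(d)))
                hit <- hit | (pos >= d$start_aa[j] & pos <= d$end_aa[j])
            inside[i] <- sum(hit)
        }
    }
    data.frame(protein = prot, n_nonsyn = total, n_in_domain = inside,
               stringsAsFactors = FALSE)
}

#' Fraction of non-synonymous SNPs falling inside protein domains
#'
#' Among the non-synonymous SNPs of the given proteins, the fraction whose
#' encoded amino-acid position (\code{ceiling(cds_pos / 3)}) lies inside any
#' domain interval of that protein. Intervals are 1-based inclusive
#' amino-acid coordinates.
#'
#' @param proteins character vector of protein IDs (non-empty).
#' @param domains data.frame with columns \code{protein}, \code{start_aa},
#'   \code{end_aa}.
#' @param consequences annotated variants (from
#'   \code{\link{annotateVariants}}), with \code{kind} and \code{cds_pos}.
#' @return a single fraction in [0, 1].
#' @export
domainSnpFraction <- function(proteins, domains, consequences) {
    if (length(proteins) == 0) stop("proteins must be non-empty")
    cnt <- .domainSnpCounts(domains, consequences)
    sel <- cnt$protein %in% proteins
    tot <- sum(cnt$n_nonsyn[sel])
    if (tot == 0)
        stop("no non-synonymous SNPs in the given protein set; fraction undefined")
    sum(cnt$n_in_domain[sel]) / tot
}

#' Randomization test for domain depletion of non-synonymous SNPs
#'
#' The observed statistic is the domain SNP fraction of the target set.
#' Each replicate draws |target| proteins from the universe without
#' replacement and recomputes the fraction. The literal p estimator is the
#' proportion of replicates with a value strictly lower than the observed
#' one (small p: the target carries unusually few domain SNPs); the add-one
#' smoothed estimator (r+1)/(n+1) is reported alongside because the literal
#' one can return 0. Replicates whose sampled set has no non-synonymous
#' SNPs are redrawn (at most 100 attempts each) and counted. Per-replicate
#' RNG substreams are derived from the master seed by counter, so extending
#' the replicate count preserves earlier null values.
#'
#' @param target protein IDs of the tested set (subset of universe).
#' @param universe protein IDs to sample from.
#' @param domains domain interval table.
#' @param consequences annotated variants.
#' @param nReplicates number of null replicates (default 10000).
#' @param seed master seed.
#' @return a \linkS4class{PermutationTestResult}.
#' @export
domainRandomizationTest <- function(target, universe, domains, consequences,
                                    nReplicates = 10000, seed = 1) {
    K <- length(target)
    if (K == 0 || K > length(universe)) stop("need 0 < |target| <= |universe|")
    if (!all(target %in% universe)) stop("target must be a subset of universe")
    cnt <- .domainSnpCounts(domains, consequences)
    tot <- cnt$n_nonsyn[match(universe, cnt$protein)]
    ind <- cnt$n_in_domain[match(universe, cnt$protein)]
    tot[is.na(tot)] <- 0L
    ind[is.na(ind)] <- 0L
    observed <- domainSnpFraction(target, domains, consequences)
    nullv <- numeric(nReplicates)
    nResampled <- 0L
    nU <- length(universe)
    for (r in seq_len(nReplicates)) {
        set.seed(substreamSeed(seed, r))
        for (attempt in 1:100) {
            idx <- sample.int(nU, K)
            denom <- sum(tot[idx])
            if (denom > 0) break
            nResampled <- nResampled + 1L
        }
        if (denom == 0)
            stop("replicate ", r, " degenerate after 100 resampling attempts")
        nullv[r] <- sum(ind[idx]) / denom
    }
    rLow <- sum(nullv < observed)
    methods::new("PermutationTestResult",
                 observed = observed, nullValues = nullv,
                 pValue = rLow / nReplicates,
                 pSmoothed = (rLow + 1) / (nReplicates + 1),
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed), nResampled = nResampled)
}

# sign of the HNB - NHB median dN difference for one classified network;
# returns list(defined, median1, median2, p, sign)
.hnbNhbComparison <- function(metrics, dnLookup) {
    cl <- classifyNodes(metrics)
    .hnbNhbComparisonAt(metrics, dnLookup, cl)
}

.hnbNhbComparisonAt <- function(metrics, dn, classification) {
    asg <- classAssignments(classification)
    a <- dn$dn[match(names(asg)[asg == "HNB"], dn$protein)]
    b <- dn$dn[match(names(asg)[asg == "NHB"], dn$protein)]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0)
        return(list(defined = FALSE, median1 = NA_real_, median2 = NA_real_,
                    p = NA_real_, sign = NA_real_))
    cmp <- mannWhitneyCompare(a, b)
    list(defined = TRUE, median1 = cmp$median1, median2 = cmp$median2,
         p = cmp$p_value, sign = sign(cmp$median1 - cmp$median2))
}

#' Node/edge subsampling robustness of the HNB-vs-NHB contrast
#'
#' Each replicate samples \code{floor(fraction * N)} nodes (inducing the
#' subgraph) or \code{floor(fraction * E)} edges (keeping their endpoints;
#' nodes losing all edges are removed), recomputes degree and betweenness,
#' reclassifies at the given cut-offs, and repeats the HNB-vs-NHB dN
#' comparison. The summary reports the fraction of defined replicates whose
#' median-difference sign matches the full-network sign. At
#' \code{fraction = 1} every replicate reproduces the full analysis.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param dn dN table (\code{protein}, \code{dn}).
#' @param mode "nodes" or "edges".
#' @param fraction subsampling fraction in (0, 1].
#' @param nReps number of replicates.
#' @param qHub,qBottleneck classification cut-offs.
#' @param seed master seed (per-replicate substreams by counter).
#' @return a \linkS4class{SubsampleSummary}.
#' @export
networkSubsampleRobustness <- function(net, dn, mode = c("nodes", "edges"),
                                       fraction = 0.8, nReps = 1000,
                                       qHub = 0.2, qBottleneck = 0.2,
                                       seed = 1) {
    mode <- match.arg(mode)
    if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
    if (nReps < 1) stop("nReps must be >= 1")
    fullMetrics <- nodeMetrics(net)
    fullCl <- classifyNodes(fullMetrics, qHub, qBottleneck)
    full <- .hnbNhbComparisonAt(fullMetrics, dn, fullCl)
    N <- numNodes(net); E <- numEdges(net)
    recs <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        set.seed(substreamSeed(seed, r))
        sub <- if (mode == "nodes") {
            keep <- networkNodes(net)[sample.int(N, floor(fraction * N))]
            inducedSubgraph(net, keep)
        } else {
            .edgeSubgraph(net, sample.int(E, floor(fraction * E)))
        }
        res <- if (numNodes(sub) >= 2) {
            m <- nodeMetrics(sub)
            .hnbNhbComparisonAt(m, dn, classifyNodes(m, qHub, qBottleneck))
        } else list(defined = FALSE, median1 = NA_real_, median2 = NA_real_,
                    p = NA_real_, sign = NA_real_)
        recs[[r]] <- data.frame(rep = r, defined = res$defined,
                                median1 = res$median1, median2 = res$median2,
                                p = res$p, sign = res$sign)
    }
    recs <- do.call(rbind, recs)
    defined <- recs$defined
    sc <- if (any(defined) && !is.na(full$sign))
        mean(recs$sign[defined] == full$sign) else NA_real_
    methods::new("SubsampleSummary", mode = mode, fraction = fraction,
                 nReps = as.integer(nReps), repRecords = recs,
                 fullSign = as.numeric(full$sign),
                 signConsistency = sc, seed = as.integer(seed))
}
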