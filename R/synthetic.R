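#' Scenario configuration for the synthetic-data generator
#'
#' The defaults define the standard study conditions: a modular scale-free
#' network of 2000 proteins (8 preferential-attachment modules, 3 edges per
#' new node, sparse inter-module bridges),
#' CDS lengths of 100-300 codons, hub-side classes (HB, HNB) at
#' non-synonymous density 0.008 per non-synonymous site and the
#' bottleneck/background classes (NHB, NHNB) at 0.012 — echoing the
#' magnitudes of the human analysis without claiming to reproduce it — 20
#' percent cut-offs, 30 percent domain coverage with no depletion, 15
#' tissues and a two-fold hub expression shift with an expression-matched
#' stratum.
#'
#' @param nProteins number of network nodes (>= 20).
#' @param attachmentEdges edges added per new node in the preferential
#'   attachment generator.
#' @param nModules number of scale-free modules joined by bridge edges
#'   (1 = a single preferential-attachment graph).
#' @param cdsCodonsRange (min, max) CDS length in codons.
#' @param dnByClass named per-non-synonymous-site SNP probability for HB,
#'   HNB, NHB, NHNB.
#' @param synDensity per-synonymous-site synonymous SNP probability.
#' @param domainCoverage fraction of each protein's length inside domains.
#' @param domainDepletion multiplier on the in-domain non-synonymous
#'   probability of \code{depletedClass} (1 = no depletion).
#' @param depletedClass class subject to domain depletion.
#' @param nTissues number of expression tissues.
#' @param expressionEffect multiplicative hub-side expression shift outside
#'   the matched stratum.
#' @param matchedFraction fraction of proteins placed in the
#'   expression-matched stratum.
#' @param cpgFraction target fraction of generated SNPs in CpG context
#'   (decoys for the exclusion filter).
#' @param zeroInflation probability that a tissue FPKM is zeroed.
#' @param qHub,qBottleneck cut-offs used for the generation-time class
#'   assignment.
#' @param essentialFraction fraction of proteins labelled essential.
#' @param idmapNoise fraction of source IDs made unmapped/multi-mapped in
#'   the raw files.
#' @param seed master seed.
#' @return validated config list (class \code{"ScenarioConfig"}).
#' @export
scenarioConfig <- function(nProteins = 2000, attachmentEdges = 3,
                           nModules = 8,
                           cdsCodonsRange = c(100, 300),
                           dnByClass = c(HB = 0.008, HNB = 0.008,
                                         NHB = 0.012, NHNB = 0.012),
                           synDensity = 0.01,
                           domainCoverage = 0.3, domainDepletion = 1,
                           depletedClass = "HNB",
                           nTissues = 15, expressionEffect = 2,
                           matchedFraction = 0.4, cpgFraction = 0.1,
                           zeroInflation = 0,
                           qHub = 0.2, qBottleneck = 0.2,
                           essentialFraction = 0.1, idmapNoise = 0,
                           seed = 1) {
    cfg <- list(nProteins = nProteins, attachmentEdges = attachmentEdges,
                nModules = nModules,
                cdsCodonsRange = cdsCodonsRange, dnByClass = dnByClass,
                synDensity = synDensity, domainCoverage = domainCoverage,
                domainDepletion = domainDepletion,
                depletedClass = depletedClass, nTissues = nTissues,
                expressionEffect = expressionEffect,
                matchedFraction = matchedFraction,
                cpgFraction = cpgFraction, zeroInflation = zeroInflation,
                qHub = qHub, qBottleneck = qBottleneck,
                essentialFraction = essentialFraction,
                idmapNoise = idmapNoise, seed = seed)
    bad <- character(0)
    if (nProteins < 20) bad <- c(bad, "nProteins must be >= 20")
    if (attachmentEdges < 1 || attachmentEdges >= nProteins)
        bad <- c(bad, "attachmentEdges must satisfy 1 <= m < nProteins")
    if (nModules < 1 || nProteins %/% nModules <= attachmentEdges)
        bad <- c(bad, "each module must have more than attachmentEdges nodes")
    if (length(cdsCodonsRange) != 2 || cdsCodonsRange[1] < 10 ||
        cdsCodonsRange[2] < cdsCodonsRange[1])
        bad <- c(bad, "cdsCodonsRange must be (min >= 10, max >= min)")
    if (!all(.TOPO_CLASSES %in% names(dnByClass)))
        bad <- c(bad, "dnByClass needs entries for HB, HNB, NHB, NHNB")
    if (any(dnByClass < 0 | dnByClass > 1) || synDensity < 0 || synDensity > 1)
        bad <- c(bad, "densities must lie in [0, 1]")
    if (domainCoverage <= 0 || domainCoverage >= 1)
        bad <- c(bad, "domainCoverage must lie in (0, 1)")
    if (domainDepletion < 0 || domainDepletion > 1)
        bad <- c(bad, "domainDepletion must lie in [0, 1]")
    if (!depletedClass %in% .TOPO_CLASSES)
        bad <- c(bad, "depletedClass must be a topological class")
    if (nTissues < 2) bad <- c(bad, "nTissues must be >= 2")
    if (cpgFraction < 0 || cpgFraction >= 1)
        bad <- c(bad, "cpgFraction must lie in [0, 1)")
    if (length(bad)) stop("invalid scenario config: ",
                          paste(bad, collapse = "; "))
    class(cfg) <- "ScenarioConfig"
    cfg
}

#' Scale-free network by preferential attachment
#'
#' Starts from \code{m} unconnected seed nodes; each subsequent node
#' attaches \code{m} edges to distinct existing nodes with probability
#' proportional to degree + 1. Yields exactly \code{m * (n - m)} edges, no
#' self-loops or multi-edges.
#'
#' @param n number of nodes (> m).
#' @param m edges per new node (>= 1).
#' @param seed RNG seed.
#' @return a \linkS4class{PPINetwork} with node IDs \code{P00001}, ...
#' @export
generateNetwork <- function(n, m, seed = 1) {
    if (m < 1 || n <= m) stop("need n > m >= 1")
    ids <- sprintf("P%05d", seq_len(n))
    withSeed(seed, {
        deg <- integer(n)
        ea <- integer(m * (n - m)); eb <- integer(m * (n - m))
        k <- 0L
        for (v in (m + 1L):n) {
            existing <- seq_len(v - 1L)
            tgt <- if (v - 1L == m) existing else
                sample(existing, m, prob = deg[existing] + 1)
            ea[k + seq_len(m)] <- v
            eb[k + seq_len(m)] <- tgt
            k <- k + m
            deg[v] <- deg[v] + m
            deg[tgt] <- deg[tgt] + 1L
        }
        PPINetwork(cbind(ids[ea], ids[eb]))
    })
}

#' Modular scale-free network
#'
#' Several preferential-attachment modules joined by a small number of
#' random inter-module bridge edges. This emulates the modular organisation
#' of real interactomes, in which bottlenecks (high betweenness) are bridge
#' proteins rather than simply the highest-degree hubs: within modules
#' degree and betweenness correlate, while cross-module shortest paths
#' concentrate betweenness on nodes near bridges, decorrelating the two
#' rankings enough for sizeable hub-non-bottleneck and non-hub-bottleneck
#' classes to exist.
#'
#' @param n total number of nodes.
#' @param m edges per new node within each module.
#' @param nModules number of modules.
#' @param nBridges number of random inter-module edges.
#' @param seed RNG seed.
#' @return a \linkS4class{PPINetwork}.
#' @export
generateModularNetwork <- function(n, m, nModules = 8,
                                   nBridges = max(nModules, round(0.015 * n)),
                                   seed = 1) {
    if (nModules < 1 || n %/% nModules <= m)
        stop("modules must have more than m nodes each")
    sizes <- rep(n %/% nModules, nModules)
    sizes[1] <- sizes[1] + n %% nModules
    ids <- sprintf("P%05d", seq_len(n))
    moduleOf <- rep(seq_len(nModules), sizes)
    edges <- NULL
    off <- 0L
    for (k in seq_len(nModules)) {
        g <- generateNetwork(sizes[k], m, seed = substreamSeed(seed, 100 + k))
        e <- networkEdges(g)
        idx <- matrix(as.integer(sub("P", "", e)), ncol = 2) + off
        edges <- rbind(edges, idx)
        off <- off + sizes[k]
    }
    withSeed(substreamSeed(seed, 99), {
        for (b in seq_len(nBridges)) {
            repeat {
                ij <- sample.int(n, 2)
                if (moduleOf[ij[1]] != moduleOf[ij[2]]) break
            }
            edges <- rbind(edges, ij)
        }
    })
    PPINetwork(cbind(ids[edges[, 1]], ids[edges[, 2]]))
}

#' Random CDS models without internal stops
#'
#' Sense codons drawn uniformly; lengths uniform in \code{codonsRange}.
#'
#' @param proteins protein IDs.
#' @param codonsRange (min, max) length in codons, min >= 10.
#' @param seed RNG seed.
#' @return named character vector of CDS strings.
#' @export
generateGeneModels <- function(proteins, codonsRange = c(100, 300), seed = 1) {
    if (codonsRange[1] < 10) stop("minimum CDS length is 10 codons")
    ct <- .codonTables()
    withSeed(seed, {
        lens <- if (codonsRange[1] == codonsRange[2])
            rep(codonsRange[1], length(proteins))
        else sample(seq(codonsRange[1], codonsRange[2]), length(proteins),
                    replace = TRUE)
        cod <- sample(ct$sense_codons, sum(lens), replace = TRUE)
        idx <- rep.int(seq_along(proteins), lens)
        out <- vapply(split(cod, idx), paste0, character(1), collapse = "")
        names(out) <- proteins
        out
    })
}

# Per-position tables for one CDS: codon index, non-synonymous site
# fraction, CpG context flag.
.cdsPositionTables <- function(cds) {
    ct <- .codonTables()
    codons <- .cdsCodons(cds)
    ci <- codonIndex(codons)
    L <- nchar(cds)
    posInCodon <- rep(1:3, length(codons))
    ciPos <- rep(ci, each = 3)
    nsFrac <- 1 - ct$syn_frac[cbind(ciPos, posInCodon)]
    list(L = L, codonIdx = ciPos, posInCodon = posInCodon, nsFrac = nsFrac,
         cpg = cpgContext(cds, seq_len(L)))
}

.sampleAlt <- function(codonIdx, posInCodon, kind) {
    ct <- .codonTables()
    alts <- if (kind == "nonsynonymous")
        ct$nonsyn_alts[[codonIdx, posInCodon]]
    else ct$syn_alts[[codonIdx, posInCodon]]
    if (length(alts) == 0) return(NA_character_)
    if (length(alts) == 1) alts else sample(alts, 1)
}

#' Place SNPs on CDS models at class-specific non-synonymous densities
#'
#' For each protein, every CDS position can receive a non-synonymous SNP
#' with probability (class density) x (per-position non-synonymous site
#' fraction), realized by sampling an alternative base whose consequence is
#' non-synonymous, so that the expected surviving non-synonymous count is
#' density x non-synonymous sites. Baseline SNPs are confined to non-CpG
#' positions, with the placement probability rescaled by the ratio of all
#' to non-CpG non-synonymous sites: the dN recovered after CpG exclusion is
#' unbiased at the generating density. CpG-context decoy SNPs are added at
#' a rate targeting \code{cpgFraction} of all SNPs, for the exclusion
#' filter to remove. In-domain positions of the depleted class have their
#' non-synonymous probability multiplied by \code{domainDepletion}.
#' Synonymous SNPs are placed independently at \code{synDensity}.
#'
#' @param models named CDS vector.
#' @param classes named character vector protein -> topological class.
#' @param dnByClass named density vector (HB, HNB, NHB, NHNB).
#' @param synDensity synonymous per-site density.
#' @param domains optional domain table (needed when depletion < 1).
#' @param domainDepletion in-domain multiplier for \code{depletedClass}.
#' @param depletedClass class subject to depletion.
#' @param cpgFraction target CpG SNP fraction.
#' @param seed RNG seed.
#' @return data.frame \code{protein}, \code{cds_pos}, \code{ref},
#'   \code{alt}; attribute \code{skipped} counts positions where no
#'   alternative base of the required kind existed.
#' @export
generateVariants <- function(models, classes, dnByClass, synDensity = 0.01,
                             domains = NULL, domainDepletion = 1,
                             depletedClass = "HNB", cpgFraction = 0.1,
                             seed = 1) {
    stopifnot(all(names(models) %in% names(classes)))
    domSplit <- if (!is.null(domains)) split(domains, domains$protein) else NULL
    skipped <- 0L
    withSeed(seed, {
        out <- vector("list", length(models))
        for (i in seq_along(models)) {
            prot <- names(models)[i]
            cds <- models[[i]]
            pt <- .cdsPositionTables(cds)
            p <- unname(dnByClass[classes[[prot]]])
            pvec <- p * pt$nsFrac
            if (domainDepletion < 1 && classes[[prot]] == depletedClass &&
                !is.null(domSplit[[prot]])) {
                d <- domSplit[[prot]]
                aa <- ceiling(seq_len(pt$L) / 3)
                inDom <- rep(FALSE, pt$L)
                for (j in seq_len(nrow(d)))
                    inDom <- inDom | (aa >= d$start_aa[j] & aa <= d$end_aa[j])
                pvec[inDom] <- pvec[inDom] * domainDepletion
            }
            # confine baseline non-synonymous SNPs to non-CpG positions,
            # rescaled so the post-exclusion expectation is unchanged
            sAll <- sum(pvec)
            sNc <- sum(pvec[!pt$cpg])
            if (sNc > 0) {
                pvec[pt$cpg] <- 0
                pvec[!pt$cpg] <- pmin(1, pvec[!pt$cpg] * sAll / sNc)
            }
            u <- runif(pt$L)
            nsPos <- which(u < pvec)
            qvec <- synDensity * (1 - pt$nsFrac)
            qvec[pt$cpg] <- 0
            u2 <- runif(pt$L)
            synPos <- setdiff(which(u2 < qvec), nsPos)
            # CpG decoys on top, at a rate targeting cpgFraction of all SNPs
            cpgIdx <- which(pt$cpg)
            nMain <- sAll + sum(qvec)
            decoyPos <- integer(0)
            if (cpgFraction > 0 && length(cpgIdx) > 0) {
                rate <- min(1, (cpgFraction / (1 - cpgFraction)) *
                                nMain / length(cpgIdx))
                u3 <- runif(length(cpgIdx))
                decoyPos <- cpgIdx[u3 < rate]
            }
            mk <- function(pos, kind) {
                if (length(pos) == 0) return(NULL)
                alt <- vapply(pos, function(pp) {
                    if (is.na(kind))
                        sample(setdiff(.BASES, substr(cds, pp, pp)), 1)
                    else .sampleAlt(pt$codonIdx[pp], pt$posInCodon[pp], kind)
                }, character(1))
                ok <- !is.na(alt)
                skipped <<- skipped + sum(!ok)
                if (!any(ok)) return(NULL)
                data.frame(protein = prot, cds_pos = pos[ok],
                           ref = substring(cds, pos[ok], pos[ok]),
                           alt = alt[ok], stringsAsFactors = FALSE)
            }
            out[[i]] <- rbind(mk(nsPos, "nonsynonymous"),
                              mk(synPos, "synonymous"),
                              mk(decoyPos, NA))
        }
        res <- do.call(rbind, out)
        if (is.null(res))
            res <- data.frame(protein = character(0), cds_pos = integer(0),
                              ref = character(0), alt = character(0))
        res <- res[idOrder(res$protein, res$cds_pos, res$alt), , drop = FALSE]
        rownames(res) <- NULL
        attr(res, "skipped") <- skipped
        res
    })
}

#' Non-overlapping domain intervals covering a target fraction
#'
#' Intervals of 10-30 amino acids are laid down left to right with random
#' gaps until the per-protein covered length reaches
#' \code{round(coverage * length)} exactly (the last interval is trimmed).
#'
#' @param models named CDS vector (amino-acid length = nchar / 3).
#' @param coverage target covered fraction in (0, 1).
#' @param seed RNG seed.
#' @return data.frame \code{protein}, \code{start_aa}, \code{end_aa}.
#' @export
generateDomains <- function(models, coverage = 0.3, seed = 1) {
    if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
    withSeed(seed, {
        out <- vector("list", length(models))
        for (i in seq_along(models)) {
            Laa <- nchar(models[[i]]) / 3
            target <- round(coverage * Laa)
            placed <- 0L; pos <- 0L
            st <- integer(0); en <- integer(0)
            while (placed < target) {
                gap <- sample(2:10, 1)
                len <- min(sample(10:30, 1), target - placed)
                start <- pos + gap + 1L
                if (start + len - 1L > Laa) break
                st <- c(st, start); en <- c(en, start + len - 1L)
                pos <- start + len - 1L
                placed <- placed + len
            }
            out[[i]] <- if (length(st))
                data.frame(protein = names(models)[i], start_aa = st,
                           end_aa = en, stringsAsFactors = FALSE) else NULL
        }
        res <- do.call(rbind, out)
        rownames(res) <- NULL
        res
    })
}

#' Synthetic tissue expression with a matched stratum
#'
#' Per-protein levels are log-normal. A random \code{matchedFraction}
#' stratum of every class is drawn from a common baseline distribution (so
#' a K-means cluster with balanced expression exists by construction);
#' outside that stratum, hub-side proteins (HB, HNB) have their level
#' multiplied by \code{effect}. Tissue FPKM = level x log-normal noise,
#' optionally zero-inflated.
#'
#' @param proteins protein IDs.
#' @param classes named class vector.
#' @param nTissues number of tissues (>= 2).
#' @param effect multiplicative hub-side shift.
#' @param matchedFraction stratum fraction.
#' @param zeroInflation probability of zeroing a tissue value.
#' @param seed RNG seed.
#' @return list: \code{expression} (long data.frame protein/tissue/fpkm),
#'   \code{stratum} (named integer: 1 = matched, 2 = shifted).
#' @export
generateExpression <- function(proteins, classes, nTissues = 15, effect = 2,
                               matchedFraction = 0.4, zeroInflation = 0,
                               seed = 1) {
    if (nTissues < 2) stop("need at least 2 tissues")
    withSeed(seed, {
        n <- length(proteins)
        stratum <- ifelse(runif(n) < matchedFraction, 1L, 2L)
        names(stratum) <- proteins
        level <- rlnorm(n, meanlog = log(2), sdlog = 0.8)
        hubSide <- classes[proteins] %in% c("HB", "HNB")
        level[hubSide & stratum == 2L] <- level[hubSide & stratum == 2L] * effect
        fpkm <- level[rep(seq_len(n), each = nTissues)] *
            rlnorm(n * nTissues, 0, 0.3)
        if (zeroInflation > 0)
            fpkm[runif(n * nTissues) < zeroInflation] <- 0
        expr <- data.frame(
            protein = rep(proteins, each = nTissues),
            tissue = rep(sprintf("tissue%02d", seq_len(nTissues)), n),
            fpkm = round(fpkm, 4), stringsAsFactors = FALSE)
        list(expression = expr, stratum = stratum)
    })
}

#' Essential-gene list with no class enrichment
#'
#' @param proteins protein IDs.
#' @param fraction fraction labelled essential (sampled uniformly, so no
#'   class is enriched).
#' @param seed RNG seed.
#' @return character vector of essential protein IDs.
#' @export
generateEssentialGenes <- function(proteins, fraction = 0.1, seed = 1) {
    withSeed(seed, {
        k <- max(1L, round(fraction * length(proteins)))
        ids <- sample(proteins, k)
        ids[idOrder(ids)]
    })
}

.SOURCE_PREFIX <- c(biogrid = "BG", dip = "DIP", hprd = "HP", intact = "IA")

#' Write raw interaction dialect files plus an ID-mapping table
#'
#' The network's edges are distributed across the four source dialects
#' (biogrid-heavy, with overlap), written under source-specific IDs with
#' duplicates in both orders, plus decoy rows each dialect's filter must
#' remove (wrong taxid, genetic/association types, self-interactions,
#' non-protein interactors). With \code{idmapNoise = 0},
#' parse -> map -> merge over the files reconstructs the network exactly;
#' a positive noise fraction leaves some source IDs unmapped and makes
#' others multi-mapped.
#'
#' @param net a \linkS4class{PPINetwork}.
#' @param dir output directory.
#' @param idmapNoise fraction of source IDs corrupted in the mapping.
#' @param seed RNG seed.
#' @return named character vector of file paths (biogrid, dip, hprd,
#'   intact, idmap).
#' @export
generateRawFiles <- function(net, dir, idmapNoise = 0, seed = 1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    nodes <- networkNodes(net)
    e <- networkEdges(net)
    nE <- nrow(e)
    srcId <- function(source, prot)
        paste0(.SOURCE_PREFIX[[source]], "_", prot)
    withSeed(seed, {
        # every edge goes to biogrid (ensures full coverage); others overlap
        inSrc <- list(biogrid = rep(TRUE, nE),
                      dip = runif(nE) < 0.05,
                      hprd = runif(nE) < 0.25,
                      intact = runif(nE) < 0.05)
        nDecoy <- max(3L, round(0.05 * nE))
        decoyA <- sprintf("DEC%04d", seq_len(nDecoy))
        decoyB <- sprintf("DEC%04d", seq_len(nDecoy) + nDecoy)
        paths <- character(0)

        writeDialect <- function(source, path) {
            sel <- which(inSrc[[source]])
            a <- srcId(source, e[sel, 1]); b <- srcId(source, e[sel, 2])
            # duplicates: 10% repeated, half of those order-swapped
            ndup <- floor(0.1 * length(sel))
            if (ndup > 0) {
                di <- sample(seq_along(sel), ndup)
                swap <- seq_len(ndup) %% 2 == 0
                a <- c(a, ifelse(swap, b[di], a[di]))
                b <- c(b, ifelse(swap, a[seq_len(length(sel))][di], b[di]))
            }
            da <- srcId(source, decoyA); db <- srcId(source, decoyB)
            if (source == "biogrid") {
                rows <- data.frame(
                    `Interactor A` = c(a, da),
                    `Interactor B` = c(b, db),
                    `Organism Interactor A` =
                        c(rep("9606", length(a)),
                          rep(c("10090", "9606"), length.out = nDecoy)),
                    `Organism Interactor B` = rep("9606", length(a) + nDecoy),
                    `Experimental System Type` =
                        c(rep("physical", length(a)),
                          rep(c("physical", "genetic"), length.out = nDecoy)),
                    check.names = FALSE, stringsAsFactors = FALSE)
                writeTsv(rows, path)
            } else if (source == "dip") {
                # cols 3..9 are unused MITAB filler
                rows <- cbind(c(a, da), c(b, db),
                              matrix("-", length(a) + nDecoy, 7),
                              c(rep("taxid:9606(Homo sapiens)", length(a)),
                                rep(c("taxid:10090(Mus musculus)",
                                      "taxid:9606(Homo sapiens)"),
                                    length.out = nDecoy)),
                              rep("taxid:9606(Homo sapiens)",
                                  length(a) + nDecoy),
                              c(rep(c("physical interaction",
                                      "direct interaction"),
                                    length.out = length(a)),
                                rep(c("physical interaction",
                                      "genetic interaction"),
                                    length.out = nDecoy)))
                write.table(rows, path, sep = "\t", quote = FALSE,
                            row.names = FALSE, col.names = FALSE)
            } else if (source == "hprd") {
                rows <- cbind(c(a, da), c(b, da))  # decoys are self-pairs
                write.table(rows, path, sep = "\t", quote = FALSE,
                            row.names = FALSE, col.names = FALSE)
            } else {
                rows <- data.frame(
                    `ID A` = c(a, da), `ID B` = c(b, db),
                    `Type A` = c(rep("protein", length(a)),
                                 rep(c("gene", "protein"),
                                     length.out = nDecoy)),
                    `Type B` = rep("protein", length(a) + nDecoy),
                    `Interaction type` =
                        c(rep("direct interaction", length(a)),
                          rep(c("direct interaction", "association"),
                              length.out = nDecoy)),
                    check.names = FALSE, stringsAsFactors = FALSE)
                writeTsv(rows, path)
            }
            path
        }
        for (s in names(inSrc))
            paths[s] <- writeDialect(s, file.path(dir, paste0(s, ".tsv")))

        # idmapping: every used source ID -> its protein; optional noise
        pairs <- do.call(rbind, lapply(names(inSrc), function(s) {
            used <- unique(c(e[inSrc[[s]], 1], e[inSrc[[s]], 2]))
            data.frame(src = srcId(s, used), tgt = used,
                       stringsAsFactors = FALSE)
        }))
        pairs <- unique(pairs)
        if (idmapNoise > 0) {
            n <- nrow(pairs)
            corrupt <- which(runif(n) < idmapNoise)
            half <- length(corrupt) %/% 2
            drop <- corrupt[seq_len(half)]
            multi <- setdiff(corrupt, drop)
            if (length(multi))
                pairs <- rbind(pairs,
                               data.frame(src = pairs$src[multi],
                                          tgt = paste0(pairs$tgt[multi], "X"),
                                          stringsAsFactors = FALSE))
            if (length(drop)) pairs <- pairs[-drop, , drop = FALSE]
        }
        pairs <- pairs[idOrder(pairs$src, pairs$tgt), , drop = FALSE]
        paths["idmap"] <- file.path(dir, "idmapping.tsv")
        write.table(pairs, paths["idmap"], sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        paths
    })
}

#' Generate a complete synthetic scenario in memory
#'
#' Orchestrates all generators: network, generation-time class assignment
#' from the network's true metrics at the configured cut-offs, CDS models,
#' variants at class-specific densities, domains, expression, essential
#' genes. The ground truth (classes, densities, strata) is fixed before any
#' pipeline code sees the data and is never read by the pipeline.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @return list with \code{config}, \code{net}, \code{metrics},
#'   \code{models}, \code{variants}, \code{domains}, \code{expression},
#'   \code{essential}, \code{truth}.
#' @export
generateScenarioData <- function(config = scenarioConfig()) {
    stopifnot(inherits(config, "ScenarioConfig"))
    s <- function(k) substreamSeed(config$seed, k)
    net <- if (config$nModules > 1)
        generateModularNetwork(config$nProteins, config$attachmentEdges,
                               nModules = config$nModules, seed = s(1))
    else generateNetwork(config$nProteins, config$attachmentEdges, s(1))
    metrics <- nodeMetrics(net)
    cl <- classifyNodes(metrics, config$qHub, config$qBottleneck)
    classes <- classAssignments(cl)
    models <- generateGeneModels(networkNodes(net), config$cdsCodonsRange,
                                 s(2))
    domains <- generateDomains(models, config$domainCoverage, s(3))
    variants <- generateVariants(models, classes, config$dnByClass,
                                 synDensity = config$synDensity,
                                 domains = domains,
                                 domainDepletion = config$domainDepletion,
                                 depletedClass = config$depletedClass,
                                 cpgFraction = config$cpgFraction,
                                 seed = s(4))
    expr <- generateExpression(networkNodes(net), classes,
                               nTissues = config$nTissues,
                               effect = config$expressionEffect,
                               matchedFraction = config$matchedFraction,
                               zeroInflation = config$zeroInflation,
                               seed = s(5))
    essential <- generateEssentialGenes(networkNodes(net),
                                        config$essentialFraction, s(6))
    truth <- list(classes = classes, dnByClass = config$dnByClass,
                  domainDepletion = config$domainDepletion,
                  depletedClass = config$depletedClass,
                  expressionEffect = config$expressionEffect,
                  stratum = expr$stratum, seed = config$seed)
    list(config = config, net = net, metrics = metrics, models = models,
         variants = variants, domains = domains,
         expression = expr$expression, essential = essential, truth = truth)
}

#' Write a full synthetic input bundle to disk
#'
#' Produces the four raw dialect files, the ID mapping, CDS FASTA, variant
#' TSV, domain TSV, expression TSV, essential-gene list, a ground-truth
#' JSON and a manifest JSON recording seed and parameters. Byte-identical
#' for identical configs.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param dir output directory (created).
#' @return invisible list with \code{paths} (named), \code{data} (the
#'   in-memory bundle) and \code{truth}.
#' @export
generateScenario <- function(config = scenarioConfig(), dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    d <- generateScenarioData(config)
    paths <- generateRawFiles(d$net, dir, idmapNoise = config$idmapNoise,
                              seed = substreamSeed(config$seed, 7))
    paths["cds"] <- file.path(dir, "cds.fasta")
    writeLines(paste0(">", names(d$models), "\n", unname(d$models)),
               paths["cds"])
    paths["variants"] <- file.path(dir, "variants.tsv")
    writeTsv(d$variants[, c("protein", "cds_pos", "ref", "alt")],
             paths["variants"])
    paths["domains"] <- file.path(dir, "domains.tsv")
    writeTsv(d$domains, paths["domains"])
    paths["expression"] <- file.path(dir, "expression.tsv")
    writeTsv(d$expression, paths["expression"])
    paths["essential"] <- file.path(dir, "essential.txt")
    writeLines(d$essential, paths["essential"])
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(
        list(classes = as.list(d$truth$classes),
             dnByClass = as.list(d$truth$dnByClass),
             domainDepletion = d$truth$domainDepletion,
             depletedClass = d$truth$depletedClass,
             stratum = as.list(d$truth$stratum),
             seed = d$truth$seed),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    paths["manifest"] <- file.path(dir, "manifest.json")
    cfg <- unclass(config)
    jsonlite::write_json(cfg, paths["manifest"], auto_unbox = TRUE,
                         digits = NA)
    invisible(list(paths = paths, data = d, truth = d$truth))
}
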