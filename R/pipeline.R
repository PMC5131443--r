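#' Pipeline configuration
#'
#' Defaults mirror the analysis settings of the human study design: 20
#' percent hub/bottleneck cut-offs, CpG exclusion on, 10,000 randomization
#' replicates, 80 percent subsampling repeated 1000 times, cut-off sweep
#' from 5 to 40 percent in 5-percent steps.
#'
#' @param interactions named character vector of interaction file paths;
#'   names are dialects ("biogrid", "dip", "hprd", "intact"). A single
#'   entry runs the pipeline in single-source mode.
#' @param idmap,cds,variants,domains,expression,essential input paths.
#' @param qHub,qBottleneck classification cut-offs.
#' @param excludeCpg drop CpG-context SNPs from dN (default TRUE).
#' @param nPerm domain randomization replicates.
#' @param subsampleFraction,subsampleReps robustness settings.
#' @param sweepQs cut-off sweep values.
#' @param kmeansK K-means cluster count for the expression-matched
#'   subgroup.
#' @param seed master seed for all randomized stages.
#' @param outDir output directory for report files (NULL: no files).
#' @return config list (class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(interactions, idmap, cds, variants,
                           domains = NULL, expression = NULL,
                           essential = NULL,
                           qHub = 0.2, qBottleneck = 0.2, excludeCpg = TRUE,
                           nPerm = 10000, subsampleFraction = 0.8,
                           subsampleReps = 1000,
                           sweepQs = seq(0.05, 0.40, by = 0.05),
                           kmeansK = 3, seed = 1, outDir = NULL) {
    if (is.null(names(interactions)) ||
        !all(names(interactions) %in% .DIALECTS))
        stop("interactions must be named by dialect")
    stopifnot(qHub > 0, qHub <= 0.5, qBottleneck > 0, qBottleneck <= 0.5,
              subsampleFraction > 0, subsampleFraction <= 1)
    cfg <- list(interactions = interactions, idmap = idmap, cds = cds,
                variants = variants, domains = domains,
                expression = expression, essential = essential,
                qHub = qHub, qBottleneck = qBottleneck,
                excludeCpg = excludeCpg, nPerm = nPerm,
                subsampleFraction = subsampleFraction,
                subsampleReps = subsampleReps, sweepQs = sweepQs,
                kmeansK = kmeansK, seed = seed, outDir = outDir)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' The three headline group comparisons of dN
#'
#' Hubs vs non-hubs, bottlenecks vs non-bottlenecks, and
#' hub-non-bottlenecks vs non-hub-bottlenecks, each a two-sided
#' Mann-Whitney comparison of per-protein dN. Proteins lacking a dN record
#' are excluded, with counts reported; an empty comparison group marks that
#' comparison undefined rather than failing.
#'
#' @param dn dN table (\code{protein}, \code{dn}).
#' @param classes a \linkS4class{ClassificationResult}.
#' @return list with \code{hub_vs_nonhub}, \code{bottleneck_vs_nonbottleneck},
#'   \code{hnb_vs_nhb} (GroupComparison or NULL when undefined) and
#'   \code{n_missing_dn}.
#' @export
compareHeadline <- function(dn, classes) {
    asg <- classAssignments(classes)
    prot <- names(asg)
    dnv <- dn$dn[match(prot, dn$protein)]
    miss <- is.na(dnv)
    cmpSets <- function(sel1, sel2) {
        a <- dnv[sel1 & !miss]; b <- dnv[sel2 & !miss]
        if (length(a) < 2 || length(b) < 2) return(NULL)
        mannWhitneyCompare(a, b)
    }
    isHub <- prot %in% hubSet(classes)
    isBot <- prot %in% bottleneckSet(classes)
    list(hub_vs_nonhub = cmpSets(isHub, !isHub),
         bottleneck_vs_nonbottleneck = cmpSets(isBot, !isBot),
         hnb_vs_nhb = cmpSets(asg == "HNB", asg == "NHB"),
         n_missing_dn = sum(miss))
}

.cmpAsList <- function(cmp) {
    if (is.null(cmp)) return(list(defined = FALSE))
    list(defined = TRUE, n1 = cmp$n1, n2 = cmp$n2, median1 = cmp$median1,
         median2 = cmp$median2, u = cmp$u_statistic, p = cmp$p_value)
}

#' Run the full analysis pipeline
#'
#' parse -> map -> merge -> metrics -> classify -> dN -> headline
#' comparisons -> confound checks (essential-gene enrichment, expression
#' breadth/level, K-means matched subgroup) -> domain randomization tests
#' (HNB and NHB, plus Fisher between their domain SNP tables) -> node/edge
#' subsampling robustness -> cut-off sweep. Fully deterministic given the
#' config (including its seed). Stages whose inputs were not configured are
#' marked skipped in the report.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the report as a nested list (also written to
#'   \code{report.json}/\code{report.md} and per-stage TSVs when
#'   \code{outDir} is set).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    report <- list(provenance = list(
        package = "ppivar",
        version = as.character(utils::packageVersion("ppivar")),
        seed = config$seed,
        q_hub = config$qHub, q_bottleneck = config$qBottleneck,
        exclude_cpg = config$excludeCpg,
        n_perm = config$nPerm,
        subsample_fraction = config$subsampleFraction,
        subsample_reps = config$subsampleReps,
        sources = names(config$interactions)))

    # --- network assembly -------------------------------------------------
    idmap <- readIdMap(config$idmap)
    dropped <- c(unmapped = 0L, ambiguous = 0L)
    recs <- lapply(names(config$interactions), function(src) {
        r <- parseInteractions(config$interactions[[src]], src)
        m <- mapIdentifiers(r, idmap)
        dropped <<- dropped + m$dropped
        m$records
    })
    net <- buildNetwork(do.call(rbind, recs))
    if (numNodes(net) < 2) stop("merged network has fewer than 2 nodes")
    metrics <- nodeMetrics(net)
    plfit <- tryCatch(fitDegreePowerlaw(net),
                      error = function(e) NULL)
    report$network <- list(
        n_nodes = numNodes(net), n_edges = numEdges(net),
        dropped_unmapped = unname(dropped["unmapped"]),
        dropped_ambiguous = unname(dropped["ambiguous"]),
        powerlaw = if (is.null(plfit)) list(defined = FALSE) else
            c(list(defined = TRUE), plfit))

    # --- classification ---------------------------------------------------
    classes <- classifyNodes(metrics, config$qHub, config$qBottleneck)
    report$class_counts <- as.list(classCounts(classes))

    # --- variation --------------------------------------------------------
    models <- readCdsFasta(config$cds)
    variants <- readVariants(config$variants)
    cons <- annotateVariants(models, variants)
    dn <- computeDn(models, cons, excludeCpg = config$excludeCpg)
    report$variation <- list(
        n_proteins_with_model = nrow(dn),
        n_variants = nrow(cons),
        n_nonsynonymous = sum(cons$kind == "nonsynonymous"),
        n_cpg_related = sum(cons$cpg_related),
        median_dn = median(dn$dn))

    # --- correlations -----------------------------------------------------
    common <- intersect(metrics$protein, dn$protein)
    dnv <- dn$dn[match(common, dn$protein)]
    degv <- metrics$degree[match(common, metrics$protein)]
    btwv <- metrics$betweenness[match(common, metrics$protein)]
    report$correlations <- list(
        dn_degree = spearmanAssoc(dnv, degv),
        dn_betweenness = spearmanAssoc(dnv, btwv),
        degree_betweenness = spearmanAssoc(degv, btwv))

    # --- headline comparisons --------------------------------------------
    hl <- compareHeadline(dn, classes)
    report$comparisons <- list(
        hub_vs_nonhub = .cmpAsList(hl$hub_vs_nonhub),
        bottleneck_vs_nonbottleneck =
            .cmpAsList(hl$bottleneck_vs_nonbottleneck),
        hnb_vs_nhb = .cmpAsList(hl$hnb_vs_nhb),
        n_missing_dn = hl$n_missing_dn)

    asg <- classAssignments(classes)
    hnb <- names(asg)[asg == "HNB"]
    nhb <- names(asg)[asg == "NHB"]

    # --- confounds --------------------------------------------------------
    conf <- list()
    if (!is.null(config$essential)) {
        ess <- readEssentialGenes(config$essential)
        tbl <- matrix(c(sum(hnb %in% ess), sum(!hnb %in% ess),
                        sum(nhb %in% ess), sum(!nhb %in% ess)),
                      nrow = 2, byrow = TRUE)
        fe <- fisherEnrichment(tbl)
        conf$essential <- list(defined = TRUE,
                               n_essential_hnb = tbl[1, 1],
                               n_essential_nhb = tbl[2, 1],
                               odds_ratio = fe$odds_ratio, p = fe$p_value)
    } else conf$essential <- list(defined = FALSE)
    if (!is.null(config$expression)) {
        expr <- expressionProfiles(readExpression(config$expression))
        prof <- function(ids) expr[match(ids, expr$protein), , drop = FALSE]
        eh <- prof(hnb); en <- prof(nhb)
        ok <- sum(!is.na(eh$level)) >= 2 && sum(!is.na(en$level)) >= 2
        if (ok) {
            conf$expression_breadth <- .cmpAsList(mannWhitneyCompare(
                eh$breadth[!is.na(eh$breadth)], en$breadth[!is.na(en$breadth)]))
            conf$expression_level <- .cmpAsList(mannWhitneyCompare(
                eh$level[!is.na(eh$level)], en$level[!is.na(en$level)]))
            groups <- c(rep("HNB", length(hnb)), rep("NHB", length(nhb)))
            names(groups) <- c(hnb, nhb)
            groups <- groups[names(groups) %in% expr$protein]
            km <- kmeansExpressionMatch(groups, expr, dn, k = config$kmeansK,
                                        seed = substreamSeed(config$seed, 11))
            conf$matched_subgroup <- list(
                matched = km$matched, cluster = km$cluster,
                n_proteins = length(km$proteins),
                expression = .cmpAsList(km$expr_comparison),
                dn = .cmpAsList(km$dn_comparison))
        } else {
            conf$expression_breadth <- list(defined = FALSE)
            conf$expression_level <- list(defined = FALSE)
            conf$matched_subgroup <- list(matched = FALSE)
        }
    } else {
        conf$expression_breadth <- list(defined = FALSE)
        conf$expression_level <- list(defined = FALSE)
        conf$matched_subgroup <- list(matched = FALSE)
    }
    report$confounds <- conf

    # --- domain randomization tests --------------------------------------
    if (!is.null(config$domains)) {
        domains <- readDomains(config$domains)
        universe <- dn$protein
        runDom <- function(target, k) {
            if (length(target) == 0) return(list(defined = FALSE))
            res <- tryCatch(
                domainRandomizationTest(target, universe, domains, cons,
                                        nReplicates = config$nPerm,
                                        seed = substreamSeed(config$seed, k)),
                error = function(e) NULL)
            if (is.null(res)) return(list(defined = FALSE))
            list(defined = TRUE, observed = observedStat(res),
                 p = pValue(res), p_smoothed = res@pSmoothed,
                 n_replicates = res@nReplicates)
        }
        domCounts <- .domainSnpCounts(domains, cons)
        domTbl <- function(ids) {
            sel <- domCounts$protein %in% ids
            c(inside = sum(domCounts$n_in_domain[sel]),
              outside = sum(domCounts$n_nonsyn[sel]) -
                  sum(domCounts$n_in_domain[sel]))
        }
        th <- domTbl(hnb); tn <- domTbl(nhb)
        feDom <- fisherEnrichment(matrix(c(th, tn), nrow = 2, byrow = TRUE))
        report$domain_tests <- list(
            hnb = runDom(hnb, 21), nhb = runDom(nhb, 22),
            fisher_hnb_vs_nhb = list(
                hnb_inside = unname(th["inside"]),
                hnb_outside = unname(th["outside"]),
                nhb_inside = unname(tn["inside"]),
                nhb_outside = unname(tn["outside"]),
                odds_ratio = feDom$odds_ratio, p = feDom$p_value))
    } else report$domain_tests <- list(hnb = list(defined = FALSE),
                                       nhb = list(defined = FALSE))

    # --- robustness -------------------------------------------------------
    robust <- function(mode, k) {
        ss <- networkSubsampleRobustness(
            net, dn, mode = mode, fraction = config$subsampleFraction,
            nReps = config$subsampleReps, qHub = config$qHub,
            qBottleneck = config$qBottleneck,
            seed = substreamSeed(config$seed, k))
        rr <- repRecords(ss)
        list(mode = mode, fraction = config$subsampleFraction,
             n_reps = ss@nReps, full_sign = ss@fullSign,
             sign_consistency = signConsistency(ss),
             n_undefined = sum(!rr$defined),
             frac_significant = mean(rr$p[rr$defined] < 0.05))
    }
    report$robustness <- list(nodes = robust("nodes", 31),
                              edges = robust("edges", 32))

    # --- sweep ------------------------------------------------------------
    sweep <- cutoffSweep(metrics, dn, config$sweepQs)
    report$sweep <- lapply(seq_len(nrow(sweep)), function(i)
        as.list(sweep[i, , drop = FALSE]))

    if (!is.null(config$outDir))
        .writeReport(report, config, net, metrics, classes, dn, sweep)
    report
}

.writeReport <- function(report, config, net, metrics, classes, dn, sweep) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeEdgeList(net, file.path(config$outDir, "edges.tsv"))
    cls <- data.frame(protein = metrics$protein, degree = metrics$degree,
                      betweenness = metrics$betweenness,
                      class = unname(classAssignments(classes)[metrics$protein]))
    writeTsv(cls, file.path(config$outDir, "classification.tsv"))
    writeTsv(dn, file.path(config$outDir, "dn.tsv"))
    writeTsv(sweep, file.path(config$outDir, "sweep.tsv"))
    md <- c("# Analysis report", "",
            sprintf("- Network: %d nodes, %d edges",
                    report$network$n_nodes, report$network$n_edges),
            if (isTRUE(report$network$powerlaw$defined))
                sprintf("- Degree power-law fit: exponent %.3f, R^2 %.3f",
                        report$network$powerlaw$exponent,
                        report$network$powerlaw$r_squared),
            sprintf("- Class counts: %s",
                    paste(names(report$class_counts), report$class_counts,
                          sep = "=", collapse = " ")),
            sprintf("- dN ~ degree: rho %.3f (p %.3g); dN ~ betweenness: rho %.3f (p %.3g)",
                    report$correlations$dn_degree$rho,
                    report$correlations$dn_degree$p_value,
                    report$correlations$dn_betweenness$rho,
                    report$correlations$dn_betweenness$p_value),
            if (isTRUE(report$comparisons$hnb_vs_nhb$defined))
                sprintf("- HNB vs NHB dN: medians %.5f vs %.5f, p %.3g",
                        report$comparisons$hnb_vs_nhb$median1,
                        report$comparisons$hnb_vs_nhb$median2,
                        report$comparisons$hnb_vs_nhb$p),
            sprintf("- Subsampling sign consistency: nodes %.3f, edges %.3f",
                    report$robustness$nodes$sign_consistency,
                    report$robustness$edges$sign_consistency))
    writeLines(md[!vapply(md, is.null, logical(1))],
               file.path(config$outDir, "report.md"))
    invisible(NULL)
}
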