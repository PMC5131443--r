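test_that("preferential attachment yields m*(n-m) edges, reproducibly", {
  g <- generateNetwork(100, 2, seed = 1)
  expect_equal(numNodes(g), 100)
  expect_equal(numEdges(g), 2 * (100 - 2))
  g2 <- generateNetwork(100, 2, seed = 1)
  expect_identical(networkEdges(g), networkEdges(g2))
  g3 <- generateNetwork(100, 2, seed = 2)
  expect_false(identical(networkEdges(g), networkEdges(g3)))
  expect_error(generateNetwork(3, 3), "n > m")
})

test_that("modular network keeps all nodes and decorrelates degree from betweenness", {
  net <- generateModularNetwork(400, 3, nModules = 4, seed = 9)
  expect_equal(numNodes(net), 400)
  m <- nodeMetrics(net)
  rho <- spearmanAssoc(m$degree, m$betweenness)$rho
  expect_gt(rho, 0.3)   # positively related, as in real interactomes
  expect_lt(rho, 0.98)  # but not rank-identical
  cc <- classCounts(classifyNodes(m))
  expect_gt(unname(cc["HNB"]), 0)
  expect_gt(unname(cc["NHB"]), 0)
})

test_that("gene models have the requested lengths and no internal stops", {
  prot <- sprintf("G%03d", 1:200)
  models <- generateGeneModels(prot, c(100, 100), seed = 4)
  expect_true(all(nchar(models) == 300))
  models2 <- generateGeneModels(prot, c(50, 80), seed = 5)
  expect_true(all(nchar(models2) %% 3 == 0))
  codons <- unlist(lapply(models2, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  expect_identical(generateGeneModels(prot, c(50, 80), seed = 5), models2)
  expect_error(generateGeneModels(prot, c(5, 20)), "10 codons")
})

test_that("variant generation respects class densities", {
  prot <- sprintf("G%03d", 1:100)
  models <- generateGeneModels(prot, c(60, 100), seed = 6)
  zero <- generateVariants(models, setNames(rep("HNB", 100), prot),
                           c(HB = 0, HNB = 0, NHB = 0, NHNB = 0),
                           synDensity = 0, cpgFraction = 0, seed = 7)
  expect_equal(nrow(zero), 0)

  p <- 0.01
  classes <- setNames(rep("NHB", 100), prot)
  v <- generateVariants(models, classes,
                        c(HB = 0, HNB = 0, NHB = p, NHNB = 0),
                        synDensity = 0, cpgFraction = 0, seed = 8)
  cons <- annotateVariants(models, v)
  expect_true(all(cons$kind == "nonsynonymous"))
  dn <- computeDn(models, cons, excludeCpg = FALSE)
  totalSites <- sum(dn$nonsyn_sites)
  se <- sqrt(p * (1 - p) / totalSites)
  expect_lt(abs(sum(dn$n_nonsyn) / totalSites - p), 3 * se)
  # refs always match the CDS (constructive invariant)
  expect_true(all(substr(models[v$protein], v$cds_pos, v$cds_pos) == v$ref))
})

test_that("domain depletion halves the in-domain non-synonymous density", {
  prot <- sprintf("G%03d", 1:300)
  models <- generateGeneModels(prot, c(150, 150), seed = 14)
  doms <- generateDomains(models, 0.4, seed = 15)
  classes <- setNames(rep("HNB", 300), prot)
  v <- generateVariants(models, classes,
                        c(HB = 0, HNB = 0.02, NHB = 0, NHNB = 0),
                        synDensity = 0, domains = doms,
                        domainDepletion = 0.5, depletedClass = "HNB",
                        cpgFraction = 0, seed = 16)
  cons <- annotateVariants(models, v)
  ns <- cons[cons$kind == "nonsynonymous", ]
  inDom <- mapply(function(p, aa) {
    d <- doms[doms$protein == p, ]
    any(aa >= d$start_aa & aa <= d$end_aa)
  }, ns$protein, ns$aa_pos)
  aaLen <- nchar(models) / 3
  totAA <- sum(aaLen)
  domAA <- sum(doms$end_aa - doms$start_aa + 1)
  rateIn <- sum(inDom) / domAA
  rateOut <- sum(!inDom) / (totAA - domAA)
  expect_gt(rateIn / rateOut, 0.35)
  expect_lt(rateIn / rateOut, 0.65)
})

test_that("domains are non-overlapping, in range, and cover the target fraction", {
  prot <- sprintf("G%03d", 1:50)
  models <- generateGeneModels(prot, c(100, 100), seed = 17)  # 100 aa each
  doms <- generateDomains(models, 0.3, seed = 18)
  byProt <- split(doms, doms$protein)
  for (p in names(byProt)) {
    d <- byProt[[p]][order(byProt[[p]]$start_aa), ]
    expect_true(all(d$start_aa >= 1 & d$end_aa <= 100))
    expect_true(all(d$start_aa <= d$end_aa))
    if (nrow(d) > 1)
      expect_true(all(d$start_aa[-1] > d$end_aa[-nrow(d)]))
    covered <- sum(d$end_aa - d$start_aa + 1)
    expect_gte(covered, 20); expect_lte(covered, 40)
  }
  expect_identical(generateDomains(models, 0.3, seed = 18), doms)
})

test_that("expression generator builds a null, an effect, and a matched stratum", {
  prot <- sprintf("G%03d", 1:500)
  classes <- setNames(rep(c("HNB", "NHB"), 250), prot)
  nullex <- generateExpression(prot, classes, nTissues = 10, effect = 1,
                               seed = 19)
  profN <- expressionProfiles(nullex$expression)
  a <- profN$level[classes[profN$protein] == "HNB"]
  b <- profN$level[classes[profN$protein] == "NHB"]
  expect_gt(mannWhitneyCompare(a, b)$p_value, 0.05)
  expect_true(all(profN$breadth == 10))   # zeroInflation 0

  eff <- generateExpression(prot, classes, nTissues = 10, effect = 3,
                            seed = 20)
  profE <- expressionProfiles(eff$expression)
  a2 <- profE$level[classes[profE$protein] == "HNB"]
  b2 <- profE$level[classes[profE$protein] == "NHB"]
  expect_lt(mannWhitneyCompare(a2, b2)$p_value, 0.05)
  # matched stratum: within stratum 1 the groups stay indistinguishable
  s1 <- names(eff$stratum)[eff$stratum == 1]
  a3 <- profE$level[profE$protein %in% s1 & classes[profE$protein] == "HNB"]
  b3 <- profE$level[profE$protein %in% s1 & classes[profE$protein] == "NHB"]
  expect_gt(mannWhitneyCompare(a3, b3)$p_value, 0.05)
})

test_that("raw dialect files round-trip to the exact generated network", {
  net <- generateNetwork(150, 3, seed = 21)
  dir <- file.path(tempdir(), "rawrt")
  paths <- generateRawFiles(net, dir, idmapNoise = 0, seed = 22)
  idmap <- readIdMap(paths["idmap"])
  recs <- do.call(rbind, lapply(c("biogrid", "dip", "hprd", "intact"),
    function(s) mapIdentifiers(parseInteractions(paths[s], s), idmap)$records))
  rebuilt <- buildNetwork(recs)
  expect_identical(networkEdges(rebuilt), networkEdges(net))
  expect_identical(networkNodes(rebuilt), networkNodes(net))
  # decoy interactors never survive parsing
  expect_false(any(grepl("DEC", c(recs$interactor_a, recs$interactor_b))))
})

test_that("idmap noise drops or multi-maps identifiers, reported as drops", {
  net <- generateNetwork(100, 3, seed = 23)
  dir <- file.path(tempdir(), "rawnoise")
  paths <- generateRawFiles(net, dir, idmapNoise = 0.2, seed = 24)
  idmap <- readIdMap(paths["idmap"])
  m <- mapIdentifiers(parseInteractions(paths["biogrid"], "biogrid"), idmap)
  expect_gt(sum(m$dropped), 0)
  expect_lt(numEdges(buildNetwork(m$records)), numEdges(net))
})

test_that("scenario bundles are byte-identical for identical configs", {
  cfg <- smallScenarioConfig(seed = 42)
  d1 <- file.path(tempdir(), "sc1"); d2 <- file.path(tempdir(), "sc2")
  b1 <- generateScenario(cfg, d1)
  b2 <- generateScenario(smallScenarioConfig(seed = 42), d2)
  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     info = nm)
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # ground truth stores generation-time classes for every node
  expect_setequal(names(b1$truth$classes), networkNodes(b1$data$net))
})

test_that("invalid scenario configs report all violations", {
  expect_error(scenarioConfig(nProteins = 5),
               "nProteins")
  expect_error(scenarioConfig(domainCoverage = 1.5), "domainCoverage")
  expect_error(scenarioConfig(nProteins = 5, domainCoverage = 2),
               "nProteins.*domainCoverage")
})
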