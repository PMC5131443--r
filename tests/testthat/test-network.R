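test_that("dialect parsers apply the source-specific filters", {
  bg <- parseInteractions(biogridFixture(), "biogrid")
  expect_equal(nrow(bg), 1)
  expect_equal(bg$interactor_a, "P1")
  expect_equal(unname(attr(bg, "counts")["n_filtered"]), 2L)

  dip <- parseInteractions(dipFixture(), "dip")
  expect_equal(nrow(dip), 2)  # genetic and mouse-taxid rows dropped
  expect_setequal(dip$interactor_b, c("D2", "D3"))

  hp <- parseInteractions(hprdFixture(), "hprd")
  expect_equal(nrow(hp), 2)   # self-interaction H1-H1 dropped
  expect_false(any(hp$interactor_a == hp$interactor_b))

  ia <- parseInteractions(intactFixture(), "intact")
  expect_equal(nrow(ia), 1)   # gene-typed and association rows dropped
  expect_equal(ia$interactor_b, "I2")

  expect_error(parseInteractions(tempfile(), "biogrid"), "not found")
})

test_that("malformed rows are skipped with a warning, not fatal", {
  f <- writeLinesTmp(c("H1\tH2", "H3", "H4\tH5"))
  expect_warning(out <- parseInteractions(f, "hprd"), "malformed")
  expect_equal(nrow(out), 2)
  expect_equal(unname(attr(out, "counts")["n_malformed"]), 1L)
})

test_that("identifier mapping drops unmapped and ambiguous records", {
  idmap <- asIdMap(data.frame(
    src = c("A", "B", "M", "M"), tgt = c("TA", "TB", "T1", "T2")))
  recs <- data.frame(interactor_a = c("A", "A", "M"),
                     interactor_b = c("B", "C", "B"),
                     source = "hprd", stringsAsFactors = FALSE)
  out <- mapIdentifiers(recs, idmap)
  expect_equal(out$records$interactor_a, "TA")
  expect_equal(out$records$interactor_b, "TB")
  expect_equal(out$dropped, c(unmapped = 1L, ambiguous = 1L))
})

test_that("network build dedupes, drops self-pairs, and is idempotent", {
  recs <- data.frame(interactor_a = c("A", "B", "A", "A"),
                     interactor_b = c("B", "A", "A", "C"))
  net <- buildNetwork(recs)
  expect_equal(numNodes(net), 3)
  expect_equal(numEdges(net), 2)
  expect_equal(networkEdges(net)[1, ], c(a = "A", b = "B"))
  rebuilt <- buildNetwork(data.frame(interactor_a = networkEdges(net)[, 1],
                                     interactor_b = networkEdges(net)[, 2]))
  expect_identical(networkEdges(rebuilt), networkEdges(net))
  expect_identical(networkNodes(rebuilt), networkNodes(net))

  empty <- buildNetwork(data.frame())
  expect_equal(numNodes(empty), 0)
  expect_equal(numEdges(empty), 0)
})

test_that("degree matches simple cases and sums to twice the edges", {
  path <- PPINetwork(rbind(c("A", "B"), c("B", "C")))
  expect_equal(nodeDegree(path), c(A = 1L, B = 2L, C = 1L))
  star <- PPINetwork(cbind("S", c("L1", "L2", "L3", "L4")))
  expect_equal(unname(nodeDegree(star)["S"]), 4L)
  iso <- PPINetwork(rbind(c("A", "B")), nodes = "Z")
  expect_equal(unname(nodeDegree(iso)["Z"]), 0L)
  net <- randomTestNet(15, 0.3, seed = 11)
  expect_equal(sum(nodeDegree(net)), 2 * numEdges(net))
})

test_that("betweenness handles canonical small graphs", {
  path <- PPINetwork(rbind(c("A", "B"), c("B", "C")))
  expect_equal(nodeBetweenness(path), c(A = 0, B = 1, C = 0))
  star <- PPINetwork(cbind("S", c("L1", "L2", "L3", "L4")))
  expect_equal(unname(nodeBetweenness(star)["S"]), choose(4, 2))
  expect_equal(unname(nodeBetweenness(star)["L1"]), 0)
  cyc <- PPINetwork(rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D")))
  expect_equal(unname(nodeBetweenness(cyc)), rep(0.5, 4))
  # two components: cross pairs contribute nothing
  two <- PPINetwork(rbind(c("A", "B"), c("B", "C"), c("X", "Y")))
  expect_equal(unname(nodeBetweenness(two)[c("X", "Y")]), c(0, 0))
})

test_that("betweenness equals brute-force path enumeration on random graphs", {
  for (i in 1:25) {
    net <- randomTestNet(sample(5:18, 1), runif(1, 0.1, 0.45), seed = 7000 + i)
    expect_equal(nodeBetweenness(net), bruteForceBetweenness(net),
                 tolerance = 1e-12)
  }
})

test_that("total betweenness equals the summed interior lengths of shortest paths", {
  for (i in 1:5) {
    net <- randomTestNet(12, 0.3, seed = 400 + i)
    nodes <- networkNodes(net)
    # via BFS distances: each connected pair contributes (d - 1)
    e <- networkEdges(net)
    n <- length(nodes)
    adj <- lapply(seq_len(n), function(x) integer(0))
    ia <- match(e[, 1], nodes); ib <- match(e[, 2], nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
    total <- 0
    for (s in seq_len(n - 1)) {
      dist <- rep(NA_integer_, n); dist[s] <- 0L; fr <- s
      while (length(fr)) {
        nx <- integer(0)
        for (v in fr) for (w in adj[[v]])
          if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; nx <- c(nx, w) }
        fr <- unique(nx)
      }
      d <- dist[(s + 1):n]
      total <- total + sum(pmax(d[!is.na(d)] - 1, 0))
    }
    expect_equal(sum(nodeBetweenness(net)), total, tolerance = 1e-9)
  }
})

test_that("betweenness agrees with igraph's undirected convention", {
  skip_if_not_installed("igraph")
  net <- randomTestNet(30, 0.15, seed = 99)
  g <- igraph::graph_from_edgelist(networkEdges(net), directed = FALSE)
  ref <- igraph::betweenness(g, directed = FALSE)
  expect_equal(nodeBetweenness(net)[names(ref)], ref, tolerance = 1e-9)
})

test_that("power-law fit recovers an exact k^-2 law and rejects thin input", {
  k <- 1:8
  counts <- 705600 / k^2      # integer counts exactly proportional to k^-2
  degrees <- rep(k, counts)
  fit <- fitPowerlawFromDegrees(degrees)
  expect_equal(fit$exponent, -2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$points_used, 8)

  # degree-frequency normalisation: histogram sums to 1
  net <- randomTestNet(20, 0.2, seed = 31)
  deg <- nodeDegree(net)
  expect_equal(sum(table(deg) / length(deg)), 1)

  ring <- PPINetwork(cbind(sprintf("R%02d", 1:6),
                           sprintf("R%02d", c(2:6, 1))))
  expect_error(fitDegreePowerlaw(ring), "fewer than 3")
})

test_that("power-law fit on the package generator is scale-free-like", {
  net <- generateNetwork(1000, 3, seed = 1234)
  fit <- fitDegreePowerlaw(net)
  expect_lt(fit$exponent, -1)
  expect_gte(fit$r_squared, 0.7)
  expect_gte(fit$points_used, 3)
})

test_that("edge-list round trip is byte-stable", {
  net <- randomTestNet(12, 0.3, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  writeEdgeList(net, f1)
  writeEdgeList(readEdgeList(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})
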