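# Independent oracles used across the suite. Deliberately naive
# implementations that share no code with the package internals.

# All-shortest-path enumeration betweenness: for every unordered pair,
# enumerate every shortest path explicitly (BFS + predecessor DAG walk) and
# split one unit of credit among them, accumulating on interior nodes.
bruteForceBetweenness <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  e <- networkEdges(net)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(e) > 0) {
    ia <- match(e[, 1], nodes); ib <- match(e[, 2], nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  bfs <- function(s) {
    dist <- rep(NA_integer_, n)
    preds <- lapply(seq_len(n), function(i) integer(0))
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
        if (!is.na(dist[w]) && dist[w] == dist[v] + 1L)
          preds[[w]] <- c(preds[[w]], v)
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, preds = preds)
  }
  allPaths <- function(preds, s, t) {
    if (t == s) return(list(s))
    out <- list()
    for (p in unique(preds[[t]]))
      for (pa in allPaths(preds, s, p)) out <- c(out, list(c(pa, t)))
    out
  }
  bc <- setNames(rep(0, n), nodes)
  for (s in seq_len(n - 1)) {
    b <- bfs(s)
    for (t in (s + 1):n) {
      if (is.na(b$dist[t])) next
      paths <- allPaths(b$preds, s, t)
      credit <- 1 / length(paths)
      for (pa in paths) {
        interior <- pa[-c(1, length(pa))]
        if (length(interior)) bc[interior] <- bc[interior] + credit
      }
    }
  }
  bc
}

# Erdos-Renyi style random test graph with guaranteed >= 1 edge.
randomTestNet <- function(n, p, seed) {
  set.seed(seed)
  ut <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < p
  if (!any(keep)) keep[sample(nrow(ut), 1)] <- TRUE
  ids <- sprintf("N%02d", seq_len(n))
  PPINetwork(cbind(ids[ut[keep, 1]], ids[ut[keep, 2]]))
}

# Exhaustive 9-mutation codon site-count oracle via seqinr translation.
oracleCodonSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  ref_aa <- seqinr::translate(strsplit(codon, "")[[1]])
  syn <- 0
  for (pos in 1:3) for (b in setdiff(bases, substr(codon, pos, pos))) {
    mut <- strsplit(codon, "")[[1]]
    mut[pos] <- b
    aa <- seqinr::translate(mut)
    if (aa == ref_aa && aa != "*") syn <- syn + 1
  }
  c(syn_sites = syn / 3, nonsyn_sites = 3 - syn / 3)
}

# Two-sided Fisher p by direct hypergeometric enumeration.
oracleFisherP <- function(tbl) {
  a <- tbl[1, 1]
  m <- sum(tbl[1, ]); n2 <- sum(tbl[2, ]); k <- sum(tbl[, 1])
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n2, k)
  p0 <- dhyper(a, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Spearman rho by the hand formula on midranks.
oracleSpearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
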