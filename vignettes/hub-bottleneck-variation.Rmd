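---
title: "Differential variation of hubs and bottlenecks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential variation of hubs and bottlenecks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppivar)
```

## The question

Protein-protein interaction (PPI) networks have two classic notions of
topological importance: *hubs*, proteins in the top quantile of the degree
distribution, and *bottlenecks*, proteins in the top quantile of the
betweenness distribution. The two sets overlap heavily, so the interesting
contrast is between their exclusive members — hub-non-bottlenecks (HNB) and
non-hub-bottlenecks (NHB). ppivar implements a complete pipeline for asking
whether these two groups differ in their rate of recent sequence variation,
measured as the density of non-synonymous SNPs per non-synonymous site
(dN), together with the resampling and confound controls such an analysis
needs, and a synthetic-data module that generates inputs with known ground
truth so every stage can be validated end to end.

## The measurement model

**Network.** Interaction records from four source dialects (biogrid-lite,
dip-lite, hprd-lite, intact-lite) are filtered by source-specific rules
(human taxid, physical/direct interaction types, protein interactors, no
self-interactions), mapped to transcript IDs, and merged into one
undirected simple graph. A source ID mapping to more than one transcript is
dropped rather than expanded: expanding would fabricate edges the source
never asserted. Degree is the number of incident edges; betweenness is the
Brandes accumulation

$$C_B(v) = \sum_{s \ne v \ne t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$

undirected, unnormalized, endpoints excluded, each unordered pair counted
once, with disconnected pairs contributing zero. The compiled
implementation is verified in the test suite against a brute-force
enumeration of all shortest paths on random graphs, and against an
independent graph library.

**Classification.** Hubs are the exactly `floor(q*N)` nodes of highest
degree (default q = 0.20), with ties broken by higher betweenness and then
by protein ID; bottlenecks analogously by betweenness. Deterministic
tie-breaks give fixed set sizes, which keeps the subsampling and
permutation machinery exactly reproducible. The cut-off is also swept from
5% to 40% in 5% steps to show the contrast is not an artifact of q = 0.20.

**Variation rate.** For each CDS, the nine single-base changes of every
codon are classified as synonymous or non-synonymous under the standard
genetic code (changes to stop codons count as non-synonymous; the per-codon
identity syn + nonsyn = 3 holds exactly). dN is then the number of observed
non-synonymous SNPs divided by the summed non-synonymous sites. This is a
counting (NG86-style) estimator: for population SNP data with at most one
variant per site it equals the substitution density to first order, and it
replaces a likelihood-based pairwise estimate deliberately — the one
methodological substitution in the package, made so the estimator is exact,
fast and dependency-free. SNPs in CpG dinucleotide context (reference
strand; one-sided at the sequence ends) are excluded by default because of
their elevated mutation rate; proteins with zero surviving variants keep
dN = 0 and stay in the analysis.

**Tests.** Group contrasts use the two-sided Mann-Whitney test (exact for
tiny tie-free groups, normal approximation with tie correction otherwise),
correlations use Spearman's rank test with midranks, and 2×2 enrichments
use Fisher's exact test. These four classical procedures delegate to R's
stats package; each is nevertheless pinned in the test suite to an
independent enumeration oracle (rank arrangements, hypergeometric sums,
midrank formula). Raw p-values are reported without multiplicity
correction, with the number of tests annotated in the report.

## Resampling machinery

**Domain randomization.** To ask whether a protein set carries unusually
few non-synonymous SNPs inside its domains, the observed in-domain fraction
of the set is compared with the fractions of 10,000 random same-size sets
drawn from the universe without replacement. The p-value is the literal
proportion of replicates with a *strictly lower* fraction; because that
estimator can return 0, the add-one (r+1)/(n+1) estimator is reported
alongside. Replicates whose random set contains no non-synonymous SNP carry
no information and are redrawn (at most 100 times, counted) rather than
scored as ties.

**Subsampling robustness.** Because interactome coverage is incomplete, the
HNB-vs-NHB contrast is recomputed on networks built from 80% of the nodes
(induced subgraph) or 80% of the edges (endpoints kept, freshly isolated
nodes removed), re-deriving degree, betweenness and the classification per
replicate — the cut-off quantiles apply to each replicate's own surviving
node set. The summary is the fraction of defined replicates whose
median-difference sign matches the full network. At fraction 1.0 the
procedure reproduces the full analysis identically, which is tested.

**RNG discipline.** Every replicate draws its seed from the master seed by
a counter, so results are reproducible, independent of replicate order, and
stream-stable: raising the replicate count extends the null vector without
changing earlier entries.

## The synthetic scenario: what it emulates and what it does not

The generator produces every input the pipeline consumes, with ground truth
fixed *before* the pipeline runs: classes are assigned from the generated
network's true metrics, and variant densities are set per class.

- **Network**: preferential-attachment modules (default 8) joined by sparse
  random bridges. A single preferential-attachment graph makes degree and
  betweenness almost rank-identical, leaving nearly no exclusive HNB/NHB
  members; modularity is both more realistic for interactomes — bottlenecks
  are inter-module bridges — and produces a degree-betweenness rank
  correlation around 0.76 with exclusive classes of ~120 proteins at
  N = 2000. The degree distribution remains scale-free-like (log-log
  R² ≈ 0.9).
- **Variation**: the hub-side classes (HB, HNB) generate non-synonymous
  SNPs at 0.008 per non-synonymous site and the others at 0.012, echoing
  the magnitudes reported for human interactomes without claiming to
  reproduce them. Placement probability at each position is the class
  density times that position's non-synonymous site fraction, so the
  expected count equals density × sites exactly. Because the pipeline
  excludes CpG-context SNPs by default, the generator confines these
  baseline SNPs to non-CpG positions and rescales by (all sites)/(non-CpG
  sites); the dN recovered after exclusion is therefore unbiased at the
  generating density, while separately placed CpG-context decoy SNPs
  (targeting ~10% of all SNPs) give the exclusion filter real work.
- **Domains** cover 30% of each protein in non-overlapping 10–30 aa
  intervals; a depletion scenario multiplies the in-domain non-synonymous
  probability of one class (HNB) by 0.5.
- **Expression** is log-normal FPKM over 15 tissues with a two-fold
  hub-side shift, except in a randomly chosen ~40% "matched" stratum where
  both groups share one distribution — guaranteeing that the K-means
  confound control has a balanced cluster to find.
- **Raw files** distribute the edges across the four dialects (biogrid
  dominant, as in the real databases) with duplicates in both orders and
  decoy rows that every filter must remove; with zero ID-mapping noise the
  parse → map → merge round trip reconstructs the network exactly.

What the generator does **not** emulate: real gene structure (introns,
splicing, UTRs), linkage between variants, ascertainment bias in variant
calling, study-specific interactome size (~15,700 proteins; the default
here is 2000), or duplication-divergence network growth. Passing tests
therefore demonstrate that the pipeline's statistics do what they claim on
data obeying its model assumptions — not that any biological conclusion
about real interactomes is reproduced.

## Numerical and design choices

- **Quantile ties**: exact-size top sets with deterministic tie-breaks
  (betweenness, then ID for hubs; degree, then ID for bottlenecks).
- **Power-law fit**: ordinary least squares on log10 p(k) vs log10 k over
  raw (unbinned) frequencies with p(k) > 0, at least three distinct
  degrees required; maximum-likelihood exponent fitting is out of scope.
- **One-to-many ID mappings** are dropped and counted, never expanded.
- **Stop-codon changes** count as non-synonymous.
- **K-means confound control**: clusters on log10(level + 1) with k = 3 by
  default (k is a parameter; the choice is not critical because the
  matched stratum is found whenever some cluster is expression-balanced),
  selects the cluster with the largest minority-group count among clusters
  whose within-cluster expression comparison has p > 0.05, and reports the
  dN contrast inside it. Median FPKM across tissues is the expression
  level; breadth is the count of tissues with nonzero FPKM.
- **Degenerate inputs**: empty record sets give empty networks; empty
  HNB/NHB sets give rows or replicates flagged undefined, never errors;
  malformed input rows are skipped with warnings and counted.

## Problem sizes used by the tests and acceptance script

The shipped test suite and `scripts/acceptance.R` exercise the pipeline at
sizes chosen for a single-CPU desk run: the standard scenario at 2000
proteins with 200 subsampling replicates per mode; parameter recovery and
the domain-depletion scenario at 500 proteins (≈150 per special class, CDS
100–300 codons); permutation calibration with 500 runs of 500 replicates
on an 80-protein universe; oracle equivalence on 100 random graphs of up
to 25 nodes. Full-scale settings (10,000 randomization replicates, 1000
subsampling replicates) remain the pipeline defaults.

## Worked example

```{r example, eval = FALSE}
library(ppivar)

# 1. write a synthetic input bundle with known ground truth
b <- generateScenario(scenarioConfig(seed = 1), "bundle")

# 2. run the full analysis
cfg <- pipelineConfig(
  interactions = c(biogrid = "bundle/biogrid.tsv", dip = "bundle/dip.tsv",
                   hprd = "bundle/hprd.tsv", intact = "bundle/intact.tsv"),
  idmap = "bundle/idmapping.tsv", cds = "bundle/cds.fasta",
  variants = "bundle/variants.tsv", domains = "bundle/domains.tsv",
  expression = "bundle/expression.tsv", essential = "bundle/essential.txt",
  nPerm = 2000, subsampleReps = 200, seed = 2, outDir = "report")
rep <- runPipeline(cfg)

rep$comparisons$hnb_vs_nhb   # the headline HNB-vs-NHB dN contrast
rep$robustness$nodes         # sign consistency under 80% node subsampling
```

## Known limitations

- The counting dN estimator ignores multiple hits per site; it is the
  appropriate regime for sparse population SNPs, not for divergent
  sequence pairs.
- Betweenness is recomputed exactly per subsampling replicate; very large
  networks (beyond ~10^5 edges × 10^3 replicates) would need approximate
  centrality, which is out of scope.
- Variant input is CDS-relative and single-transcript; genomic coordinates
  and splice-aware projection are the loader's responsibility upstream.
- The uniform-sampling nulls deliberately do not preserve the degree
  sequence; degree-preserving rewiring nulls are a non-goal.
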