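# ppivar

Differential variation of hubs and bottlenecks in protein-protein
interaction (PPI) networks.

## What this package is for

In a PPI network, *hubs* are the proteins in the top quantile (default
20%) of the degree distribution and *bottlenecks* the top quantile of the
betweenness distribution

$$C_B(v) = \sum_{s \ne v \ne t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$

where σ_st counts shortest s–t paths. The two sets overlap strongly, so
the discriminating comparison is between their exclusive members:
hub-non-bottlenecks (HNB) versus non-hub-bottlenecks (NHB). ppivar asks
whether these groups differ in recent sequence variation, measured per
protein as

dN = (non-synonymous SNPs) / (non-synonymous sites),

with non-synonymous sites counted by enumerating all nine single-base
changes of each codon (NG86-style counting), and CpG-context SNPs excluded
by default.

The package provides, as composable functions behind a single pipeline:

- parsers for four interaction-table dialects (biogrid-lite, dip-lite,
  hprd-lite, intact-lite) with source-specific filters, ID mapping and
  merging into one undirected simple network;
- degree, Brandes betweenness (compiled), and a log-log power-law fit of
  the degree distribution;
- the HB/HNB/NHB/NHNB classification with deterministic tie-breaks and a
  5–40% cut-off sweep;
- SNP consequence annotation, CpG filtering and dN computation;
- Spearman/Mann-Whitney/Fisher tests and a K-means expression-matched
  subgroup control;
- a 10,000-replicate domain-SNP randomization test and 80% node/edge
  subsampling robustness analysis, both with counter-derived, stream-stable
  RNG;
- a synthetic-data module that generates complete input bundles (raw
  dialect files, ID map, CDS FASTA, variants, domains, expression,
  essential genes) with known ground truth.

It is aimed at systems-biology analysts who want a tested, reproducible
desk-scale implementation of this analysis, exercised end to end on
synthetic data rather than on any bundled database snapshot.

## Worked example

```r
library(ppivar)

b <- generateScenario(scenarioConfig(seed = 1), "bundle")  # synthetic inputs
cfg <- pipelineConfig(
  interactions = c(biogrid = "bundle/biogrid.tsv", dip = "bundle/dip.tsv",
                   hprd = "bundle/hprd.tsv", intact = "bundle/intact.tsv"),
  idmap = "bundle/idmapping.tsv", cds = "bundle/cds.fasta",
  variants = "bundle/variants.tsv", domains = "bundle/domains.tsv",
  expression = "bundle/expression.tsv", essential = "bundle/essential.txt",
  nPerm = 2000, subsampleReps = 200, seed = 2, outDir = "report")
rep <- runPipeline(cfg)

rep$comparisons$hnb_vs_nhb
```

On the default scenario (2000 proteins, hub-side generating density 0.008
vs 0.012 per non-synonymous site) this prints:

```
$defined
[1] TRUE
$n1
[1] 123
$n2
[1] 123
$median1
[1] 0.006711409
$median2
[1] 0.01206434
$u
[1] 3493
$p
[1] 2.980931e-13
```

i.e. 123 hub-non-bottlenecks with median dN ≈ 0.0067 versus 123
non-hub-bottlenecks at ≈ 0.0121 — the generated "hubs vary more slowly"
effect, recovered from raw files through the whole chain, with a two-sided
Mann-Whitney p ≈ 3×10⁻¹³. `rep$robustness` reports that the sign of the
difference survives all 200 node- and edge-subsampling replicates
(sign consistency 1.0), and `rep$sweep` rechecks the contrast at cut-offs
from 5% to 40%. A thin shell interface for the two common entry points
(simulate a bundle, run the full analysis) is in
`inst/scripts/run-analysis.R`.

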