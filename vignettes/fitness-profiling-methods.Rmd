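---
title: "Methods: Tn-seq conditional fitness profiling with tnprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tn-seq conditional fitness profiling with tnprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnprof)
```

## The measurement model

A dense transposon library is a population of mutant lineages, one per
unique insertion site. Sequencing the insertion junctions before and
after growth yields, for each site, a read count proportional to the
lineage's abundance. Aggregating sites over gene intervals gives each
gene's share `N` of all mapped reads in a sample. If the population
expands `d = 2^g`-fold over `g` generations while mutants of a gene
expand `d^w`-fold, the gene's relative fitness `w` is estimated by

```
W = ln(N_t2 * d / N_t1) / ln((1 - N_t2) * d / (1 - N_t1))
```

where `t1` is the reference (input library after one generation of
untreated outgrowth) and `t2` the selected sample. The numerator is the
gene's log fold-expansion; the denominator is the log fold-expansion of
everything else, which plays the role of the neutral reference. The
estimator has three useful exact properties, all under test:

* **neutral identity** — `N_t2 = N_t1` gives `W = 1` for any proportion
  in (0, 1) (machine-exact to 1e-12);
* **zero point** — a lineage depleted by the full factor `d`
  (`N_t2 = N_t1 / d`) gives `W = 0` exactly;
* **rare-gene consistency** — for `N_t1 -> 0`, `W -> w` when the gene's
  lineages truly expand as `d^w` among a reference expanding as `d`
  (checked at `N_t1 = 1e-5` to 1e-3).

Its assumptions: selection is exponential and constant over the window;
the non-mutant bulk is effectively neutral (true when most genes have no
phenotype in a given condition — see "Estimator bias" below); and read
counts are multinomial draws from lineage abundances (no bottleneck, no
amplification jackpots).

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_reads` | 2 | reads/site | unique insertions supported by a single read are treated as junction noise and dropped |
| `generations` | 10 | doublings | selective window between the 1-generation reference and an 11-generation selected culture; `d = 1024` |
| `denominator` | `"all"` | — | gene proportions are shares of *all* filtered reads, intergenic included; `"genic"` offered for sensitivity analysis |
| strong band | 0.75 / 1.25 | fitness | a strong phenotype is `W` below/above this in ≥ 1 condition |
| moderate band | 0.9 / 1.1 | fitness | likewise for moderate; bands are strict inequalities, so a score exactly at a boundary does not trigger |
| clustering | euclidean + complete | — | the defaults of the standard heatmap clustering routines; correlation distance (`1 - r`) offered because profile correlations are the natural similarity for fingerprints |

Replicate handling: reference replicates are pooled by **summing counts
site-wise** before filtering and proportions. For multinomial counts this
is the variance-optimal way to combine replicates, and it is equivalent
to averaging proportions up to per-replicate depth weights. (Averaging
per-gene proportions instead is available by computing proportions per
replicate and averaging outside the pipeline; pooling is the default.)

Zero handling: a gene with reference reads but none after selection has
an undefined log ratio. It receives **one pseudo-read** in its selected
total (the sample total incremented accordingly) and the flag
`pseudocounted`: the reported `W` is then a conservative *lower bound*
magnitude of the defect, not an unbiased estimate. A gene with no
filtered reference reads is `no_data` (`NA`): nothing was there to
deplete. These flags travel with every cell through the matrix, the TSV
round trip and the summaries.

## What the simulator emulates

`simulate_genome()` lays out non-overlapping gamma-length genes on one
contig with a configurable intergenic fraction and essential fraction
(defaults 0.1 and 0.15, the scale of a small actinobacterial genome
where ~15% of genes are essential). `simulate_library()` places distinct
insertion sites uniformly outside essential genes — essential genes are
modelled as *zero insertion sites*, because a real library simply lacks
viable mutants there — and gives each site a log-normal(0, 1) abundance
mass; read counts are one multinomial draw over those masses. The
log-normal skew is a stand-in: the true site-abundance distribution of
real libraries is not published, so it is a parameter (`meanlog`,
`sdlog`), not a claim.

`simulate_selection()` grows each lineage by `2^(w * generations)`
(intergenic lineages at `w = 1`, i.e. the bulk reference) and draws
`depth` reads multinomially from the expanded masses. Counts therefore
sum exactly to the requested depth, composition is preserved in
expectation under neutrality, and doubling the window squares every
lineage's relative expansion — all property-tested.

One modelling decision deserves emphasis. The experiment this emulates
sequences the reference after **1** untreated generation and the
selected culture after **11** treated generations, while the estimator
uses a fixed `2^10` expansion. One neutral generation leaves composition
unchanged, so the simulator draws reference replicates as 1-generation
neutral resamples and applies the designed fitness over the
10-generation *differential* (`generations_t2 - generations_t1`). This
is the dynamics under which the printed estimator is consistent, and it
is the package's reading of what that estimator measures.

What the simulator does **not** emulate: PCR amplification bias and
duplicate reads, positional (e.g. GC or replication-origin) insertion
preferences, within-gene domain structure (the 5′/3′ ends of a gene are
not treated differently — and correspondingly the estimator applies no
terminal-region trimming), cross-condition batch effects, and reads in
multiply-mapping repeats. Passing recovery tests therefore show the
*estimator and pipeline* are correct under the stated sampling model,
not that real libraries satisfy that model.

## Designed recovery conditions

The recovery experiment simulates 2,000 genes, 20,000 sites and 10^6
reads per sample, with designed classes `w ∈ {0, 0.5, 0.9, 1.0, 1.1}`.
Class sizes are 10% of genes per non-neutral class (60% neutral),
mirroring real screens where roughly 40% of genes show some phenotype
across a panel; giving each class hundreds of genes makes class means
stable. The unit suite uses a scaled replica (400 genes, 4,000 sites,
3×10^5 reads) so the default test run stays fast; the full-scale run
lives in the acceptance suite and completes in a few seconds either way.

**Estimator bias.** Because the denominator treats "everything else" as
the neutral reference, designed non-neutral classes shift the whole
scale slightly: with 40% of genes non-neutral the population expansion
is ≈ 2% below `2^10`, and all class means shift up by ≈ +0.01–0.02. This
is a property of the statistic, not a bug, and it vanishes as the
non-neutral fraction shrinks.

**The pseudocount floor.** A fully arrested gene (`w = 0`) is expected
to drop 1024-fold; at 10^6 reads a typical gene (N_t1 ≈ 5×10⁻⁴) then
expects ~0.5 reads after selection. Nearly every such gene is
pseudocounted, and the score floor is approximately
`-ln(depth · N_t1 / 1024) / ln(1024)` ≈ 0.10–0.12. The pipeline
therefore reports `w = 0` genes as strong defects (W ≈ 0.1, flagged
`pseudocounted`) but cannot resolve scores much below ~0.1 at this
depth; recovering the exact zero would need ~100× deeper sequencing of
the selected sample or a smaller pseudocount with worse variance
properties. Classes from 0.5 upward recover within ±0.05 (typically
±0.025) for genes with ≥ 5 sites.

## Numerical and algorithmic choices

* Neutral identity tolerance: 1e-12 relative — the formula is evaluated
  as written, with no rearrangement; deviations are pure floating-point.
* Clustering input rows are sorted lexicographically by gene id before
  agglomeration, and neighbour rankings break correlation ties
  lexicographically, so all orderings are platform-deterministic.
* `NA` cells are imputed to the neutral value 1.0 *only* for clustering
  (absent evidence should not create distance); correlation neighbours
  instead use pairwise-complete cells, because imputing a constant into
  a correlation shrinks it artificially.
* Zero-variance profiles have no defined correlation; under the
  correlation metric they are pinned at the maximal distance 2 with a
  warning rather than dropped.
* Degenerate inputs fail loudly: empty insertion tables (no
  denominator), genes carrying sites without a designed fitness,
  malformed GFF3 coordinates (with the line number), duplicate sites,
  negative counts, incomplete score matrices. Readers never repair
  input silently.
* A single-gene matrix clusters to a singleton tree (no `hclust`
  object) rather than erroring, so pipelines degrade gracefully.
* Ward linkage maps to `ward.D2` (Ward's criterion on squared
  distances), the variant consistent with feeding unsquared distances.

## Reproducibility

Every stochastic function takes an integer seed and restores the RNG
state afterwards (`withr::with_seed`), so library generation, selection
draws and experiment assembly are byte-reproducible. The analysis
pipeline itself is deterministic: rerunning `run_pipeline()` with an
identical configuration reproduces every data output byte for byte
(each output records the package version and a configuration hash; the
one exception is the optional heatmap PDF, whose device embeds a
creation timestamp). Simulated experiment outputs are identical under a
fixed seed.

## Known limitations

* No uncertainty quantification: the score is a point estimate; no
  confidence intervals or significance calls are produced, and
  replicate concordance must be judged by comparing runs.
* Essentiality is an *input* (annotation flag), not inferred from
  insertion saturation.
* The pseudocount floor bounds how deep a depletion can be measured
  (see above); depth, not the estimator, is the binding constraint.
* Condition columns are never clustered or merged — two concentrations
  of one drug stay separate columns — and condition ordering is the
  manifest's, on the view that condition grouping is a presentation
  choice, not an inference.
* Interval aggregation assumes non-overlapping gene models; a read in
  an overlap region would be counted into every covering gene.
```{r demo, eval = FALSE}
# end-to-end demonstration at desk scale
cfg <- simulate_demo(tempfile("demo"), n_genes = 500, n_sites = 5000,
                     depth = 2e5, seed = 1)
res <- run_pipeline(cfg)
glance(res$phenotypes)
autoplot(res$matrix, cluster = res$cluster)
```
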