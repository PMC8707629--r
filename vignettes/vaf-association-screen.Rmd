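---
title: "Screening candidate genes for flax plant-type association from VAF profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate genes for flax plant-type association from VAF profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flaxfta)
library(dplyr)
```

## The problem and the model

Cultivated flax (*Linum usitatissimum* L.) comes in two plant types bred for
different products: fiber flax (tall, little branching, grown for stem bast
fiber) and linseed (grown for seed oil). `flaxfta` screens a candidate-gene
panel — 424 genes from the lignin, chitinase-like (CTL), β-galactosidase
(BGAL), ABC-transporter/heavy-metal-associated (ABC/HMA), lignan, tubulin,
cellulose-synthase (CESA), rhamnogalacturonan-lyase (RGL), fatty-acid and
actin families — for polymorphisms whose allelic state separates the two
types across a cohort of varieties.

The key modelling choice is to work with the **variant allele frequency**
(VAF), the per-variety fraction of reads supporting the alternate allele at
a site, rather than with called genotypes. The cohorts this screen targets
are sequenced at low effective coverage (about 7× after duplicate marking),
where hard genotype calls are unreliable but the read-level allele balance
still carries the signal; flax varieties are inbred lines of a largely
self-pollinating species, so true VAFs concentrate near 0 and 1 and the VAF
is close to a noisy genotype dosage.

For each variant the screen computes, over the samples with at least one
read at the site (pairwise-complete; the missing-data rule is ours, as the
upstream convention is unstated):

* Spearman's \(r_s\), Pearson's \(r_p\) and Kendall's \(\tau_b\) between the
  VAF vector and the binary type label (linseed = 0, fiber = 1);
* a two-sided Mann–Whitney U test between the two groups' VAFs — exact by
  enumeration when both groups have ≤ 25 samples and the data are tie-free,
  otherwise the normal approximation with tie correction;
* Benjamini–Hochberg adjusted q-values, per statistic, across all tested
  variants of the panel (a per-gene scope is available via
  `screen_config(bh_scope = "gene")`).

A polymorphism is called **flax type-associated (FTA)** when
\(|r_s| \ge 0.4\), and *very strong* at \(|r_s| \ge 0.6\); both thresholds
are inclusive and the call depends on the coefficient only. Since the
classification uses \(|r_s|\), swapping the 0/1 coding of the types changes
the sign of every coefficient but no FTA call — a property the test suite
asserts. q-values are reported alongside but deliberately do not gate the
FTA call; with ~190 samples, \(|r_s| = 0.4\) corresponds to a tiny p-value
anyway (the null standard deviation of \(r_s\) is about
\(1/\sqrt{190} \approx 0.07\)).

Undefined statistics are flagged, not silently dropped: variants whose VAF
has zero variance get `status = "undefined"` (no test is run and they are
excluded from FTA calls and from the BH input), and variants with fewer than
`min_informative_samples` (default 10) informative samples, or only one
class among them, get `status = "untestable"`.

## Upstream filters and the census

Two rules come before the statistics:

* **Read support.** A record is kept if its alternate allele has ≥ 4
  supporting reads in at least one sample (`filter_supported()`), a rule
  tuned to ~7× coverage; VAF plays no role here. The filter is monotone in
  the threshold.
* **Gene regions.** A variant belongs to a gene when its position falls in
  the gene body extended by 500 bp on each side, under half-open interval
  arithmetic; a variant inside two genes' regions counts for both (the
  per-gene analyses are independent and no deduplication rule is imposed).

`census_polymorphisms()` reports per-gene counts and densities per kb of
analyzed region, whose length is gene length + 1000 bp (both flanks).
Multiallelic sites are decomposed into one record per alternate allele,
sharing the site depth, so censuses count alleles, not VCF lines — the
choice is documented here because printed per-gene counts elsewhere may use
either convention.

## Variety clustering

`vaf_distance()` embeds each variety as its VAF profile across variants and
takes Euclidean distances. Missing VAFs are handled pairwise-complete with
rescaling, \(d = \sqrt{(D/m_\text{used}) \cdot m_\text{total}}\): the mean
squared difference over mutually observed variants is extrapolated to the
full profile length, so pairs with different coverage remain comparable. A
zero-imputation mode is available; at 7× depth about 0.1 % of entries are
missing per variety pair, so the two modes rarely disagree. A sample pair
with no mutually observed variants is an error, not a guess.

`ward_cluster()` applies Ward's minimum-variance method in its `ward.D2`
form (squared dissimilarities inside the Lance–Williams update) via
`stats::hclust`. The test suite checks it against a naive oracle that
recomputes cluster means at every step, on all instances with n ≤ 10.
`similarity_from_distance()` defines the similarity view as
\(1 - d/\max(d)\) so the similarity heatmap and the dendrogram share one
geometry; the transform is recorded in an attribute and is pluggable.
`cluster_composition()` needs an explicit `k` — reading cluster composition
off a dendrogram is a judgement call, and the report makes no claim to
reproduce any particular visual cut.

## Expression preprocessing

The companion module reproduces the standard heatmap pipeline for
tissue-panel RNA-seq counts over the same 424 genes: CPM normalization by
total mapped reads per sample (`cpm_normalize()`, via `edgeR::cpm`; library
sizes default to panel column sums when genome-wide totals are not
supplied), flagging of genes with CPM < 10 in **every** sample
(`flag_low_expression()`), `log2(CPM + 1)` with per-gene mean-centering
(`log2_center()`; the pseudocount of 1 keeps zeros at zero and is our
choice where the upstream convention is silent), optional tissue-mean
aggregation before centering (`tissue_aggregate()`, against a controlled
tissue vocabulary including the stem-dissection tissues cPAR, iFIB, tFIB
and sXYL), and Euclidean/ward.D2 clustering of genes and tissues
(`cluster_heatmap()`). Both per-sample and per-tissue heatmap modes exist
because published panels are shown per tissue without stating the
aggregation.

## The synthetic cohort generator

`simulate_cohort()` generates the study design the screen assumes, with
truth tables for recovery tests. Its defaults are fixed once and encode the
target design:

* 79 fiber + 112 linseed varieties; mean sequencing depth 7
  (Poisson-distributed per site and sample).
* The packaged 424-gene panel, with a synthetic but realistic layout
  (15 chromosomes, gene lengths 1–5 kb, 10 kb spacing).
* `inbreeding = 1`: genotypes are drawn as homozygotes
  (2·Bernoulli(p) alt copies), reflecting inbred lines of a
  self-pollinating crop — the varieties' true heterozygosity is not a
  documented quantity, so this default is a modelling choice and can be
  relaxed toward Hardy–Weinberg draws.
* `frac_associated_genes = 0.34`: roughly a third of panel genes carry
  associated variants, the order of magnitude such screens report.
* `delta = 0.8`: associated variants differ between the group allele
  frequencies by 0.8 — strongly differentiated, as expected for loci under
  divergent selection between the two breeding pools.
* Null allele frequencies from a U-shaped Beta(0.8, 0.8) rescaled to
  [0.02, 0.98], the spectrum of ascertained polymorphic sites.
* `variants_per_gene` Poisson with mean 12 and a 10 % indel fraction — a
  desk-scale density (≈ 5,000 variants panel-wide) chosen so full-cohort
  analyses run in seconds; real panels can be denser, which only adds
  more rows of the same structure.
* `base_error = 0.005` per-read miscall probability.

Read support follows `depth ~ Poisson(7)` and
`alt reads ~ Binomial(depth, g/2·(1−e) + (1−g/2)·e)`. Variants are
independent: no linkage disequilibrium is simulated (v1 limitation), no
population substructure within a type, and no mapping artefacts — so
passing recovery tests demonstrates the statistical machinery, not
robustness to the full messiness of resequencing data.

`simulate_expression()` draws negative-binomial counts (dispersion 0.1)
around log-normal baseline abundances, with 20 % of genes designated tissue
markers at a 50-fold elevation in one tissue and log-normal library sizes
around 2 × 10⁶ reads.

## Numerical choices and edge cases

* Internal coordinates are 0-based half-open; VCF I/O converts from/to
  1-based, BED panels are taken as-is.
* Depths are read from `AD` when present, else `AO`/`RO`; a VCF without
  either errors out naming the first site. Genotype fields are ignored.
* Spearman p-values use the t-approximation (ties are ubiquitous in binary
  labels, ruling out the exact null distribution); Kendall is tau-b with
  tie correction.
* `adjust_bh()` errors on p-values outside [0, 1]; `NA`s pass through
  without counting toward the number of tests.
* Ward agglomeration inherits `hclust`'s deterministic tie handling;
  distances must be finite.
* An all-zero distance matrix yields the identity similarity with a
  warning; an empty panel file yields an empty panel with a warning;
  `k` outside [1, n] and unknown tissue labels are errors that name the
  offender.

## Problem sizes in the tests

The test suite and the acceptance script run the full 191-variety design at
reduced panel sizes (36–106 genes, i.e. 400–1,300 variants) and verify the
statistics against brute-force oracles at ≤ 10 samples, where enumeration
is exact. These sizes are the package's own test-design choice: every
property asserted (oracle equality, full recovery at delta = 1, null rates,
purity) is size-stable, and the full panel runs the same code path — a
complete 424-gene, 191-variety screen takes under a minute.

## Known limitations

* No LD, kinship or population-structure correction — the screen is a
  marginal per-variant analysis by design, and its FTA calls are
  correlates, not causal claims.
* The packaged panel's coordinates are synthetic; real analyses must supply
  genome coordinates in the BED panel.
* The similarity metric and missing-VAF rescaling are internal conventions
  (documented above), not community standards; both are switchable.
* Expression library sizes computed from panel counts understate true
  totals; supply genome-wide mapped-read counts when available.
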