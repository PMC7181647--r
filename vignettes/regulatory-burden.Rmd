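---
title: "Burden testing of non-coding regulatory mutations with reburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burden testing of non-coding regulatory mutations with reburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reburden)
```

## The problem

Most somatic mutations in a tumor genome fall outside protein-coding
exons, and a fraction of them land in active promoters and enhancers,
where a single base change can rewire the expression of a target gene.
Deciding whether a regulatory element (RE) is mutated *more often than
chance would allow* is harder than it is for genes: mutation rates vary
by orders of magnitude between tumors, so a recurrence count that is
remarkable in a quiet cohort is unremarkable in a hypermutated one.

`reburden` implements a cohort-level burden test for regulatory
elements, the machinery to group elements into gene-wise collections,
and the downstream readouts (expression fold changes, TF-binding-site
enrichment, super-enhancer gene enrichment) that turn a significant
element into a biological hypothesis.

## The burden model

Index tumors by $k$ and regulatory elements by $i$. Each tumor
contributes a global background rate

$$p_k = \frac{n_k}{n_{cov}},$$

the ratio of its filtered non-coding SNV count to the total width of
the H3K27ac-positive ("covered") regions. For an element of width
$n_i$ bp, the chance that tumor $k$ hits it at least once under a
uniform per-bp model is

$$q_{ik} = 1 - (1 - p_k)^{n_i},$$

so the number of tumors with at least one SNV in element $i$,

$$X_i \sim \mathrm{PoissonBinomial}\left(q_{i1}, \dots, q_{iK}\right),$$

and the element's p-value is the exact upper tail
$P(X_i \ge s_i)$ at the observed mutated-tumor count $s_i$. P-values
are Benjamini–Hochberg adjusted across elements and the frequently
mutated regulatory elements (FMREs) are those with $q \le$ the chosen
FDR (0.25 by default, with 0.10 as the conventional stricter flag).

Gene-level testing is identical after pooling: all elements associated
with a gene (its CREAG, plus an annotated promoter when one is
supplied) are concatenated into a pseudo-element of width
$n_j = \sum_i n_i$, and $s_j$ counts tumors mutated in *any* member —
a tumor hitting two members still counts once.

The Poisson-binomial distribution is computed exactly by the iterative
convolution dynamic program over samples ($O(K^2)$), not by a
characteristic-function transform: at cohort sizes of a few hundred the
exact method costs milliseconds and is verified in the test suite
against exhaustive $2^n$ enumeration. Tails are accumulated from the
largest count downward so that tiny terms are added first; `s = 0`
returns exactly 1; hit probabilities use `expm1`/`log1p` so that
per-bp rates of $10^{-6}$ do not lose precision.

### The numerator/denominator convention

The background-rate formula leaves open whether $n_k$ counts all
non-coding SNVs genome-wide or only those inside the covered regions
that form the denominator. The package defaults to the self-consistent
reading — numerator restricted to the covered regions
(`sample_snv_counts(mode = "covered")`) — and exposes
`mode = "global"` for the looser one. Under the restricted mode the
null simulation is exactly the model the test assumes, which is what
makes the calibration experiments below meaningful.

## Mapping elements to genes

Enhancer–gene pairs are scored by the one-sided Spearman correlation of
H3K27ac activity against expression (CPM) across samples, and retained
when all four gates hold:

* $\rho > 0.4$;
* one-sided $P < 0.05$ (positive association only);
* distance $< 500$ kb, measured RE midpoint to gene start
  (strand-agnostic — the least surprising anchor choice, and recorded
  per pair for audit);
* same TAD, required of *both* anchors: the RE midpoint and the gene
  start must fall inside one common TAD interval. Features outside all
  TADs are ineligible. Requiring both anchors is the unambiguous choice
  when a feature spans a boundary.

For $n \le 8$ samples the Spearman p-value is exact (all $n!$ rank
permutations, midranks for ties); above that the usual
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation applies — at the
package's intended cohort sizes (around 20 paired samples) this is the
standard regime. The pseudo-element width sums raw member widths, as
the gene-level model defines it; `merge_overlaps = TRUE` gives the
union-width alternative for users who prefer double-counted bases
removed.

## What the synthetic cohorts emulate

Every statistical claim in the package is exercised on generated
cohorts (`simulate_cohort()`), whose defaults were fixed once as the
package's study conditions:

* 50 tumors, 2 chromosomes × 5 Mb, 10 TADs tiling the chromosomes;
* 500 REs of mean width 1 kb placed without overlap inside TADs
  (~5% genome coverage), 40 genes;
* per-tumor background rates drawn uniformly from
  $[10^{-5}, 10^{-3}]$ per bp — over the ~0.5 Mb covered toy genome
  this spans per-tumor SNV counts from a handful to several hundred,
  the same several-orders-of-magnitude spread real whole-genome
  cohorts show;
* optional "hot" elements whose per-bp rate is multiplied (default
  ×20) — the alternative hypothesis for power checks;
* for each gene, planted cognate REs (2 per gene by default) whose
  activity shares a latent per-sample factor with the gene's
  expression: gene latent $l + \varepsilon$, RE latent
  $w\,l + \varepsilon'$ with linkage $w = 0.9$ and noise sd 0.3 by
  default. Latents are exponentiated (lognormal marginals), which is
  immaterial to rank-based association but keeps signal matrices
  non-negative.

Mutations are realized as Poisson counts per (element, tumor) at rate
width × $p_k$ × multiplier, placed uniformly with collisions redrawn —
at these rates this is the per-bp Bernoulli model to numerical
accuracy, at linear cost. All stages draw from named substreams of a
single master seed, so adding a stage never silently shifts another
stage's output, and every output is a pure function of the
configuration.

What the generator does *not* emulate: trinucleotide signature bias,
regional covariates of mutation rate (replication timing, chromatin
state), copy-number and structural events, and correlated RE activity
beyond the planted pairs. Passing the calibration and recovery suites
therefore shows the statistics are correct *under the stated model*,
not that real tumor cohorts satisfy that model; on real data the
uniform-rate null is known to be liberal in late-replicating regions,
which is why a permissive FDR with downstream functional follow-up is
the intended operating point.

## Calibration and power, as run in the tests

The acceptance suite (deterministic seeds, run on every check) performs:

* **Null calibration** — 20 cohorts with no hot elements: the empirical
  fraction of burden p-values at or below $\alpha \in \{0.01, 0.05\}$
  must sit within $3\sqrt{\alpha(1-\alpha)/500}$ of $\alpha$ (the
  Monte-Carlo standard error at 500 elements). With 50 tumors the test
  statistic is discrete (support $\{0..50\}$), so attained levels sit
  slightly *below* $\alpha$ — the band accommodates exactly this
  conservatism, and no finer band is attainable by any exact discrete
  test. The mean false-discovery proportion of BH at FDR 0.25 (under
  the global null, 1 whenever anything is called) must stay at or
  below 0.25.
* **Spike recovery** — 5 hot elements at multiplier 20 among 500 must
  all rank in the top 10 p-values in at least 95% of 20 replicates.
* **Mapping recovery** — with 20 samples, linkage 0.9 and noise 0.3
  (100 REs, 40 genes), the retained associations must recover planted
  pairs with precision and recall ≥ 0.8 under the standard four gates.
  The element/gene counts here were chosen as a realistic per-TAD
  density (4 genes and 10 elements per TAD); denser layouts dilute
  precision simply because the number of null pairs grows
  quadratically while true pairs grow linearly — the same trade-off a
  real cohort faces.

Problem sizes in these experiments (500 elements, 50 tumors, 20
replicates) are the package's chosen study conditions; they keep each
suite in the tens of seconds while leaving the Monte-Carlo error well
below the tested margins.

## Downstream readouts

* **Expression association** (`mutation_expression_scan()`): for each
  gene/unit pair with ≥ 2 mutated samples, the fold change is the ratio
  of median expression in mutated vs wild-type samples, with a
  two-sided rank-sum p (exact for combined n ≤ 20 without ties). Calls
  are directional at FC > 2 / FC < 0.5; a zero wild-type median is
  skipped and logged rather than patched with a pseudocount, because a
  pseudocount would change exactly those records the guard affects.
  The global over/under skew is tested by an exact two-sided sign test
  (`skew_test()`); both the per-gene and the global p-values are
  reported separately so either reading of "binomial p < 0.05" is
  auditable.
* **TF-binding-site enrichment** (`tfbs_enrichment()`): observed =
  sites carrying ≥ 1 SNV; expected = $\sum_i [1 - \prod_k (1-q_{ik})]$
  under the same background model; FC = observed/expected; the p-value
  is the Poisson-binomial upper tail over the per-site probabilities.
  This site-level null is the package's own definition — one documented
  null model shared with the element test, with sites as units — and is
  labelled as such in the output metadata.
* **Super-enhancer assignment** (`assign_se_genes()`): each SE goes to
  the highest expressed overlapping gene (mean CPM across samples;
  missing expression counts as zero, ties break lexicographically and
  are logged). Enrichment of SE-associated genes near the top of the
  gene-level burden ranking uses the unweighted Kolmogorov–Smirnov
  running-sum statistic with label permutation and the add-one
  permutation p-value $(1 + \#\{perm \ge obs\})/(1 + N)$, which can
  never be 0 nor exceed 1. SE *calling* is deliberately an input, not a
  computation.

## Numerical and design notes

* All coordinates are 0-based half-open everywhere (BED convention);
  VCF positions convert on ingest; abutting intervals never overlap.
  Chromosome labels compare as exact strings; `normalize_chroms()` is
  the explicit escape hatch, because silent "chr1" vs "1" mismatches
  are the dominant interval bug in practice.
* Duplicate SNV records (same sample, position, alt) are dropped on
  load with a warning — burden counts samples, not records. A position
  carrying different alternate alleles in different samples counts once
  per record in the multiplicity table, which is what makes its two
  conservation identities exact.
* BH adjustment delegates to `stats::p.adjust`; the step-up formula is
  re-verified against a hand implementation in the tests.
* p-values are reported at full double precision with no flooring, so
  QQ plots of the burden ranking reflect the raw tail.
* The pipeline writes no timestamps into outputs; a rerun with the same
  inputs, thresholds and seed is byte-identical, and the JSON manifest
  records input checksums, thresholds and the package version.

## Known limitations

The background model is uniform within the covered regions and global
per tumor; covariate-adjusted rates (expression-coupled, replication
timing) are out of scope. Burden is SNV-only — indels and structural
events are not modeled. The TAD gate treats boundary-spanning features
as ineligible rather than ambiguous. Whether per-histotype cohorts
should use pooled or cohort-specific rates is left to the caller: rates
are always computed within whichever sample set is passed.
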