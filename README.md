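# reburden

Mutational burden testing of non-coding regulatory elements in tumor
cohorts.

Whole-genome sequenced tumors carry thousands of somatic single
nucleotide variants (SNVs), the vast majority outside coding exons.
Some of those land in active promoters and enhancers and deregulate
target genes. `reburden` asks, for every regulatory element (RE) in a
cohort, whether the number of tumors carrying at least one SNV in the
element exceeds what the cohort's background mutation rates predict —
and then connects significant elements to genes and expression
consequences. It is written for cancer-genomics analysts working with
H3K27ac-defined regulatory maps, somatic SNV calls, and matched
expression data.

## The model

Each tumor $k$ gets an empirical background rate
$p_k = n_k / n_{cov}$: its filtered non-coding SNV count over the
total width of the H3K27ac-positive regions. For an element of width
$n_i$, tumor $k$ hits it with probability
$q_{ik} = 1 - (1 - p_k)^{n_i}$, so the mutated-tumor count follows a
Poisson-binomial distribution and the element's p-value is the exact
upper tail $P(X_i \ge s_i)$, computed by convolution (no
approximation), then Benjamini–Hochberg adjusted. Elements passing
FDR ≤ 0.25 are flagged as frequently mutated REs (FMREs). Gene-level
collections of correlated elements (CREAGs — elements whose activity
correlates with the gene's expression at Spearman ρ > 0.4, one-sided
P < 0.05, within 500 kb and a shared TAD) are tested the same way
after concatenating member widths into a pseudo-element.

Downstream modules quantify expression fold change by mutation status
(median ratio, rank-sum test, over/under skew sign test),
TF-binding-site mutation enrichment (observed/expected under the same
background model), and super-enhancer gene enrichment along the burden
ranking (unweighted running-sum statistic with label permutation).
A fully seeded synthetic-cohort generator provides the null and
spike-in conditions every statistical claim is tested under.

## Worked example

Simulate a 50-tumor cohort with two "hot" elements mutating at 20× the
background rate, and test every element:

```r
library(reburden)

cfg <- cohort_config(hot_res = setNames(rep(20, 2), c("RE_1", "RE_2")),
                     seed = 11)
co  <- simulate_cohort(cfg)
burden <- cohort_burden(co, fdr = 0.25)
head(burden, 5)
#>   unit_id  s    n  p_value  q_value  fmre
#> 1    RE_1 47  717 1.99e-23 9.93e-21  TRUE
#> 2    RE_2 49 1024 1.99e-21 4.97e-19  TRUE
#> 3  RE_294 19  487 9.95e-03 1.00e+00 FALSE
#> 4  RE_166 29 1078 1.35e-02 1.00e+00 FALSE
#> 5  RE_372 21  598 1.39e-02 1.00e+00 FALSE
```

Both planted hot elements are recovered — `RE_1` is 717 bp wide, was
mutated in 47 of 50 tumors (`s`), and its exact Poisson-binomial tail
p-value of 2.0e-23 survives BH adjustment (`q`), while the best cold
element (p ≈ 0.01) does not. Mapping elements to genes and summarizing
the catalog:

```r
cm <- build_creags(co$layout$res, co$re_signal, co$layout$genes,
                   co$gene_expr, co$layout$tads)
creag_summary(cm$creags, cm$associations)
#> $n_associations       80
#> $n_genes              40
#> $n_res                80
#> $median_res_per_creag  2
#> $mean_genes_per_re     1
```

All 40 genes acquire a CREAG with a median of 2 associated elements —
matching the 2 cognate elements the generator plants per gene.
On-disk workflows use the same machinery through
`run_pipeline(input_dir, out_dir)` (TSV/BED in, TSV + JSON manifest
out; byte-identical on rerun), or the thin CLI at
`inst/scripts/reburden` (`simulate`, `run`, `report` subcommands).

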