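# dexbg — background-aware differential expression and polyadenylation for RNA-seq

Reads assigned to a gene's exons are not all transcription: a fraction comes
from sequencing error and misalignment. `dexbg` measures that background
directly — from counts over matched non-exonic regions — and models the
observed exonic count of each gene as

```
X = S + B,    S ~ NB(r, p),    B ~ Poisson(λ)
```

so that `X` follows a Delaporte (negative binomial ⊕ Poisson convolution)
distribution with gamma shape `α = r`, gamma scale `β = 1/p − 1`, and
background mean `λ`. Differential expression between two groups is then
tested against a null that *includes each group's measured background*,
instead of attributing background reads to biology.

The package is aimed at bulk (and small single-cell) RNA-seq analyses where
a background annotation is available, and at methodologists who want a
controlled simulation and benchmarking harness for count-based tests.

It provides:

* the Delaporte distribution: `ddelap()`, `pdelap()`, `rdelap()`,
  `delap_to_nb()`;
* per-gene estimation: moment-based (`estimate_params_np()`, default) and
  maximum likelihood via BFGS (`estimate_params_mle()`), plus
  median-of-ratios `estimate_size_factors()`;
* differential expression: a moderated conditional exact test
  (`delap_exact_test()`) for moderate pooled counts and a fast
  beta-distribution approximation (`beta_approx_test()`) for large ones,
  wired together by the fitting function `dexbg()` (S3 object with `print`,
  `summary`, `coef`, `plot`, `simulate` methods), with BH adjustment and the
  standard reporting filter `filter_de()`;
* differential alternative polyadenylation: length-normalized short/long
  isoform ratios (`mM_ratio()`), ratio-of-ratios effect sizes, pairwise
  Fisher exact tests combined by Fisher's method (`apa_test()`,
  `filter_apa()`);
* read summarization from SAM/BAM over GTF/BED annotations with
  ambiguous-read exclusion (`count_reads()`, `count_matrix()`,
  `count_apa()`);
* a simulation engine and benchmark harness (`simulate_experiment()`,
  `run_benchmark()`) measuring ROC AUC, false discoveries among top-ranked
  genes, and statistical power, overall and by expression stratum.

A command-line front end over the same functions ships at
`inst/cli/dexbg.R` with subcommands `count`, `detest`, `apa`, `simulate`,
`benchmark`.

## Worked example

Count the packaged toy alignment over its two-gene annotation:

```r
library(dexbg)
ann <- read_annotation(system.file("extdata", "genes.gtf", package = "dexbg"))
count_reads(system.file("extdata", "reads.sam", package = "dexbg"), ann)
#> geneA geneB
#>     2     0
#> attr(,"ambiguous")
#> [1] 1
#> attr(,"unassigned")
#> [1] 4
#> attr(,"eligible")
#> [1] 7
```

Two reads fall inside `geneA`'s exon union; one read overlaps exons of both
genes and is discarded as ambiguous; four eligible reads overlap no exon;
one unmapped record is never eligible. Assigned + ambiguous + unassigned
always equals the eligible total.

Simulate a two-group experiment (500 genes, 10% differentially expressed at
1.5-fold, 3 samples per group, measured background) and test it:

```r
sim <- simulate_experiment(sim_config(n_genes = 500, seed = 42))
fit <- dexbg(sim$X, sim$B, sim$groups)
fit
#> Background-aware differential expression fit
#>   500 genes, 3 + 3 samples (cond1 vs cond2)
#>   estimation: np; big_count = 900
#>   test routing: beta=269, exact=231
#>   genes with padj < 0.1: 197
head(de_results(fit)[order(de_results(fit)$pval), c(1:3, 5:8)], 3)
#>     gene_id mean_A mean_B log2fc      pval      padj test
#> 405 gene405   3203   5958  0.896 1.00e-320 5.00e-318 beta
#> 440 gene440   2982   1634 -0.868 7.49e-266 1.87e-263 beta
#> 448 gene448  12900  10113 -0.351 1.54e-219 2.56e-217 beta
roc_auc(de_results(fit)$pval, sim$de)
#> [1] 0.706
```

Genes whose pooled count exceeds `big_count` are routed to the beta
approximation (its p-values are a clamped density statistic — extremely
small values are routing artifacts of that printed form, useful for ranking;
see the vignette's calibration notes), the rest to the exact enumeration.
`filter_de(fit)` applies the standard reporting rules (two-sided fold change
≥ 1.5, expression above the median, adjusted p < 0.1), and
`roc_auc()` scores the ranking against the simulation's ground truth.

## Documentation

The methods vignette (`vignettes/background-aware-de.Rmd`) describes the
model, both estimators, both tests and their calibration, the APA
procedure, the simulation design and its deliberate simplifications, and
all numerical conventions. Every exported function carries roxygen
documentation with examples.
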