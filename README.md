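# wheatTriads

Bread wheat (*Triticum aestivum*) is a recent allohexaploid: two
hybridization + whole-genome-duplication steps combined the A, B and D
subgenomes, and most genes now exist as **triads** — one homoeologous copy
per subgenome. The gene balance hypothesis predicts that dosage-sensitive
genes such as transcription factors (TFs) resist the gene loss
(fractionation) that follows polyploidization. `wheatTriads` implements a
full analysis pipeline for testing that prediction and its corollaries,
plus a synthetic-study generator so every stage can be exercised and
parameter-recovery tested without any external downloads.

The pipeline covers:

- **Homoeolog group classification** from homoeology tables in two
  dialects (pairwise Biomart-style `one2one` rows for hexaploid;
  per-group rows with `singleton` / `hit2homolog` labels for tetraploid),
  giving diads (A:B 1:1) and triads (A:B:D 1:1:1).
- **Per-family retention** with Fisher's exact enrichment tests
  (Benjamini–Hochberg corrected) and the loss-adjusted **normalized
  retention**:

  `normalized % in triads = 100 × (% genes in triads in hexaploid) / (% genes in diads in tetraploid)`

  i.e. the share of *potential* triads actually formed — a family with
  60% triads but only 80% surviving diads scores 75%.
- **Tandem duplication detection** from gene-order adjacency: gene
  identifiers increase by 100 between adjacent genes, and same-family
  genes within ±k positions (k = 1, 2, 3) are chained into clusters; a
  cluster of m genes counts m − 1 duplication events. Family-level tandem
  rates and log median expression are regressed on triad retention.
- **Homoeolog expression divergence**: triads filtered at > 0.5 tpm
  (replicate means), per-tissue expression normalized to sum to 1 across
  the three homoeologs, and the standard deviation of those fractions
  compared between TF and non-TF triads per tissue (Mann–Whitney).
- **Homoeolog coexpression**: pairwise Pearson correlation (A–B, B–D,
  A–D) across tissues, aggregated with a Fisher z-transform median, plus
  coexpression-network module co-membership (module 0 excluded) with a
  Fisher test.
- **Cohort mutation load**: an eight-stage SNP filter cascade (canonical
  CDS, splice overlaps, SIFT availability, > 25% missingness, MAF ≥ 0.01,
  expression, selection/introgression regions, multi-annotated synonymous
  sites), SIFT-based effect classes (score ≤ 0.05 = deleterious), per-site
  nucleotide diversity π = 2j(n−j)/(n(n−1)), per-individual
  homozygous-alternate load per kb of canonical transcript, 2.5%-tail
  extreme-individual flagging, per-family SNP effect proportions, and
  ANOVA + Tukey contrasts of TF vs non-TF loads.

## Worked example

```r
library(wheatTriads)

cfg <- sim_config(n_groups = 10000, n_individuals = 200, seed = 1)
res <- run_pipeline(cfg)
print(res$headline, n = 20)
#> # A tibble: 20 x 2
#>    metric                                  value
#>    <chr>                                   <dbl>
#>  1 pct_tf_diploid_A                        5.99
#>  2 pct_tf_diploid_D                        5.99
#>  3 pct_tf_hexaploid                        6.73
#>  4 pct_tf_tetraploid                       6.39
#>  5 pct_tf_genes_in_triads                 79.4
#>  6 pct_nontf_genes_in_triads              73.6
#>  7 pct_tf_genes_in_diads                  90.1
#>  8 pct_nontf_genes_in_diads               82.2
#>  9 normalized_retention_nontf             89.6
#> 10 r2_tandem_vs_triads                     0.607
#> 11 r2_log_expression_vs_triads             0.829
#> 12 median_r_tf                             0.911
#> 13 median_r_nontf                          0.911
#> 14 pct_comembership_tf                    37.3
#> 15 pct_comembership_nontf                 28.2
#> 16 pct_load_deficit_deleterious_missense  21.2
#> 17 pct_load_deficit_stop_gained           -1.97
#> 18 pct_load_deficit_synonymous            16.0
#> 19 pct_load_deficit_tolerated_missense   -11.9
#> 20 anova_f_group                         170.
```

Reading the output: the TF share of the gene complement rises with each
polyploidization step because TF homoeolog groups are retained complete
more often (here ~79% of TF genes sit in triads vs ~74% of non-TF genes,
reflecting the generator's configured retention probabilities). Tandem
duplication and expression level both explain family-level retention
(`r2_*` rows, over families with more than 10 triads). Homoeolog
coexpression is high for both groups, TF triads share coexpression
modules more often (37.3% vs 28.2%), and TF genes carry fewer homozygous
deleterious missense mutations per kb than non-TF genes (at this single
seed the point estimate is 21% against a configured 32% deficit — the
per-seed spread of this heavy-tailed statistic is wide, which is why the
acceptance suite averages it over seeds).

`normalized_retention()` works directly on printed percentages:

```r
normalized_retention(60, 80)
#> [1] 75
round(normalized_retention(51.0, 74.5), 1)   # NAC family
#> [1] 68.5
```

A thin command-line wrapper with `simulate` / `retention` / `tandem` /
`expression` / `variants` / `all` subcommands is installed at
`inst/cli/wheattriads.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wheattriads.R", package="wheatTriads"))')" all --seed 1 --outdir out
```

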