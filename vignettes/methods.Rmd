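---
title: "Models and methods behind wheatTriads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheatTriads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatTriads)
```

## The scientific setting

Bread wheat is an allohexaploid assembled in two steps: a tetraploid
(AABB) formed by hybridization and whole-genome duplication roughly 0.4
million years ago, and the hexaploid (AABBDD) formed about ten thousand
years ago when the tetraploid hybridized with the D-genome donor. After
each duplication, fractionation removes duplicate genes — but not at
random. The gene balance hypothesis predicts that dosage-sensitive genes,
transcription factors (TFs) foremost, are preferentially retained as
complete homoeolog groups: **diads** (one A and one B copy) in the
tetraploid and **triads** (one copy per subgenome) in the hexaploid.

`wheatTriads` packages the full chain of analyses used to interrogate
this prediction — group classification, retention statistics, tandem
duplication, expression divergence, coexpression, and cohort mutation
load — together with a generator that synthesizes inputs with the same
statistical structure, so every stage is testable end to end and the
configured parameters can be recovered from the pipeline's own output.

## Homoeolog classification and retention

Hexaploid homoeology arrives as pairwise `one2one` rows (the format of an
Ensembl Biomart export); the package builds the homoeology graph and
takes connected components, classifying each by subgenome composition
(triad = exactly one A, one B, one D). Tetraploid homoeology arrives as
per-group rows whose `singleton` and `hit2homolog` (paralogous hit)
labels are removed before the remaining 1:1 rows become diads. Only
high-confidence gene models enter the hexaploid analysis; whether an
analogous filter applies to the tetraploid input is not specified by the
data conventions we follow, so none is applied there by default. All
removals are logged per stage, and the log is asserted monotone in the
tests.

TF family labels are resolved at two levels. A gene with isoforms
assigned to different families keeps the family of the longest isoform
(ties broken by the lexicographically smallest isoform identifier, a
deterministic, input-order-independent rule). A group whose members
disagree keeps the majority family; a three-way disagreement is flagged
unresolved — such groups are excluded from per-family summaries but still
count as TF in TF-versus-non-TF totals, a conservative treatment of a
case that affects a fraction of a percent of groups.

Per-family retention is the percentage of the family's genes that are
members of complete groups. Enrichment against the pooled non-TF genes
uses a two-sided Fisher's exact test with Benjamini–Hochberg adjustment
across families (two-sided because no direction is assumed; BH because it
is the field's default FDR control). Figure-level summaries restrict to
families with more than 10 complete groups, a threshold exposed as an
argument.

**Normalized retention** adjusts the hexaploid triad percentage for loss
that had already happened in the tetraploid:

$$\text{normalized %} = 100 \times \frac{\%\ \text{genes in triads (hexaploid)}}{\%\ \text{genes in diads (tetraploid)}}$$

It reads as the share of *potential* triads actually formed: 60% triads
against 80% surviving diads gives 75%. The statistic is scale-invariant
and undefined at a zero diad percentage (reported `NA`). Computation is
at full precision; printed values are rounded to one decimal. Rounding
the inputs first can shift the result by a tenth of a percentage point,
which is why the package never rounds intermediates.

## Tandem duplication

Gene identifiers in these assemblies increase by 100 between adjacent
genes, so gene order is recoverable from the identifier alone. Within a
chromosome, same-family genes whose ordinal gap is at most k (k = 1, 2 or
3; default 3, i.e. up to two intervening genes) are chained into
clusters; intervening genes of other families do not break a link — that
is precisely what the wider windows are for, since a duplication event
can capture a TF and a non-TF gene together. A cluster of m genes counts
m − 1 events. Chained linkage is used (A–B and B–C linked implies one
cluster even if A and C are farther apart than k), which reproduces the
cluster-of-three = two-events accounting; the tests verify equivalence
with a brute-force connected-components oracle over random ordinal sets.

Family-level analyses regress the percentage of the family in triads on
(i) the percentage of tandem-duplicated genes (events over family gene
count) and (ii) the log of the family's median expression — the median
over genes of each gene's mean tpm across tissues. Families whose median
is zero cannot enter the log regression and are dropped with a warning.

## Expression divergence and coexpression

Expression arrives as a tpm matrix over tissues × replicates (the study
design the generator emulates: 15 tissues, 2 replicates). All filters
work on replicate means. A triad enters the divergence analysis when at
least one homoeolog exceeds 0.5 tpm in at least one tissue; correlation
analyses additionally require all three homoeologs expressed (tpm > 0
somewhere).

For divergence, each triad's expression per tissue is normalized to sum
to 1 across the three homoeologs, and the sample standard deviation
(divisor n − 1 = 2) of the three fractions is the per-tissue divergence.
The sample convention matters — medians near 0.09–0.10 shift visibly
under the population convention — so it is fixed and documented here.
Tissues where the triad is silent yield no value rather than a
degenerate (0, 0, 0) observation, because fractions are undefined at
zero total. TF and non-TF divergence distributions are compared per
tissue (no cross-tissue averaging) with a two-sided Mann–Whitney test.

Coexpression is the pairwise Pearson correlation (A–B, B–D, A–D) of
replicate-mean tpm across tissues. Aggregation uses the Fisher
z-transform: correlations are mapped with atanh, the median taken in
z-space, and mapped back — reducing the bias of averaging raw
coefficients. Values at ±1 are clipped to ±(1 − 1e−12) before the
transform. Per-family summaries pool all pairwise values of the family's
triads (rather than first collapsing each triad to its median); the
choice is flagged in the output since the alternative is defensible.

Module co-membership offers an orthogonal coexpression measure: given a
module assignment from a prior coexpression network, a triad is eligible
when all three homoeologs have a non-zero module (module 0 collects
invariant-expression genes and is excluded), and the share of eligible
triads with all three members in one module is contrasted TF versus
non-TF by Fisher's exact test.

## Cohort variant load

The SNP filter cascade runs in a fixed order, each stage logged:
canonical-CDS consequence rows only; drop splice-region co-annotations;
drop missense without SIFT; drop sites with **more than** 25% missing
calls (exactly 25% is retained — the rule is strict); keep minor allele
frequency ≥ 0.01 computed over non-missing alleles (the standard
convention for filtered or imputed genotype sets); keep sites in
expressed genes; drop sites carrying any of the four
selection/introgression region flags (the exclusions apply jointly);
drop multi-annotated synonymous sites.

Effect classes partition the filtered set: stop-gained; missense with
SIFT ≤ 0.05 (deleterious — the boundary value is deleterious); missense
with SIFT > 0.05 (tolerated); synonymous.

Per-site nucleotide diversity uses the unbiased pairwise estimator
$\pi = 2j(n-j)/(n(n-1))$ with n non-missing alleles of which j are
alternate; the tests verify it against exhaustive pairwise-difference
enumeration on every cohort of up to 10 individuals.

Mutation load is the per-individual count of homozygous-alternate calls
per effect class, scaled by the summed canonical-transcript length (kb)
of the *whole* gene group (all TF triad genes, or all non-TF triad
genes) — group totals, not per-gene lengths. Extreme individuals are
those falling strictly outside the central 95% interval
(linear-interpolation quantiles, 2.5% per tail) of any group × category
load distribution; the flag count is definition-sensitive, which is why
the quantile type is pinned. SNPs whose every alternate-allele carrier is
a flagged individual are dropped from the per-family SNP-effect
proportions (families shown need more than 10 triads and at least 5
SNPs). Group contrasts fit load on category and group (fixed effects),
report the ANOVA, and compare TF to non-TF within each category by Tukey
HSD on the cell-mean factor — adjusting over all cell pairs, which is
conservative relative to adjusting over just the four within-category
contrasts.

## The synthetic-study generator

The generator realizes each ancestral gene group through both
polyploidization steps: present in both diploid progenitors, surviving
as a diad with its family's `diad_prob`, and completing into a triad
with conditional probability `triad_prob / diad_prob` (so a triad
requires the surviving diad — loss is cumulative across steps, matching
the biology the normalized-retention statistic is designed for).
Defaults place the TF-wide averages near diad 0.82 / triad 0.70 against
0.692 / 0.559 for non-TF genes, with family-level spread that includes
low-retention, low-expression families (NAC-, B3- and MADS-M-type-like)
so the family regressions have signal.

Design choices worth knowing:

- **Gene order**: each assembly is renumbered so identifiers step by 100
  between adjacent genes; tandem duplicates get intermediate identifiers
  (+50) and so appear adjacent to their parent to any gene-order
  detector. Non-duplicate genes of one TF family are kept at least four
  positions apart (violations are swapped away in a few passes), so in
  the generated genomes every within-family adjacency is a recorded
  duplication event and a zero tandem rate implies zero detectable
  events. Real genomes also contain dispersed same-family neighbours
  that are not recent duplicates; this is a deliberate idealization that
  makes the detector's ground truth exact.
- **Expression** is lognormal: family log-mean, a group-level draw
  shared by homoeologs, a small per-homoeolog offset (triad imbalance),
  and a per-tissue profile mixing a latent profile shared by the group
  with independent gene noise. The mixing weight is solved in closed
  form so the *population* Pearson correlation between homoeolog
  replicate-mean tpm profiles equals the configured target — the
  solution accounts for the lognormal transform and for replicate-noise
  variance inflation, so the target is attained on the scale the
  pipeline actually measures. Replicates are multiplicative lognormal
  noise with unit mean. Targets too close to 1 under heavy noise are
  unattainable and are clamped with a warning.
- **Cohort**: SNP counts are Poisson per gene per effect class at per-kb
  rates; TF rates are scaled by configurable factors whose defaults
  encode the contrasts under study (0.68 for deleterious missense, 1.057
  for tolerated, 0.824 for synonymous, 1 for stop-gained). Alternate
  allele frequencies follow a Beta spectrum; genotypes are
  Hardy–Weinberg draws at the site frequency — the simplest null that
  gives the closed form q² per individual for homozygous-alt recovery
  tests — with independent per-call missingness, matching the per-site
  missingness filter's semantics. Small configured fractions of sites
  carry splice co-annotations, lack SIFT scores, sit outside the
  canonical CDS, carry region flags, or are multi-annotated synonymous
  sites, so every filter stage has work.
- **Modules**: genes fall into module 0 at a configured rate; among
  fully assigned triads, co-membership is drawn at the configured TF and
  non-TF probabilities, with non-co-member triads guaranteed not to
  collide, so the configured probability is exactly the ground-truth
  co-membership rate.

Everything is driven by one integer seed; a fixed seed reproduces every
table byte for byte, and the ground-truth tables record each realized
decision so recovery tests compare against bookkeeping, not estimates.

What the generator does **not** emulate: linkage disequilibrium between
sites, selection dynamics, sequence-level data, biased subgenome
fractionation, and the long-tailed family-size distribution of real TF
annotations. Passing parameter-recovery tests therefore demonstrates
that the pipeline's estimators are consistent under the model's
assumptions, not that real wheat data meet those assumptions.

## Numerical conventions and degenerate inputs

- Exact Mann–Whitney p-values by enumeration for combined n ≤ 8
  (configurable), valid under ties; tie-corrected normal approximation
  otherwise; always two-sided.
- Fisher p-values are clamped at 1 to absorb floating-point overshoot.
- Correlations with a zero-variance profile are `NA` and excluded from
  medians; an all-`NA` input errors.
- Zero-length transcripts are skipped with a warning by the cohort
  simulator; a zero group length is an error in load computation.
- Percentages are computed at full precision and rounded only for
  display.

## Problem sizes

The shipped defaults (2,000 ancestral groups, 200 individuals) run the
full pipeline in a few seconds. The parameter-recovery studies in the
test suite use 20,000 groups over five seeds for retention probabilities
(binomial error ~0.4% per class), 400 groups over five seeds for the
correlation target, and 3,000 groups with a 30% TF fraction and 200
individuals over five seeds for the load deficit — the TF fraction is
raised there because the deficit estimator's error is dominated by the
heavy-tailed per-site allele-frequency contribution to homozygous
counts, and a realistic 5% TF fraction leaves too little TF transcript
mass for a sharp recovery; the load-recovery configuration also uses a
common family expression level so the configured rate deficit is
identified separately from expression-filter asymmetries between
families.

## Known limitations

- The hexaploid model gives the D subgenome a copy only in triads;
  A–D/B–D pairs and D singletons do not occur in generated data (the
  classifier itself handles them and labels them `other`).
- Tetraploid tandem duplication is not simulated; the tandem analysis
  targets the hexaploid assembly.
- The Tukey adjustment is conservative (all cell pairs rather than the
  four within-category contrasts).
- π is per-site only; windowed or haplotype diversity is out of scope,
  as are genotype imputation and running SIFT/VEP-type annotation, whose
  outputs are consumed as inputs.
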