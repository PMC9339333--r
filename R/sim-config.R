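#' Default transcription-factor family parameters for the generator
#'
#' Eleven families spanning the observed range of behaviour: most families
#' retain homoeologs more often than non-TF genes, while NAC, B3 and
#' MADS-M-type are configured with the low diad/triad retention and (for
#' MADS-M-type and B3) the low expression reported for those families.
#' Shares sum to 1 over TF genes; `diad_prob` is the probability an
#' ancestral group survives as a 1:1 A-B diad in the tetraploid, and
#' `triad_prob` the unconditional probability it is a 1:1:1 triad in the
#' hexaploid (so `triad_prob <= diad_prob`: the D copy can only complete a
#' surviving diad). `tandem_rate` is the per-gene probability of spawning
#' an adjacent duplicate; `log_mean`/`log_sd` parameterise the lognormal
#' baseline expression in tpm.
#'
#' @return tibble with columns `family`, `share`, `diad_prob`,
#'   `triad_prob`, `tandem_rate`, `log_mean`, `log_sd`.
#' @export
default_tf_families <- function() {
  tibble(
    family = c("WRKY", "MYB", "bHLH", "AP2/ERF-ERF", "C2H2", "bZIP",
               "MADS-MIKC", "HB-HD-ZIP", "NAC", "B3", "MADS-M-type"),
    share       = c(0.10, 0.12, 0.12, 0.12, 0.10, 0.08, 0.05, 0.08, 0.13, 0.06, 0.04),
    diad_prob   = c(0.90, 0.88, 0.87, 0.84, 0.83, 0.88, 0.87, 0.84, 0.745, 0.639, 0.613),
    triad_prob  = c(0.83, 0.80, 0.77, 0.75, 0.72, 0.78, 0.81, 0.75, 0.510, 0.387, 0.385),
    tandem_rate = c(0.02, 0.03, 0.03, 0.04, 0.04, 0.02, 0.01, 0.03, 0.08, 0.03, 0.02),
    log_mean    = log(c(8, 6, 5, 4, 4, 6, 5, 4, 1.5, 0.8, 0.5)),
    log_sd      = rep(1.0, 11)
  )
}

check_prob <- function(value, name, upper = 1) {
  if (any(is.na(value)) || any(value < 0) || any(value > upper)) {
    abort(sprintf("`%s` must lie in [0, %s].", name, upper))
  }
  invisible(value)
}

#' Configuration for a synthetic polyploid-wheat study
#'
#' Bundles and validates every tunable of the generator. Defaults describe
#' a scaled-down study with the structure of the real one: 15 tissues with
#' 2 replicates, a TF gene fraction near 5.7%, family-level diad/triad
#' retention probabilities averaging about 0.82/0.70 for TFs versus
#' 0.692/0.559 for non-TF genes, and a cohort with per-category SNP rates
#' whose TF:non-TF ratio encodes the deleterious-load deficit.
#'
#' @param n_groups number of ancestral gene groups.
#' @param tf_fraction proportion of groups that are TF genes, in \[0, 1\].
#' @param families tibble as [default_tf_families()]; shares must sum to 1.
#' @param nontf list with `diad_prob`, `triad_prob`, `tandem_rate`,
#'   `log_mean`, `log_sd` for non-TF genes.
#' @param n_tissues,n_replicates expression design (defaults 15 and 2).
#' @param homoeolog_correlation target Pearson correlation, on the tpm
#'   scale of replicate means, between homoeolog tissue profiles.
#' @param tissue_log_sd between-tissue SD of log tpm within a gene.
#' @param replicate_log_sd SD of multiplicative (log-scale) replicate noise.
#' @param balance_log_sd SD of the per-homoeolog baseline offset within a
#'   group (controls triad expression imbalance).
#' @param zero_expression_rate proportion of genes silenced in all tissues.
#' @param n_chromosomes chromosomes per subgenome (wheat: 7).
#' @param n_individuals cohort size for the variant simulation.
#' @param snp_rates named per-kb rates for `stop_gained`, `missense`,
#'   `synonymous` sites in non-TF genes.
#' @param sift_deleterious_fraction fraction of missense SNPs with SIFT
#'   score at or below 0.05.
#' @param tf_rate_factor named multipliers applied to TF genes' site rates
#'   for `stop_gained`, `deleterious_missense`, `tolerated_missense`,
#'   `synonymous` (defaults encode the cohort contrasts: 32% fewer
#'   deleterious, 5.7% more tolerated, 17.6% fewer synonymous).
#' @param maf_spectrum named `shape1`, `shape2` of the Beta distribution of
#'   minor allele frequencies.
#' @param missing_rate per-call missingness probability.
#' @param missense_no_sift_rate fraction of missense SNPs lacking a SIFT
#'   score (exercises the filter cascade).
#' @param splice_overlap_rate probability a coding SNP carries an
#'   additional splice-region annotation.
#' @param non_canonical_rate probability a SNP falls outside the canonical
#'   transcript CDS.
#' @param multi_annotation_rate probability a synonymous SNP has a second
#'   annotation.
#' @param region_flag_rates named probabilities for the four exclusion
#'   flags (`adaptation`, `improvement`, `sweep`, `introgression`).
#' @param n_modules,module0_rate,module_comembership coexpression-module
#'   generator: module count, per-gene probability of the unassigned
#'   module 0, and named target co-membership probabilities (`tf`,
#'   `nontf`) among eligible triads.
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_groups = 2000,
                       tf_fraction = 0.057,
                       families = default_tf_families(),
                       nontf = list(diad_prob = 0.692, triad_prob = 0.559,
                                    tandem_rate = 0.02, log_mean = log(2),
                                    log_sd = 1.0),
                       n_tissues = 15,
                       n_replicates = 2,
                       homoeolog_correlation = 0.9,
                       tissue_log_sd = 0.5,
                       replicate_log_sd = 0.1,
                       balance_log_sd = 0.3,
                       zero_expression_rate = 0.05,
                       n_chromosomes = 7,
                       n_individuals = 200,
                       snp_rates = c(stop_gained = 0.15, missense = 3.0,
                                     synonymous = 4.0),
                       sift_deleterious_fraction = 0.25,
                       tf_rate_factor = c(stop_gained = 1,
                                          deleterious_missense = 0.68,
                                          tolerated_missense = 1.057,
                                          synonymous = 0.824),
                       maf_spectrum = c(shape1 = 0.3, shape2 = 2.5),
                       missing_rate = 0.03,
                       missense_no_sift_rate = 0.02,
                       splice_overlap_rate = 0.02,
                       non_canonical_rate = 0.05,
                       multi_annotation_rate = 0.02,
                       region_flag_rates = c(adaptation = 0.01, improvement = 0.01,
                                             sweep = 0.01, introgression = 0.01),
                       n_modules = 20,
                       module0_rate = 0.08,
                       module_comembership = c(tf = 0.355, nontf = 0.293),
                       seed = 1L) {
  if (n_groups < 1) abort("`n_groups` must be at least 1.")
  check_prob(tf_fraction, "tf_fraction")
  families <- as_tibble(families)
  needed <- c("family", "share", "diad_prob", "triad_prob", "tandem_rate",
              "log_mean", "log_sd")
  if (!all(needed %in% names(families))) {
    abort(sprintf("`families` must have columns: %s", paste(needed, collapse = ", ")))
  }
  check_prob(families$share, "families$share")
  if (abs(sum(families$share) - 1) > 1e-8) abort("`families$share` must sum to 1.")
  check_prob(families$diad_prob, "families$diad_prob")
  check_prob(families$triad_prob, "families$triad_prob")
  check_prob(families$tandem_rate, "families$tandem_rate")
  if (any(families$triad_prob > families$diad_prob + 1e-12)) {
    abort("`families$triad_prob` cannot exceed `families$diad_prob` (a triad requires the surviving diad).")
  }
  check_prob(nontf$diad_prob, "nontf$diad_prob")
  check_prob(nontf$triad_prob, "nontf$triad_prob")
  check_prob(nontf$tandem_rate, "nontf$tandem_rate")
  if (nontf$triad_prob > nontf$diad_prob + 1e-12) {
    abort("`nontf$triad_prob` cannot exceed `nontf$diad_prob`.")
  }
  if (n_tissues < 2) abort("`n_tissues` must be at least 2 (correlation over tissues is undefined otherwise).")
  if (n_replicates < 1) abort("`n_replicates` must be at least 1.")
  if (homoeolog_correlation < -1 || homoeolog_correlation > 1) {
    abort("`homoeolog_correlation` must lie in [-1, 1].")
  }
  check_prob(zero_expression_rate, "zero_expression_rate")
  if (any(snp_rates < 0) ||
      !all(c("stop_gained", "missense", "synonymous") %in% names(snp_rates))) {
    abort("`snp_rates` must be non-negative and name stop_gained, missense, synonymous.")
  }
  check_prob(sift_deleterious_fraction, "sift_deleterious_fraction")
  check_prob(missing_rate, "missing_rate")
  check_prob(missense_no_sift_rate, "missense_no_sift_rate")
  check_prob(splice_overlap_rate, "splice_overlap_rate")
  check_prob(non_canonical_rate, "non_canonical_rate")
  check_prob(multi_annotation_rate, "multi_annotation_rate")
  check_prob(region_flag_rates, "region_flag_rates")
  check_prob(module0_rate, "module0_rate")
  check_prob(module_comembership, "module_comembership")
  if (any(maf_spectrum <= 0)) abort("`maf_spectrum` shapes must be positive.")

  cfg <- list(
    n_groups = as.integer(n_groups), tf_fraction = tf_fraction,
    families = families, nontf = nontf,
    n_tissues = as.integer(n_tissues), n_replicates = as.integer(n_replicates),
    homoeolog_correlation = homoeolog_correlation,
    tissue_log_sd = tissue_log_sd, replicate_log_sd = replicate_log_sd,
    balance_log_sd = balance_log_sd, zero_expression_rate = zero_expression_rate,
    n_chromosomes = as.integer(n_chromosomes),
    n_individuals = as.integer(n_individuals),
    snp_rates = snp_rates, sift_deleterious_fraction = sift_deleterious_fraction,
    tf_rate_factor = tf_rate_factor, maf_spectrum = maf_spectrum,
    missing_rate = missing_rate, missense_no_sift_rate = missense_no_sift_rate,
    splice_overlap_rate = splice_overlap_rate,
    non_canonical_rate = non_canonical_rate,
    multi_annotation_rate = multi_annotation_rate,
    region_flag_rates = region_flag_rates,
    n_modules = as.integer(n_modules), module0_rate = module0_rate,
    module_comembership = module_comembership,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  groups: %d (TF fraction %.3f), %d TF families\n",
              x$n_groups, x$tf_fraction, nrow(x$families)))
  cat(sprintf("  expression: %d tissues x %d replicates, target homoeolog r = %.2f\n",
              x$n_tissues, x$n_replicates, x$homoeolog_correlation))
  cat(sprintf("  cohort: %d individuals, seed %d\n", x$n_individuals, x$seed))
  invisible(x)
}
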