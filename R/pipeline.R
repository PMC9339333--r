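#' Resolve homoeolog-group families and TF status
#'
#' Attaches to each classified group the majority-rule family of its
#' members and whether any member is an annotated TF. Groups whose
#' members' families all disagree keep `NA` family (excluded from
#' per-family summaries) but still count as TF in TF-vs-non-TF totals.
#'
#' @param groups classified groups from [classify_groups()].
#' @param genes gene table with `gene_id`, `family`.
#' @return groups with `family` and `is_tf` columns added.
#' @export
add_group_family <- function(groups, genes) {
  fam_of <- setNames(genes$family, genes$gene_id)
  f1 <- unname(fam_of[groups$A])
  f2 <- unname(fam_of[groups$B])
  f3 <- unname(fam_of[groups$D])
  groups$family <- resolve_group_family_vec(f1, f2, f3)
  groups$is_tf <- (!is.na(f1)) | (!is.na(f2)) | (!is.na(f3))
  groups
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulates a study (unless one is supplied), then runs every analysis
#' stage in dependency order: homoeolog-group classification and
#' retention for tetraploid and hexaploid, normalized retention, tandem
#' duplication detection and family-level regressions, homoeolog
#' expression divergence and coexpression, and the cohort variant-load
#' analysis. Thresholds default to the study's conventions (0.5 tpm
#' expression, MAF 0.01, 25% missingness, SIFT 0.05, 2.5% load tails,
#' family sizes >10 groups and >=5 SNPs, adjacency window 3).
#'
#' @param config a [sim_config()].
#' @param study optionally, an existing `synthetic_study` (the config is
#'   then only used for thresholds' defaults).
#' @param outdir if non-NULL, write all inputs, result tables and the
#'   manifest there.
#' @param window_k tandem adjacency window (1, 2 or 3).
#' @param tpm_threshold expression filter threshold in tpm.
#' @param min_maf,max_missing,sift_cutoff,tail variant-stage thresholds.
#' @param min_triads,min_snps family-size thresholds for figure-style
#'   summaries.
#' @return list with `headline` (tibble metric, value), `retention`,
#'   `tandem`, `expression`, `variants` (stage result lists), `manifest`,
#'   and the `study`.
#' @export
run_pipeline <- function(config = sim_config(), study = NULL, outdir = NULL,
                         window_k = 3, tpm_threshold = 0.5, min_maf = 0.01,
                         max_missing = 0.25, sift_cutoff = 0.05, tail = 0.025,
                         min_triads = 10, min_snps = 5) {
  if (is.null(study)) study <- simulate_study(config)

  genes_hex <- study$genes |>
    filter(.data$ploidy == "hexaploid", .data$confidence == "HC")
  genes_tet <- study$genes |> filter(.data$ploidy == "tetraploid")

  ## -- retention ---------------------------------------------------------
  tf_share <- study$genes |>
    group_by(.data$ploidy) |>
    summarise(pct_tf = 100 * mean(!is.na(.data$family)))

  tet_groups <- classify_groups(study$homoeologs$zavitan, "zavitan")
  hex_groups <- classify_groups(study$homoeologs$biomart, "biomart",
                                genes = genes_hex)
  ret_tet <- retention_percentages(genes_tet, tet_groups, "diad")
  ret_hex <- retention_percentages(genes_hex, hex_groups, "triad")

  norm_tbl <- ret_hex$per_family |>
    select("family", pct_triads = "pct_complete",
           n_triads = "n_complete_groups") |>
    inner_join(ret_tet$per_family |>
                 select("family", pct_diads = "pct_complete"),
               by = "family") |>
    mutate(normalized_pct = suppressWarnings(
      normalized_retention(.data$pct_triads, .data$pct_diads)))

  retention <- list(
    tf_share_per_ploidy = tf_share,
    tetraploid = ret_tet, hexaploid = ret_hex,
    normalized = norm_tbl,
    filter_logs = list(zavitan = attr(tet_groups, "filter_log"),
                       biomart = attr(hex_groups, "filter_log"))
  )

  ## -- tandem duplication ------------------------------------------------
  tf_genes_hex <- genes_hex |> filter(!is.na(.data$family))
  events <- detect_tandem_events(tf_genes_hex, window_k = window_k)
  fam_counts <- table(tf_genes_hex$family)
  pct_tandem <- pct_tandem_per_family(events, setNames(as.integer(fam_counts),
                                                       names(fam_counts)))
  med_expr <- family_median_expression(study$expression, study$sample_map,
                                       genes_hex)
  fam_tbl <- ret_hex$per_family |>
    filter(.data$family != "non-TF", .data$n_complete_groups > min_triads) |>
    left_join(pct_tandem, by = "family") |>
    left_join(med_expr |> select("family", "median_tpm"), by = "family")
  reg_tandem <- if (nrow(fam_tbl) >= 3 && stats::var(fam_tbl$pct_tandem) > 0) {
    fit_retention_regression(fam_tbl, "pct_tandem", "pct_complete")
  } else NULL
  reg_expr <- if (nrow(fam_tbl) >= 3) {
    fit_retention_regression(fam_tbl, "median_tpm", "pct_complete",
                             log_transform_x = TRUE)
  } else NULL
  tandem <- list(events = events, pct_per_family = pct_tandem,
                 family_table = fam_tbl,
                 regression_tandem = reg_tandem,
                 regression_expression = reg_expr)

  ## -- expression divergence & coexpression ------------------------------
  triads <- hex_groups |>
    filter(.data$cardinality_class == "triad") |>
    add_group_family(genes_hex)
  tf_ids <- triads$group_id[triads$is_tf]
  expressed <- filter_expressed_triads(study$expression, study$sample_map,
                                       triads, threshold = tpm_threshold)
  profiles <- triad_profiles(study$expression, study$sample_map, expressed)
  divergence <- compare_divergence(profiles, tf_ids)
  all_expr <- filter_expressed_triads(study$expression, study$sample_map,
                                      triads, threshold = tpm_threshold,
                                      require_all_expressed = TRUE)
  corr <- pairwise_homoeolog_correlation(study$expression, study$sample_map,
                                         all_expr)
  corr$tf <- corr$group_id %in% tf_ids
  med_r <- corr |>
    group_by(group = ifelse(.data$tf, "TF", "non-TF")) |>
    summarise(median_r = median_correlation(.data$r), n_pairs = sum(!is.na(.data$r)))
  corr_test <- mann_whitney(corr$r[corr$tf & !is.na(corr$r)],
                            corr$r[!corr$tf & !is.na(corr$r)])
  comember <- module_comembership(study$modules, triads, tf_ids)
  expression <- list(expressed_triads = expressed, profiles = profiles,
                     divergence = divergence, correlations = corr,
                     median_correlation = med_r,
                     correlation_test = corr_test,
                     comembership = comember)

  ## -- variant load ------------------------------------------------------
  tm <- replicate_means(study$expression, study$sample_map)
  expressed_genes <- rownames(tm)[apply(tm > tpm_threshold, 1L, any)]
  filt <- filter_snps(study$variants, study$genotypes, expressed_genes,
                      max_missing = max_missing, min_maf = min_maf)
  classified <- classify_effect(filt$variants, sift_cutoff = sift_cutoff)
  pi_tbl <- tibble(snp_id = classified$snp_id,
                   category = classified$category,
                   pi = site_pi(filt$genotypes))
  triad_members <- genes_hex |>
    filter(.data$gene_id %in% c(triads$A, triads$B, triads$D))
  load_tbl <- mutation_load(classified, filt$genotypes, triad_members)
  extreme <- flag_extreme_individuals(load_tbl, tail = tail)
  fam_of_gene <- setNames(triad_members$family, triad_members$gene_id)
  triad_fam_counts <- table(triads$family[!is.na(triads$family)])
  fam_props <- family_snp_proportions(
    classified, filt$genotypes, fam_of_gene,
    setNames(as.integer(triad_fam_counts), names(triad_fam_counts)),
    extreme, min_triads = min_triads, min_snps = min_snps)
  contrasts <- compare_loads(load_tbl)
  variants <- list(filter_log = filt$log, variants = classified,
                   pi = pi_tbl, load = load_tbl, extreme = extreme,
                   family_proportions = fam_props, contrasts = contrasts)

  ## -- headline ----------------------------------------------------------
  hl <- function(metric, value) tibble(metric = metric, value = value)
  headline <- bind_rows(
    hl(paste0("pct_tf_", tf_share$ploidy), tf_share$pct_tf),
    hl("pct_tf_genes_in_triads", ret_hex$overall$pct_tf),
    hl("pct_nontf_genes_in_triads", ret_hex$overall$pct_nontf),
    hl("pct_tf_genes_in_diads", ret_tet$overall$pct_tf),
    hl("pct_nontf_genes_in_diads", ret_tet$overall$pct_nontf),
    hl("normalized_retention_nontf",
       norm_tbl$normalized_pct[norm_tbl$family == "non-TF"]),
    if (!is.null(reg_tandem)) hl("r2_tandem_vs_triads", reg_tandem$r_squared),
    if (!is.null(reg_expr)) hl("r2_log_expression_vs_triads", reg_expr$r_squared),
    hl("median_r_tf", med_r$median_r[med_r$group == "TF"]),
    hl("median_r_nontf", med_r$median_r[med_r$group == "non-TF"]),
    if (nrow(comember$summary) == 2L)
      hl(paste0("pct_comembership_", c("tf", "nontf")),
         c(comember$summary$pct_comember[comember$summary$group == "TF"],
           comember$summary$pct_comember[comember$summary$group == "non-TF"])),
    hl(paste0("pct_load_deficit_", contrasts$percent_difference$category),
       contrasts$percent_difference$pct_difference),
    hl("anova_f_group",
       contrasts$anova$statistic[contrasts$anova$term == "factor_b"])
  )

  manifest <- list(
    seed = config$seed,
    config = config_as_list(config),
    thresholds = list(window_k = window_k, tpm_threshold = tpm_threshold,
                      min_maf = min_maf, max_missing = max_missing,
                      sift_cutoff = sift_cutoff, tail = tail,
                      min_triads = min_triads, min_snps = min_snps),
    counts = list(
      genes = nrow(study$genes),
      tetraploid_diads = sum(tet_groups$cardinality_class == "diad"),
      hexaploid_triads = sum(hex_groups$cardinality_class == "triad"),
      tandem_events = nrow(events),
      expressed_triads = nrow(expressed),
      snps_filtered = nrow(classified),
      extreme_individuals = length(extreme)
    )
  )

  result <- list(headline = headline, retention = retention, tandem = tandem,
                 expression = expression, variants = variants,
                 manifest = manifest, study = study)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_study(result$study, file.path(outdir, "inputs"))
  p <- function(f) file.path(outdir, f)
  readr::write_tsv(result$headline, p("report.tsv"))
  readr::write_tsv(result$retention$normalized, p("retention_normalized.tsv"))
  readr::write_tsv(result$retention$hexaploid$per_family,
                   p("retention_hexaploid.tsv"))
  readr::write_tsv(result$retention$tetraploid$per_family,
                   p("retention_tetraploid.tsv"))
  readr::write_tsv(result$tandem$events, p("tandem_events.tsv"))
  readr::write_tsv(result$tandem$pct_per_family, p("tandem_pct.tsv"))
  readr::write_tsv(result$expression$divergence, p("divergence_tests.tsv"))
  readr::write_tsv(result$expression$correlations, p("homoeolog_correlations.tsv"))
  readr::write_tsv(result$variants$filter_log, p("snp_filter_log.tsv"))
  readr::write_tsv(result$variants$pi, p("site_pi.tsv"))
  readr::write_tsv(result$variants$load, p("mutation_load.tsv"))
  readr::write_tsv(result$variants$family_proportions,
                   p("family_snp_proportions.tsv"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
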