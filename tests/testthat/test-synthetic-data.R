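test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(tf_fraction = 1.5), "tf_fraction")
  expect_error(sim_config(missing_rate = -0.1), "missing_rate")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(sim_config(n_tissues = 1), "n_tissues")
  fam <- default_tf_families()
  fam$share <- fam$share * 2
  expect_error(sim_config(families = fam), "share")
  fam2 <- default_tf_families()
  fam2$triad_prob[1] <- fam2$diad_prob[1] + 0.1
  expect_error(sim_config(families = fam2), "triad_prob")
})

test_that("a fixed seed reproduces the study exactly", {
  cfg <- small_config(seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  for (part in c("genes", "homoeologs", "isoforms", "modules", "variants")) {
    expect_identical(a[[part]], b[[part]])
  }
  expect_identical(a$expression, b$expression)
  expect_identical(a$genotypes, b$genotypes)
})

test_that("gene ordinals step by one along each chromosome before tandem insertion", {
  st <- simulate_genomes(small_config(seed = 2))
  base <- st$genes[st$genes$ordinal == round(st$genes$ordinal), ]
  steps <- base |>
    dplyr::group_by(.data$ploidy, .data$chromosome) |>
    dplyr::summarise(ok = all(diff(sort(ordinal)) == 1), .groups = "drop")
  expect_true(all(steps$ok))
  # tandem duplicates sit between their parent and the next gene
  dups <- st$truth$tandem
  expect_true(all(parse_gene_ordinal(dups$gene_id) %% 1 == 0.5))
})

test_that("forced retention probabilities propagate to realized cardinalities", {
  fam <- uniform_families(diad = 1, triad = 1)
  cfg <- sim_config(n_groups = 150, families = fam,
                    nontf = list(diad_prob = 1, triad_prob = 1,
                                 tandem_rate = 0, log_mean = log(2), log_sd = 1),
                    seed = 3)
  st <- simulate_genomes(cfg)
  expect_true(all(st$truth$groups$cardinality_hexaploid == "triad"))
  genes_hex <- dplyr::filter(st$genes, ploidy == "hexaploid")
  hx <- classify_groups(st$homoeologs$biomart, "biomart", genes = genes_hex)
  expect_equal(sum(hx$cardinality_class == "triad"), 150)
})

test_that("ground-truth realized fractions equal the bookkeeping, not an estimate", {
  st <- simulate_genomes(small_config(seed = 9))
  genes_hex <- dplyr::filter(st$genes, ploidy == "hexaploid")
  hx <- classify_groups(st$homoeologs$biomart, "biomart", genes = genes_hex)
  expect_equal(sum(hx$cardinality_class == "triad"),
               sum(st$truth$groups$cardinality_hexaploid == "triad"))
  tet <- classify_groups(st$homoeologs$zavitan, "zavitan")
  expect_equal(nrow(tet),
               sum(st$truth$groups$cardinality_tetraploid == "diad"))
})

test_that("a zero tandem rate yields zero detected events", {
  fam <- uniform_families()
  fam$tandem_rate <- 0
  cfg <- sim_config(n_groups = 400, families = fam,
                    nontf = list(diad_prob = 0.692, triad_prob = 0.559,
                                 tandem_rate = 0, log_mean = log(2), log_sd = 1),
                    seed = 4)
  st <- simulate_genomes(cfg)
  tf_genes <- dplyr::filter(st$genes, ploidy == "hexaploid", !is.na(family))
  for (k in 1:3) {
    expect_equal(nrow(detect_tandem_events(tf_genes, window_k = k)), 0L)
  }
})

test_that("configured triad probabilities are recovered within binomial error", {
  fam <- uniform_families(triad = 0.705, diad = 0.825)
  tf_hits <- 0; tf_n <- 0; nt_hits <- 0; nt_n <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_groups = 4000, families = fam, seed = s)
    st <- simulate_genomes(cfg)
    truth <- st$truth$groups
    tf_hits <- tf_hits + sum(truth$is_tf & truth$cardinality_hexaploid == "triad")
    tf_n <- tf_n + sum(truth$is_tf)
    nt_hits <- nt_hits + sum(!truth$is_tf & truth$cardinality_hexaploid == "triad")
    nt_n <- nt_n + sum(!truth$is_tf)
  }
  expect_lt(abs(tf_hits / tf_n - 0.705), 3 * sqrt(0.705 * 0.295 / tf_n))
  expect_lt(abs(nt_hits / nt_n - 0.559), 3 * sqrt(0.559 * 0.441 / nt_n))
})

test_that("perfect homoeolog correlation with no replicate noise gives r = 1", {
  cfg <- sim_config(n_groups = 60, families = uniform_families(),
                    homoeolog_correlation = 1, replicate_log_sd = 0,
                    zero_expression_rate = 0, seed = 6)
  st <- simulate_genomes(cfg)
  st <- simulate_expression(st, cfg)
  genes_hex <- dplyr::filter(st$genes, ploidy == "hexaploid")
  hx <- classify_groups(st$homoeologs$biomart, "biomart", genes = genes_hex)
  triads <- dplyr::filter(hx, cardinality_class == "triad")
  corr <- pairwise_homoeolog_correlation(st$expression, st$sample_map, triads)
  expect_true(all(abs(corr$r - 1) < 1e-9))
})

test_that("the target homoeolog correlation is recovered on the tpm scale", {
  rs <- sapply(1:2, function(s) {
    cfg <- sim_config(n_groups = 400, families = uniform_families(),
                      homoeolog_correlation = 0.9, zero_expression_rate = 0,
                      seed = s)
    st <- simulate_genomes(cfg)
    st <- simulate_expression(st, cfg)
    genes_hex <- dplyr::filter(st$genes, ploidy == "hexaploid")
    hx <- classify_groups(st$homoeologs$biomart, "biomart", genes = genes_hex)
    triads <- dplyr::filter(hx, cardinality_class == "triad")
    corr <- pairwise_homoeolog_correlation(st$expression, st$sample_map, triads)
    mean(corr$r, na.rm = TRUE)
  })
  expect_lt(abs(mean(rs) - 0.9), 0.05)
})

test_that("family log-means order downstream family medians", {
  fam <- uniform_families()
  fam$log_mean[fam$family == "WRKY"] <- log(10)
  fam$log_mean[fam$family == "NAC"] <- log(1)
  cfg <- sim_config(n_groups = 1500, families = fam,
                    zero_expression_rate = 0, seed = 8)
  st <- simulate_genomes(cfg)
  st <- simulate_expression(st, cfg)
  genes_hex <- dplyr::filter(st$genes, ploidy == "hexaploid")
  med <- family_median_expression(st$expression, st$sample_map, genes_hex)
  expect_gt(med$median_tpm[med$family == "WRKY"],
            med$median_tpm[med$family == "NAC"])
})

test_that("zero SNP rates give an empty variant table", {
  cfg <- small_config(snp_rates = c(stop_gained = 0, missense = 0, synonymous = 0),
                      seed = 10)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$variants), 0L)
  expect_equal(nrow(st$genotypes), 0L)
})

test_that("no missingness and a tight MAF spectrum pass the downstream filters", {
  cfg <- small_config(missing_rate = 0,
                      maf_spectrum = c(shape1 = 5000, shape2 = 5000),
                      splice_overlap_rate = 0, non_canonical_rate = 0,
                      missense_no_sift_rate = 0, multi_annotation_rate = 0,
                      region_flag_rates = c(adaptation = 0, improvement = 0,
                                            sweep = 0, introgression = 0),
                      seed = 11)
  st <- simulate_study(cfg)
  filt <- filter_snps(st$variants, st$genotypes,
                      expressed_genes = unique(st$variants$gene_id))
  log <- filt$log
  for (stage in c("canonical_cds", "no_splice_overlap", "missense_has_sift",
                  "missingness", "maf", "no_region_flag",
                  "single_annotation_synonymous")) {
    expect_equal(log$n[log$stage == stage], nrow(st$variants))
  }
})

test_that("genotypes follow Hardy-Weinberg at the site allele frequency", {
  cfg <- sim_config(n_groups = 500, n_individuals = 150, missing_rate = 0,
                    seed = 12)
  st <- simulate_study(cfg)
  hom <- rowSums(st$genotypes == 2L)
  expected <- st$variants$alt_freq^2 * ncol(st$genotypes)
  # pooled homozygous-alt count against its closed-form HW expectation
  tot_var <- sum(ncol(st$genotypes) * st$variants$alt_freq^2 *
                   (1 - st$variants$alt_freq^2))
  expect_lt(abs(sum(hom) - sum(expected)), 4 * sqrt(tot_var))
})

test_that("configured TF deleterious rate deficit is realized in site counts", {
  cfg <- sim_config(n_groups = 2500, tf_fraction = 0.3,
                    families = uniform_families(), seed = 13)
  st <- simulate_study(cfg)
  tri <- st$truth$groups$group_id[st$truth$groups$cardinality_hexaploid == "triad"]
  genes <- dplyr::filter(st$genes, ploidy == "hexaploid", group_id %in% tri)
  genes$tf <- !is.na(genes$family)
  v <- st$variants
  v$tf <- genes$tf[match(v$gene_id, genes$gene_id)]
  kb <- tapply(genes$transcript_length, genes$tf, sum) / 1000
  del <- v[v$true_category == "deleterious_missense", ]
  rate_tf <- sum(del$tf) / kb[["TRUE"]]
  rate_nt <- sum(!del$tf) / kb[["FALSE"]]
  ratio <- rate_tf / rate_nt
  se <- ratio * sqrt(1 / sum(del$tf) + 1 / sum(!del$tf))
  expect_lt(abs(ratio - 0.68), 3 * se)
})

test_that("zero-length transcripts are skipped with a warning", {
  cfg <- small_config(seed = 14)
  st <- simulate_genomes(cfg)
  tri <- st$truth$groups$group_id[st$truth$groups$cardinality_hexaploid == "triad"]
  idx <- which(st$genes$ploidy == "hexaploid" & st$genes$group_id %in% tri)[1:5]
  st$genes$transcript_length[idx] <- 0L
  expect_warning(simulate_cohort(st, cfg), "zero-length")
})
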