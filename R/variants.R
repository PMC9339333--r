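VALID_CONSEQUENCES <- c("stop_gained", "missense", "synonymous",
                        "splice_region", "other")
REGION_FLAGS <- c("adaptation", "improvement", "sweep", "introgression")

#' Apply the SNP filter cascade
#'
#' Ordered filter stages, each logged with the row count remaining:
#' (1) keep SNPs in the coding sequence of the canonical transcript;
#' (2) drop SNPs that also carry a splice-region annotation;
#' (3) drop missense SNPs without a SIFT score;
#' (4) drop SNPs with more than `max_missing` missing calls (a fraction of
#' exactly `max_missing` is retained — the rule is strict);
#' (5) keep SNPs with minor allele frequency at least `min_maf`, computed
#' over non-missing alleles;
#' (6) keep SNPs in expressed genes;
#' (7) drop SNPs carrying any selection/introgression region flag;
#' (8) drop synonymous SNPs with more than one annotation.
#'
#' @param variants variant table (columns `snp_id`, `gene_id`,
#'   `consequence`, `sift`, `in_canonical_cds`, `splice_region`, the four
#'   region flags, `n_annotations`).
#' @param genotypes integer matrix sites x individuals (0/1/2 alternate
#'   allele counts, `NA` = missing), rownames = `snp_id`.
#' @param expressed_genes character vector of gene ids that passed the
#'   expression filter (> 0.5 tpm in at least one tissue).
#' @param max_missing maximum tolerated missing-call fraction (default 0.25).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return list with `variants` (filtered), `genotypes` (matching rows)
#'   and `log` (tibble stage, n).
#' @export
filter_snps <- function(variants, genotypes, expressed_genes,
                        max_missing = 0.25, min_maf = 0.01) {
  variants <- as_tibble(variants)
  unknown <- setdiff(unique(variants$consequence), VALID_CONSEQUENCES)
  if (length(unknown)) {
    abort(sprintf("unknown consequence value: \"%s\"", unknown[1L]))
  }
  genotypes <- genotypes[match(variants$snp_id, rownames(genotypes)), ,
                         drop = FALSE]
  log <- tibble(stage = "input", n = nrow(variants))
  keep_stage <- function(v, keep, stage) {
    v <- v[keep, , drop = FALSE]
    log <<- bind_rows(log, tibble(stage = stage, n = nrow(v)))
    v
  }
  variants <- keep_stage(variants, variants$in_canonical_cds &
                           variants$consequence %in% c("stop_gained", "missense", "synonymous"),
                         "canonical_cds")
  variants <- keep_stage(variants, !variants$splice_region, "no_splice_overlap")
  variants <- keep_stage(variants,
                         !(variants$consequence == "missense" & is.na(variants$sift)),
                         "missense_has_sift")
  g <- genotypes[match(variants$snp_id, rownames(genotypes)), , drop = FALSE]
  miss_frac <- rowMeans(is.na(g))
  variants <- keep_stage(variants, miss_frac <= max_missing + 1e-12, "missingness")
  g <- genotypes[match(variants$snp_id, rownames(genotypes)), , drop = FALSE]
  p_alt <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  maf <- pmin(p_alt, 1 - p_alt)
  variants <- keep_stage(variants, maf >= min_maf - 1e-12, "maf")
  variants <- keep_stage(variants, variants$gene_id %in% expressed_genes,
                         "expressed_gene")
  flagged <- Reduce(`|`, lapply(REGION_FLAGS, function(f) variants[[f]]))
  variants <- keep_stage(variants, !flagged, "no_region_flag")
  variants <- keep_stage(variants,
                         !(variants$consequence == "synonymous" & variants$n_annotations > 1L),
                         "single_annotation_synonymous")
  list(
    variants = variants,
    genotypes = genotypes[match(variants$snp_id, rownames(genotypes)), ,
                          drop = FALSE],
    log = log
  )
}

#' Classify filtered SNPs into effect categories
#'
#' Stop-gained SNPs keep their class regardless of any SIFT field;
#' missense SNPs with SIFT score at or below 0.05 are deleterious and
#' above 0.05 tolerated; synonymous SNPs form the fourth category.
#'
#' @param variants filtered variant table.
#' @param sift_cutoff deleterious threshold (default 0.05, inclusive).
#' @return the table with a `category` column added.
#' @export
classify_effect <- function(variants, sift_cutoff = 0.05) {
  variants <- as_tibble(variants)
  if (any(variants$consequence == "missense" & is.na(variants$sift))) {
    abort("missense SNP without SIFT score: run filter_snps() first.")
  }
  variants$category <- case_when(
    variants$consequence == "stop_gained" ~ "stop_gained",
    variants$consequence == "missense" & variants$sift <= sift_cutoff ~ "deleterious_missense",
    variants$consequence == "missense" ~ "tolerated_missense",
    variants$consequence == "synonymous" ~ "synonymous",
    TRUE ~ NA_character_
  )
  variants
}

#' Per-site nucleotide diversity
#'
#' For a diploid site with `n` non-missing alleles of which `j` are
#' alternate, pi = 2 j (n - j) / (n (n - 1)): the expected proportion of
#' differing allele pairs drawn without replacement.
#'
#' @param genotypes integer matrix sites x individuals (0/1/2, `NA`
#'   missing), or a single site's vector.
#' @return numeric vector of pi per site; `NA` where fewer than 2 alleles
#'   are observed.
#' @export
site_pi <- function(genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
  j <- rowSums(genotypes, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(genotypes))
  out <- ifelse(n >= 2, 2 * j * (n - j) / (n * pmax(n - 1, 1)), NA_real_)
  unname(out)
}

#' Per-individual mutation load per kb
#'
#' For each individual and effect category, counts homozygous-alternate
#' calls and scales by the summed canonical transcript length (in kb) of
#' the whole gene group (all TF triad genes or all non-TF triad genes),
#' not the per-gene length.
#'
#' @param variants classified variant table (with `category`).
#' @param genotypes matching genotype matrix.
#' @param genes gene table of all triad genes with `gene_id`,
#'   `transcript_length` and `family` (`NA` = non-TF); defines the group
#'   denominators.
#' @return tibble `individual`, `group` (TF / non-TF), `category`,
#'   `n_hom_alt`, `load_per_kb`.
#' @export
mutation_load <- function(variants, genotypes, genes) {
  genes <- as_tibble(genes)
  genes$group <- ifelse(is.na(genes$family), "non-TF", "TF")
  kb <- genes |>
    group_by(.data$group) |>
    summarise(kb = sum(.data$transcript_length) / 1000)
  if (any(kb$kb <= 0) || nrow(kb) < 1L) {
    abort("total canonical transcript length must be positive for each group.")
  }
  variants <- as_tibble(variants)
  variants$group <- genes$group[match(variants$gene_id, genes$gene_id)]
  if (any(is.na(variants$group))) {
    abort("variant in a gene absent from the gene table.")
  }
  g <- genotypes[match(variants$snp_id, rownames(genotypes)), , drop = FALSE]
  hom <- !is.na(g) & g == 2L
  cats <- c("stop_gained", "deleterious_missense", "tolerated_missense",
            "synonymous")
  combos <- expand.grid(group = kb$group, category = cats,
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(combos)), function(i) {
    rows <- variants$group == combos$group[i] &
      variants$category == combos$category[i]
    counts <- colSums(hom[rows, , drop = FALSE])
    tibble(
      individual = colnames(genotypes),
      group = combos$group[i], category = combos$category[i],
      n_hom_alt = as.integer(counts),
      load_per_kb = unname(counts) / kb$kb[kb$group == combos$group[i]]
    )
  })
  bind_rows(out)
}

#' Flag individuals with extreme mutation loads
#'
#' An individual is flagged when its load falls strictly outside the
#' central 1 - 2*`tail` empirical quantile interval (linear-interpolation
#' quantiles) of *any* group-by-category load distribution.
#'
#' @param load_table output of [mutation_load()].
#' @param tail tail mass on each side (default 0.025).
#' @return character vector of flagged individual ids.
#' @export
flag_extreme_individuals <- function(load_table, tail = 0.025) {
  flagged <- load_table |>
    group_by(.data$group, .data$category) |>
    group_modify(function(d, key) {
      q <- stats::quantile(d$load_per_kb, c(tail, 1 - tail), type = 7,
                           names = FALSE)
      d[d$load_per_kb < q[1L] | d$load_per_kb > q[2L], "individual"]
    }) |>
    ungroup()
  sort(unique(flagged$individual))
}

#' Per-family SNP effect proportions
#'
#' Drops SNPs whose alternate allele is carried only by flagged extreme
#' individuals, then tabulates the proportion of SNPs in each effect
#' category for every TF family with more than `min_triads` triads and at
#' least `min_snps` SNPs, plus the pooled non-TF genes. Families are
#' sorted by their share of deleterious missense plus stop-gained SNPs.
#'
#' @param variants classified variant table.
#' @param genotypes matching genotype matrix.
#' @param gene_families named character vector gene_id -> family (`NA` for
#'   non-TF genes).
#' @param family_triad_counts named vector of triad counts per family.
#' @param extreme character vector of extreme individual ids.
#' @param min_triads,min_snps inclusion thresholds (defaults: more than 10
#'   triads, at least 5 SNPs).
#' @return tibble per family: `family`, `n_snps`, one proportion column
#'   per category, `pct_deleterious_plus_stop`.
#' @export
family_snp_proportions <- function(variants, genotypes, gene_families,
                                   family_triad_counts, extreme,
                                   min_triads = 10, min_snps = 5) {
  variants <- as_tibble(variants)
  g <- genotypes[match(variants$snp_id, rownames(genotypes)), , drop = FALSE]
  carrier <- !is.na(g) & g >= 1L
  non_extreme <- !(colnames(genotypes) %in% extreme)
  # a SNP survives if at least one carrier is a non-extreme individual
  keep <- rowSums(carrier[, non_extreme, drop = FALSE]) > 0
  variants <- variants[keep, ]

  variants$family <- unname(gene_families[variants$gene_id])
  variants$fam_label <- ifelse(is.na(variants$family), "non-TF", variants$family)
  eligible_fams <- names(family_triad_counts)[family_triad_counts > min_triads]
  variants <- variants[variants$fam_label == "non-TF" |
                         variants$fam_label %in% eligible_fams, ]
  cats <- c("stop_gained", "deleterious_missense", "tolerated_missense",
            "synonymous")
  out <- variants |>
    group_by(family = .data$fam_label) |>
    summarise(
      n_snps = n(),
      prop_stop_gained = mean(.data$category == "stop_gained"),
      prop_deleterious_missense = mean(.data$category == "deleterious_missense"),
      prop_tolerated_missense = mean(.data$category == "tolerated_missense"),
      prop_synonymous = mean(.data$category == "synonymous")
    ) |>
    filter(.data$family == "non-TF" | .data$n_snps >= min_snps) |>
    mutate(pct_deleterious_plus_stop =
             100 * (.data$prop_deleterious_missense + .data$prop_stop_gained)) |>
    arrange(desc(.data$family == "non-TF"),
            desc(.data$pct_deleterious_plus_stop))
  out
}

#' Contrast TF and non-TF mutation loads
#'
#' Fits a fixed-effects linear model of load on effect category and gene
#' group, reports the ANOVA, the Tukey honest-significant-difference
#' contrast of TF vs non-TF within each category, and the percent load
#' difference 100 * (load_nonTF - load_TF) / load_nonTF per category.
#'
#' @param load_table output of [mutation_load()].
#' @return list `anova`, `tukey`, `percent_difference` (tibble: category,
#'   mean_tf, mean_nontf, pct_difference).
#' @export
compare_loads <- function(load_table) {
  at <- anova_tukey(load_table$load_per_kb,
                    factor(load_table$category),
                    factor(load_table$group, levels = c("non-TF", "TF")))
  pd <- load_table |>
    group_by(.data$category, .data$group) |>
    summarise(mean_load = mean(.data$load_per_kb), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_load") |>
    mutate(pct_difference = 100 * (.data$`non-TF` - .data$TF) / .data$`non-TF`) |>
    rename(mean_tf = "TF", mean_nontf = "non-TF")
  list(anova = at$anova,
       tukey = rename(at$tukey, category = "level_a"),
       percent_difference = pd)
}
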