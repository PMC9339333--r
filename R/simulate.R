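#' Simulate gene complements and homoeolog tables across ploidy levels
#'
#' Realizes each ancestral gene group through the two
#' hybridization/whole-genome-duplication steps: every group is present in
#' both diploid progenitor genomes (A and D); it survives as a 1:1 A-B diad
#' in the tetraploid with its family's `diad_prob` (otherwise a single A or
#' B copy remains); a surviving diad is completed into a 1:1:1 A-B-D triad
#' in the hexaploid with conditional probability `triad_prob / diad_prob`.
#' Within each assembly, genes are renumbered so identifiers increase by
#' 100 between adjacent genes; tandem duplicates are then inserted with
#' intermediate identifiers (+50) so a gene-order detector sees them as
#' adjacent. Non-duplicate genes of the same TF family are kept at least
#' four positions apart so that every gene-order adjacency within a family
#' is a recorded duplication event.
#'
#' @param config a [sim_config()] object.
#' @return a `synthetic_study` list with `genes` (all ploidy levels),
#'   `homoeologs` (`zavitan` and `biomart` dialect tables), `isoforms`,
#'   and `truth` (per-group realized cardinality and per-duplicate tandem
#'   events).
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_groups
  fam <- config$families

  groups <- tibble(
    group_id = sprintf("G%06d", seq_len(n)),
    is_tf = runif(n) < config$tf_fraction
  )
  groups$family <- NA_character_
  n_tf <- sum(groups$is_tf)
  if (n_tf > 0) {
    groups$family[groups$is_tf] <-
      sample(fam$family, n_tf, replace = TRUE, prob = fam$share)
  }
  par_of <- function(col) {
    out <- rep(config$nontf[[col]], n)
    idx <- match(groups$family, fam$family)
    out[!is.na(idx)] <- fam[[col]][idx[!is.na(idx)]]
    out
  }
  p_diad <- par_of("diad_prob")
  p_triad <- par_of("triad_prob")
  groups$chrom_idx <- sample.int(config$n_chromosomes, n, replace = TRUE)
  groups$diad <- runif(n) < p_diad
  cond <- ifelse(p_diad > 0, p_triad / p_diad, 0)
  groups$triad <- groups$diad & (runif(n) < cond)
  groups$single_sub <- ifelse(runif(n) < 0.5, "A", "B")

  # ancestral order within each chromosome (shared by all ploidy levels)
  groups <- groups |>
    group_by(.data$chrom_idx) |>
    mutate(anc_order = sample.int(n())) |>
    ungroup()

  member_rows <- function(g, sub) {
    tibble(group_id = g$group_id, family = g$family, is_tf = g$is_tf,
           chrom_idx = g$chrom_idx, anc_order = g$anc_order, subgenome = sub)
  }
  ploidy_members <- list(
    diploid_A  = member_rows(groups, "A"),
    diploid_D  = member_rows(groups, "D"),
    tetraploid = bind_rows(
      member_rows(groups[groups$diad, ], "A"),
      member_rows(groups[groups$diad, ], "B"),
      member_rows(groups[!groups$diad, ],
                  groups$single_sub[!groups$diad])
    ),
    hexaploid  = bind_rows(
      member_rows(groups[groups$diad, ], "A"),
      member_rows(groups[groups$diad, ], "B"),
      member_rows(groups[!groups$diad, ],
                  groups$single_sub[!groups$diad]),
      member_rows(groups[groups$triad, ], "D")
    )
  )

  genes <- bind_rows(lapply(names(ploidy_members), function(pl) {
    m <- ploidy_members[[pl]]
    m$ploidy <- pl
    m$chromosome <- paste0(m$chrom_idx, m$subgenome)
    m <- m |> arrange(.data$chromosome, .data$anc_order)
    if (pl == "hexaploid") m <- space_out_families(m)
    m |>
      group_by(.data$chromosome) |>
      mutate(ordinal = as.numeric(seq_len(n()))) |>
      ungroup()
  }))
  genes$gene_id <- sprintf("SynG%s%s%07d", substr(genes$ploidy, 1, 1),
                           genes$chromosome, as.integer(genes$ordinal * 100))
  genes$confidence <- "HC"
  genes$transcript_length <- pmax(150L, as.integer(round(
    rlnorm(nrow(genes), meanlog = log(1200), sdlog = 0.35))))

  # tandem duplicates in the hexaploid assembly, inserted between neighbours
  tandem_rate <- rep(config$nontf$tandem_rate, nrow(genes))
  idx <- match(genes$family, fam$family)
  tandem_rate[!is.na(idx)] <- fam$tandem_rate[idx[!is.na(idx)]]
  dup_parent <- genes$ploidy == "hexaploid" & runif(nrow(genes)) < tandem_rate
  dups <- genes[dup_parent, ]
  tandem_truth <- tibble(
    parent_gene_id = dups$gene_id, family = dups$family,
    chromosome = dups$chromosome, ordinal_parent = dups$ordinal
  )
  if (nrow(dups)) {
    dups$ordinal <- dups$ordinal + 0.5
    dups$gene_id <- sprintf("SynGh%s%07d", dups$chromosome,
                            as.integer(dups$ordinal * 100))
    dups$group_id <- NA_character_
    dups$transcript_length <- pmax(150L, as.integer(round(
      dups$transcript_length * exp(rnorm(nrow(dups), 0, 0.1)))))
    tandem_truth$gene_id <- dups$gene_id
    genes <- bind_rows(genes, dups)
  } else {
    tandem_truth$gene_id <- character(0)
  }
  genes <- genes |>
    arrange(.data$ploidy, .data$chromosome, .data$ordinal) |>
    select("gene_id", "ploidy", "group_id", "subgenome", "chromosome",
           "ordinal", "confidence", "transcript_length", "family", "is_tf")

  hexa <- genes[genes$ploidy == "hexaploid", ]
  id_of <- function(gid, sub) {
    key <- paste(hexa$group_id, hexa$subgenome)
    hexa$gene_id[match(paste(gid, sub), key)]
  }
  tet <- genes[genes$ploidy == "tetraploid", ]
  tid_of <- function(gid, sub) {
    key <- paste(tet$group_id, tet$subgenome)
    tet$gene_id[match(paste(gid, sub), key)]
  }

  # tetraploid dialect: one row per group, non-1:1 groups labelled
  zavitan <- tibble(
    group_id = groups$group_id,
    gene_A = tid_of(groups$group_id, "A"),
    gene_B = tid_of(groups$group_id, "B"),
    type = ifelse(groups$diad, "homoeolog", "singleton")
  )
  # hexaploid dialect: pairwise one2one rows (A-B for diads; A-B, B-D, A-D
  # for triads), as a Biomart homoeolog export would list them
  di <- groups[groups$diad, ]
  tr <- groups[groups$triad, ]
  biomart <- bind_rows(
    tibble(gene_1 = id_of(di$group_id, "A"), gene_2 = id_of(di$group_id, "B"),
           homoeology_type = "one2one"),
    tibble(gene_1 = id_of(tr$group_id, "B"), gene_2 = id_of(tr$group_id, "D"),
           homoeology_type = "one2one"),
    tibble(gene_1 = id_of(tr$group_id, "A"), gene_2 = id_of(tr$group_id, "D"),
           homoeology_type = "one2one")
  )

  isoforms <- simulate_isoforms(genes[genes$ploidy == "hexaploid", ], config)

  truth_groups <- groups |>
    mutate(
      cardinality_tetraploid = ifelse(.data$diad, "diad", "singleton"),
      cardinality_hexaploid = case_when(
        .data$triad ~ "triad",
        .data$diad ~ "diad",
        TRUE ~ "singleton"
      )
    ) |>
    select("group_id", "family", "is_tf", "cardinality_tetraploid",
           "cardinality_hexaploid")

  structure(
    list(
      config = config,
      genes = genes,
      homoeologs = list(zavitan = zavitan, biomart = biomart),
      isoforms = isoforms,
      truth = list(groups = truth_groups, tandem = tandem_truth)
    ),
    class = "synthetic_study"
  )
}

# keep non-duplicate genes of the same TF family at least 4 positions apart
# so every within-family gene-order adjacency is an inserted duplicate
space_out_families <- function(members) {
  members |>
    group_by(.data$chromosome) |>
    group_modify(function(d, key) {
      fam <- d$family
      m <- nrow(d)
      ord <- seq_len(m)
      for (pass in seq_len(50)) {
        bad <- integer(0)
        for (off in 1:3) {
          i <- seq_len(max(0, m - off))
          hit <- i[!is.na(fam[i]) & !is.na(fam[i + off]) & fam[i] == fam[i + off]]
          bad <- union(bad, hit + off)
        }
        if (!length(bad)) break
        for (j in bad) {
          k <- sample.int(m, 1)
          if (k == j) next
          fam[c(j, k)] <- fam[c(k, j)]
          ord[c(j, k)] <- ord[c(k, j)]
        }
      }
      d[ord, ]
    }) |>
    ungroup()
}

# a small fraction of TF genes get a second, truncated isoform carrying a
# vaguer family label; the gene table keeps the longest isoform's family
simulate_isoforms <- function(hexa, config) {
  tf <- hexa[!is.na(hexa$family), ]
  iso <- tibble(
    gene_id = tf$gene_id,
    isoform_id = paste0(tf$gene_id, ".1"),
    length = tf$transcript_length,
    family = tf$family
  )
  second <- runif(nrow(tf)) < 0.05
  if (any(second)) {
    iso2 <- tibble(
      gene_id = tf$gene_id[second],
      isoform_id = paste0(tf$gene_id[second], ".2"),
      length = pmax(90L, as.integer(round(tf$transcript_length[second] * 0.6))),
      family = paste0(tf$family[second], "-related")
    )
    iso <- bind_rows(iso, iso2) |> arrange(.data$gene_id, .data$isoform_id)
  }
  iso
}

#' Simulate a tissue-by-replicate tpm expression matrix
#'
#' Expression is lognormal: each gene has a baseline (family-level
#' log-mean, group-level draw, small per-homoeolog offset) and a tissue
#' profile built from a latent profile shared by the whole homoeolog group
#' plus independent gene noise. The mixing weight is solved in closed form
#' so that the population Pearson correlation between homoeolog profiles
#' of replicate-mean tpm equals `config$homoeolog_correlation` (the
#' solution accounts for the lognormal transform and for replicate-noise
#' variance inflation). Replicates are multiplicative lognormal noise with
#' unit mean.
#'
#' @param study a `synthetic_study` from [simulate_genomes()].
#' @param config the same [sim_config()].
#' @return the study with `expression` (matrix genes x samples) and
#'   `sample_map` (tibble sample, tissue, replicate) added.
#' @export
simulate_expression <- function(study, config) {
  stopifnot(inherits(study, "synthetic_study"))
  if (config$n_tissues < 2) abort("`n_tissues` must be at least 2 (correlation over tissues is undefined).")
  set.seed(config$seed + 1L)
  genes <- study$genes |> filter(.data$ploidy == "hexaploid")
  fam <- config$families
  n_g <- nrow(genes)
  Tn <- config$n_tissues; R <- config$n_replicates
  sb <- config$tissue_log_sd; sr <- config$replicate_log_sd
  rho <- config$homoeolog_correlation

  v_rep <- (exp(sr^2) - 1) / R
  denom <- exp(sb^2) * (1 + v_rep) - 1
  a <- log(1 + rho * denom) / sb^2
  if (a < 0 || a > 1) {
    warn(sprintf("target correlation %.3f not attainable with tissue_log_sd %.2f and replicate noise; clamping latent weight.",
                 rho, sb))
    a <- min(max(a, 0), 1)
  }

  grp <- ifelse(is.na(genes$group_id), genes$gene_id, genes$group_id)
  grp_ids <- unique(grp)
  S <- matrix(rnorm(length(grp_ids) * Tn), nrow = length(grp_ids),
              dimnames = list(grp_ids, NULL))

  log_mean <- rep(config$nontf$log_mean, n_g)
  log_sd <- rep(config$nontf$log_sd, n_g)
  idx <- match(genes$family, fam$family)
  log_mean[!is.na(idx)] <- fam$log_mean[idx[!is.na(idx)]]
  log_sd[!is.na(idx)] <- fam$log_sd[idx[!is.na(idx)]]
  b_group <- setNames(rnorm(length(grp_ids)), grp_ids)
  b_gene <- log_mean + log_sd * b_group[grp] +
    config$balance_log_sd * rnorm(n_g)

  E <- matrix(rnorm(n_g * Tn), nrow = n_g)
  L <- b_gene + sb * (sqrt(a) * S[grp, , drop = FALSE] + sqrt(1 - a) * E)

  tpm <- matrix(0, nrow = n_g, ncol = Tn * R)
  for (r in seq_len(R)) {
    eta <- matrix(rnorm(n_g * Tn, 0, sr), nrow = n_g)
    tpm[, (r - 1L) * Tn + seq_len(Tn)] <- exp(L + eta - sr^2 / 2)
  }
  silenced <- runif(n_g) < config$zero_expression_rate
  tpm[silenced, ] <- 0

  sample_map <- tibble(
    tissue = rep(sprintf("tissue%02d", seq_len(Tn)), times = R),
    replicate = rep(seq_len(R), each = Tn)
  )
  sample_map$sample <- paste0(sample_map$tissue, "_rep", sample_map$replicate)
  dimnames(tpm) <- list(genes$gene_id, sample_map$sample)

  study$expression <- tpm
  study$sample_map <- sample_map[, c("sample", "tissue", "replicate")]
  study$truth$expression <- list(latent_weight = a, target_r = rho,
                                 silenced = genes$gene_id[silenced])
  study
}

#' Simulate coexpression-network module assignments
#'
#' Emulates a module table from a prior WGCNA-style network: each gene may
#' fall in the unassigned module 0; among triads whose three homoeologs
#' all have a non-zero module, all three share a module with the
#' configured TF or non-TF co-membership probability, otherwise their
#' modules are drawn so that they do not all coincide.
#'
#' @inheritParams simulate_expression
#' @return the study with `modules` (tibble gene_id, module) added.
#' @export
simulate_modules <- function(study, config) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(config$seed + 2L)
  genes <- study$genes |> filter(.data$ploidy == "hexaploid")
  K <- config$n_modules
  module <- ifelse(runif(nrow(genes)) < config$module0_rate, 0L,
                   sample.int(K, nrow(genes), replace = TRUE))
  names(module) <- genes$gene_id

  triads <- study$truth$groups |> filter(.data$cardinality_hexaploid == "triad")
  members <- genes |>
    filter(.data$group_id %in% triads$group_id) |>
    group_by(.data$group_id) |>
    summarise(ids = list(.data$gene_id), tf = any(.data$is_tf))
  comember_truth <- logical(nrow(members))
  for (i in seq_len(nrow(members))) {
    ids <- members$ids[[i]]
    if (any(module[ids] == 0L)) next
    p <- if (members$tf[i]) config$module_comembership[["tf"]] else
      config$module_comembership[["nontf"]]
    if (runif(1) < p) {
      module[ids] <- sample.int(K, 1)
      comember_truth[i] <- TRUE
    } else {
      repeat {
        m3 <- sample.int(K, 3, replace = TRUE)
        if (length(unique(m3)) > 1) break
      }
      module[ids] <- m3
    }
  }
  study$modules <- tibble(gene_id = names(module), module = unname(module))
  study$truth$modules <- tibble(group_id = members$group_id,
                                comember = comember_truth)
  study
}

#' Simulate a cohort variant table and genotype matrix
#'
#' Places SNPs in the canonical coding sequence of hexaploid triad genes
#' at per-kb Poisson rates per effect category; TF genes' rates are scaled
#' by `config$tf_rate_factor`. Each site draws an alternate-allele
#' frequency from the configured Beta spectrum; genotypes follow
#' Hardy-Weinberg at that frequency, with independent per-call
#' missingness. SIFT scores are drawn at or below 0.05 for deleterious
#' missense sites and above 0.05 for tolerated ones; small fractions of
#' sites carry splice co-annotations, fall outside the canonical CDS,
#' carry selection/introgression region flags, or are multi-annotated
#' synonymous sites, so the downstream filter cascade has work to do.
#'
#' @inheritParams simulate_expression
#' @return the study with `variants` (tibble) and `genotypes` (integer
#'   matrix sites x individuals, NA = missing call) added.
#' @export
simulate_cohort <- function(study, config) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(config$seed + 3L)
  genes <- study$genes |> filter(.data$ploidy == "hexaploid")
  triads <- study$truth$groups |> filter(.data$cardinality_hexaploid == "triad")
  genes <- genes |> filter(.data$group_id %in% triads$group_id)
  if (any(genes$transcript_length <= 0)) {
    warn(sprintf("%d genes with zero-length canonical transcript skipped.",
                 sum(genes$transcript_length <= 0)))
    genes <- genes[genes$transcript_length > 0, ]
  }

  sift_frac <- config$sift_deleterious_fraction
  base <- c(
    stop_gained        = unname(config$snp_rates[["stop_gained"]]),
    deleterious_missense = unname(config$snp_rates[["missense"]]) * sift_frac,
    tolerated_missense = unname(config$snp_rates[["missense"]]) * (1 - sift_frac),
    synonymous         = unname(config$snp_rates[["synonymous"]])
  )
  fac <- config$tf_rate_factor[names(base)]
  len_kb <- genes$transcript_length / 1000

  site_list <- lapply(names(base), function(cat) {
    lam <- base[[cat]] * len_kb * ifelse(genes$is_tf, fac[[cat]], 1)
    k <- rpois(nrow(genes), lam)
    tibble(gene_id = rep(genes$gene_id, k), true_category = cat)
  })
  sites <- bind_rows(site_list)
  n_s <- nrow(sites)
  if (n_s == 0) {
    study$variants <- empty_variant_table()
    study$genotypes <- matrix(integer(0), nrow = 0, ncol = config$n_individuals)
    study$truth$cohort <- list(rates = base, tf_factor = fac)
    return(study)
  }
  gi <- match(sites$gene_id, genes$gene_id)
  sites <- sites[order(genes$chromosome[gi], genes$ordinal[gi]), ]
  gi <- match(sites$gene_id, genes$gene_id)

  sites$snp_id <- sprintf("snp%07d", seq_len(n_s))
  sites$chromosome <- genes$chromosome[gi]
  sites$position <- as.integer(genes$ordinal[gi] * 100000) +
    unlist(lapply(rle(sites$gene_id)$lengths, sample.int, replace = FALSE))
  sites$consequence <- c(stop_gained = "stop_gained",
                         deleterious_missense = "missense",
                         tolerated_missense = "missense",
                         synonymous = "synonymous")[sites$true_category]
  sites$sift <- NA_real_
  del <- sites$true_category == "deleterious_missense"
  tol <- sites$true_category == "tolerated_missense"
  sites$sift[del] <- runif(sum(del), 0, 0.05)
  sites$sift[tol] <- runif(sum(tol), 0.05 + 1e-9, 1)
  drop_sift <- (del | tol) & runif(n_s) < config$missense_no_sift_rate
  sites$sift[drop_sift] <- NA_real_
  sites$in_canonical_cds <- runif(n_s) >= config$non_canonical_rate
  sites$splice_region <- runif(n_s) < config$splice_overlap_rate
  for (flag in names(config$region_flag_rates)) {
    sites[[flag]] <- runif(n_s) < config$region_flag_rates[[flag]]
  }
  sites$n_annotations <- 1L + as.integer(
    sites$consequence == "synonymous" & runif(n_s) < config$multi_annotation_rate)

  shp <- config$maf_spectrum
  N <- config$n_individuals
  floor_f <- 1 / (2 * N)
  sites$alt_freq <- pmin(pmax(rbeta(n_s, shp[["shape1"]], shp[["shape2"]]),
                              floor_f), 1 - floor_f)

  geno <- matrix(rbinom(n_s * N, 2L, rep(sites$alt_freq, times = N)),
                 nrow = n_s)
  geno[matrix(runif(n_s * N) < config$missing_rate, nrow = n_s)] <- NA_integer_
  rownames(geno) <- sites$snp_id
  colnames(geno) <- sprintf("ind%04d", seq_len(N))

  study$variants <- sites |>
    select("snp_id", "gene_id", "chromosome", "position", "consequence",
           "sift", "in_canonical_cds", "splice_region", "adaptation",
           "improvement", "sweep", "introgression", "n_annotations",
           "true_category", "alt_freq")
  study$genotypes <- geno
  study$truth$cohort <- list(rates = base, tf_factor = fac)
  study
}

empty_variant_table <- function() {
  tibble(
    snp_id = character(0), gene_id = character(0), chromosome = character(0),
    position = integer(0), consequence = character(0), sift = numeric(0),
    in_canonical_cds = logical(0), splice_region = logical(0),
    adaptation = logical(0), improvement = logical(0), sweep = logical(0),
    introgression = logical(0), n_annotations = integer(0),
    true_category = character(0), alt_freq = numeric(0)
  )
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_genomes()], [simulate_expression()],
#' [simulate_modules()] and [simulate_cohort()] in order and attaches a
#' run manifest echoing the configuration and per-table row counts.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_study` list.
#' @export
simulate_study <- function(config = sim_config()) {
  study <- simulate_genomes(config)
  study <- simulate_expression(study, config)
  study <- simulate_modules(study, config)
  study <- simulate_cohort(study, config)
  study$manifest <- list(
    seed = config$seed,
    config = config_as_list(config),
    counts = list(
      genes = nrow(study$genes),
      groups = nrow(study$truth$groups),
      expression_samples = ncol(study$expression),
      variants = nrow(study$variants),
      individuals = ncol(study$genotypes)
    )
  )
  study
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$families <- as.data.frame(out$families)
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat(sprintf("  %d ancestral groups; %d gene records over 4 ploidy levels\n",
              nrow(x$truth$groups), nrow(x$genes)))
  if (!is.null(x$expression)) {
    cat(sprintf("  expression: %d genes x %d samples\n",
                nrow(x$expression), ncol(x$expression)))
  }
  if (!is.null(x$variants)) {
    cat(sprintf("  cohort: %d SNPs x %d individuals\n",
                nrow(x$variants), ncol(x$genotypes)))
  }
  invisible(x)
}
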