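#' Parse the gene-order ordinal out of a gene identifier
#'
#' Gene identifiers in these assemblies end in a number that increases by
#' 100 between adjacent genes, so the ordinal is the trailing number
#' divided by 100 (tandem insertions carry intermediate numbers and yield
#' half-integer ordinals).
#'
#' @param gene_id character vector of gene identifiers.
#' @return numeric ordinals.
#' @export
parse_gene_ordinal <- function(gene_id) {
  num <- sub("^.*?([0-9]+)$", "\\1", gene_id)
  bad <- !grepl("[0-9]+$", gene_id)
  if (any(bad)) {
    abort(sprintf("gene id without a trailing ordinal: %s", gene_id[bad][1L]))
  }
  as.numeric(num) / 100
}

#' Resolve a gene's TF family from its transcript isoforms
#'
#' When isoforms of one gene are assigned to different TF families
#' (typically because a truncated isoform lacks the domain that pins down
#' the family), the family of the longest isoform is kept. Ties in length
#' are broken deterministically by the lexicographically smallest isoform
#' identifier.
#'
#' @param isoforms data frame with columns `isoform_id`, `length`,
#'   `family` (one gene's isoforms).
#' @return single family string.
#' @export
resolve_family <- function(isoforms) {
  isoforms <- as_tibble(isoforms)
  if (nrow(isoforms) == 0) abort("`isoforms` must contain at least one isoform.")
  ord <- order(-isoforms$length, isoforms$isoform_id)
  isoforms$family[ord[1L]]
}

#' Resolve a homoeolog group's family from its members' families
#'
#' The family shared by the majority of members is kept (for a triad,
#' unanimity or two-of-three). If no family reaches a majority (all
#' members disagree), the group is flagged unresolved and `NA` is
#' returned.
#'
#' @param member_families character vector of the group's member families.
#' @return single family string, or `NA` if unresolved.
#' @export
resolve_group_family <- function(member_families) {
  member_families <- member_families[!is.na(member_families)]
  if (!length(member_families)) return(NA_character_)
  tab <- sort(table(member_families), decreasing = TRUE)
  if (tab[1L] >= 2L) names(tab)[1L] else NA_character_
}

# vectorized majority rule over up to three member families (NA = non-TF);
# equivalent to resolve_group_family() row by row
resolve_group_family_vec <- function(f1, f2, f3) {
  eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
  out <- rep(NA_character_, length(f1))
  out[eq(f2, f3)] <- f2[eq(f2, f3)]
  out[eq(f1, f3)] <- f1[eq(f1, f3)]
  out[eq(f1, f2)] <- f1[eq(f1, f2)]
  out
}

#' Classify homoeolog groups from a raw homoeology table
#'
#' Two input dialects are supported. `"zavitan"` (tetraploid): one row per
#' group with `group_id`, `gene_A`, `gene_B`, `type`; rows labelled
#' `"singleton"` or `"hit2homolog"` (paralogous hits) are removed and the
#' remaining 1:1 rows become diads. `"biomart"` (hexaploid): pairwise rows
#' `gene_1`, `gene_2`, `homoeology_type`; only `"one2one"` rows are kept,
#' genes are optionally restricted to high-confidence models, and the
#' connected components of the resulting homoeology graph are classified
#' as triad (one gene each on A, B and D), diad (one A and one B),
#' singleton, or other. Per-stage removal counts are attached as the
#' `"filter_log"` attribute.
#'
#' @param tbl the raw homoeolog table.
#' @param dialect `"biomart"` or `"zavitan"`.
#' @param genes optional gene table (columns `gene_id`, `confidence`) used
#'   to restrict the biomart dialect to high-confidence genes; subgenomes
#'   are parsed from the chromosome letter in the gene identifiers.
#' @param confidence_filter keep only genes with this confidence class in
#'   the biomart dialect (default `"HC"`; `NULL` disables the filter).
#' @return tibble with `group_id`, `A`, `B`, `D`, `cardinality_class`,
#'   `n_members`; attribute `filter_log` holds per-stage counts.
#' @export
classify_groups <- function(tbl, dialect = c("biomart", "zavitan"),
                            genes = NULL, confidence_filter = "HC") {
  dialect <- match.arg(dialect)
  tbl <- as_tibble(tbl)
  if (dialect == "zavitan") {
    log <- tibble(stage = "input", n = nrow(tbl))
    drop_lab <- c("singleton", "hit2homolog")
    for (lab in drop_lab) {
      tbl <- tbl[tbl$type != lab, ]
      log <- bind_rows(log, tibble(stage = paste0("remove_", lab), n = nrow(tbl)))
    }
    all_genes <- c(tbl$gene_A, tbl$gene_B)
    dup <- all_genes[duplicated(all_genes)]
    if (length(dup)) {
      abort(sprintf("gene %s appears in more than one homoeolog group.", dup[1L]))
    }
    out <- tibble(
      group_id = tbl$group_id, A = tbl$gene_A, B = tbl$gene_B,
      D = NA_character_, cardinality_class = "diad", n_members = 2L
    )
    attr(out, "filter_log") <- log
    return(out)
  }

  log <- tibble(stage = "input", n = nrow(tbl))
  tbl <- tbl[tbl$homoeology_type == "one2one", ]
  log <- bind_rows(log, tibble(stage = "one2one_only", n = nrow(tbl)))
  if (!is.null(genes) && !is.null(confidence_filter)) {
    hc <- genes$gene_id[genes$confidence == confidence_filter]
    tbl <- tbl[tbl$gene_1 %in% hc & tbl$gene_2 %in% hc, ]
    log <- bind_rows(log, tibble(stage = "high_confidence_only", n = nrow(tbl)))
  }
  ids <- unique(c(tbl$gene_1, tbl$gene_2))
  if (!length(ids)) {
    out <- tibble(group_id = character(0), A = character(0), B = character(0),
                  D = character(0), cardinality_class = character(0),
                  n_members = integer(0))
    attr(out, "filter_log") <- log
    return(out)
  }
  g <- igraph::graph_from_data_frame(tbl[, c("gene_1", "gene_2")],
                                     directed = FALSE, vertices = ids)
  comp <- unname(igraph::components(g)$membership)
  sub <- parse_subgenome(ids)
  k <- max(comp)
  n_members <- tabulate(comp, nbins = k)
  count_sub <- function(letter) tabulate(comp[sub == letter], nbins = k)
  first_sub <- function(letter) {
    idx <- which(sub == letter)
    idx <- idx[!duplicated(comp[idx])]
    out <- rep(NA_character_, k)
    out[comp[idx]] <- ids[idx]
    out
  }
  nA <- count_sub("A"); nB <- count_sub("B"); nD <- count_sub("D")
  cls <- rep("other", k)
  cls[n_members == 1L] <- "singleton"
  cls[n_members == 2L & nA == 1L & nB == 1L] <- "diad"
  cls[n_members == 3L & nA == 1L & nB == 1L & nD == 1L] <- "triad"
  out <- tibble(
    group_id = sprintf("HG%06d", seq_len(k)),
    A = first_sub("A"), B = first_sub("B"), D = first_sub("D"),
    cardinality_class = cls, n_members = n_members
  )
  attr(out, "filter_log") <- log
  out
}

parse_subgenome <- function(gene_id) {
  s <- sub("^.*([ABD])[0-9]+$", "\\1", gene_id)
  bad <- !s %in% c("A", "B", "D")
  if (any(bad)) {
    abort(sprintf("cannot parse subgenome from gene id %s", gene_id[bad][1L]))
  }
  s
}

#' Per-family homoeolog retention with enrichment tests
#'
#' For each TF family (and the pooled non-TF genes), computes the number
#' of genes, the number that are members of complete homoeolog groups
#' (triads in hexaploid, diads in tetraploid) and the percentage retained.
#' Each TF family is tested against the non-TF genes with a two-sided
#' Fisher's exact test on the (retained, not-retained) 2x2 table, with
#' Benjamini-Hochberg adjustment across families. Group-level family
#' counts use the majority rule of [resolve_group_family()]; groups whose
#' three members all disagree are excluded from per-family group counts.
#'
#' @param genes gene table for one ploidy level, with columns `gene_id`
#'   and `family` (`NA` for non-TF genes).
#' @param groups classified groups from [classify_groups()].
#' @param complete which cardinality class counts as complete
#'   (`"triad"` or `"diad"`).
#' @param min_groups if positive, per-family rows are restricted to
#'   families with strictly more than `min_groups` complete groups (the
#'   figure-level rule uses 10); the non-TF row is always kept.
#' @return list with `per_family` (tibble: family, n_genes,
#'   n_in_complete, pct_complete, n_complete_groups, odds_ratio, p_value,
#'   p_adjusted) and `overall` (one-row tibble comparing all TF genes to
#'   non-TF genes).
#' @export
retention_percentages <- function(genes, groups,
                                  complete = c("triad", "diad"),
                                  min_groups = 0) {
  complete <- match.arg(complete)
  genes <- as_tibble(genes)
  comp <- groups[groups$cardinality_class == complete, , drop = FALSE]
  member_ids <- c(comp$A, comp$B, comp$D)
  member_ids <- member_ids[!is.na(member_ids)]

  fam_of <- setNames(genes$family, genes$gene_id)
  grp_fams <- resolve_group_family_vec(unname(fam_of[comp$A]),
                                       unname(fam_of[comp$B]),
                                       unname(fam_of[comp$D]))
  grp_counts <- table(grp_fams[!is.na(grp_fams)])

  tab <- genes |>
    mutate(
      fam_label = ifelse(is.na(.data$family), "non-TF", .data$family),
      in_complete = .data$gene_id %in% member_ids
    ) |>
    group_by(.data$fam_label) |>
    summarise(
      n_genes = n(),
      n_in_complete = sum(.data$in_complete),
      pct_complete = 100 * .data$n_in_complete / .data$n_genes
    ) |>
    rename(family = "fam_label")
  tab$n_complete_groups <- as.integer(grp_counts[tab$family])
  tab$n_complete_groups[is.na(tab$n_complete_groups)] <- 0L

  nt <- tab[tab$family == "non-TF", ]
  if (nrow(nt) == 0) {
    nt <- tibble(n_genes = 0L, n_in_complete = 0L)
  }
  test_one <- function(n_in, n_genes) {
    if (nt$n_genes == 0 || n_genes == 0) return(c(NA_real_, NA_real_))
    ft <- fisher_exact_2x2(matrix(c(n_in, n_genes - n_in,
                                    nt$n_in_complete, nt$n_genes - nt$n_in_complete),
                                  nrow = 2))
    c(ft$statistic, ft$p_value)
  }
  res <- t(mapply(test_one, tab$n_in_complete, tab$n_genes))
  tab$odds_ratio <- res[, 1L]
  tab$p_value <- res[, 2L]
  tab$odds_ratio[tab$family == "non-TF"] <- NA_real_
  tab$p_value[tab$family == "non-TF"] <- NA_real_
  is_fam <- tab$family != "non-TF"
  tab$p_adjusted <- NA_real_
  tab$p_adjusted[is_fam] <- bh_adjust(tab$p_value[is_fam])

  tf <- genes |>
    mutate(in_complete = .data$gene_id %in% member_ids,
           tf = !is.na(.data$family)) |>
    group_by(.data$tf) |>
    summarise(n_genes = n(), n_in = sum(.data$in_complete))
  overall <- tibble(pct_tf = NA_real_, pct_nontf = NA_real_,
                    odds_ratio = NA_real_, p_value = NA_real_)
  if (nrow(tf) == 2L) {
    a <- tf[tf$tf, ]; b <- tf[!tf$tf, ]
    ft <- fisher_exact_2x2(matrix(c(a$n_in, a$n_genes - a$n_in,
                                    b$n_in, b$n_genes - b$n_in), nrow = 2))
    overall <- tibble(
      pct_tf = 100 * a$n_in / a$n_genes,
      pct_nontf = 100 * b$n_in / b$n_genes,
      odds_ratio = ft$statistic, p_value = ft$p_value
    )
  }
  if (min_groups > 0) {
    tab <- tab[tab$family == "non-TF" | tab$n_complete_groups > min_groups, ]
  }
  list(per_family = arrange(tab, desc(.data$family == "non-TF"),
                            desc(.data$pct_complete)),
       overall = overall)
}

#' Loss-adjusted (normalized) triad retention
#'
#' Adjusts a family's hexaploid triad percentage for the homoeolog loss
#' that had already happened in the tetraploid: the normalized percentage
#' is `100 * pct_triads_hexaploid / pct_diads_tetraploid`, i.e. the share
#' of *potential* triads (those whose diad survived) actually formed. For
#' example, 60% of genes in triads over 80% in diads gives 75%.
#'
#' @param pct_triads_hexaploid percentage of the family's genes in triads
#'   in the hexaploid (0-100); vectorized.
#' @param pct_diads_tetraploid percentage of the family's genes in diads
#'   in the tetraploid (0-100); vectorized.
#' @return normalized percentage(s); `NA` with a warning where the diad
#'   percentage is zero (undefined).
#' @examples
#' normalized_retention(60, 80)  # 75
#' @export
normalized_retention <- function(pct_triads_hexaploid, pct_diads_tetraploid) {
  h <- as.numeric(pct_triads_hexaploid)
  d <- as.numeric(pct_diads_tetraploid)
  if (any(h < 0 | h > 100, na.rm = TRUE) || any(d < 0 | d > 100, na.rm = TRUE)) {
    abort("percentages must lie in [0, 100].")
  }
  out <- ifelse(d > 0, 100 * h / d, NA_real_)
  if (any(d == 0, na.rm = TRUE)) {
    warn("diad percentage of zero: normalized retention undefined, returned as NA.")
  }
  out
}
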