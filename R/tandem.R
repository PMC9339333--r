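#' Detect tandem duplication events from gene-order adjacency
#'
#' Within each chromosome, genes of the same family are sorted by their
#' gene-identifier ordinal and consecutive genes with an ordinal gap of at
#' most `window_k` are chained into a cluster (chained linkage: A-B and
#' B-C linked implies one cluster even if A and C are further apart). A
#' cluster of `m` genes contributes `m - 1` duplication events, reported
#' as the consecutive linked pairs. Intervening genes of other families do
#' not break a link; that is precisely what the wider windows permit.
#'
#' @param genes gene table with columns `gene_id`, `family`, `chromosome`
#'   and either `ordinal` or parseable identifiers
#'   (see [parse_gene_ordinal()]). Rows with `NA` family are ignored.
#' @param window_k adjacency window in genes: 1 (no gene between), 2 (one
#'   between) or 3 (up to two between).
#' @return tibble of events: `family`, `chromosome`, `gene_1`, `gene_2`,
#'   `ordinal_1`, `ordinal_2`, `gap` (intervening gene-ID slots).
#' @export
detect_tandem_events <- function(genes, window_k = 3) {
  if (!window_k %in% 1:3) abort("`window_k` must be 1, 2 or 3.")
  genes <- as_tibble(genes)
  if (is.null(genes$ordinal)) genes$ordinal <- parse_gene_ordinal(genes$gene_id)
  genes <- genes[!is.na(genes$family), ]
  dup <- genes |>
    group_by(.data$chromosome) |>
    filter(duplicated(.data$ordinal)) |>
    ungroup()
  if (nrow(dup)) {
    abort(sprintf("duplicate ordinal %s on chromosome %s.",
                  format(dup$ordinal[1L]), dup$chromosome[1L]))
  }
  genes |>
    group_by(.data$family, .data$chromosome) |>
    arrange(.data$ordinal, .by_group = TRUE) |>
    reframe({
      o <- .data$ordinal
      id <- .data$gene_id
      if (length(o) < 2L) {
        tibble(gene_1 = character(0), gene_2 = character(0),
               ordinal_1 = numeric(0), ordinal_2 = numeric(0),
               gap = integer(0))
      } else {
        linked <- which(diff(o) <= window_k + 1e-9)
        tibble(
          gene_1 = id[linked], gene_2 = id[linked + 1L],
          ordinal_1 = o[linked], ordinal_2 = o[linked + 1L],
          gap = pmax(0L, as.integer(ceiling(o[linked + 1L] - o[linked])) - 1L)
        )
      }
    })
}

#' Percentage of tandem-duplicated genes per family
#'
#' The total number of tandem duplication events in a family is divided by
#' the family's gene count (events, not genes: a cluster of three genes
#' counts twice).
#'
#' @param events event table from [detect_tandem_events()].
#' @param family_gene_counts named vector (or tibble with `family`,
#'   `n_genes`) of gene counts per family.
#' @return tibble `family`, `n_events`, `n_genes`, `pct_tandem`.
#' @export
pct_tandem_per_family <- function(events, family_gene_counts) {
  if (is.data.frame(family_gene_counts)) {
    counts <- setNames(family_gene_counts$n_genes, family_gene_counts$family)
  } else {
    counts <- family_gene_counts
  }
  if (any(counts <= 0)) abort("family gene counts must be positive.")
  ev <- table(factor(events$family, levels = names(counts)))
  tibble(
    family = names(counts),
    n_events = as.integer(ev),
    n_genes = as.integer(counts),
    pct_tandem = 100 * as.integer(ev) / as.integer(counts)
  )
}

#' Regress per-family triad retention on a family-level predictor
#'
#' Ordinary least squares of the percentage of the family in triads on a
#' predictor such as the percentage of tandem-duplicated genes or the
#' (log) median expression level. Families with non-positive predictor
#' values are dropped with a warning when `log_transform_x` is set.
#'
#' @param data tibble with one row per family.
#' @param x,y names of the predictor and response columns.
#' @param log_transform_x take `log(x)` before fitting.
#' @return one-row tibble from [ols_fit()] (slope, intercept, r_squared,
#'   p_value, n).
#' @export
fit_retention_regression <- function(data, x, y, log_transform_x = FALSE) {
  xv <- data[[x]]; yv <- data[[y]]
  if (log_transform_x) {
    bad <- !is.na(xv) & xv <= 0
    if (any(bad)) {
      warn(sprintf("%d families dropped: non-positive `%s` cannot be log-transformed.",
                   sum(bad), x))
      xv <- xv[!bad]; yv <- yv[!bad]
    }
    xv <- log(xv)
  }
  ols_fit(xv, yv)
}

#' Median expression level per family
#'
#' Computes, for each gene, the mean tpm across tissues (tissue values
#' being replicate means), then the median of these gene-level means per
#' family.
#'
#' @param expr tpm matrix, genes x samples.
#' @param sample_map tibble `sample`, `tissue`, `replicate`.
#' @param genes gene table with `gene_id` and `family`.
#' @return tibble `family`, `n_genes`, `median_tpm`.
#' @export
family_median_expression <- function(expr, sample_map, genes) {
  tm <- replicate_means(expr, sample_map)
  gene_mean <- rowMeans(tm)
  genes <- as_tibble(genes)
  genes$mean_tpm <- gene_mean[match(genes$gene_id, names(gene_mean))]
  genes |>
    filter(!is.na(.data$mean_tpm)) |>
    mutate(fam_label = ifelse(is.na(.data$family), "non-TF", .data$family)) |>
    group_by(.data$fam_label) |>
    summarise(n_genes = n(), median_tpm = stats::median(.data$mean_tpm)) |>
    rename(family = "fam_label")
}
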