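#' Collapse an expression matrix to per-tissue replicate means
#'
#' @param expr tpm matrix, genes x samples (sample names must match
#'   `sample_map$sample`).
#' @param sample_map tibble `sample`, `tissue`, `replicate`.
#' @return matrix genes x tissues of replicate-mean tpm.
#' @export
replicate_means <- function(expr, sample_map) {
  missing <- setdiff(sample_map$sample, colnames(expr))
  if (length(missing)) {
    abort(sprintf("sample %s absent from the expression matrix.", missing[1L]))
  }
  tissues <- unique(sample_map$tissue)
  out <- vapply(tissues, function(ti) {
    cols <- sample_map$sample[sample_map$tissue == ti]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr), tissues)
  out
}

#' Filter triads to those with evidence of expression
#'
#' A triad is kept when at least one homoeolog's replicate-mean tpm
#' exceeds `threshold` (default 0.5) in at least one tissue. For
#' correlation analyses, `require_all_expressed` additionally demands
#' every homoeolog have tpm > 0 in at least one tissue. Triads with a
#' member absent from the matrix are dropped with a warning.
#'
#' @param expr tpm matrix, genes x samples.
#' @param sample_map tibble `sample`, `tissue`, `replicate`.
#' @param triads tibble with columns `group_id`, `A`, `B`, `D`.
#' @param threshold tpm threshold on replicate means (default 0.5).
#' @param require_all_expressed also require all three homoeologs
#'   expressed (tpm > 0 somewhere).
#' @return the filtered `triads` tibble.
#' @export
filter_expressed_triads <- function(expr, sample_map, triads, threshold = 0.5,
                                    require_all_expressed = FALSE) {
  triads <- as_tibble(triads)
  present <- triads$A %in% rownames(expr) & triads$B %in% rownames(expr) &
    triads$D %in% rownames(expr)
  if (any(!present)) {
    warn(sprintf("%d triads dropped: member absent from the expression matrix.",
                 sum(!present)))
    triads <- triads[present, ]
  }
  if (!nrow(triads)) return(triads)
  tm <- replicate_means(expr, sample_map)
  mx <- cbind(
    apply(tm[triads$A, , drop = FALSE], 1L, max),
    apply(tm[triads$B, , drop = FALSE], 1L, max),
    apply(tm[triads$D, , drop = FALSE], 1L, max)
  )
  keep <- apply(mx > threshold, 1L, any)
  if (require_all_expressed) keep <- keep & apply(mx > 0, 1L, all)
  triads[keep, ]
}

#' Per-tissue normalized triad expression profiles and divergence
#'
#' Normalizes each triad's expression per tissue so the three homoeolog
#' fractions sum to 1 (on replicate-mean tpm), then computes the sample
#' standard deviation (divisor n-1 = 2) of the three fractions as the
#' per-tissue homoeolog divergence. Tissues where the triad's total
#' expression is zero yield no row: the fractions are undefined there.
#'
#' @inheritParams filter_expressed_triads
#' @return long tibble: `group_id`, `tissue`, `f_A`, `f_B`, `f_D`,
#'   `sd_fraction`.
#' @export
triad_profiles <- function(expr, sample_map, triads) {
  triads <- as_tibble(triads)
  tm <- replicate_means(expr, sample_map)
  a <- tm[triads$A, , drop = FALSE]
  b <- tm[triads$B, , drop = FALSE]
  d <- tm[triads$D, , drop = FALSE]
  tot <- a + b + d
  tissues <- colnames(tm)
  out <- lapply(seq_along(tissues), function(j) {
    ok <- tot[, j] > 0
    fa <- a[ok, j] / tot[ok, j]
    fb <- b[ok, j] / tot[ok, j]
    fd <- d[ok, j] / tot[ok, j]
    m <- (fa + fb + fd) / 3
    tibble(
      group_id = triads$group_id[ok], tissue = tissues[j],
      f_A = fa, f_B = fb, f_D = fd,
      sd_fraction = sqrt(((fa - m)^2 + (fb - m)^2 + (fd - m)^2) / 2)
    )
  })
  bind_rows(out)
}

#' Compare TF and non-TF homoeolog divergence per tissue
#'
#' Two-sided Mann-Whitney test, for each tissue, of the per-triad
#' standard deviation of normalized homoeolog fractions between TF and
#' non-TF triads.
#'
#' @param profiles output of [triad_profiles()].
#' @param tf_group_ids character vector of group ids that are TF triads.
#' @return tibble per tissue: group sizes, group medians, U statistic and
#'   two-sided p-value. Tissues with an empty group are skipped with a
#'   warning.
#' @export
compare_divergence <- function(profiles, tf_group_ids) {
  out <- profiles |>
    mutate(tf = .data$group_id %in% tf_group_ids) |>
    group_by(.data$tissue) |>
    group_modify(function(d, key) {
      x <- d$sd_fraction[d$tf]
      y <- d$sd_fraction[!d$tf]
      if (length(x) < 2L || length(y) < 2L) {
        warn(sprintf("tissue %s skipped: fewer than 2 observations in a group.",
                     key$tissue))
        return(tibble())
      }
      mw <- mann_whitney(x, y)
      tibble(n_tf = length(x), n_nontf = length(y),
             median_tf = stats::median(x), median_nontf = stats::median(y),
             statistic = mw$statistic, p_value = mw$p_value)
    }) |>
    ungroup()
  out
}

#' Pairwise Pearson correlation between homoeologs of each triad
#'
#' For every triad, the Pearson correlation of replicate-mean tpm across
#' tissues for the three homoeolog pairs (A-B, B-D, A-D). Pairs involving
#' a homoeolog with zero variance across tissues are recorded as `NA`.
#'
#' @inheritParams filter_expressed_triads
#' @return tibble `group_id`, `pair` (`"AB"`, `"BD"`, `"AD"`), `r`.
#' @export
pairwise_homoeolog_correlation <- function(expr, sample_map, triads) {
  triads <- as_tibble(triads)
  tm <- replicate_means(expr, sample_map)
  if (ncol(tm) < 3L) abort("at least 3 tissues are required for correlation.")
  zrow <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowSums((m - mu)^2))
    z <- (m - mu) / s
    z[s == 0, ] <- NA_real_
    z
  }
  za <- zrow(tm[triads$A, , drop = FALSE])
  zb <- zrow(tm[triads$B, , drop = FALSE])
  zd <- zrow(tm[triads$D, , drop = FALSE])
  bind_rows(
    tibble(group_id = triads$group_id, pair = "AB", r = unname(rowSums(za * zb))),
    tibble(group_id = triads$group_id, pair = "BD", r = unname(rowSums(zb * zd))),
    tibble(group_id = triads$group_id, pair = "AD", r = unname(rowSums(za * zd)))
  )
}

#' Median correlation through the Fisher z-transform
#'
#' Correlations are mapped with atanh, the median is taken in z-space and
#' mapped back with tanh, reducing the bias of averaging raw correlation
#' coefficients. Values at exactly +/-1 are clipped to +/-(1 - 1e-12)
#' before the transform (atanh diverges at the boundary); the result
#' therefore never leaves [-1, 1].
#'
#' @param r numeric vector of correlation coefficients; `NA`s are dropped.
#' @return single median correlation.
#' @export
median_correlation <- function(r) {
  r <- r[!is.na(r)]
  if (!length(r)) abort("no non-missing correlation values supplied.")
  if (any(abs(r) > 1 + 1e-9)) abort("correlations must lie in [-1, 1].")
  clip <- 1 - 1e-12
  tanh(stats::median(atanh(pmin(pmax(r, -clip), clip))))
}

#' Coexpression-module co-membership of triads
#'
#' A triad is eligible when all three homoeologs have a module assigned,
#' excluding module 0 (the catch-all for invariant expression); genes
#' missing from the module table count as unassigned. Among eligible
#' triads, the percentage whose three homoeologs share one module is
#' reported for TF and non-TF triads, with a two-sided Fisher's exact
#' test of the contrast.
#'
#' @param modules tibble `gene_id`, `module` (module 0 = unassigned).
#' @param triads tibble `group_id`, `A`, `B`, `D`.
#' @param tf_group_ids character vector of TF triad group ids.
#' @return list with `per_triad` (group_id, eligible, comember),
#'   `summary` (per group: n_eligible, n_comember, pct_comember) and
#'   `test` (Fisher result tibble).
#' @export
module_comembership <- function(modules, triads, tf_group_ids) {
  triads <- as_tibble(triads)
  mod_of <- setNames(modules$module, modules$gene_id)
  m3 <- cbind(mod_of[triads$A], mod_of[triads$B], mod_of[triads$D])
  eligible <- apply(m3, 1L, function(v) all(!is.na(v)) && all(v != 0))
  comember <- eligible & m3[, 1L] == m3[, 2L] & m3[, 2L] == m3[, 3L]
  comember[!eligible] <- NA
  per_triad <- tibble(group_id = triads$group_id, eligible = eligible,
                      comember = comember)
  per_triad$tf <- per_triad$group_id %in% tf_group_ids
  summary <- per_triad |>
    filter(.data$eligible) |>
    group_by(group = ifelse(.data$tf, "TF", "non-TF")) |>
    summarise(
      n_eligible = n(), n_comember = sum(.data$comember),
      pct_comember = 100 * .data$n_comember / .data$n_eligible
    )
  test <- NULL
  if (nrow(summary) == 2L) {
    test <- fisher_exact_2x2(matrix(c(
      summary$n_comember[summary$group == "TF"],
      summary$n_eligible[summary$group == "TF"] - summary$n_comember[summary$group == "TF"],
      summary$n_comember[summary$group == "non-TF"],
      summary$n_eligible[summary$group == "non-TF"] - summary$n_comember[summary$group == "non-TF"]
    ), nrow = 2))
  }
  list(per_triad = per_triad[, c("group_id", "eligible", "comember")],
       summary = summary, test = test)
}
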