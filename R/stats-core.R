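#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Convenience wrapper used throughout the package for enrichment tests
#' (family vs non-TF retention, module co-membership). The two-sided p-value
#' is the sum of hypergeometric point probabilities no larger than that of
#' the observed table, i.e. the classical Fisher rule.
#'
#' @param tbl a 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts.
#' @return a one-row tibble with columns `method`, `statistic` (conditional
#'   odds-ratio estimate), `p_value` and `sided`.
#' @examples
#' fisher_exact_2x2(matrix(c(30, 10, 100, 100), nrow = 2))
#' @export
fisher_exact_2x2 <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2L, 2L))) {
    abort("`tbl` must be a 2x2 table of counts.")
  }
  if (any(is.na(tbl)) || any(tbl < 0) || any(tbl != round(tbl))) {
    abort("`tbl` must contain non-negative integer counts.")
  }
  ft <- stats::fisher.test(tbl, alternative = "two.sided")
  tibble(
    method    = "Fisher's exact test",
    statistic = unname(ft$estimate),
    p_value   = min(ft$p.value, 1),  # guards the floating-point overshoot of 1
    sided     = "two-sided"
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1))) {
    abort("`p` must contain p-values in [0, 1] with no missing values.")
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' For small samples (combined n at or below `exact_threshold`) the p-value
#' is computed by exhaustive enumeration of all group labelings, which is
#' valid in the presence of ties; larger samples use the tie-corrected
#' normal approximation. The statistic reported is U for the first sample.
#'
#' @param x,y numeric vectors, at least one observation each.
#' @param exact_threshold switch to the exact enumeration when
#'   `length(x) + length(y)` is at most this value (default 8).
#' @return one-row tibble with `method`, `statistic` (U), `p_value`, `sided`.
#' @export
mann_whitney <- function(x, y, exact_threshold = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) abort("both groups must contain at least one observation.")
  if (any(is.na(c(x, y)))) abort("missing values are not allowed.")
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  if (m + n <= exact_threshold) {
    # exhaustive two-sided p: the U distribution under exchangeability is
    # symmetric about mn/2 (swap the group labels), so extremeness is
    # measured as |U - mn/2|
    combos <- utils::combn(m + n, m)
    us <- apply(combos, 2L, u_of)
    centre <- m * n / 2
    p <- mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
    method <- "Mann-Whitney (exact enumeration)"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "Mann-Whitney (normal approximation, tie-corrected)"
  }
  tibble(method = method, statistic = u_obs, p_value = p, sided = "two-sided")
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y numeric vectors of equal length, at least 3 points, with
#'   non-zero variance in `x`.
#' @return one-row tibble with `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided t-test on the slope) and `n`.
#' @export
ols_fit <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  if (length(x) < 3) abort("at least 3 complete (x, y) points are required.")
  if (stats::var(x) == 0) abort("`x` has zero variance; the slope is not identifiable.")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble(
    slope     = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value   = sm$coefficients[2L, 4L],
    n         = length(x)
  )
}

#' Two-factor fixed-effects ANOVA with Tukey contrasts within one factor
#'
#' Fits `response ~ factor_a + factor_b` for the ANOVA table (sequential
#' sums of squares, the default of a linear-regression ANOVA), then refits
#' on the crossed cell-mean factor and extracts the Tukey honest
#' significant difference contrasts comparing the two levels of `factor_b`
#' within each level of `factor_a`.
#'
#' @param response numeric vector.
#' @param factor_a factor (e.g. variant category).
#' @param factor_b factor with two levels (e.g. TF vs non-TF).
#' @return list with `anova` (tibble: term, df, statistic, p_value) and
#'   `tukey` (tibble: level_a, diff, lwr, upr, p_adjusted).
#' @export
anova_tukey <- function(response, factor_a, factor_b) {
  factor_a <- factor(factor_a); factor_b <- factor(factor_b)
  if (nlevels(factor_b) != 2) abort("`factor_b` must have exactly two levels.")
  cells <- table(factor_a, factor_b)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1L, ]
    abort(sprintf("empty design cell: %s x %s",
                  levels(factor_a)[bad[1L]], levels(factor_b)[bad[2L]]))
  }
  fit <- stats::lm(response ~ factor_a + factor_b)
  an <- stats::anova(fit)
  anova_tbl <- tibble(
    term      = c("factor_a", "factor_b", "residuals"),
    df        = an$Df,
    statistic = an$`F value`,
    p_value   = an$`Pr(>F)`
  )
  cell <- interaction(factor_a, factor_b, sep = ":")
  hsd <- stats::TukeyHSD(stats::aov(response ~ cell))$cell
  lv <- levels(factor_b)
  wanted <- paste0(levels(factor_a), ":", lv[2L], "-", levels(factor_a), ":", lv[1L])
  rows <- match(wanted, rownames(hsd))
  # TukeyHSD orders pairs by factor-level order; fall back to the reversed
  # label (sign-flipped) where needed
  flipped <- is.na(rows)
  if (any(flipped)) {
    alt <- paste0(levels(factor_a), ":", lv[1L], "-", levels(factor_a), ":", lv[2L])
    rows[flipped] <- match(alt[flipped], rownames(hsd))
  }
  est <- hsd[rows, , drop = FALSE]
  sign_flip <- ifelse(flipped, -1, 1)
  list(
    anova = anova_tbl,
    tukey = tibble(
      level_a    = levels(factor_a),
      diff       = unname(est[, "diff"] * sign_flip),
      lwr        = unname(ifelse(flipped, -est[, "upr"], est[, "lwr"])),
      upr        = unname(ifelse(flipped, -est[, "lwr"], est[, "upr"])),
      p_adjusted = unname(est[, "p adj"])
    )
  )
}
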