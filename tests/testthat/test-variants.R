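toy_variants <- function() {
  # 12 SNPs, one per filter behaviour (gene gX is unexpressed)
  v <- tibble::tibble(
    snp_id = sprintf("s%02d", 1:12),
    gene_id = c(rep("g1", 5), rep("g2", 6), "gX"),
    chromosome = "1A", position = 1:12 * 10L,
    consequence = c("missense",    # s01 survives everything
                    "synonymous",  # s02 survives
                    "missense",    # s03 not canonical
                    "missense",    # s04 splice overlap
                    "missense",    # s05 no SIFT
                    "stop_gained", # s06 too much missingness
                    "synonymous",  # s07 below MAF
                    "stop_gained", # s08 region-flagged
                    "synonymous",  # s09 multi-annotated
                    "missense",    # s10 survives (sift 0.05 boundary)
                    "synonymous",  # s11 missingness exactly 25% - kept
                    "synonymous"), # s12 unexpressed gene
    sift = c(0.3, NA, 0.2, 0.2, NA, NA, NA, NA, NA, 0.05, NA, NA),
    in_canonical_cds = c(TRUE, TRUE, FALSE, rep(TRUE, 9)),
    splice_region = c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 8)),
    adaptation = c(rep(FALSE, 7), TRUE, rep(FALSE, 4)),
    improvement = FALSE, sweep = FALSE, introgression = FALSE,
    n_annotations = c(rep(1L, 8), 2L, 1L, 1L, 1L)
  )
  g <- matrix(1L, nrow = 12, ncol = 4,
              dimnames = list(v$snp_id, sprintf("ind%d", 1:4)))
  g["s06", 1:2] <- NA_integer_   # 50% missing
  g["s07", ] <- 0L               # monomorphic: MAF 0
  g["s11", 1] <- NA_integer_     # exactly 25% missing
  list(variants = v, genotypes = g)
}

test_that("the filter cascade matches the hand trace and is monotone", {
  toy <- toy_variants()
  out <- filter_snps(toy$variants, toy$genotypes,
                     expressed_genes = c("g1", "g2"))
  expect_setequal(out$variants$snp_id, c("s01", "s02", "s10", "s11"))
  expect_true(all(diff(out$log$n) <= 0))
  expect_equal(out$log$n, c(12, 11, 10, 9, 8, 7, 6, 5, 4))
  expect_equal(rownames(out$genotypes), out$variants$snp_id)
})

test_that("missingness of exactly 25% is retained (the rule is strict)", {
  toy <- toy_variants()
  out <- filter_snps(toy$variants, toy$genotypes,
                     expressed_genes = c("g1", "g2"))
  expect_true("s11" %in% out$variants$snp_id)
})

test_that("empty input and unknown consequences are handled", {
  toy <- toy_variants()
  empty <- filter_snps(toy$variants[0, ], toy$genotypes[0, , drop = FALSE],
                       expressed_genes = character(0))
  expect_equal(nrow(empty$variants), 0L)
  expect_true(all(empty$log$n == 0))

  bad <- toy$variants
  bad$consequence[1] <- "frameshift"
  expect_error(filter_snps(bad, toy$genotypes, c("g1", "g2")), "frameshift")
})

test_that("effect classification respects the SIFT boundary", {
  v <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    consequence = c("missense", "missense", "stop_gained", "synonymous"),
    sift = c(0.05, 0.2, 0.01, NA)
  )
  out <- classify_effect(v)
  expect_equal(out$category,
               c("deleterious_missense", "tolerated_missense",
                 "stop_gained", "synonymous"))
  v2 <- v; v2$sift[1] <- NA
  expect_error(classify_effect(v2), "SIFT")
})

test_that("site pi matches the closed form and the pairwise oracle", {
  expect_equal(site_pi(c(0L, 0L, 0L)), 0)
  # genotypes {0/0, 1/1}: n = 4 alleles, j = 2 -> 2*2*2/(4*3)
  expect_equal(site_pi(c(0L, 2L)), 2 / 3)
  expect_true(is.na(site_pi(c(NA_integer_, NA_integer_))))

  set.seed(55)
  for (i in 1:300) {
    n <- sample(2:10, 1)
    g <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE)
    expect_equal(site_pi(g), oracle_pi(g), tolerance = 1e-12,
                 info = paste(g, collapse = ","))
  }
})

toy_load_input <- function() {
  genes <- tibble::tibble(
    gene_id = c("tf1", "tf2", "n1", "n2"),
    transcript_length = c(4000L, 6000L, 12000L, 8000L),
    family = c("NAC", "WRKY", NA, NA)
  )
  v <- tibble::tibble(
    snp_id = sprintf("s%d", 1:4),
    gene_id = c("tf1", "tf2", "n1", "n2"),
    category = c("deleterious_missense", "deleterious_missense",
                 "synonymous", "deleterious_missense")
  )
  g <- rbind(c(2L, 1L, 0L),
             c(2L, 1L, 0L),
             c(2L, 1L, 1L),
             c(0L, 1L, 2L))
  dimnames(g) <- list(v$snp_id, c("i1", "i2", "i3"))
  list(genes = genes, variants = v, genotypes = g)
}

test_that("mutation load counts homozygous-alt calls over group kb", {
  toy <- toy_load_input()
  load <- mutation_load(toy$variants, toy$genotypes, toy$genes)
  # individual i1: two deleterious hom-alt in TF genes, TF total 10 kb
  x <- load[load$individual == "i1" & load$group == "TF" &
              load$category == "deleterious_missense", ]
  expect_equal(x$load_per_kb, 0.2)
  # all-heterozygous individual i2 has zero load everywhere
  expect_true(all(load$load_per_kb[load$individual == "i2"] == 0))
  # per-category count identity across individuals
  for (cat in unique(toy$variants$category)) {
    rows <- toy$variants$category == cat
    expect_equal(sum(load$n_hom_alt[load$category == cat]),
                 sum(toy$genotypes[rows, , drop = FALSE] == 2L, na.rm = TRUE))
  }
})

test_that("mutation load is invariant to individual ordering", {
  toy <- toy_load_input()
  a <- mutation_load(toy$variants, toy$genotypes, toy$genes)
  perm <- c(3, 1, 2)
  b <- mutation_load(toy$variants, toy$genotypes[, perm], toy$genes)
  a <- a[order(a$individual, a$group, a$category), ]
  b <- b[order(b$individual, b$group, b$category), ]
  expect_equal(a$load_per_kb, b$load_per_kb)
})

test_that("degenerate and continuous load distributions flag the 2.5% tails", {
  lt <- tibble::tibble(
    individual = sprintf("i%03d", 1:200),
    group = "TF", category = "synonymous",
    n_hom_alt = 0L, load_per_kb = 1
  )
  expect_equal(flag_extreme_individuals(lt), character(0))

  lt$load_per_kb <- seq_len(200)
  flagged <- flag_extreme_individuals(lt)
  expect_equal(length(flagged), 10L)  # 5 per tail for 200 distinct loads
  expect_true(all(c("i001", "i200") %in% flagged))

  # extreme in any single distribution suffices
  lt2 <- dplyr::bind_rows(
    lt |> dplyr::mutate(load_per_kb = 1),
    lt |> dplyr::mutate(category = "stop_gained",
                        load_per_kb = c(100, rep(1, 199)))
  )
  expect_true("i001" %in% flag_extreme_individuals(lt2))
})

test_that("family SNP proportions apply carrier and size rules", {
  v <- tibble::tibble(
    snp_id = sprintf("s%d", 1:8),
    gene_id = c(rep("tf1", 5), "tf2", "n1", "n1"),
    category = c(rep("deleterious_missense", 2), rep("synonymous", 3),
                 "synonymous", "stop_gained", "synonymous")
  )
  g <- matrix(0L, nrow = 8, ncol = 3,
              dimnames = list(v$snp_id, c("i1", "i2", "iext")))
  g[1:5, "i1"] <- 1L
  g["s6", "iext"] <- 2L      # carried only by the extreme individual
  g["s7", "i2"] <- 1L
  g["s8", "i2"] <- 2L
  fams <- c(tf1 = "NAC", tf2 = "NAC", n1 = NA)
  counts <- c(NAC = 20, WRKY = 3)
  out <- family_snp_proportions(v, g, fams, counts, extreme = "iext")
  nac <- out[out$family == "NAC", ]
  expect_equal(nac$n_snps, 5L)  # s6 dropped: only carried by the extreme
  expect_equal(nac$prop_deleterious_missense, 0.4)
  expect_equal(out$n_snps[out$family == "non-TF"], 2L)

  # below the >=5 SNP threshold the family disappears
  out2 <- family_snp_proportions(v[c(1:4, 7:8), ], g[c(1:4, 7:8), ], fams,
                                 counts, extreme = "iext")
  expect_false("NAC" %in% out2$family)
  expect_true("non-TF" %in% out2$family)
})

test_that("load contrasts recover group differences and percent deficits", {
  set.seed(77)
  cats <- c("deleterious_missense", "synonymous")
  lt <- expand.grid(individual = sprintf("i%02d", 1:40),
                    group = c("TF", "non-TF"), category = cats,
                    stringsAsFactors = FALSE)
  lt <- tibble::as_tibble(lt)
  mu <- ifelse(lt$group == "TF" & lt$category == "deleterious_missense", 0.68, 1)
  lt$load_per_kb <- mu
  lt$n_hom_alt <- 0L
  out <- compare_loads(lt)
  pd <- out$percent_difference
  expect_equal(pd$pct_difference[pd$category == "deleterious_missense"], 32)
  expect_equal(pd$pct_difference[pd$category == "synonymous"], 0)

  # identical group means: all contrasts nonsignificant, differences zero
  lt2 <- lt; lt2$load_per_kb <- rep(c(1, 2), length.out = nrow(lt2))
  out2 <- compare_loads(lt2)
  expect_true(all(out2$percent_difference$pct_difference == 0))
  expect_true(all(out2$tukey$p_adjusted > 0.9))
})
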