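# Brute-force reference implementations, kept deliberately independent of
# the package code paths they check.

# two-sided Fisher p by summing hypergeometric point probabilities <= observed
oracle_fisher_p <- function(tbl) {
  a <- tbl[1, 1]
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ]); c1 <- sum(tbl[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracle_mw_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) sum(rank(pooled)[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(m + n, m), 2, u_of)
  centre <- m * n / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# per-site pi as the fraction of differing allele pairs, enumerated
oracle_pi <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  alleles <- unlist(lapply(g, function(v) c(rep(1, v), rep(0, 2 - v))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    diffs <- diffs + sum(alleles[i] != alleles[(i + 1):n])
  }
  diffs / choose(n, 2)
}

# tandem events as sum(component size - 1) over the pair graph with edges
# between ordinals at gap <= k (connected components by label propagation)
oracle_tandem_events <- function(ordinals, k) {
  n <- length(ordinals)
  if (n < 2) return(0L)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(ordinals[i] - ordinals[j]) <= k + 1e-9 && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  sum(sizes - 1L)
}

# small expression fixture: genes x (tissue, replicate) from a per-tissue
# matrix, replicates exact copies unless noise is supplied
make_expr <- function(tissue_matrix, n_replicates = 2) {
  Tn <- ncol(tissue_matrix)
  expr <- do.call(cbind, replicate(n_replicates, tissue_matrix, simplify = FALSE))
  map <- tibble::tibble(
    tissue = rep(sprintf("tissue%02d", seq_len(Tn)), times = n_replicates),
    replicate = rep(seq_len(n_replicates), each = Tn)
  )
  map$sample <- paste0(map$tissue, "_rep", map$replicate)
  colnames(expr) <- map$sample
  list(expr = expr, sample_map = map[, c("sample", "tissue", "replicate")])
}

# uniform-retention family table used by parameter-recovery tests
uniform_families <- function(diad = 0.825, triad = 0.705, log_mean = log(2)) {
  fam <- default_tf_families()
  fam$diad_prob <- diad
  fam$triad_prob <- triad
  fam$log_mean <- log_mean
  fam
}

small_config <- function(...) {
  sim_config(n_groups = 200, n_individuals = 40, ...)
}
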