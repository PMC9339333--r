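#' Write every table of a synthetic study to a directory
#'
#' Emits plain-text artifacts: gene, homoeolog, isoform, module and
#' ground-truth tables as TSV; the expression matrix as TSV (rows =
#' genes, columns = tissue_replicate samples); the cohort as a minimal
#' GT-only VCF plus a VEP-like effect TSV; exclusion regions as BED; and
#' a JSON run manifest echoing the configuration.
#'
#' @param study a `synthetic_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(study$genes, p("genes.tsv"))
  readr::write_tsv(study$homoeologs$zavitan, p("homoeologs_zavitan.tsv"))
  readr::write_tsv(study$homoeologs$biomart, p("homoeologs_biomart.tsv"))
  readr::write_tsv(study$isoforms, p("isoforms.tsv"))
  expr <- as_tibble(study$expression, rownames = "gene_id")
  readr::write_tsv(expr, p("expression.tsv"))
  readr::write_tsv(study$sample_map, p("sample_map.tsv"))
  readr::write_tsv(study$modules, p("modules.tsv"))
  eff <- study$variants |>
    select("snp_id", "gene_id", "chromosome", "position", "consequence",
           "sift", "in_canonical_cds", "splice_region", "n_annotations")
  readr::write_tsv(eff, p("effects.tsv"))
  write_vcf_gt(study$variants, study$genotypes, p("cohort.vcf"))
  write_bed_regions(study$variants, p("exclusions.bed"))
  readr::write_tsv(study$truth$groups, p("truth_groups.tsv"))
  readr::write_tsv(study$truth$tandem, p("truth_tandem.tsv"))
  jsonlite::write_json(study$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Write a minimal GT-only VCF
#'
#' Emits a VCFv4.2 file carrying only the genotype (GT) field, with
#' placeholder REF/ALT alleles: downstream analyses use alternate-allele
#' counts only.
#'
#' @param variants variant table with `snp_id`, `chromosome`, `position`.
#' @param genotypes integer matrix sites x individuals (0/1/2, NA).
#' @param path output file.
#' @export
write_vcf_gt <- function(variants, genotypes, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(genotypes), ncol = ncol(genotypes))
  ok <- !is.na(genotypes)
  gt[ok] <- gt_code[genotypes[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=wheatTriads synthetic cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  body <- paste(variants$chromosome, variants$position, variants$snp_id,
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read a GT-only VCF into an alternate-allele-count matrix
#'
#' @param path VCF file.
#' @return integer matrix sites x individuals (0/1/2, NA for missing),
#'   rownames = VCF ID column.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  counts[gt %in% c("0/0", "0|0")] <- 0L
  counts[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  counts[gt %in% c("1/1", "1|1")] <- 2L
  counts
}

#' Write selection/introgression exclusion regions as BED
#'
#' One zero-length-plus-one interval per flagged SNP, named by the flag.
#'
#' @param variants variant table carrying the four region-flag columns.
#' @param path output BED file.
#' @export
write_bed_regions <- function(variants, path) {
  rows <- lapply(REGION_FLAGS, function(f) {
    v <- variants[variants[[f]], , drop = FALSE]
    if (!nrow(v)) return(NULL)
    tibble(chrom = v$chromosome, start = v$position - 1L,
           end = v$position, name = f)
  })
  bed <- bind_rows(rows)
  readr::write_tsv(bed, path, col_names = FALSE)
}

#' Read a BED exclusion file
#'
#' @param path BED file (chrom, start, end, name).
#' @return tibble `chrom`, `start`, `end`, `name`.
#' @export
read_bed_regions <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                  col_types = "ciic")
}

#' Assign region flags to variants from BED exclusion regions
#'
#' Sets each of the four flag columns to whether the SNP position falls
#' inside any BED interval carrying that name (BED half-open convention).
#'
#' @param variants variant table with `chromosome`, `position`.
#' @param regions tibble from [read_bed_regions()].
#' @return the variant table with the flag columns set.
#' @export
assign_region_flags <- function(variants, regions) {
  variants <- as_tibble(variants)
  for (f in REGION_FLAGS) {
    hit <- rep(FALSE, nrow(variants))
    rg <- regions[regions$name == f, , drop = FALSE]
    for (cr in unique(rg$chrom)) {
      r <- rg[rg$chrom == cr, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      idx <- which(variants$chromosome == cr)
      if (!length(idx)) next
      pos0 <- variants$position[idx] - 1L
      k <- findInterval(pos0, r$start)
      cm <- cummax(r$end)
      hit[idx] <- k > 0 & ifelse(k > 0, cm[pmax(k, 1L)] > pos0, FALSE)
    }
    variants[[f]] <- hit
  }
  variants
}

#' Read an expression TSV back into a matrix
#'
#' @param path TSV with a `gene_id` column followed by sample columns.
#' @return numeric matrix genes x samples.
#' @export
read_expression_matrix <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(tb[, -1L])
  rownames(m) <- tb$gene_id
  m
}
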