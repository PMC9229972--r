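# Standard-format input/output: genotype TSV/VCF, analysis tables,
# cohort export.

#' Read a genotype dosage matrix
#'
#' TSV: first column sample ids, remaining columns one SNP each (additive
#' 0/1/2 or fractional dosages).  VCF: the `DS` FORMAT field if present,
#' otherwise alternate-allele counts from `GT` (requires the vcfR
#' package).  Chromosome labels are parsed into the SNP metadata.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return list with `dosages` (samples x SNPs matrix) and `snp_meta`
#'   (tibble: `snp_id`, `chromosome`, `position`).
#' @export
read_genotype_matrix <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    dos <- as.matrix(tb[, -1, drop = FALSE])
    rownames(dos) <- as.character(tb[[1]])
    return(list(
      dosages = dos,
      snp_meta = tibble(snp_id = colnames(dos),
                        chromosome = NA_character_, position = NA_integer_)
    ))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  fmt <- unique(v@gt[, "FORMAT"])
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  dos <- t(ds)
  colnames(dos) <- ids
  list(dosages = dos,
       snp_meta = tibble(snp_id = ids,
                         chromosome = as.character(fix[, "CHROM"]),
                         position = as.integer(fix[, "POS"])))
}

#' Read a samples-by-variables TSV into a matrix
#'
#' First column is taken as sample ids (row names).
#'
#' @param path TSV file.
#' @return numeric matrix.
#' @export
read_table_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- as.character(tb[[1]])
  m
}

write_matrix_tsv <- function(m, ids, path) {
  tb <- dplyr::bind_cols(tibble(sample_id = ids),
                         as_tibble(as.data.frame(m)))
  readr::write_tsv(tb, path)
  path
}

#' Write a cohort to plain-text files
#'
#' One TSV per data type (genotypes, metabolites by timepoint,
#' phenotypes, covariates), a pair table with strata, the node metadata
#' table, and optionally a minimal dosage VCF (`DS` FORMAT field) per
#' genotype matrix.
#'
#' @param cohort a `trio_cohort`.
#' @param dir output directory.
#' @param vcf also write dosage VCFs (default `FALSE`).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  stopifnot(inherits(cohort, "trio_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$pair_ids
  files <- c(
    pairs = {
      readr::write_tsv(tibble(pair_id = ids, stratum = cohort$strata),
                       file.path(dir, "pairs.tsv"))
      file.path(dir, "pairs.tsv")
    },
    node_meta = {
      readr::write_tsv(cohort$node_meta, file.path(dir, "node_meta.tsv"))
      file.path(dir, "node_meta.tsv")
    }
  )
  for (m in cohort_matrices()) {
    if (!ncol(cohort[[m]])) next
    files[[m]] <- write_matrix_tsv(cohort[[m]], ids,
                                   file.path(dir, paste0(m, ".tsv")))
  }
  if (vcf) {
    meta <- cohort$node_meta
    for (side in c("maternal_genotypes", "offspring_genotypes")) {
      dos <- cohort[[side]]
      if (!ncol(dos)) next
      chrom <- meta$chromosome[match(colnames(dos), meta$node_id)]
      files[[paste0(side, "_vcf")]] <-
        write_minimal_vcf(dos, chrom, ids,
                          file.path(dir, paste0(side, ".vcf")))
    }
  }
  invisible(files)
}

# Minimal VCF 4.2 serializer for a dosage matrix (DS FORMAT field only).
write_minimal_vcf <- function(dosages, chromosomes, sample_ids, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dosages)), function(j) {
    paste(c(chromosomes[j] %||% "1", j, colnames(dosages)[j], "A", "G",
            ".", "PASS", ".", "DS",
            format(dosages[, j], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
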