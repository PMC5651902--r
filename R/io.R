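# Plain-text readers/writers for cohorts: delimited matrices with a header
# of sample ids, (id, chrom, bp) maps, a minimal VCF with GT genotypes, and
# a flat truth-registry table.

.write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        rownames_as),
               as.data.frame(x))
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param snp_map SNP map with `snp_id`, `chrom`, `bp`, `allele_ref`,
#'   `allele_alt`.
#' @param path Output file path (uncompressed VCF).
#' @export
write_vcf <- function(genotypes, snp_map, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(snp_map$chrom[j], snp_map$bp[j], snp_map$snp_id[j],
                       snp_map$allele_ref[j], snp_map$allele_alt[j], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()] back into a dosage matrix
#'
#' @param path VCF file path.
#' @return List with `genotypes` (samples x SNPs) and `snp_map`.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  fields <- strsplit(lines[hdr], "\t")[[1]]
  samples <- fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  parts <- strsplit(body, "\t")
  snp_map <- data.frame(
    snp_id = vapply(parts, `[[`, "", 3),
    chrom = as.integer(vapply(parts, `[[`, "", 1)),
    bp = as.integer(vapply(parts, `[[`, "", 2)),
    allele_ref = vapply(parts, `[[`, "", 4),
    allele_alt = vapply(parts, `[[`, "", 5), stringsAsFactors = FALSE)
  G <- vapply(parts, function(p) {
    gt <- p[-(1:9)]
    out <- rep(NA_integer_, length(gt))
    out[gt == "0/0"] <- 0L
    out[gt == "0/1" | gt == "1/0"] <- 1L
    out[gt == "1/1"] <- 2L
    out
  }, integer(length(samples)))
  dimnames(G) <- list(samples, snp_map$snp_id)
  list(genotypes = G, snp_map = snp_map)
}

#' Write a simulated cohort to a directory of delimited text files
#'
#' Emits `genotypes.vcf`, `genotypes.tsv` (0/1/2 with NA), `snp_map.tsv`,
#' `methylation.tsv`, `cpg_map.tsv`, `covariates.tsv` and, when a truth
#' registry is attached, `truth.tsv` (one record per planted effect).
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(cohort$genotypes, cohort$snp_map,
            file.path(dir, "genotypes.vcf"))
  .write_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"), "sample_id")
  .write_tsv(cohort$snp_map, file.path(dir, "snp_map.tsv"))
  .write_tsv(cohort$methylation_beta, file.path(dir, "methylation.tsv"),
             "sample_id")
  .write_tsv(cohort$cpg_map, file.path(dir, "cpg_map.tsv"))
  .write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"))
  if (!is.null(cohort$truth) && length(cohort$truth$effects))
    .write_tsv(as.data.frame(cohort$truth), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @param role Cohort role label.
#' @return A `cohort` object (without probe dosages or truth registry).
#' @export
read_cohort <- function(dir, role = "discovery") {
  mat <- function(f) {
    d <- read.table(file.path(dir, f), header = TRUE, sep = "\t",
                    check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  tsv <- function(f) read.table(file.path(dir, f), header = TRUE,
                                sep = "\t", check.names = FALSE,
                                stringsAsFactors = FALSE)
  structure(list(role = role, genotypes = mat("genotypes.tsv"),
                 snp_map = tsv("snp_map.tsv"),
                 methylation_beta = mat("methylation.tsv"),
                 cpg_map = tsv("cpg_map.tsv"),
                 covariates = tsv("covariates.tsv"),
                 probe_dosages = list(), truth = NULL),
            class = "cohort")
}
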