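#' Pairwise LD as squared dosage correlation
#'
#' Composite (genotype-dosage) linkage disequilibrium: the squared Pearson
#' correlation of the two dosage vectors over pairwise-complete entries.
#' This is the statistic used consistently for pruning, LD-threshold
#' calibration and LD-block classification; no haplotype phasing is
#' involved.
#'
#' @param a,b Dosage vectors (0/1/2, `NA` allowed) over the same samples;
#'   at least 3 complete pairs, both polymorphic on the complete pairs.
#' @return Squared correlation in [0, 1].
#' @export
genotype_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 complete genotype pairs")
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0)
    stop("monomorphic input on complete pairs")
  cor(a, b)^2
}

#' Empirical LD threshold from cross-chromosome SNP pairs
#'
#' Estimates the level of dosage r2 that is unlikely (at the configured
#' quantile, default 1 - 0.001) to occur between truly independent SNPs in
#' the sample at hand, by sampling random pairs of SNPs located on
#' different chromosomes and taking the empirical quantile of their r2.
#' Under independence `n * r2` is approximately chi-squared with 1 df, so at
#' n = 533 the 0.999 quantile is about 10.83 / 533 = 0.020; values above
#' the returned threshold are treated as genuine LD downstream.
#'
#' @param genotypes Samples x SNPs dosage matrix.
#' @param snp_map SNP map matching the columns; at least 2 chromosomes.
#' @param n_pairs Number of independent cross-chromosome pairs to draw
#'   (with replacement; default 10,000).
#' @param quantile Quantile of the null r2 sample (default 0.999).
#' @param seed Integer seed.
#' @return Object of class `ld_threshold_result`: `threshold_r2`,
#'   `quantile`, `n_pairs`, `seed` and `null_summary` (mean and selected
#'   quantiles of the null sample).
#' @export
empirical_ld_threshold <- function(genotypes, snp_map, n_pairs = 10000L,
                                   quantile = 0.999, seed = 1L) {
  stopifnot(identical(colnames(genotypes), snp_map$snp_id))
  if (length(unique(snp_map$chrom)) < 2L)
    stop("at least 2 chromosomes are required")
  set.seed(seed)
  m <- ncol(genotypes)
  i1 <- sample.int(m, n_pairs, replace = TRUE)
  i2 <- vapply(i1, function(i) {
    cand <- which(snp_map$chrom != snp_map$chrom[i])
    cand[sample.int(length(cand), 1L)]
  }, 0L)
  r2 <- vapply(seq_len(n_pairs), function(p) {
    tryCatch(genotype_r2(genotypes[, i1[p]], genotypes[, i2[p]]),
             error = function(e) NA_real_)
  }, 0)
  r2 <- r2[!is.na(r2)]
  thr <- stats::quantile(r2, quantile, names = FALSE, type = 7)
  structure(list(threshold_r2 = thr, quantile = quantile,
                 n_pairs = n_pairs, seed = seed,
                 null_summary = c(mean = mean(r2),
                                  stats::quantile(r2, c(0.5, 0.95, 0.99)))),
            class = "ld_threshold_result")
}

#' @export
print.ld_threshold_result <- function(x, ...) {
  cat(sprintf(
    "<ld_threshold_result: r2 > %.4g at quantile %.4g (%d pairs, seed %d)>\n",
    x$threshold_r2, x$quantile, x$n_pairs, x$seed))
  invisible(x)
}
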