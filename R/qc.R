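#' SNP quality-control thresholds
#'
#' Defaults follow common practice for scan-oriented genotype QC: minor
#' allele frequency above 2 percent, exact Hardy-Weinberg p above 0.001,
#' per-SNP missing rate below 1 percent, smallest genotype group of at least
#' 15 subjects (applied to the scan set only), and LD pruning with a 50-SNP
#' window shifted by 5 SNPs at a dosage r2 of 0.95.
#'
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param hwe_p_min Minimum exact Hardy-Weinberg p-value (exclusive).
#' @param miss_max Maximum per-SNP missing rate (exclusive).
#' @param min_genotype_group Minimum size of the smallest genotype group
#'   (inclusive); enforced for the scan set only.
#' @param prune_window,prune_step LD-pruning window size and shift, in SNPs.
#' @param prune_r2 Dosage r2 above which the later-positioned SNP of a pair
#'   is pruned.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.02, hwe_p_min = 0.001, miss_max = 0.01,
                          min_genotype_group = 15L, prune_window = 50L,
                          prune_step = 5L, prune_r2 = 0.95) {
  th <- list(maf_min = maf_min, hwe_p_min = hwe_p_min, miss_max = miss_max,
             min_genotype_group = as.integer(min_genotype_group),
             prune_window = as.integer(prune_window),
             prune_step = as.integer(prune_step), prune_r2 = prune_r2)
  stopifnot(th$maf_min > 0, th$maf_min < 1, th$hwe_p_min > 0,
            th$hwe_p_min < 1, th$miss_max > 0, th$miss_max < 1,
            th$min_genotype_group > 0, th$prune_window >= 2L,
            th$prune_step >= 1L, th$prune_r2 > 0, th$prune_r2 <= 1)
  class(th) <- "qc_thresholds"
  th
}

#' Minor allele frequency of a dosage vector
#'
#' @param g Vector of genotypes coded 0/1/2 with `NA` for missing; at least
#'   one non-missing entry.
#' @return `min(f, 1 - f)` where `f` is the mean dosage over non-missing
#'   entries divided by 2.
#' @export
compute_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing")
  if (!all(g %in% 0:2)) stop("genotypes must be coded 0/1/2")
  f <- mean(g) / 2
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test computed by enumerating every heterozygote count
#' compatible with the observed allele counts and summing the probabilities
#' of all configurations no more likely than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return The exact p-value; 1 by convention for monomorphic input.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- function(h) {
    homr <- (rare - h) / 2
    homc <- (n - h - homr)
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(homr) -
      lfactorial(homc) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }
  lp <- vapply(hets, logp, 0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

.genotype_group_stats <- function(G) {
  n <- nrow(G)
  n0 <- colSums(G == 0L, na.rm = TRUE)
  n1 <- colSums(G == 1L, na.rm = TRUE)
  n2 <- colSums(G == 2L, na.rm = TRUE)
  nm <- n - (n0 + n1 + n2)
  maf <- (n1 + 2 * n2) / (2 * (n0 + n1 + n2))
  maf <- pmin(maf, 1 - maf)
  hwe <- mapply(hwe_exact_test, n0, n1, n2)
  data.frame(maf = maf, hwe_p = hwe, miss_rate = nm / n,
             min_group = pmin(n0, n1, n2))
}

#' Filter SNPs on quality criteria in both cohorts
#'
#' A SNP is kept only if it passes every criterion in both the discovery and
#' the replication cohort. The smallest-genotype-group criterion is applied
#' only when building the scan set; the larger modeling set omits it.
#'
#' @param discovery,replication `cohort` objects sharing a SNP map, or plain
#'   genotype matrices.
#' @param thresholds A [qc_thresholds()] object.
#' @param set_label `"scan"` or `"modeling"`.
#' @return An object of class `snp_keep_set`: `kept` (SNP ids), `label`, and
#'   `stats` (per-SNP criteria for both cohorts).
#' @export
filter_snps <- function(discovery, replication,
                        thresholds = qc_thresholds(),
                        set_label = c("scan", "modeling")) {
  set_label <- match.arg(set_label)
  Gd <- if (inherits(discovery, "cohort")) discovery$genotypes else discovery
  Gr <- if (inherits(replication, "cohort")) replication$genotypes
        else replication
  stopifnot(identical(colnames(Gd), colnames(Gr)))
  sd_ <- .genotype_group_stats(Gd)
  sr <- .genotype_group_stats(Gr)
  pass <- function(s) {
    ok <- s$maf > thresholds$maf_min & s$hwe_p > thresholds$hwe_p_min &
      s$miss_rate < thresholds$miss_max
    if (set_label == "scan")
      ok <- ok & s$min_group >= thresholds$min_genotype_group
    ok
  }
  keep <- pass(sd_) & pass(sr)
  stats <- data.frame(snp_id = colnames(Gd),
                      maf_discovery = sd_$maf, maf_replication = sr$maf,
                      hwe_p_discovery = sd_$hwe_p,
                      hwe_p_replication = sr$hwe_p,
                      miss_discovery = sd_$miss_rate,
                      miss_replication = sr$miss_rate,
                      min_group_discovery = sd_$min_group,
                      min_group_replication = sr$min_group,
                      kept = keep, stringsAsFactors = FALSE)
  if (!any(keep)) warning("no SNP passed the QC filters")
  structure(list(kept = colnames(Gd)[keep], label = set_label,
                 stats = stats),
            class = "snp_keep_set")
}

#' @export
print.snp_keep_set <- function(x, ...) {
  cat(sprintf("<snp_keep_set '%s': %d of %d SNPs kept>\n", x$label,
              length(x$kept), nrow(x$stats)))
  invisible(x)
}

#' Sliding-window LD pruning
#'
#' Within each window of `prune_window` SNPs (advanced by `prune_step`,
#' within chromosomes), pairs of kept SNPs with dosage r2 above `prune_r2`
#' are reduced by repeatedly removing the later-positioned SNP of the worst
#' pair. Pruning is decided on one cohort's data (the discovery sample) and
#' the resulting keep set is meant to be applied to both.
#'
#' @param genotypes Samples x SNPs dosage matrix (discovery cohort).
#' @param snp_map SNP map sorted by (chrom, bp) and matching the columns.
#' @param thresholds A [qc_thresholds()] object.
#' @return An object of class `snp_keep_set` with label `"pruned"`.
#' @export
ld_prune <- function(genotypes, snp_map, thresholds = qc_thresholds()) {
  stopifnot(identical(colnames(genotypes), snp_map$snp_id))
  if (thresholds$prune_window < 2L) stop("prune window must be >= 2")
  o <- order(snp_map$chrom, snp_map$bp)
  if (!identical(o, seq_len(nrow(snp_map))))
    stop("snp_map must be sorted by (chrom, bp)")
  keep <- rep(TRUE, ncol(genotypes))
  for (ch in unique(snp_map$chrom)) {
    idx <- which(snp_map$chrom == ch)
    m <- length(idx)
    starts <- seq(1L, max(1L, m), by = thresholds$prune_step)
    for (s in starts) {
      win <- idx[s:min(s + thresholds$prune_window - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      r2 <- suppressWarnings(cor(genotypes[, win, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      while (max(r2) > thresholds$prune_r2) {
        w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        # remove the later-positioned SNP of the worst pair
        drop_local <- max(w)
        keep[win[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
      if (s + thresholds$prune_window - 1L >= m) break
    }
  }
  structure(list(kept = snp_map$snp_id[keep], label = "pruned",
                 stats = data.frame(snp_id = snp_map$snp_id, kept = keep,
                                    stringsAsFactors = FALSE)),
            class = "snp_keep_set")
}
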