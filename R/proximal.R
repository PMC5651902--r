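# Proximal main-effect-first search: instead of the exhaustive pair scan,
# test single-SNP main effects inside a +/- 3.5 MB window around each CpG,
# replicate them, then test interactions only among the replicated
# main-effect SNPs.

#' Per-CpG proximal main-effect scan with two-stage replication
#'
#' Every SNP within `window_bp` of the CpG is tested with a 2-df genotype
#' ANOVA in the discovery cohort; survivors of the per-CpG Bonferroni
#' correction (`alpha / n_tested_discovery`) are re-tested in the
#' replication cohort against `alpha / n_tested_replication`, where the
#' replication multiplicity counts the SNPs carried forward.
#'
#' @param cpg_id The CpG.
#' @param discovery,replication `cohort` objects.
#' @param window_bp Window half-width around the CpG (default 3.5 MB).
#' @param alpha Per-CpG alpha (default 0.05).
#' @return Data frame of replicated main effects (`snp_id`, `p_discovery`,
#'   `p_replication`) with the tested counts as attributes.
#' @export
proximal_main_scan <- function(cpg_id, discovery, replication,
                               window_bp = 3.5e6, alpha = 0.05) {
  stopifnot(window_bp > 0)
  cmap <- discovery$cpg_map
  ci <- match(cpg_id, cmap$cpg_id)
  smap <- discovery$snp_map
  in_win <- smap$chrom == cmap$chrom[ci] &
    abs(smap$bp - cmap$bp[ci]) <= window_bp
  snps <- smap$snp_id[in_win]
  empty <- data.frame(snp_id = character(), p_discovery = numeric(),
                      p_replication = numeric(), stringsAsFactors = FALSE)
  if (!length(snps)) return(empty)
  yd <- .signal_matrix(discovery)[, cpg_id]
  p_d <- main_effect_scan(discovery$genotypes[, snps, drop = FALSE], yd)
  tested_d <- sum(!is.na(p_d))
  sig_d <- names(p_d)[!is.na(p_d) & p_d < alpha / max(tested_d, 1)]
  if (!length(sig_d)) {
    attr(empty, "n_tested_discovery") <- tested_d
    return(empty)
  }
  yr <- .signal_matrix(replication)[, cpg_id]
  p_r <- main_effect_scan(replication$genotypes[, sig_d, drop = FALSE], yr)
  tested_r <- sum(!is.na(p_r))
  keep <- !is.na(p_r) & p_r < alpha / max(tested_r, 1)
  out <- data.frame(snp_id = sig_d[keep], p_discovery = p_d[sig_d][keep],
                    p_replication = p_r[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_tested_discovery") <- tested_d
  attr(out, "n_tested_replication") <- tested_r
  out
}

#' Interaction tests among replicated proximal main-effect SNPs
#'
#' For a CpG with at least two significant main effects, every pair among
#' them is tested with the exact 4-df interaction ANOVA in both cohorts,
#' requiring all 9 cells with minimal group size strictly above `min_cell`
#' in both, and a per-CpG Bonferroni correction over the number of pairs
#' tested, in both cohorts.
#'
#' @param cpg_id The CpG.
#' @param significant_mains Data frame from [proximal_main_scan()] (or a
#'   character vector of SNP ids); needs >= 2 SNPs.
#' @param discovery,replication `cohort` objects.
#' @param alpha Per-CpG alpha.
#' @param min_cell Minimal group-size bound (strictly greater than).
#' @return Data frame of significant pairs (`snp_a`, `snp_b`,
#'   `p_discovery`, `p_replication`).
#' @export
proximal_interaction_scan <- function(cpg_id, significant_mains, discovery,
                                      replication, alpha = 0.05,
                                      min_cell = 3) {
  snps <- if (is.data.frame(significant_mains)) significant_mains$snp_id
          else significant_mains
  if (length(snps) < 2L)
    stop("need at least two significant main-effect SNPs")
  prs <- t(utils::combn(snps, 2L))
  yd <- .signal_matrix(discovery)[, cpg_id]
  yr <- .signal_matrix(replication)[, cpg_id]
  res <- lapply(seq_len(nrow(prs)), function(k) {
    ga_d <- discovery$genotypes[, prs[k, 1]]
    gb_d <- discovery$genotypes[, prs[k, 2]]
    ga_r <- replication$genotypes[, prs[k, 1]]
    gb_r <- replication$genotypes[, prs[k, 2]]
    cnt_d <- table(factor(ga_d, 0:2), factor(gb_d, 0:2))
    cnt_r <- table(factor(ga_r, 0:2), factor(gb_r, 0:2))
    if (min(cnt_d) <= min_cell || min(cnt_r) <= min_cell)
      return(data.frame(snp_a = prs[k, 1], snp_b = prs[k, 2],
                        p_discovery = NA_real_, p_replication = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(snp_a = prs[k, 1], snp_b = prs[k, 2],
               p_discovery = exact_interaction_anova(ga_d, gb_d, yd)$p,
               p_replication = exact_interaction_anova(ga_r, gb_r, yr)$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  n_tested <- sum(!is.na(res$p_discovery))
  thr <- alpha / max(n_tested, 1)
  keep <- !is.na(res$p_discovery) & res$p_discovery < thr &
    !is.na(res$p_replication) & res$p_replication < thr
  out <- res[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

#' Full proximal search for one CpG
#'
#' Runs the proximal main-effect scan, then (given at least two replicated
#' mains) the interaction scan among them, and finally the stepwise-forward
#' selection over all significant mains and pairs.
#'
#' @inheritParams proximal_main_scan
#' @param min_cell Minimal group-size bound for interaction tests.
#' @return List with `mains`, `pairs` and `model` (a `cpg_model`, or `NULL`
#'   when no main effect replicates).
#' @export
proximal_search <- function(cpg_id, discovery, replication,
                            window_bp = 3.5e6, alpha = 0.05, min_cell = 3) {
  mains <- proximal_main_scan(cpg_id, discovery, replication, window_bp,
                              alpha)
  if (!nrow(mains)) return(list(mains = mains, pairs = NULL, model = NULL))
  pairs <- if (nrow(mains) >= 2L)
    proximal_interaction_scan(cpg_id, mains, discovery, replication, alpha,
                              min_cell)
  else NULL
  model <- forward_select(cpg_id, mains$snp_id,
                          if (!is.null(pairs) && nrow(pairs))
                            pairs[, c("snp_a", "snp_b")] else NULL,
                          discovery, replication, alpha, min_cell)
  list(mains = mains, pairs = pairs, model = model)
}
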