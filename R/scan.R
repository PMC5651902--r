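#' 3x3 genotype-cell summaries for one SNP pair and one CpG
#'
#' Cross-tabulates the two genotype vectors (listwise deletion of missing
#' entries) and records per-cell counts, sums, means and the pooled
#' within-cell sum of squares -- the sufficient statistics for the 8-df joint
#' and 4-df interaction tests.
#'
#' @param geno_a,geno_b Dosage vectors (0/1/2, `NA` allowed).
#' @param y Phenotype (adjusted M-value) vector of the same length.
#' @return Object of class `cell_summary`: `counts`, `sums`, `means` (3x3,
#'   `NA` where a cell is empty), `n_total`, `ss_within`, `grand_mean`.
#' @export
cell_summaries <- function(geno_a, geno_b, y) {
  stopifnot(length(geno_a) == length(y), length(geno_b) == length(y))
  ok <- !is.na(geno_a) & !is.na(geno_b) & !is.na(y)
  if (sum(ok) < 10L) stop("fewer than 10 complete observations")
  a <- geno_a[ok]; b <- geno_b[ok]; yy <- y[ok]
  counts <- matrix(0, 3, 3); sums <- matrix(0, 3, 3); ss <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) {
    sel <- a == i & b == j
    counts[i + 1, j + 1] <- sum(sel)
    sums[i + 1, j + 1] <- sum(yy[sel])
    if (any(sel)) ss[i + 1, j + 1] <- sum((yy[sel] - mean(yy[sel]))^2)
  }
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(counts = counts, sums = sums, means = means,
                 n_total = sum(counts), ss_within = sum(ss),
                 grand_mean = sum(sums) / sum(counts)),
            class = "cell_summary")
}

#' Fast 8-df joint and 4-df approximate interaction tests
#'
#' From 9-cell summaries: the 8-df F tests the joint deviation of the cell
#' means from the grand mean (all main plus interaction effects). For the
#' 4-df interaction approximation, the additive and dominance effects at
#' each locus -- the count-weighted marginal means -- are subtracted from
#' the cell means; the test measures the remaining deviation. The
#' approximation is exact when the two SNPs are independent (orthogonal,
#' e.g. balanced designs) and tends to overshoot the exact interaction F
#' otherwise, which is why downstream filtering recalculates candidate
#' pairs exactly.
#'
#' @param cells A [cell_summaries()] object with `n_total` > 9 and positive
#'   `ss_within`.
#' @return List with `F8`, `F4_approx` and `all_cells_present`. With empty
#'   cells the statistics are computed over the occupied cells and the flag
#'   is `FALSE` (such pairs are filtered downstream).
#' @export
approx_two_locus_test <- function(cells) {
  stopifnot(inherits(cells, "cell_summary"))
  if (cells$n_total <= 9L) stop("n_total must exceed 9")
  if (cells$ss_within <= 0) stop("ss_within must be positive")
  N <- cells$counts; S <- cells$sums; mu <- cells$grand_mean
  occ <- N > 0
  mse <- cells$ss_within / (cells$n_total - 9)
  ss_joint <- sum((S[occ]^2 / N[occ])) - cells$n_total * mu^2
  rmean <- rowSums(S) / pmax(rowSums(N), 1)
  cmean <- colSums(S) / pmax(colSums(N), 1)
  pred <- outer(rmean, cmean, function(r, cc) r + cc - mu)
  M <- cells$means
  ss_int <- sum(N[occ] * (M[occ] - pred[occ])^2)
  list(F8 = (ss_joint / 8) / mse, F4_approx = (ss_int / 4) / mse,
       all_cells_present = all(occ))
}

#' Exact two-locus interaction ANOVA
#'
#' Compares the additive model (each SNP as a 3-level factor, 2 df each)
#' with the saturated 9-cell-mean model:
#' `F = [(RSS_add - RSS_sat) / 4] / [RSS_sat / (n - 9)]`, with the p-value
#' from the upper tail of F(4, n - 9). Tail probabilities are computed on
#' the log scale; values below the smallest representable double are
#' reported as that minimum with the `underflow` flag set.
#'
#' @param geno_a,geno_b Dosage vectors; after listwise deletion all 9
#'   genotype cells must be occupied.
#' @param y Phenotype vector.
#' @return List with `F`, `p`, `log10_p`, `df` (c(4, n - 9)) and
#'   `underflow`.
#' @export
exact_interaction_anova <- function(geno_a, geno_b, y) {
  ok <- !is.na(geno_a) & !is.na(geno_b) & !is.na(y)
  a <- geno_a[ok]; b <- geno_b[ok]; yy <- y[ok]
  n <- length(yy)
  if (n <= 9L) stop("need more than 9 complete observations")
  cnt <- table(factor(a, 0:2), factor(b, 0:2))
  if (any(cnt == 0)) stop("all 9 genotype cells must be occupied")
  # saturated RSS: pooled within-cell sum of squares
  cellid <- a * 3L + b
  sums <- vapply(split(yy, cellid), sum, 0)
  ns <- vapply(split(yy, cellid), length, 0L)
  rss_sat <- sum(yy^2) - sum(sums^2 / ns)
  X <- cbind(1, a == 1L, a == 2L, b == 1L, b == 2L)
  storage.mode(X) <- "double"
  rss_add <- sum(qr.resid(qr(X), yy)^2)
  if (rss_sat <= 1e-12 * sum(yy^2)) {
    # noise-free saturated fit: the statistic diverges
    return(list(F = Inf, p = .Machine$double.xmin, log10_p = -Inf,
                df = c(4, n - 9), underflow = TRUE))
  }
  F <- ((rss_add - rss_sat) / 4) / (rss_sat / (n - 9))
  F <- max(F, 0)
  logp <- pf(F, 4, n - 9, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  underflow <- p == 0
  if (underflow) p <- .Machine$double.xmin
  list(F = F, p = p, log10_p = logp / log(10), df = c(4, n - 9),
       underflow = underflow)
}

#' Number of tests in an exhaustive two-locus scan
#'
#' `n_cpgs * n_snps * (n_snps - 1) / 2`, the count every Bonferroni
#' correction of the discovery phase is based on.
#'
#' @param n_cpgs,n_snps Non-negative counts.
#' @return The exact test count (as a double; exact up to 2^53).
#' @export
count_exhaustive_tests <- function(n_cpgs, n_snps) {
  if (n_cpgs < 0 || n_snps < 0) stop("counts must be non-negative")
  if (n_snps < 2) return(0)
  n_cpgs * (n_snps * (n_snps - 1) / 2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Power of the two-locus interaction F test
#'
#' Power of the `df1`-df F test (default the 4-df interaction test with
#' denominator df `n - 9`) at significance level `alpha` for an effect of
#' correlation `r`, using the noncentral F distribution with noncentrality
#' `n * r^2 / (1 - r^2)`.
#'
#' @param r Effect size as a correlation in [0, 1).
#' @param n Sample size (must exceed `df1 + 5`).
#' @param alpha Significance level.
#' @param df1 Numerator degrees of freedom (default 4).
#' @param df2 Denominator degrees of freedom (default `n - 9`).
#' @return Rejection probability.
#' @export
interaction_power <- function(r, n, alpha, df1 = 4, df2 = n - 9) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(r >= 0, r < 1, n > df1 + 5)
  ncp <- n * r^2 / (1 - r^2)
  crit <- qf(alpha, df1, df2, lower.tail = FALSE)
  pf(crit, df1, df2, ncp = ncp, lower.tail = FALSE)
}

.signal_matrix <- function(cohort, cpg_ids = NULL) {
  M <- if (!is.null(cohort$M)) cohort$M else beta_to_m(cohort$methylation_beta)
  if (!is.null(cpg_ids)) M <- M[, cpg_ids, drop = FALSE]
  M
}

.indicator_list <- function(G) {
  lapply(0:2, function(a) {
    I <- G == a
    I[is.na(I)] <- FALSE
    storage.mode(I) <- "double"
    I
  })
}

#' Exhaustive two-locus interaction scan (discovery phase)
#'
#' For every (CpG, unordered SNP pair) combination the 4-df approximate
#' interaction F is computed from 9-cell summaries (vectorized across
#' pairs). Pairs with all 9 cells present and `F4_approx` above `f_filter`
#' are recalculated with the exact factorial ANOVA, and hits are kept when
#' the exact p falls below the Bonferroni threshold for the full test count
#' (`alpha / (n_cpgs * n_pairs)`). Alternatively (`mode = "direct"`) the
#' Bonferroni correction is applied directly to the p-value of the
#' approximate statistic before exact recalculation.
#'
#' Missing genotypes are handled by per-pair listwise deletion.
#'
#' @param discovery Discovery `cohort` (its adjusted signal is taken from
#'   `cohort$M` if present, else from the M-transform of the beta matrix).
#' @param replication Optional replication `cohort`; when supplied, each
#'   hit also records its minimal replication-cell size and cell presence.
#' @param cpg_ids,snp_ids Subsets to scan (defaults: all).
#' @param f_filter Approximate-F filter (default 22, the conventional value
#'   for methylome-scale scans where it sits close to the Bonferroni
#'   threshold). `"auto"` instead derives the filter from this scan's own
#'   Bonferroni threshold (`qf(alpha / n_tests, 4, n - 9)` upper tail), the
#'   analogous choice at smaller scan sizes where a fixed 22 would be far
#'   stricter than the correction it is meant to approximate.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param mode `"f_filter"` (default) or `"direct"`.
#' @return Object of class `scan_result`: `hits` data frame (cpg_id, snp_a,
#'   snp_b, F8, F4_approx, F_exact, p_exact, df2, min_cell_discovery,
#'   min_cell_replication, all_cells_present), plus `n_tests`, `threshold`,
#'   `f_filter`, `n_filtered` (pairs passing the approximate filter).
#' @export
exhaustive_scan <- function(discovery, replication = NULL, cpg_ids = NULL,
                            snp_ids = NULL, f_filter = 22, alpha = 0.05,
                            mode = c("f_filter", "direct")) {
  mode <- match.arg(mode)
  if (is.null(snp_ids)) snp_ids <- colnames(discovery$genotypes)
  M <- .signal_matrix(discovery, cpg_ids)
  cpg_ids <- colnames(M)
  if (!length(cpg_ids) || length(snp_ids) < 2L)
    stop("need at least one CpG and two SNPs")
  G <- discovery$genotypes[, snp_ids, drop = FALSE]
  n <- nrow(G)
  m <- ncol(G)
  Ind <- .indicator_list(G)
  miss <- is.na(G) * 1
  any_missing_geno <- any(miss > 0)
  # y-independent cell counts (valid when y is complete)
  N0 <- vector("list", 9L)
  for (a in 0:2) for (b in 0:2)
    N0[[a * 3 + b + 1]] <- crossprod(Ind[[a + 1]], Ind[[b + 1]])
  upper <- upper.tri(matrix(0, m, m))
  n_tests <- count_exhaustive_tests(length(cpg_ids), m)
  threshold <- bonferroni_threshold(alpha, n_tests)
  if (identical(f_filter, "auto"))
    f_filter <- qf(threshold, 4, n - 9, lower.tail = FALSE)
  stopifnot(is.numeric(f_filter))

  Gr <- if (!is.null(replication)) replication$genotypes[, snp_ids,
                                                         drop = FALSE]
  hits <- list()
  n_filtered <- 0L
  for (cg in cpg_ids) {
    y <- M[, cg]
    if (anyNA(y)) {
      keep_rows <- !is.na(y)
      Gi <- G[keep_rows, , drop = FALSE]
      yi <- y[keep_rows]
      Indi <- .indicator_list(Gi)
      missi <- is.na(Gi) * 1
      Ncell <- vector("list", 9L)
      for (a in 0:2) for (b in 0:2)
        Ncell[[a * 3 + b + 1]] <- crossprod(Indi[[a + 1]], Indi[[b + 1]])
    } else {
      Gi <- G; yi <- y; Indi <- Ind; missi <- miss; Ncell <- N0
    }
    y2 <- yi^2
    Scell <- vector("list", 9L)
    for (a in 0:2) for (b in 0:2)
      Scell[[a * 3 + b + 1]] <- crossprod(Indi[[a + 1]] * yi, Indi[[b + 1]])
    ntot <- Reduce(`+`, Ncell)
    sumy <- Reduce(`+`, Scell)
    # per-pair sum of y^2 over included samples (adjust for missing)
    if (any_missing_geno || anyNA(y)) {
      qa <- colSums(missi * y2)
      both <- crossprod(missi * y2, missi)
      sumy2 <- sum(y2) - outer(qa, rep(1, m)) - outer(rep(1, m), qa) + both
    } else {
      sumy2 <- matrix(sum(y2), m, m)
    }
    between <- matrix(0, m, m)
    for (k in seq_len(9L)) {
      Nk <- Ncell[[k]]
      contrib <- Scell[[k]]^2 / pmax(Nk, 1)
      contrib[Nk == 0] <- 0
      between <- between + contrib
    }
    ssw <- sumy2 - between
    mu <- sumy / ntot
    # marginal (additive + dominance) predictions
    Rsum <- lapply(0:2, function(a)
      Scell[[a * 3 + 1]] + Scell[[a * 3 + 2]] + Scell[[a * 3 + 3]])
    Rn <- lapply(0:2, function(a)
      Ncell[[a * 3 + 1]] + Ncell[[a * 3 + 2]] + Ncell[[a * 3 + 3]])
    Csum <- lapply(0:2, function(b)
      Scell[[b + 1]] + Scell[[3 + b + 1]] + Scell[[6 + b + 1]])
    Cn <- lapply(0:2, function(b)
      Ncell[[b + 1]] + Ncell[[3 + b + 1]] + Ncell[[6 + b + 1]])
    ss_int <- matrix(0, m, m)
    allcells <- matrix(TRUE, m, m)
    mincell <- matrix(Inf, m, m)
    for (a in 0:2) for (b in 0:2) {
      k <- a * 3 + b + 1
      Nk <- Ncell[[k]]
      allcells <- allcells & (Nk > 0)
      mincell <- pmin(mincell, Nk)
      cellmean <- Scell[[k]] / pmax(Nk, 1)
      pred <- Rsum[[a + 1]] / pmax(Rn[[a + 1]], 1) +
        Csum[[b + 1]] / pmax(Cn[[b + 1]], 1) - mu
      d2 <- Nk * (cellmean - pred)^2
      d2[Nk == 0] <- 0
      ss_int <- ss_int + d2
    }
    F4 <- (ss_int / 4) / (ssw / (ntot - 9))
    if (mode == "f_filter") {
      cand <- which(upper & allcells & F4 > f_filter & ssw > 0)
    } else {
      p_approx <- pf(F4, 4, ntot - 9, lower.tail = FALSE)
      cand <- which(upper & allcells & p_approx < threshold & ssw > 0)
    }
    n_filtered <- n_filtered + length(cand)
    for (idx in cand) {
      i <- (idx - 1L) %% m + 1L
      j <- (idx - 1L) %/% m + 1L
      ex <- exact_interaction_anova(Gi[, i], Gi[, j], yi)
      keep_hit <- if (mode == "f_filter") ex$p < threshold else TRUE
      if (keep_hit) {
        ss_joint <- between[idx] - sumy[idx]^2 / ntot[idx]
        F8 <- (ss_joint / 8) / (ssw[idx] / (ntot[idx] - 9))
        rep_min <- NA_real_
        rep_all <- NA
        if (!is.null(Gr)) {
          cntr <- table(factor(Gr[, i], 0:2), factor(Gr[, j], 0:2))
          rep_min <- min(cntr)
          rep_all <- all(cntr > 0)
        }
        hits[[length(hits) + 1L]] <- data.frame(
          cpg_id = cg, snp_a = snp_ids[i], snp_b = snp_ids[j],
          F8 = F8, F4_approx = F4[idx], F_exact = ex$F, p_exact = ex$p,
          log10_p_exact = ex$log10_p, df2 = ex$df[2],
          min_cell_discovery = mincell[idx],
          min_cell_replication = rep_min,
          all_cells_present = allcells[idx] &&
            (is.na(rep_all) || rep_all),
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(cpg_id = character(), snp_a = character(),
               snp_b = character(), F8 = numeric(), F4_approx = numeric(),
               F_exact = numeric(), p_exact = numeric(),
               log10_p_exact = numeric(), df2 = numeric(),
               min_cell_discovery = numeric(),
               min_cell_replication = numeric(),
               all_cells_present = logical(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  structure(list(hits = hits, n_tests = n_tests, threshold = threshold,
                 f_filter = f_filter, mode = mode, n_filtered = n_filtered,
                 n_cpgs = length(cpg_ids), n_snps = m),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(paste0("<scan_result: %d CpGs x %d SNPs, %.3g tests, ",
                     "%d pairs past approximate filter, %d hits at p < ",
                     "%.3g>\n"),
              x$n_cpgs, x$n_snps, x$n_tests, x$n_filtered, nrow(x$hits),
              x$threshold))
  invisible(x)
}
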