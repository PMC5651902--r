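#' Adaptive per-CpG Bonferroni threshold for the replication phase
#'
#' The baseline multiplicity is the number of unique CpGs entering
#' replication; a CpG carrying several interaction signals is corrected
#' more stringently by adding its own hit count:
#' `alpha / (n_unique_cpgs + n_hits_this_cpg)`.
#'
#' @param n_unique_cpgs Number of unique CpGs entering replication (>= 1).
#' @param n_hits_this_cpg Number of interaction hits on this CpG (>= 1).
#' @param alpha Family-wise alpha (default 0.05).
#' @return The per-CpG p-value threshold.
#' @export
per_cpg_threshold <- function(n_unique_cpgs, n_hits_this_cpg, alpha = 0.05) {
  stopifnot(n_unique_cpgs >= 1, n_hits_this_cpg >= 1)
  alpha / (n_unique_cpgs + n_hits_this_cpg)
}

# Orthonormal bases for the additive and saturated two-locus designs on the
# complete cases; used to compute exact interaction F for many phenotype
# columns at once.
.pair_projectors <- function(a, b) {
  X_add <- cbind(1, a == 1L, a == 2L, b == 1L, b == 2L)
  storage.mode(X_add) <- "double"
  cell <- factor(a * 3L + b)
  X_sat <- model.matrix(~ cell - 1)
  qa <- qr(X_add)
  qs <- qr(X_sat)
  list(Qa = qr.Q(qa)[, seq_len(qa$rank), drop = FALSE],
       Qs = qr.Q(qs)[, seq_len(qs$rank), drop = FALSE])
}

.pair_F <- function(proj, Y, n) {
  yss <- colSums(Y^2)
  rss_add <- yss - colSums(crossprod(proj$Qa, Y)^2)
  rss_sat <- yss - colSums(crossprod(proj$Qs, Y)^2)
  pmax(((rss_add - rss_sat) / 4) / (rss_sat / (n - 9)), 0)
}

#' Permutation empirical p-value for one interaction test
#'
#' Permutes the CpG signal across samples (genotypes fixed), recomputes the
#' exact interaction F each time, and reports the add-one estimator
#' `p_emp = (1 + #{F_perm >= F_obs}) / (B + 1)`. Optionally stops early
#' once the Clopper-Pearson lower confidence bound for `p_emp` exceeds ten
#' times the target threshold (the hit can no longer pass).
#'
#' @param geno_a,geno_b Dosage vectors; all 9 cells must be occupied after
#'   listwise deletion.
#' @param y Phenotype vector.
#' @param F_obs Observed exact interaction F.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed (ignored when `perm_idx` is given).
#' @param perm_idx Optional precomputed permutation matrix
#'   (`length(y)` x B) of sample orderings, allowing a shared per-CpG
#'   permutation stream across the SNP pairs of one CpG.
#' @param early_stop Enable sequential early stopping (default off).
#' @param stop_threshold Target threshold used by the early-stop rule.
#' @return The empirical p-value (>= 1/(B+1)).
#' @export
empirical_interaction_p <- function(geno_a, geno_b, y, F_obs, B = 999L,
                                    seed = NULL, perm_idx = NULL,
                                    early_stop = FALSE,
                                    stop_threshold = NULL) {
  if (B < 100L) stop("B must be >= 100")
  ok <- !is.na(geno_a) & !is.na(geno_b) & !is.na(y)
  a <- geno_a[ok]; b <- geno_b[ok]
  n <- sum(ok)
  if (any(table(factor(a, 0:2), factor(b, 0:2)) == 0))
    stop("all 9 genotype cells must be occupied")
  proj <- .pair_projectors(a, b)
  if (is.null(perm_idx)) {
    if (!is.null(seed)) set.seed(seed)
    perm_idx <- replicate(B, sample.int(length(y)))
  }
  B <- ncol(perm_idx)
  exceed <- 0L
  done <- 0L
  chunk <- 200L
  while (done < B) {
    take <- seq(done + 1L, min(done + chunk, B))
    Yp <- matrix(y[perm_idx[, take]], nrow = length(y))[ok, , drop = FALSE]
    Fp <- .pair_F(proj, Yp, n)
    exceed <- exceed + sum(Fp >= F_obs - 1e-12)
    done <- done + length(take)
    if (early_stop && !is.null(stop_threshold)) {
      lower <- qbeta(0.005, exceed, done - exceed + 1)
      if (lower > 10 * stop_threshold)
        return((1 + exceed) / (done + 1))
    }
  }
  (1 + exceed) / (B + 1)
}

#' Sign test: correlation of the 9 cell means across cohorts
#'
#' Pearson correlation of the 3x3 genotype-cell mean methylation levels
#' between discovery and replication, cells aligned by genotype
#' combination. Used to discard hits with inconsistent effect direction
#' (pass at r > 0.85).
#'
#' @param cells_discovery,cells_replication [cell_summaries()] objects with
#'   all 9 cells occupied.
#' @return List with `r` (correlation, `NA` on degenerate input) and `ok`
#'   (`FALSE` when either table has zero variance among its cell means).
#' @export
sign_test_r <- function(cells_discovery, cells_replication) {
  stopifnot(inherits(cells_discovery, "cell_summary"),
            inherits(cells_replication, "cell_summary"))
  if (any(cells_discovery$counts == 0) || any(cells_replication$counts == 0))
    stop("all 9 cells must be occupied in both cohorts")
  md <- as.vector(cells_discovery$means)
  mr <- as.vector(cells_replication$means)
  if (sd(md) == 0 || sd(mr) == 0) return(list(r = NA_real_, ok = FALSE))
  list(r = cor(md, mr), ok = TRUE)
}

#' Apply the triple replication filter to scan hits
#'
#' For every hit: (i) requires a minimal 9-cell group size strictly above
#' `min_cell` in both cohorts; (ii) recomputes the exact interaction test in
#' the replication cohort and compares it with the adaptive per-CpG
#' Bonferroni threshold; (iii) computes a per-CpG permutation empirical
#' p-value against the same threshold; (iv) computes the 9-cell sign-test
#' correlation (pass at `r > sign_r_min`). `pass_all` is the conjunction of
#' the four flags. Permutation streams are shared across the SNP pairs of
#' one CpG.
#'
#' @param hits A `scan_result` or its `hits` data frame.
#' @param discovery,replication `cohort` objects.
#' @param B Number of permutations per CpG (default 999).
#' @param alpha Family-wise alpha for the per-CpG thresholds.
#' @param seed Integer seed for the permutation streams.
#' @param min_cell Minimal group size bound (strictly greater than;
#'   default 3).
#' @param sign_r_min Sign-test pass threshold (default 0.85).
#' @param pooled_permutations When `TRUE`, the empirical null of a CpG pools
#'   the permuted F values of all its pairs (one empirical distribution per
#'   CpG); default is a per-pair null on the shared stream.
#' @return Object of class `replication_result` whose `verdicts` data frame
#'   holds per-hit thresholds, p-values, sign r and pass flags.
#' @export
replicate_hits <- function(hits, discovery, replication, B = 999L,
                           alpha = 0.05, seed = 1L, min_cell = 3,
                           sign_r_min = 0.85, pooled_permutations = FALSE) {
  hdf <- if (inherits(hits, "scan_result")) hits$hits else hits
  if (!nrow(hdf))
    return(structure(list(verdicts = data.frame(), n_unique_cpgs = 0L),
                     class = "replication_result"))
  Md <- .signal_matrix(discovery)
  Mr <- .signal_matrix(replication)
  n_unique <- length(unique(hdf$cpg_id))
  hits_per_cpg <- table(hdf$cpg_id)
  nrep <- nrow(replication$genotypes)
  out <- vector("list", nrow(hdf))
  for (cg in unique(hdf$cpg_id)) {
    rows <- which(hdf$cpg_id == cg)
    yr <- Mr[, cg]
    set.seed(seed + match(cg, colnames(Mr)))
    perm_idx <- replicate(min(B, 2000000L), sample.int(nrep))
    thr <- per_cpg_threshold(n_unique, length(rows), alpha)
    pair_stats <- lapply(rows, function(rw) {
      ga_d <- discovery$genotypes[, hdf$snp_a[rw]]
      gb_d <- discovery$genotypes[, hdf$snp_b[rw]]
      ga_r <- replication$genotypes[, hdf$snp_a[rw]]
      gb_r <- replication$genotypes[, hdf$snp_b[rw]]
      yd <- Md[, cg]
      cd <- cell_summaries(ga_d, gb_d, yd)
      cr <- tryCatch(cell_summaries(ga_r, gb_r, yr), error = function(e) NULL)
      min_d <- min(cd$counts)
      min_r <- if (is.null(cr)) 0 else min(cr$counts)
      pass_min <- min_d > min_cell && min_r > min_cell
      p_rep <- NA_real_
      F_rep <- NA_real_
      p_emp <- NA_real_
      Fp <- NULL
      sr <- list(r = NA_real_, ok = FALSE)
      if (!is.null(cr) && all(cr$counts > 0) && all(cd$counts > 0)) {
        ex <- exact_interaction_anova(ga_r, gb_r, yr)
        p_rep <- ex$p
        F_rep <- ex$F
        if (pooled_permutations) {
          okr <- !is.na(ga_r) & !is.na(gb_r) & !is.na(yr)
          proj <- .pair_projectors(ga_r[okr], gb_r[okr])
          Yp <- matrix(yr[perm_idx], nrow = nrep)[okr, , drop = FALSE]
          Fp <- .pair_F(proj, Yp, sum(okr))
        } else {
          p_emp <- empirical_interaction_p(ga_r, gb_r, yr, ex$F, B = B,
                                           perm_idx = perm_idx)
        }
        sr <- sign_test_r(cd, cr)
      }
      list(min_d = min_d, min_r = min_r, pass_min = pass_min, p_rep = p_rep,
           F_rep = F_rep, p_emp = p_emp, Fp = Fp, sign_r = sr$r,
           sign_ok = sr$ok)
    })
    if (pooled_permutations) {
      pool <- unlist(lapply(pair_stats, `[[`, "Fp"))
      for (k in seq_along(pair_stats)) {
        st <- pair_stats[[k]]
        if (!is.na(st$F_rep) && length(pool))
          pair_stats[[k]]$p_emp <-
            (1 + sum(pool >= st$F_rep - 1e-12)) / (length(pool) + 1)
      }
    }
    for (k in seq_along(rows)) {
      st <- pair_stats[[k]]
      pass_bonf <- !is.na(st$p_rep) && st$p_rep < thr
      pass_emp <- !is.na(st$p_emp) && st$p_emp < thr
      pass_sign <- st$sign_ok && !is.na(st$sign_r) && st$sign_r > sign_r_min
      out[[rows[k]]] <- data.frame(
        cpg_id = cg, snp_a = hdf$snp_a[rows[k]], snp_b = hdf$snp_b[rows[k]],
        per_cpg_threshold = thr, p_rep = st$p_rep, p_emp = st$p_emp,
        sign_r = st$sign_r, min_cell_discovery = st$min_d,
        min_cell_replication = st$min_r,
        pass_min_cell = st$pass_min, pass_bonferroni = pass_bonf,
        pass_empirical = pass_emp, pass_sign = pass_sign,
        pass_all = st$pass_min && pass_bonf && pass_emp && pass_sign,
        stringsAsFactors = FALSE)
    }
  }
  verdicts <- do.call(rbind, out)
  rownames(verdicts) <- NULL
  structure(list(verdicts = verdicts, n_unique_cpgs = n_unique, B = B,
                 alpha = alpha, min_cell = min_cell,
                 sign_r_min = sign_r_min),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  v <- x$verdicts
  cat(sprintf("<replication_result: %d hits on %d CpGs, %d pass all filters>\n",
              nrow(v), x$n_unique_cpgs,
              if (nrow(v)) sum(v$pass_all) else 0L))
  invisible(x)
}

#' Summarize replication verdicts in the style of the main results table
#'
#' Counts of hits and unique CpGs before and after each filter, with
#' cis/trans composition (a SNP is cis when within `cis_window` of the
#' CpG).
#'
#' @param verdicts A `replication_result` or its `verdicts` data frame.
#' @param snp_map,cpg_map Maps providing positions.
#' @param cis_window Window defining cis (default 500 KB).
#' @return Data frame with one row per filtering stage.
#' @export
replication_summary <- function(verdicts, snp_map, cpg_map,
                                cis_window = 5e5) {
  v <- if (inherits(verdicts, "replication_result")) verdicts$verdicts
       else verdicts
  stages <- list(
    before = rep(TRUE, nrow(v)),
    after_bonferroni = v$pass_min_cell & v$pass_bonferroni,
    after_permutation_sign = v$pass_min_cell & v$pass_bonferroni &
      v$pass_empirical & v$pass_sign)
  cis_of <- function(rows) {
    if (!length(rows)) return(c(NA, NA, NA))
    sub <- v[rows, ]
    spos <- function(id) snp_map$bp[match(id, snp_map$snp_id)]
    schr <- function(id) snp_map$chrom[match(id, snp_map$snp_id)]
    cpos <- cpg_map$bp[match(sub$cpg_id, cpg_map$cpg_id)]
    cchr <- cpg_map$chrom[match(sub$cpg_id, cpg_map$cpg_id)]
    cis_a <- schr(sub$snp_a) == cchr & abs(spos(sub$snp_a) - cpos) <= cis_window
    cis_b <- schr(sub$snp_b) == cchr & abs(spos(sub$snp_b) - cpos) <= cis_window
    ncis <- cis_a + cis_b
    100 * c(mean(ncis == 2), mean(ncis == 1), mean(ncis == 0))
  }
  do.call(rbind, lapply(names(stages), function(nm) {
    rows <- which(stages[[nm]])
    cis <- cis_of(rows)
    data.frame(stage = nm, n_hits = length(rows),
               n_unique_cpgs = length(unique(v$cpg_id[rows])),
               pct_both_cis = cis[1], pct_one_cis = cis[2],
               pct_both_trans = cis[3], stringsAsFactors = FALSE)
  }))
}
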