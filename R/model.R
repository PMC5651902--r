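# Per-CpG joint modeling: candidate assembly, dual-cohort stepwise-forward
# selection of main (2-df factor) and interaction (4-df cell-contrast)
# terms, LD-block vs epistasis classification, cis/trans labeling and
# variance decomposition.

# 2-df main-effect ANOVA of a single SNP factor, vectorized over SNP columns.
# Returns the per-SNP p-value (df = observed groups - 1; SNPs with fewer
# than 2 observed groups get NA).
main_effect_scan <- function(G, y) {
  ok_y <- !is.na(y)
  res <- rep(NA_real_, ncol(G))
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    ok <- ok_y & !is.na(g)
    gg <- g[ok]; yy <- y[ok]
    ns <- tabulate(gg + 1L, 3L)
    k <- sum(ns > 0)
    if (k < 2L || length(yy) <= k) next
    sums <- vapply(0:2, function(a) sum(yy[gg == a]), 0)
    ssb <- sum((sums^2 / pmax(ns, 1))[ns > 0]) - sum(yy)^2 / length(yy)
    ssw <- sum(yy^2) - sum((sums^2 / pmax(ns, 1))[ns > 0])
    if (ssw <= 0) { res[j] <- 0; next }
    F <- (ssb / (k - 1)) / (ssw / (length(yy) - k))
    res[j] <- pf(F, k - 1, length(yy) - k, lower.tail = FALSE)
  }
  names(res) <- colnames(G)
  res
}

#' 2-df main-effect ANOVA p-value for one SNP
#'
#' Tests the SNP as a 3-level genotype factor against the CpG signal.
#'
#' @param g Dosage vector; `NA` allowed.
#' @param y Phenotype vector.
#' @return Upper-tail F p-value (`NA` with fewer than 2 observed genotype
#'   groups).
#' @export
main_effect_p <- function(g, y) {
  main_effect_scan(matrix(g, ncol = 1), y)[[1]]
}

#' Assemble per-CpG candidate terms for the forward regression
#'
#' Candidate main effects are the union of SNPs within `window` of the CpG,
#' SNPs within `window` of any SNP of a surviving interaction pair, and
#' SNPs with a genome-wide significant main effect on this CpG
#' (`alpha / n_snps` in the modeling set). Candidate pairs are the
#' surviving hit pairs plus all pairs among SNPs in LD (discovery
#' `r2 > ld_threshold`) with at least one interacting SNP.
#'
#' @param cpg_id The CpG.
#' @param hits Data frame of surviving hits for this CpG (columns `snp_a`,
#'   `snp_b`); must be non-empty.
#' @param discovery Discovery `cohort`; genotypes supply the modeling SNP
#'   set and LD.
#' @param ld_threshold LD-block threshold (e.g. the calibrated 0.021).
#' @param window Cis window in bp (default 500 KB).
#' @param alpha Alpha for the genome-wide main-effect criterion.
#' @param snp_ids Optional restriction of the modeling SNP set.
#' @return List with `mains` (SNP ids) and `pairs` (two-column matrix).
#' @export
assemble_candidates <- function(cpg_id, hits, discovery, ld_threshold,
                                window = 5e5, alpha = 0.05,
                                snp_ids = NULL) {
  stopifnot(nrow(hits) >= 1L)
  smap <- discovery$snp_map
  if (!is.null(snp_ids)) smap <- smap[smap$snp_id %in% snp_ids, ]
  cmap <- discovery$cpg_map
  ci <- match(cpg_id, cmap$cpg_id)
  hit_snps <- unique(c(hits$snp_a, hits$snp_b))
  near <- function(chrom, pos)
    smap$snp_id[smap$chrom == chrom & abs(smap$bp - pos) <= window]
  mains <- near(cmap$chrom[ci], cmap$bp[ci])
  for (s in hit_snps) {
    si <- match(s, smap$snp_id)
    if (!is.na(si)) mains <- union(mains, near(smap$chrom[si], smap$bp[si]))
  }
  y <- .signal_matrix(discovery)[, cpg_id]
  p_gw <- main_effect_scan(discovery$genotypes[, smap$snp_id, drop = FALSE],
                           y)
  gw_thr <- alpha / nrow(smap)
  mains <- union(mains, names(p_gw)[!is.na(p_gw) & p_gw < gw_thr])
  # LD partners of the interacting SNPs
  partners <- hit_snps
  for (s in hit_snps) {
    gs <- discovery$genotypes[, s]
    r2 <- vapply(smap$snp_id, function(t) {
      if (t == s) return(1)
      tryCatch(genotype_r2(gs, discovery$genotypes[, t]),
               error = function(e) 0)
    }, 0)
    partners <- union(partners, smap$snp_id[r2 > ld_threshold])
  }
  pairs <- unique(rbind(
    as.matrix(hits[, c("snp_a", "snp_b")]),
    if (length(partners) >= 2L) t(utils::combn(sort(partners), 2L))))
  colnames(pairs) <- c("snp_a", "snp_b")
  list(mains = sort(unique(mains)), pairs = pairs)
}

# Design columns of a main term (genotype factor, reference level 0) on a
# given genotype vector: up to 2 dummy columns, reduced when a level is
# absent.
.main_cols <- function(g) {
  X <- cbind(g == 1L, g == 2L)
  storage.mode(X) <- "double"
  X[is.na(X)] <- 0  # rows with missing genotypes are dropped by caller mask
  X
}

.interaction_cols <- function(ga, gb) {
  A <- .main_cols(ga); B <- .main_cols(gb)
  cbind(A[, 1] * B[, 1], A[, 1] * B[, 2], A[, 2] * B[, 1], A[, 2] * B[, 2])
}

# Partial F-test of adding `new_cols` to design `X` (complete rows only).
.partial_F <- function(X, new_cols, y, rows) {
  Xs <- X[rows, , drop = FALSE]
  Xf <- cbind(Xs, new_cols[rows, , drop = FALSE])
  qs <- qr(Xs); qf_ <- qr(Xf)
  df_num <- qf_$rank - qs$rank
  if (df_num <= 0) return(list(p = NA_real_, df = 0))
  yy <- y[rows]
  rss_s <- sum(qr.resid(qs, yy)^2)
  rss_f <- sum(qr.resid(qf_, yy)^2)
  df_den <- length(yy) - qf_$rank
  if (df_den <= 0 || rss_f <= 0) return(list(p = NA_real_, df = df_num))
  F <- ((rss_s - rss_f) / df_num) / (rss_f / df_den)
  list(p = pf(F, df_num, df_den, lower.tail = FALSE), F = F, df = df_num)
}

#' Dual-cohort stepwise-forward selection of main and interaction terms
#'
#' Candidate mains enter first in ascending order of their discovery
#' marginal 2-df p-value, then candidate pairs in ascending order of their
#' discovery exact interaction p-value. At each step the candidate term is
#' added to the current model (a main contributes its 2-df genotype factor;
#' a pair contributes its 4-df interaction contrasts on top of the two
#' supporting main factors, which are added silently if absent) and its
#' partial F-test p-value is computed in both cohorts with the identical
#' term structure. The term is kept iff both p-values are below
#' `alpha / (n_mains_tested + n_pairs_tested)`. Interaction candidates
#' require all 9 cells present and minimal cell size strictly above
#' `min_cell` in both cohorts.
#'
#' @param cpg_id The CpG.
#' @param mains Character vector of candidate main-effect SNPs.
#' @param pairs Two-column matrix/data frame of candidate pairs.
#' @param discovery,replication `cohort` objects.
#' @param alpha Alpha for the per-CpG candidate-count Bonferroni.
#' @param min_cell Minimal 9-cell group size bound for interactions.
#' @return Object of class `cpg_model` with `terms` (kept terms, entry
#'   order, per-cohort p-values), candidate counts and threshold.
#' @export
forward_select <- function(cpg_id, mains, pairs, discovery, replication,
                           alpha = 0.05, min_cell = 3) {
  yd <- .signal_matrix(discovery)[, cpg_id]
  yr <- .signal_matrix(replication)[, cpg_id]
  pairs <- if (is.null(pairs) || NROW(pairs) == 0)
    matrix(character(), 0, 2) else as.matrix(pairs)
  n_tested <- length(mains) + nrow(pairs)
  if (n_tested == 0L)
    return(structure(list(cpg_id = cpg_id, terms = .empty_terms(),
                          n_main_tested = 0L, n_int_tested = 0L,
                          threshold = NA_real_),
                     class = "cpg_model"))
  threshold <- alpha / n_tested

  p_main <- if (length(mains))
    main_effect_scan(discovery$genotypes[, mains, drop = FALSE], yd)
    else numeric()
  p_pair <- apply(pairs, 1, function(pr) {
    tryCatch(exact_interaction_anova(discovery$genotypes[, pr[1]],
                                     discovery$genotypes[, pr[2]], yd)$p,
             error = function(e) NA_real_)
  })
  if (!length(p_pair)) p_pair <- numeric()

  build <- function(cohort_g, y) {
    n <- length(y)
    list(G = cohort_g, y = y, X = matrix(1, n, 1),
         rows = !is.na(y), in_model = character())
  }
  st_d <- build(discovery$genotypes, yd)
  st_r <- build(replication$genotypes, yr)

  add_main_cols <- function(st, snp) {
    g <- st$G[, snp]
    st$X <- cbind(st$X, .main_cols(g))
    st$rows <- st$rows & !is.na(g)
    st$in_model <- c(st$in_model, snp)
    st
  }

  terms <- list()
  entry <- 0L

  try_term <- function(kind, snp_a, snp_b = NA_character_) {
    # returns list(keep, p_d, p_r, states) without committing
    if (kind == "main") {
      nc_d <- .main_cols(st_d$G[, snp_a])
      nc_r <- .main_cols(st_r$G[, snp_a])
      rows_d <- st_d$rows & !is.na(st_d$G[, snp_a])
      rows_r <- st_r$rows & !is.na(st_r$G[, snp_a])
      pd <- .partial_F(st_d$X, nc_d, st_d$y, rows_d)
      pr_ <- .partial_F(st_r$X, nc_r, st_r$y, rows_r)
      list(p_d = pd$p, p_r = pr_$p)
    } else {
      base_d <- st_d; base_r <- st_r
      for (s in c(snp_a, snp_b)) {
        if (!s %in% base_d$in_model) base_d <- add_main_cols(base_d, s)
        if (!s %in% base_r$in_model) base_r <- add_main_cols(base_r, s)
      }
      nc_d <- .interaction_cols(base_d$G[, snp_a], base_d$G[, snp_b])
      nc_r <- .interaction_cols(base_r$G[, snp_a], base_r$G[, snp_b])
      pd <- .partial_F(base_d$X, nc_d, base_d$y, base_d$rows)
      pr_ <- .partial_F(base_r$X, nc_r, base_r$y, base_r$rows)
      list(p_d = pd$p, p_r = pr_$p, base_d = base_d, base_r = base_r,
           nc_d = nc_d, nc_r = nc_r)
    }
  }

  # mains first, ascending discovery marginal p
  for (snp in mains[order(p_main)]) {
    if (is.na(p_main[snp])) next
    res <- try_term("main", snp)
    if (!is.na(res$p_d) && !is.na(res$p_r) &&
        res$p_d < threshold && res$p_r < threshold) {
      st_d <- add_main_cols(st_d, snp)
      st_r <- add_main_cols(st_r, snp)
      entry <- entry + 1L
      terms[[entry]] <- data.frame(kind = "main", snp_a = snp,
                                   snp_b = NA_character_, df = 2L,
                                   p_discovery = res$p_d,
                                   p_replication = res$p_r,
                                   entry_order = entry,
                                   stringsAsFactors = FALSE)
    }
  }
  # then interactions, ascending discovery exact interaction p
  if (nrow(pairs)) {
    for (k in order(p_pair)) {
      if (is.na(p_pair[k])) next
      pr <- pairs[k, ]
      cnt_d <- table(factor(discovery$genotypes[, pr[1]], 0:2),
                     factor(discovery$genotypes[, pr[2]], 0:2))
      cnt_r <- table(factor(replication$genotypes[, pr[1]], 0:2),
                     factor(replication$genotypes[, pr[2]], 0:2))
      if (min(cnt_d) <= min_cell || min(cnt_r) <= min_cell) next
      res <- try_term("interaction", pr[1], pr[2])
      if (!is.na(res$p_d) && !is.na(res$p_r) &&
          res$p_d < threshold && res$p_r < threshold) {
        st_d <- res$base_d; st_r <- res$base_r
        st_d$X <- cbind(st_d$X, res$nc_d)
        st_r$X <- cbind(st_r$X, res$nc_r)
        entry <- entry + 1L
        terms[[entry]] <- data.frame(kind = "interaction", snp_a = pr[1],
                                     snp_b = pr[2], df = 4L,
                                     p_discovery = res$p_d,
                                     p_replication = res$p_r,
                                     entry_order = entry,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  terms <- if (length(terms)) do.call(rbind, terms) else .empty_terms()
  terms$ld_r2 <- rep(NA_real_, nrow(terms))
  terms$ld_class <- rep(NA_character_, nrow(terms))
  terms$cis_trans <- rep(NA_character_, nrow(terms))
  structure(list(cpg_id = cpg_id, terms = terms,
                 n_main_tested = length(mains),
                 n_int_tested = nrow(pairs), threshold = threshold),
            class = "cpg_model")
}

.empty_terms <- function() {
  data.frame(kind = character(), snp_a = character(), snp_b = character(),
             df = integer(), p_discovery = numeric(),
             p_replication = numeric(), entry_order = integer(),
             stringsAsFactors = FALSE)
}

#' @export
print.cpg_model <- function(x, ...) {
  cat(sprintf("<cpg_model %s: %d terms kept of %d mains + %d pairs tested>\n",
              x$cpg_id, nrow(x$terms), x$n_main_tested, x$n_int_tested))
  if (nrow(x$terms)) print(x$terms)
  invisible(x)
}

#' Classify kept interaction pairs as LD-block or epistatic, and label cis/trans
#'
#' A kept pair is LD-block associated iff its discovery dosage
#' `r2 > ld_threshold` (strictly); otherwise it is classified as epistatic.
#' Each pair is additionally labeled `both_cis`, `one_cis` or `both_trans`
#' by whether each SNP lies within `cis_window` of the CpG.
#'
#' @param model A `cpg_model`.
#' @param discovery Discovery `cohort` (for LD and maps).
#' @param ld_threshold The calibrated LD threshold.
#' @param cis_window Cis window in bp (default 500 KB).
#' @return The model with `ld_r2`, `ld_class` and `cis_trans` filled in.
#' @export
classify_pairs <- function(model, discovery, ld_threshold,
                           cis_window = 5e5) {
  tm <- model$terms
  if (!nrow(tm)) return(model)
  smap <- discovery$snp_map
  cmap <- discovery$cpg_map
  ci <- match(model$cpg_id, cmap$cpg_id)
  for (k in which(tm$kind == "interaction")) {
    r2 <- tryCatch(genotype_r2(discovery$genotypes[, tm$snp_a[k]],
                               discovery$genotypes[, tm$snp_b[k]]),
                   error = function(e) NA_real_)
    tm$ld_r2[k] <- r2
    tm$ld_class[k] <- if (!is.na(r2) && r2 > ld_threshold) "ld_block"
                      else "epistatic"
    cis <- vapply(c(tm$snp_a[k], tm$snp_b[k]), function(s) {
      si <- match(s, smap$snp_id)
      smap$chrom[si] == cmap$chrom[ci] &&
        abs(smap$bp[si] - cmap$bp[ci]) <= cis_window
    }, TRUE)
    tm$cis_trans[k] <- c("both_trans", "one_cis", "both_cis")[sum(cis) + 1]
  }
  model$terms <- tm
  model
}

# R-squared of a least-squares fit of y on design X over complete rows.
.model_r2 <- function(X, y, rows) {
  yy <- y[rows]
  rss <- sum(qr.resid(qr(X[rows, , drop = FALSE]), yy)^2)
  tss <- sum((yy - mean(yy))^2)
  if (tss <= 0) return(0)
  1 - rss / tss
}

#' Variance decomposition of a fitted per-CpG model
#'
#' Reports, on one cohort's adjusted signal: the R-squared of the single
#' most significant main term alone, of the mains-only model, and of the
#' full kept model (interaction terms contribute their supporting main
#' factors plus the 4-df contrasts). The interaction contribution is the
#' difference of the last two.
#'
#' @param model A `cpg_model`.
#' @param cohort The `cohort` to evaluate on.
#' @return List with `most_significant_main`, `all_mains`,
#'   `all_mains_plus_interactions`, `interaction_contribution`.
#' @export
variance_decomposition <- function(model, cohort) {
  y <- .signal_matrix(cohort)[, model$cpg_id]
  tm <- model$terms
  G <- cohort$genotypes
  empty <- list(most_significant_main = 0, all_mains = 0,
                all_mains_plus_interactions = 0,
                interaction_contribution = 0)
  if (!nrow(tm)) return(empty)
  p_col <- if (cohort$role == "replication") "p_replication" else
    "p_discovery"
  mains <- tm[tm$kind == "main", , drop = FALSE]
  design <- function(snps, with_int = NULL) {
    X <- matrix(1, length(y), 1)
    rows <- !is.na(y)
    for (s in snps) {
      X <- cbind(X, .main_cols(G[, s]))
      rows <- rows & !is.na(G[, s])
    }
    if (!is.null(with_int)) for (k in seq_len(nrow(with_int))) {
      X <- cbind(X, .interaction_cols(G[, with_int$snp_a[k]],
                                      G[, with_int$snp_b[k]]))
      rows <- rows & !is.na(G[, with_int$snp_a[k]]) &
        !is.na(G[, with_int$snp_b[k]])
    }
    list(X = X, rows = rows)
  }
  best_main <- 0
  if (nrow(mains)) {
    bm <- mains$snp_a[which.min(mains[[p_col]])]
    d <- design(bm)
    best_main <- .model_r2(d$X, y, d$rows)
  }
  d <- design(mains$snp_a)
  r2_mains <- .model_r2(d$X, y, d$rows)
  ints <- tm[tm$kind == "interaction", , drop = FALSE]
  support <- unique(c(mains$snp_a, ints$snp_a, ints$snp_b))
  d <- design(support, if (nrow(ints)) ints else NULL)
  r2_full <- .model_r2(d$X, y, d$rows)
  list(most_significant_main = best_main, all_mains = r2_mains,
       all_mains_plus_interactions = r2_full,
       interaction_contribution = r2_full - r2_mains)
}
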