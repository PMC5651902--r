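# Enrichment stage: cluster correlated hit CpGs so each signal counts once,
# test annotation enrichment with 2x2 chi-squared tests, and flag CpGs
# associated with transcript expression.

#' Cluster hit CpGs by methylation correlation
#'
#' Builds a graph with an edge between two CpGs when their pairwise Pearson
#' correlation exceeds `r_threshold`; clusters are the connected components
#' (single linkage). One representative CpG is drawn uniformly per cluster
#' with the given seed. With `method = "average"`, average-linkage
#' hierarchical clustering cut at distance `1 - r_threshold` is used
#' instead.
#'
#' @param methylation Samples x hit-CpGs matrix (any consistent scale).
#' @param r_threshold Correlation threshold (default 0.8).
#' @param seed Integer seed for representative sampling.
#' @param cpg_map Optional map to compute the maximal within-cluster
#'   base-pair distance (same-chromosome members only).
#' @param method `"components"` (default) or `"average"`.
#' @return Data frame with `cpg_id`, `cluster`, `representative` flag and
#'   `max_pairwise_bp` per cluster.
#' @export
cluster_cpgs <- function(methylation, r_threshold = 0.8, seed = 1L,
                         cpg_map = NULL,
                         method = c("components", "average")) {
  method <- match.arg(method)
  ids <- colnames(methylation)
  stopifnot(length(ids) >= 1L)
  if (length(ids) == 1L) {
    memb <- setNames(1L, ids)
  } else {
    r <- suppressWarnings(cor(methylation, use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    if (method == "components") {
      adj <- (r > r_threshold)
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      memb <- igraph::components(g)$membership
      names(memb) <- ids
    } else {
      hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
      memb <- stats::cutree(hc, h = 1 - r_threshold)
      names(memb) <- ids
    }
  }
  set.seed(seed)
  out <- data.frame(cpg_id = ids, cluster = as.integer(memb[ids]),
                    representative = FALSE,
                    max_pairwise_bp = NA_real_, stringsAsFactors = FALSE)
  for (cl in sort(unique(out$cluster))) {
    members <- which(out$cluster == cl)
    rep_i <- members[sample.int(length(members), 1L)]
    out$representative[rep_i] <- TRUE
    if (!is.null(cpg_map) && length(members) > 1L) {
      sub <- cpg_map[match(out$cpg_id[members], cpg_map$cpg_id), ]
      d <- numeric()
      for (ch in unique(sub$chrom)) {
        bp <- sub$bp[sub$chrom == ch]
        if (length(bp) > 1L) d <- c(d, max(dist(bp)))
      }
      if (length(d)) out$max_pairwise_bp[members] <- max(d)
    }
  }
  out
}

#' Flag CpGs falling in annotation interval sets
#'
#' Interval sets follow the BED convention: 0-based, half-open
#' `[start, end)`. CpG coordinates are 1-based map positions; a CpG at
#' 1-based position `bp` overlaps an interval iff `start < bp <= end`.
#'
#' @param cpg_map Data frame with `cpg_id`, `chrom`, `bp`.
#' @param interval_sets Named list of data frames with `chrom`, `start`,
#'   `end` columns (one per feature, e.g. CpG islands, TFBS, DNase I).
#' @return Logical matrix, CpGs x features.
#' @export
annotate_cpgs <- function(cpg_map, interval_sets) {
  stopifnot(is.list(interval_sets), !is.null(names(interval_sets)))
  flags <- matrix(FALSE, nrow(cpg_map), length(interval_sets),
                  dimnames = list(cpg_map$cpg_id, names(interval_sets)))
  for (f in names(interval_sets)) {
    iv <- interval_sets[[f]]
    if (!nrow(iv)) next
    unknown <- setdiff(unique(iv$chrom), unique(cpg_map$chrom))
    for (ch in unique(cpg_map$chrom)) {
      sub <- iv[iv$chrom == ch, , drop = FALSE]
      rows <- which(cpg_map$chrom == ch)
      if (!nrow(sub) || !length(rows)) next
      # 0-based half-open [start, end) == 1-based closed [start+1, end]
      ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      q <- IRanges::IRanges(start = cpg_map$bp[rows],
                            end = cpg_map$bp[rows])
      flags[rows, f] <- IRanges::countOverlaps(q, ir) > 0L
    }
  }
  flags
}

#' 2x2 chi-squared enrichment of a feature in hit CpGs
#'
#' Pearson chi-squared test (1 df, no continuity correction) of feature
#' membership against group (hit vs background). The expected percentage
#' is the background proportion, the observed percentage the hit
#' proportion.
#'
#' @param hit_flags Logical vector of feature membership for hit CpGs.
#' @param background_flags Same for the background CpGs.
#' @param feature Feature name for the output row.
#' @return One-row data frame: `feature`, `expected_pct`, `observed_pct`,
#'   `chi2`, `p`, `low_expected` (warning flag when an expected cell is
#'   below 1).
#' @export
chi2_enrichment <- function(hit_flags, background_flags,
                            feature = "feature") {
  stopifnot(length(hit_flags) > 0, length(background_flags) > 0)
  tab <- rbind(hit = c(sum(hit_flags), sum(!hit_flags)),
               background = c(sum(background_flags), sum(!background_flags)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(tab[, 1] == 0) || all(tab[, 2] == 0)) {
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  data.frame(feature = feature,
             expected_pct = 100 * mean(background_flags),
             observed_pct = 100 * mean(hit_flags),
             chi2 = chi2, p = p, low_expected = any(expected < 1),
             stringsAsFactors = FALSE)
}

#' CpG-transcriptome association flags
#'
#' For every CpG-transcript pair a Pearson correlation p-value is computed.
#' A pair is genome-wide significant when
#' `p < alpha / (n_cpgs * n_transcripts)` and cis-significant when the
#' transcript lies within `cis_window` of the CpG and
#' `p < alpha / n_local_transcripts`. A CpG is flagged associated when any
#' pair meets either criterion (the union).
#'
#' @param methylation Samples x CpGs matrix.
#' @param expression Samples x transcripts matrix (same samples).
#' @param cpg_map,transcript_map Position maps for the columns.
#' @param alpha Family-wise alpha (default 0.05).
#' @param cis_window Cis window in bp (default 500 KB).
#' @return Data frame per CpG: `associated_genomewide`, `associated_cis`,
#'   `associated` (union), `top_transcript`, `top_p`, `top_is_cis`,
#'   `n_local_transcripts`.
#' @export
expression_association <- function(methylation, expression, cpg_map,
                                   transcript_map, alpha = 0.05,
                                   cis_window = 5e5) {
  stopifnot(nrow(methylation) == nrow(expression))
  n <- nrow(methylation)
  keep_tx <- apply(expression, 2, function(x) var(x, na.rm = TRUE) > 0)
  E <- expression[, keep_tx, drop = FALSE]
  tmap <- transcript_map[match(colnames(E),
                               transcript_map$transcript_id), ]
  r <- suppressWarnings(cor(methylation, E,
                            use = "pairwise.complete.obs"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  gw_thr <- alpha / (ncol(methylation) * ncol(E))
  out <- lapply(seq_len(ncol(methylation)), function(i) {
    cg <- colnames(methylation)[i]
    ci <- match(cg, cpg_map$cpg_id)
    local <- tmap$chrom == cpg_map$chrom[ci] &
      abs(tmap$bp - cpg_map$bp[ci]) <= cis_window
    n_local <- sum(local)
    gw <- any(p[i, ] < gw_thr, na.rm = TRUE)
    cis <- n_local > 0 &&
      any(p[i, local] < alpha / n_local, na.rm = TRUE)
    top <- which.min(p[i, ])
    data.frame(cpg_id = cg, associated_genomewide = gw,
               associated_cis = cis, associated = gw || cis,
               top_transcript = colnames(E)[top], top_p = p[i, top],
               top_is_cis = local[top], n_local_transcripts = n_local,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotation/expression enrichment report for hit CpGs
#'
#' Clusters the hit CpGs, keeps one representative per cluster, and
#' compares representative CpGs against all remaining CpGs for each
#' annotation feature (and, when expression data is given, for
#' expression association) using 2x2 chi-squared tests.
#'
#' @param hit_cpgs Character vector of hit CpG ids.
#' @param methylation Samples x CpGs matrix covering at least the hits.
#' @param cpg_map CpG position map for all CpGs considered.
#' @param interval_sets Named list of BED-style interval data frames.
#' @param expression,transcript_map Optional expression data.
#' @param r_threshold,seed,alpha,cis_window Passed through.
#' @return List with `clusters`, `representatives` and `table` (one
#'   enrichment row per feature).
#' @export
enrichment_report <- function(hit_cpgs, methylation, cpg_map, interval_sets,
                              expression = NULL, transcript_map = NULL,
                              r_threshold = 0.8, seed = 1L, alpha = 0.05,
                              cis_window = 5e5) {
  stopifnot(all(hit_cpgs %in% colnames(methylation)))
  cl <- cluster_cpgs(methylation[, hit_cpgs, drop = FALSE], r_threshold,
                     seed, cpg_map)
  reps <- cl$cpg_id[cl$representative]
  background <- setdiff(cpg_map$cpg_id, hit_cpgs)
  flags <- annotate_cpgs(cpg_map, interval_sets)
  rows <- lapply(colnames(flags), function(f)
    chi2_enrichment(flags[reps, f], flags[background, f], f))
  if (!is.null(expression)) {
    ea <- expression_association(methylation, expression, cpg_map,
                                 transcript_map, alpha, cis_window)
    assoc <- setNames(ea$associated, ea$cpg_id)
    have <- intersect(background, names(assoc))
    rows <- c(rows, list(chi2_enrichment(assoc[reps], assoc[have],
                                         "gene_expression")))
  }
  list(clusters = cl, representatives = reps,
       table = do.call(rbind, rows))
}
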