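# Spurious-interaction scenario: two SNPs A and B in LD with a third SNP C
# that carries a strong main effect can mimic an A x B interaction that is in
# fact fully attributable to C's main effect. The generator below plants
# exactly that configuration, with the LD triad r2(C,A) ~ 0.55,
# r2(C,B) ~ 0.25, r2(A,B) ~ 0.024.

# Three-locus haplotype frequencies from allele frequencies p = (pC, pA, pB)
# and pairwise disequilibria D = (D_CA, D_CB, D_AB) plus three-way term d3.
# Standard inclusion-exclusion parameterization; returns the 8-vector in the
# order of expand.grid(C = 0:1, A = 0:1, B = 0:1).
.triad_hap_freqs <- function(p, D, d3) {
  sgn <- function(i) ifelse(i == 1, 1, -1)
  grid <- expand.grid(C = 0:1, A = 0:1, B = 0:1)
  pr <- function(x, i) ifelse(i == 1, x, 1 - x)
  with(grid,
       pr(p[1], C) * pr(p[2], A) * pr(p[3], B) +
         sgn(C) * sgn(A) * D[1] * pr(p[3], B) +
         sgn(C) * sgn(B) * D[2] * pr(p[2], A) +
         sgn(A) * sgn(B) * D[3] * pr(p[1], C) +
         sgn(C) * sgn(A) * sgn(B) * d3)
}

# Frozen calibration: allele frequencies and pairwise r2 targets for which a
# valid (all-nonnegative) haplotype distribution exists; d3 is centered in
# its feasible interval so every haplotype has frequency >= 0.008.
.triad_params <- function(r2 = c(0.55, 0.25, 0.024),
                          p = c(0.475, 0.375, 0.25)) {
  sdv <- sqrt(p * (1 - p))
  D <- c(sqrt(r2[1]) * sdv[1] * sdv[2],
         sqrt(r2[2]) * sdv[1] * sdv[3],
         sqrt(r2[3]) * sdv[2] * sdv[3])
  base <- .triad_hap_freqs(p, D, 0)
  sgn3 <- .triad_hap_freqs(p, D, 1) - base
  lo <- max(-base[sgn3 > 0] / sgn3[sgn3 > 0])
  hi <- min(base[sgn3 < 0] / -sgn3[sgn3 < 0])
  if (hi <= lo) stop("LD targets unreachable for the given allele ",
                     "frequencies")
  list(p = p, D = D, d3 = (lo + hi) / 2,
       freqs = .triad_hap_freqs(p, D, (lo + hi) / 2))
}

.triad_genotypes <- function(n, freqs) {
  grid <- as.matrix(expand.grid(C = 0:1, A = 0:1, B = 0:1))
  h1 <- grid[sample.int(8L, n, replace = TRUE, prob = freqs), , drop = FALSE]
  h2 <- grid[sample.int(8L, n, replace = TRUE, prob = freqs), , drop = FALSE]
  g <- h1 + h2
  storage.mode(g) <- "integer"
  g
}

#' Construct the spurious-interaction (LD triad) scenario
#'
#' Generates a paired cohort set containing three SNPs C, A and B with
#' pairwise LD r2(C,A) ~ 0.55, r2(C,B) ~ 0.25 and r2(A,B) ~ 0.024, and one
#' CpG carrying a strong main effect of SNP C only. Because A and B are each
#' in LD with C but nearly independent of each other, a naive A x B
#' interaction test on this CpG tends to be significant even though no
#' interaction was planted: the 9 (A,B) genotype cells mimic the 3 genotype
#' groups of C. The truth registry marks the A x B pair as
#' `spurious_ld_triad`.
#'
#' Realized LD is checked against the targets and the draw is retried with a
#' fresh stream a bounded number of times before erroring.
#'
#' @param n_discovery,n_replication Cohort sizes (discovery must be >= 200).
#' @param seed Integer seed.
#' @param main_r2 Variance fraction of the planted main effect of C
#'   (default 0.5).
#' @param max_retry Retries allowed for hitting the LD targets.
#' @return List with `discovery`, `replication` (class `cohort`; SNPs named
#'   `snpC`, `snpA`, `snpB`, CpG `cg_triad`) and `truth`.
#' @export
make_ld_triad_scenario <- function(n_discovery = 533L, n_replication = 319L,
                               seed = 1L, main_r2 = 0.5, max_retry = 10L) {
  if (n_discovery < 200L) stop("n_discovery must be >= 200")
  par <- .triad_params()
  snp_map <- data.frame(snp_id = c("snpA", "snpC", "snpB"),
                        chrom = 1L, bp = c(1000000L, 1050000L, 1100000L),
                        maf = par$p[c(2, 1, 3)], block = 1L,
                        allele_ref = "A", allele_alt = "B",
                        stringsAsFactors = FALSE)
  cpg_map <- data.frame(cpg_id = "cg_triad", chrom = 1L, bp = 1050500L,
                        stringsAsFactors = FALSE)
  b <- sqrt(main_r2 / (1 - main_r2))  # slope on standardized dosage, noise sd 1

  one_cohort <- function(role, n, try_seed) {
    for (r in seq_len(max_retry)) {
      set.seed(try_seed + 1000L * (r - 1L))
      g <- .triad_genotypes(n, par$freqs)  # columns C, A, B
      r2 <- suppressWarnings(cor(g))^2
      ok <- !any(is.na(r2)) &&
        abs(r2["C", "A"] - 0.55) < 0.1 &&
        abs(r2["C", "B"] - 0.25) < 0.12 &&
        r2["A", "B"] < 0.12 &&
        all(apply(g, 2, function(x) length(unique(x))) == 3L)
      if (ok) {
        zc <- (g[, "C"] - mean(g[, "C"])) / sd(g[, "C"])
        y <- b * zc + rnorm(n)
        beta <- m_to_beta(matrix(y, ncol = 1,
                                 dimnames = list(NULL, "cg_triad")))
        G <- g[, c("A", "C", "B")]
        colnames(G) <- c("snpA", "snpC", "snpB")
        rownames(G) <- sprintf("%s%04d", substr(role, 1, 1), seq_len(n))
        rownames(beta) <- rownames(G)
        cov <- data.frame(sample_id = rownames(G), sex = 0L, age = 25L,
                          plate = 1L, batch = 1L, stringsAsFactors = FALSE)
        return(structure(list(role = role, genotypes = G, snp_map = snp_map,
                              methylation_beta = beta, cpg_map = cpg_map,
                              covariates = cov, probe_dosages = list(),
                              truth = NULL),
                         class = "cohort"))
      }
    }
    stop("LD targets unreachable after ", max_retry, " retries")
  }

  disc <- one_cohort("discovery", n_discovery, seed)
  repl <- one_cohort("replication", n_replication, seed + 500000L)
  eff <- list(planted_effect("cg_triad", "spurious_ld_triad",
                             c("snpA", "snpB", "snpC"), main_r2))
  truth <- structure(list(effects = eff, realized_r2 = main_r2,
                          role = "discovery"),
                     class = "truth_registry")
  disc$truth <- truth
  list(discovery = disc, replication = repl, truth = truth)
}

#' Simulate a transcript-expression matrix coupled to CpGs
#'
#' A chosen subset of CpGs (preferentially the genetically controlled ones
#' listed in the truth registry) is coupled to one cis transcript each,
#' placed within 500 KB, at the requested squared correlation; all remaining
#' transcripts are independent noise.
#'
#' @param methylation Samples x CpGs matrix (beta or M scale) providing the
#'   signals transcripts are coupled to.
#' @param cpg_map CpG map for the columns of `methylation`.
#' @param truth Optional `truth_registry`; its CpGs are coupled first.
#' @param n_transcripts Total number of transcripts (>= 1).
#' @param coupling_r2 Squared correlation of coupled pairs, in [0, 1).
#' @param n_coupled Number of coupled CpG-transcript pairs.
#' @param seed Integer seed.
#' @return List with `expression` (samples x transcripts) and
#'   `transcript_map` (`transcript_id`, `chrom`, `bp`, `coupled_cpg`).
#' @export
simulate_expression <- function(methylation, cpg_map, truth = NULL,
                                n_transcripts = 200L, coupling_r2 = 0.3,
                                n_coupled = 10L, seed = 1L) {
  if (n_transcripts < 1L) stop("n_transcripts must be >= 1")
  if (coupling_r2 < 0 || coupling_r2 >= 1)
    stop("coupling_r2 must lie in [0, 1)")
  set.seed(seed)
  n <- nrow(methylation)
  preferred <- character()
  if (!is.null(truth))
    preferred <- unique(vapply(truth$effects, function(e) e$cpg_id, ""))
  preferred <- intersect(preferred, colnames(methylation))
  pool <- setdiff(colnames(methylation), preferred)
  n_coupled <- min(n_coupled, ncol(methylation), n_transcripts)
  coupled <- c(preferred,
               sample(pool, max(0L, n_coupled - length(preferred))))
  coupled <- coupled[seq_len(n_coupled)]

  E <- matrix(rnorm(n * n_transcripts), n, n_transcripts)
  tmap <- data.frame(transcript_id = sprintf("tx%05d",
                                             seq_len(n_transcripts)),
                     chrom = sample(unique(cpg_map$chrom), n_transcripts,
                                    TRUE),
                     bp = sample.int(max(cpg_map$bp) + 500000L, n_transcripts,
                                     TRUE),
                     coupled_cpg = NA_character_, stringsAsFactors = FALSE)
  if (coupling_r2 > 0 && n_coupled > 0) {
    for (i in seq_along(coupled)) {
      j <- match(coupled[i], cpg_map$cpg_id)
      z <- scale(methylation[, coupled[i]])
      E[, i] <- sqrt(coupling_r2) * z + sqrt(1 - coupling_r2) * rnorm(n)
      tmap$chrom[i] <- cpg_map$chrom[j]
      tmap$bp[i] <- pmax(1L, cpg_map$bp[j] +
                           as.integer(sample(-450000:450000, 1L)))
      tmap$coupled_cpg[i] <- coupled[i]
    }
  }
  colnames(E) <- tmap$transcript_id
  rownames(E) <- rownames(methylation)
  list(expression = E, transcript_map = tmap)
}
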