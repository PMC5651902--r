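# Small in-code fixtures shared across the test files.

# A compact paired-cohort simulation for unit tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_discovery = 120L, n_replication = 90L, n_snps = 40L,
             n_cpgs = 8L, n_chromosomes = 2L, seed = seed, ...)
}

# Balanced 3x3 factorial design: k observations per genotype cell.
balanced_pair <- function(k = 10L) {
  list(ga = rep(0:2, each = 3L * k), gb = rep(rep(0:2, each = k), 3L))
}

# Two planted high-MAF SNPs on different chromosomes of a config's map,
# suitable for epistasis planting (all 9 cells well populated).
pick_planted_pair <- function(config, maf_min = 0.4) {
  map <- epimeth:::.simulate_snp_map(config)
  cand <- map$snp_id[map$maf > maf_min]
  ch <- map$chrom[match(cand, map$snp_id)]
  s1 <- cand[ch == unique(ch)[1]][1]
  s2 <- cand[ch == unique(ch)[2]][1]
  if (is.na(s1) || is.na(s2)) return(NULL)
  c(s1, s2)
}

# Independent brute-force oracle for the exact Hardy-Weinberg test:
# conditional probability of a heterozygote count given allele counts,
# derived directly from the multinomial coefficient over genotype
# configurations (a code path independent of the package's log-factorial
# enumeration).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, 0)
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  sum(prob[prob <= obs * (1 + 1e-12)])
}
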