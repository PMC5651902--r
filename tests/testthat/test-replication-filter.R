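test_that("per-CpG adaptive thresholds reproduce their closed form", {
  expect_equal(per_cpg_threshold(13112, 1), 0.05 / 13113)
  expect_equal(per_cpg_threshold(13112, 46314), 0.05 / 59426)
  expect_equal(per_cpg_threshold(1, 1), 0.025)
  expect_error(per_cpg_threshold(0, 1), "n_unique_cpgs")
})

test_that("empirical p hits its boundary cases", {
  set.seed(2)
  n <- 90
  ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.45)
  while (any(table(factor(ga, 0:2), factor(gb, 0:2)) == 0)) {
    ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.45)
  }
  y <- rnorm(n)
  # F_obs above every permuted value
  expect_equal(empirical_interaction_p(ga, gb, y, F_obs = 1e9, B = 199,
                                       seed = 1), 1 / 200)
  # F_obs = 0: every permutation ties or exceeds
  expect_equal(empirical_interaction_p(ga, gb, y, F_obs = 0, B = 199,
                                       seed = 1), 1)
  expect_error(empirical_interaction_p(ga, gb, y, 1, B = 50), "B must be")
})

test_that("empirical p is uniform and tracks the parametric p under the null", {
  set.seed(12)
  n <- 100
  ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.45)
  while (any(table(factor(ga, 0:2), factor(gb, 0:2)) == 0)) {
    ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.45)
  }
  res <- t(replicate(400, {
    y <- rnorm(n)
    ex <- exact_interaction_anova(ga, gb, y)
    c(ex$p, empirical_interaction_p(ga, gb, y, ex$F, B = 400))
  }))
  expect_gt(suppressWarnings(ks.test(res[, 2], "punif"))$p.value, 0.01)
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.95)
})

test_that("the sign test matches its definition and degenerate rules", {
  bp <- balanced_pair(4L)
  set.seed(5)
  y1 <- rnorm(36)
  cd <- cell_summaries(bp$ga, bp$gb, y1)
  expect_equal(sign_test_r(cd, cd)$r, 1)
  cneg <- cell_summaries(bp$ga, bp$gb, -y1)
  expect_equal(sign_test_r(cd, cneg)$r, -1)
  czero <- cell_summaries(bp$ga, bp$gb, rep(1, 36))
  expect_false(sign_test_r(cd, czero)$ok)
})

test_that("a planted effect passes the sign test at high frequency", {
  set.seed(31)
  d0 <- orthogonalize_delta(matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3),
                            epimeth:::.hwe_freqs(0.4),
                            epimeth:::.hwe_freqs(0.4))
  mk <- function(n, r2) {
    repeat {
      ga <- rbinom(n, 2, 0.4); gb <- rbinom(n, 2, 0.4)
      if (all(table(factor(ga, 0:2), factor(gb, 0:2)) > 0)) break
    }
    t <- d0[cbind(ga + 1, gb + 1)]
    y <- t * sqrt(r2 / (1 - r2) / var(t)) + rnorm(n)
    cell_summaries(ga, gb, y)
  }
  pass <- replicate(200, sign_test_r(mk(533, 0.1), mk(319, 0.1))$r > 0.85)
  expect_gt(mean(pass), 0.9)
})

test_that("the triple filter passes planted effects and rejects unreplicated ones", {
  cfg <- sim_config(n_snps = 50, n_cpgs = 5, n_chromosomes = 2, seed = 61)
  pp <- pick_planted_pair(cfg)
  eff <- list(planted_effect("cg00002", "epistatic", pp, 0.2))
  sim <- simulate_cohorts(cfg, eff)
  sc <- exhaustive_scan(sim$discovery, sim$replication, f_filter = "auto")
  rv <- replicate_hits(sc, sim$discovery, sim$replication, B = 299,
                       seed = 3)
  v <- rv$verdicts
  expect_true(all(v$pass_all == (v$pass_min_cell & v$pass_bonferroni &
                                   v$pass_empirical & v$pass_sign)))
  expect_true(all(v$p_emp >= 1 / 300, na.rm = TRUE))
  planted <- v$cpg_id == "cg00002" &
    ((v$snp_a == pp[1] & v$snp_b == pp[2]) |
       (v$snp_a == pp[2] & v$snp_b == pp[1]))
  expect_true(any(v$pass_all[planted]))
  # verdict threshold reflects the per-CpG hit count
  for (cg in unique(v$cpg_id))
    expect_equal(unique(v$per_cpg_threshold[v$cpg_id == cg]),
                 0.05 / (length(unique(v$cpg_id)) + sum(v$cpg_id == cg)))
})

test_that("a discovery-only artifact fails replication", {
  # plant the effect in the discovery cohort only by swapping in a null
  # replication cohort simulated under a different base seed
  cfg <- sim_config(n_snps = 50, n_cpgs = 5, n_chromosomes = 2, seed = 62)
  pp <- pick_planted_pair(cfg)
  eff <- list(planted_effect("cg00002", "epistatic", pp, 0.2))
  disc <- simulate_cohort(cfg, "discovery", eff)
  repl <- simulate_cohort(cfg, "replication")
  sc <- exhaustive_scan(disc, repl, f_filter = "auto")
  planted <- sc$hits$cpg_id == "cg00002"
  expect_true(any(planted))
  rv <- replicate_hits(sc, disc, repl, B = 299, seed = 3)
  expect_false(any(rv$verdicts$pass_bonferroni[
    rv$verdicts$cpg_id == "cg00002"]))
})

test_that("verdicts are invariant to hit order and support pooled nulls", {
  cfg <- sim_config(n_snps = 40, n_cpgs = 4, n_chromosomes = 2, seed = 63)
  pp <- pick_planted_pair(cfg)
  eff <- list(planted_effect("cg00001", "epistatic", pp, 0.25))
  sim <- simulate_cohorts(cfg, eff)
  sc <- exhaustive_scan(sim$discovery, sim$replication, f_filter = "auto")
  rv1 <- replicate_hits(sc, sim$discovery, sim$replication, B = 199,
                        seed = 9)
  shuffled <- sc$hits[rev(seq_len(nrow(sc$hits))), ]
  rv2 <- replicate_hits(shuffled, sim$discovery, sim$replication, B = 199,
                        seed = 9)
  key <- function(v) v[order(v$cpg_id, v$snp_a, v$snp_b),
                       c("cpg_id", "p_rep", "p_emp", "sign_r", "pass_all")]
  expect_equal(key(rv1$verdicts), key(rv2$verdicts),
               ignore_attr = TRUE)
  rvp <- replicate_hits(sc, sim$discovery, sim$replication, B = 199,
                        seed = 9, pooled_permutations = TRUE)
  expect_true(all(rvp$verdicts$p_emp > 0 & rvp$verdicts$p_emp <= 1,
                  na.rm = TRUE))
})

test_that("min-cell boundary is strict", {
  # synthetic verdict path: construct genotypes with an exactly-3 cell
  set.seed(4)
  cnts <- rbind(c(20, 20, 20), c(20, 20, 20), c(17, 10, 3))
  ga <- rep(0:2, times = rowSums(cnts))
  gb <- unlist(lapply(1:3, function(i) rep(0:2, times = cnts[i, ])))
  n <- length(ga)
  stopifnot(min(table(factor(ga, 0:2), factor(gb, 0:2))) == 3)
  hits <- data.frame(cpg_id = "cg1", snp_a = "s1", snp_b = "s2",
                     stringsAsFactors = FALSE)
  mkc <- function(role) {
    structure(list(role = role,
                   genotypes = cbind(s1 = ga, s2 = gb),
                   snp_map = data.frame(snp_id = c("s1", "s2"), chrom = 1L,
                                        bp = c(100L, 200L)),
                   methylation_beta = matrix(runif(n, 0.3, 0.7), n, 1,
                                             dimnames = list(NULL, "cg1")),
                   cpg_map = data.frame(cpg_id = "cg1", chrom = 1L,
                                        bp = 150L),
                   covariates = data.frame(sex = 0, age = 25, plate = 1,
                                           batch = 1),
                   probe_dosages = list(), truth = NULL),
              class = "cohort")
  }
  rv <- replicate_hits(hits, mkc("discovery"), mkc("replication"), B = 100,
                       seed = 1)
  expect_false(rv$verdicts$pass_min_cell[1])
})
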