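test_that("cell summaries match hand computation and the ANOVA identity", {
  bp <- balanced_pair(2L)
  y <- rep(1:9, each = 2) + rep(c(-0.5, 0.5), 9)
  cs <- cell_summaries(bp$ga, bp$gb, y)
  expect_equal(as.vector(t(cs$means)), as.numeric(1:9))
  expect_equal(cs$n_total, 18)
  expect_equal(cs$grand_mean, 5)
  # constant phenotype: zero within-SS
  csc <- cell_summaries(bp$ga, bp$gb, rep(3, 18))
  expect_equal(csc$ss_within, 0)
  expect_true(all(csc$means == 3))
  # total SS decomposition
  set.seed(1)
  yy <- rnorm(18)
  cs2 <- cell_summaries(bp$ga, bp$gb, yy)
  total <- sum((yy - mean(yy))^2)
  between <- sum(cs2$counts * (cs2$means - cs2$grand_mean)^2)
  expect_equal(cs2$ss_within + between, total, tolerance = 1e-9)
  expect_error(cell_summaries(0:2, 0:2, rnorm(3)), "complete observations")
})

test_that("zero-margin patterns put all joint SS into the interaction term", {
  bp <- balanced_pair(4L)
  pattern <- matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3, 3)
  set.seed(2)
  y <- pattern[cbind(bp$ga + 1, bp$gb + 1)] + rnorm(36, 0, 0.1)
  cs <- cell_summaries(bp$ga, bp$gb, y)
  ap <- approx_two_locus_test(cs)
  # marginal predictions are ~0, so interaction SS ~ joint SS
  expect_equal(ap$F4_approx * 4, ap$F8 * 8, tolerance = 0.05)
  expect_true(ap$all_cells_present)
})

test_that("the 4-df approximation is exact on balanced orthogonal designs", {
  set.seed(3)
  for (i in 1:25) {
    bp <- balanced_pair(sample(3:6, 1))
    y <- rnorm(length(bp$ga))
    ap <- approx_two_locus_test(cell_summaries(bp$ga, bp$gb, y))
    ex <- exact_interaction_anova(bp$ga, bp$gb, y)
    expect_equal(ap$F4_approx, ex$F, tolerance = 1e-8)
  }
})

test_that("the approximation overshoots the exact F under correlated SNPs", {
  set.seed(4)
  over <- replicate(300, {
    n <- 200
    latent <- rnorm(n)
    ga <- (latent + rnorm(n, 0, 0.6) > 0.3) + (latent + rnorm(n, 0, 0.6) > 1.2)
    gb <- (latent + rnorm(n, 0, 0.6) > 0.3) + (latent + rnorm(n, 0, 0.6) > 1.2)
    y <- ga + gb + rnorm(n)  # purely additive truth
    cs <- tryCatch(cell_summaries(ga, gb, y), error = function(e) NULL)
    if (is.null(cs) || any(cs$counts == 0)) return(NA)
    ap <- approx_two_locus_test(cs)
    ex <- exact_interaction_anova(ga, gb, y)
    ap$F4_approx >= ex$F
  })
  expect_gt(mean(over, na.rm = TRUE), 0.8)
})

test_that("the exact test agrees with the two-model lm oracle", {
  set.seed(5)
  bp <- balanced_pair(10L)
  idx <- sample(90)
  ga <- bp$ga[idx]; gb <- bp$gb  # shuffle one margin: unbalanced cells
  y <- rnorm(90)
  ex <- exact_interaction_anova(ga, gb, y)
  f1 <- lm(y ~ factor(ga) + factor(gb))
  f2 <- lm(y ~ factor(ga) * factor(gb))
  av <- anova(f1, f2)
  expect_equal(ex$F, av$F[2], tolerance = 1e-8)
  expect_equal(ex$p, av$`Pr(>F)`[2], tolerance = 1e-8)
  expect_equal(ex$df, c(4, 90 - 9))
  # saturated noiseless interaction: p collapses to the representable floor
  pattern <- matrix(rnorm(9), 3, 3)
  ynl <- pattern[cbind(bp$ga + 1, bp$gb + 1)]
  exn <- exact_interaction_anova(bp$ga, bp$gb, ynl)
  expect_lte(exn$p, .Machine$double.xmin)
  expect_error(exact_interaction_anova(rep(0:1, 45), gb, y), "occupied")
})

test_that("exact-test p-values are uniform under an additive null", {
  set.seed(6)
  n <- 120
  ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.4)
  while (any(table(factor(ga, 0:2), factor(gb, 0:2)) == 0)) {
    ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.4)
  }
  ps <- replicate(2000, exact_interaction_anova(ga, gb,
                                                ga + 0.5 * gb + rnorm(n))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("test-count and Bonferroni arithmetic are exact", {
  expect_equal(count_exhaustive_tests(1, 3), 3)
  expect_equal(count_exhaustive_tests(2, 2), 2)
  expect_equal(count_exhaustive_tests(5, 0), 0)
  expect_error(count_exhaustive_tests(-1, 5), "non-negative")
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("interaction power behaves like the noncentral F law", {
  expect_equal(interaction_power(0, 533, 0.05), 0.05, tolerance = 1e-10)
  p_r <- vapply(c(0.1, 0.2, 0.3, 0.4), interaction_power, 0, n = 533,
                alpha = 1e-5)
  expect_true(all(diff(p_r) > 0))
  p_n <- vapply(c(100, 300, 533, 1000), function(n)
    interaction_power(0.25, n, 1e-5), 0)
  expect_true(all(diff(p_n) > 0))
  expect_error(interaction_power(0.3, 533, 2), "alpha")
})

test_that("the scan recovers a planted pair and respects its filters", {
  cfg <- sim_config(n_snps = 60, n_cpgs = 6, n_chromosomes = 3, seed = 41)
  pp <- pick_planted_pair(cfg)
  eff <- list(planted_effect("cg00003", "epistatic", pp, 0.2))
  sim <- simulate_cohorts(cfg, eff)
  sc <- exhaustive_scan(sim$discovery, sim$replication, f_filter = "auto")
  found <- sc$hits$cpg_id == "cg00003" &
    ((sc$hits$snp_a == pp[1] & sc$hits$snp_b == pp[2]) |
       (sc$hits$snp_a == pp[2] & sc$hits$snp_b == pp[1]))
  expect_true(any(found))
  expect_true(all(sc$hits$p_exact < sc$threshold))
  expect_true(all(sc$hits$all_cells_present))
  # infinite filter: empty hit list
  sc_inf <- exhaustive_scan(sim$discovery, f_filter = Inf)
  expect_identical(nrow(sc_inf$hits), 0L)
  # scan output is invariant to SNP enumeration order
  perm <- sample(colnames(sim$discovery$genotypes))
  sc_p <- exhaustive_scan(sim$discovery, sim$replication, snp_ids = perm,
                          f_filter = "auto")
  key <- function(h) sort(paste(h$cpg_id, pmin(h$snp_a, h$snp_b),
                                pmax(h$snp_a, h$snp_b)))
  expect_identical(key(sc$hits), key(sc_p$hits))
})

test_that("the vectorized scan matches per-pair statistics with missing data", {
  cfg <- sim_config(n_discovery = 200, n_replication = 80, n_snps = 30,
                    n_cpgs = 4, n_chromosomes = 2, missing_rate = 0.02,
                    seed = 51)
  pp <- pick_planted_pair(cfg, maf_min = 0.35)
  effs <- list(planted_effect("cg00001", "epistatic", pp, 0.3),
               planted_effect("cg00003", "epistatic", pp, 0.25))
  sim <- simulate_cohorts(cfg, effs)
  M <- beta_to_m(sim$discovery$methylation_beta)
  sc <- exhaustive_scan(sim$discovery, f_filter = "auto")
  expect_gt(nrow(sc$hits), 0)
  for (k in seq_len(min(5, nrow(sc$hits)))) {
    h <- sc$hits[k, ]
    ex <- exact_interaction_anova(sim$discovery$genotypes[, h$snp_a],
                                  sim$discovery$genotypes[, h$snp_b],
                                  M[, h$cpg_id])
    expect_equal(h$F_exact, ex$F, tolerance = 1e-10)
    cs <- cell_summaries(sim$discovery$genotypes[, h$snp_a],
                         sim$discovery$genotypes[, h$snp_b], M[, h$cpg_id])
    ap <- approx_two_locus_test(cs)
    expect_equal(h$F4_approx, ap$F4_approx, tolerance = 1e-10)
    expect_equal(h$min_cell_discovery, min(cs$counts))
    # joint SS dominates interaction SS
    expect_gte(h$F8 * 8, h$F4_approx * 4 - 1e-9)
  }
})
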