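test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_discovery = 5), "cohort sizes")
  expect_error(sim_config(block_rho = 1), "block_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("genotype simulation is seed-reproducible and shares the SNP map", {
  cfg <- tiny_config(seed = 4)
  g1 <- simulate_genotypes(cfg, "discovery")
  g2 <- simulate_genotypes(cfg, "discovery")
  expect_identical(g1$genotypes, g2$genotypes)
  gr <- simulate_genotypes(cfg, "replication")
  expect_identical(g1$snp_map, gr$snp_map)
  expect_false(identical(dim(g1$genotypes), dim(gr$genotypes)))
  expect_true(all(g1$genotypes %in% c(0:2, NA)))
  o <- order(g1$snp_map$chrom, g1$snp_map$bp)
  expect_identical(o, seq_len(nrow(g1$snp_map)))
  expect_true(all(g1$snp_map$bp > 0))
})

test_that("block correlation controls adjacent-SNP LD", {
  cfg0 <- sim_config(n_discovery = 2000, n_replication = 100, n_snps = 60,
                     n_cpgs = 2, n_chromosomes = 1, block_rho = 0,
                     missing_rate = 0, seed = 2)
  g0 <- simulate_genotypes(cfg0, "discovery")
  adj0 <- vapply(seq_len(59), function(i)
    genotype_r2(g0$genotypes[, i], g0$genotypes[, i + 1]), 0)
  expect_lt(median(adj0), 0.01)
  cfgh <- sim_config(n_discovery = 2000, n_replication = 100, n_snps = 60,
                     n_cpgs = 2, n_chromosomes = 1, block_rho = 0.95,
                     maf_range = c(0.3, 0.30001),
                     block_len_range = c(5L, 10L), missing_rate = 0,
                     seed = 2)
  gh <- simulate_genotypes(cfgh, "discovery")
  same_block <- gh$snp_map$block[-60] == gh$snp_map$block[-1]
  adjh <- vapply(which(same_block), function(i)
    genotype_r2(gh$genotypes[, i], gh$genotypes[, i + 1]), 0)
  expect_gt(mean(adjh), 0.5)
})

test_that("methylation output is a valid beta matrix tied to the sample axis", {
  cfg <- tiny_config(seed = 9)
  sim <- simulate_cohorts(cfg)
  B <- sim$discovery$methylation_beta
  expect_true(all(B > 0 & B < 1))
  expect_identical(rownames(B), rownames(sim$discovery$genotypes))
  expect_identical(colnames(B), sim$discovery$cpg_map$cpg_id)
  sim2 <- simulate_cohorts(cfg)
  expect_identical(B, sim2$discovery$methylation_beta)
})

test_that("null cohorts show no SNP-CpG association beyond chance", {
  cfg <- tiny_config(seed = 14, missing_rate = 0)
  sim <- simulate_cohorts(cfg)
  M <- beta_to_m(sim$discovery$methylation_beta)
  r <- abs(cor(sim$discovery$genotypes, M))
  # Fisher bound for max |r| over 40 x 8 null correlations at n = 120
  expect_lt(max(r), tanh(qnorm(1 - 0.001 / (40 * 8)) / sqrt(117)))
})

test_that("orthogonalized deltas carry no weighted marginal means", {
  set.seed(5)
  for (i in 1:20) {
    d <- matrix(rnorm(9), 3, 3)
    fa <- epimeth:::.hwe_freqs(runif(1, 0.1, 0.5))
    fb <- epimeth:::.hwe_freqs(runif(1, 0.1, 0.5))
    od <- orthogonalize_delta(d, fa, fb)
    expect_lt(max(abs(od %*% fb)), 1e-12)
    expect_lt(max(abs(crossprod(od, fa))), 1e-12)
  }
})

test_that("planted epistasis induces no main effect (marginal-free)", {
  set.seed(3)
  d0 <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3)
  ps <- replicate(300, {
    n <- 1000
    ga <- rbinom(n, 2, 0.45); gb <- rbinom(n, 2, 0.45)
    d <- orthogonalize_delta(d0, epimeth:::.hwe_freqs(0.45),
                             epimeth:::.hwe_freqs(0.45))
    y <- 2 * d[cbind(ga + 1, gb + 1)] + rnorm(n)
    main_effect_p(ga, y)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted effect sizes are calibrated (realized tracks target)", {
  cfg <- sim_config(n_snps = 200, n_cpgs = 50, seed = 21)
  map <- epimeth:::.simulate_snp_map(cfg)
  set.seed(77)
  effs <- lapply(1:50, function(i) {
    tgt <- runif(1, 0.05, 0.4)
    kind <- sample(c("main_additive", "main_dominance", "epistatic"), 1)
    sn <- if (kind == "epistatic") sample(map$snp_id[map$maf > 0.3], 2)
          else sample(map$snp_id, 1)
    planted_effect(sprintf("cg%05d", i), kind, sn, tgt)
  })
  sim <- simulate_cohorts(cfg, effs)
  df <- as.data.frame(sim$truth)
  slope <- coef(lm(realized_r2 ~ target_r2, df))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
  big <- df$target_r2 >= 0.02
  expect_true(all(abs(df$realized_r2[big] - df$target_r2[big]) <=
                    0.5 * df$target_r2[big]))
})

test_that("excessive per-CpG variance targets are rejected", {
  cfg <- tiny_config(seed = 2)
  map <- epimeth:::.simulate_snp_map(cfg)
  effs <- list(planted_effect("cg00001", "main_additive", map$snp_id[1], 0.6),
               planted_effect("cg00001", "main_additive", map$snp_id[2], 0.5))
  expect_error(simulate_cohorts(cfg, effs), "sum to >= 1")
})

test_that("the LD-triad scenario reproduces its target LD and main effect", {
  sc <- make_ld_triad_scenario(533, 319, seed = 8)
  g <- sc$discovery$genotypes
  expect_lt(abs(genotype_r2(g[, "snpC"], g[, "snpA"]) - 0.55), 0.1)
  expect_lt(abs(genotype_r2(g[, "snpC"], g[, "snpB"]) - 0.25), 0.12)
  expect_lt(genotype_r2(g[, "snpA"], g[, "snpB"]), 0.12)
  y <- beta_to_m(sc$discovery$methylation_beta[, "cg_triad"])
  expect_lt(main_effect_p(g[, "snpC"], y), 1e-10)
  # the A x B interaction mimics C's main effect: nominally significant
  expect_lt(exact_interaction_anova(g[, "snpA"], g[, "snpB"], y)$p, 0.05)
  expect_identical(sc$truth$effects[[1]]$kind, "spurious_ld_triad")
})

test_that("simulated expression couples cis transcripts at the stated r2", {
  cfg <- tiny_config(seed = 6)
  sim <- simulate_cohorts(cfg)
  M <- beta_to_m(sim$discovery$methylation_beta)
  ex <- simulate_expression(M, sim$discovery$cpg_map, truth = NULL,
                            n_transcripts = 50, coupling_r2 = 0.3,
                            n_coupled = 5, seed = 3)
  tm <- ex$transcript_map
  coupled <- which(!is.na(tm$coupled_cpg))
  expect_length(coupled, 5L)
  for (i in coupled) {
    j <- match(tm$coupled_cpg[i], colnames(M))
    expect_gt(cor(ex$expression[, i], M[, j])^2, 0.1)
    ci <- match(tm$coupled_cpg[i], sim$discovery$cpg_map$cpg_id)
    expect_identical(tm$chrom[i], sim$discovery$cpg_map$chrom[ci])
    expect_lte(abs(tm$bp[i] - sim$discovery$cpg_map$bp[ci]), 5e5)
  }
  ex0 <- simulate_expression(M, sim$discovery$cpg_map, n_transcripts = 50,
                             coupling_r2 = 0, n_coupled = 5, seed = 3)
  r0 <- abs(cor(M, ex0$expression))
  expect_lt(max(r0), tanh(qnorm(1 - 0.001 / length(r0)) / sqrt(117)))
  expect_error(simulate_expression(M, sim$discovery$cpg_map,
                                   n_transcripts = 0), "n_transcripts")
})
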