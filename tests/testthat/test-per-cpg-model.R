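# Shared fixture: one planted main effect plus one independent epistatic
# pair, propagated through scan and replication.
model_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_snps = 60, n_cpgs = 6, n_chromosomes = 3,
                      seed = 71)
    map <- epimeth:::.simulate_snp_map(cfg)
    pp <- pick_planted_pair(cfg)
    # a main-effect SNP on the third chromosome, unlinked to the pair
    main_snp <- map$snp_id[map$chrom == 3 & map$maf > 0.2][1]
    effs <- list(planted_effect("cg00002", "epistatic", pp, 0.1),
                 planted_effect("cg00002", "main_additive", main_snp, 0.4))
    sim <- simulate_cohorts(cfg, effs)
    sc <- exhaustive_scan(sim$discovery, sim$replication,
                          f_filter = "auto")
    cache <<- list(cfg = cfg, sim = sim, sc = sc, pp = pp,
                   main_snp = main_snp)
    cache
  }
})

test_that("candidate assembly collects windows, LD partners and pairs", {
  fx <- model_fixture()
  hits <- fx$sc$hits[fx$sc$hits$cpg_id == "cg00002", ]
  expect_gt(nrow(hits), 0)
  cand <- assemble_candidates("cg00002", hits, fx$sim$discovery,
                              ld_threshold = 0.021)
  # the planted strong main effect is genome-wide significant -> candidate
  expect_true(fx$main_snp %in% cand$mains)
  # hit pairs are candidate pairs
  expect_true(any(cand$pairs[, 1] %in% c(fx$pp, hits$snp_a) |
                    cand$pairs[, 2] %in% c(fx$pp, hits$snp_b)))
  # LD partners of the interacting SNPs appear among candidate pairs
  hit_snps <- unique(c(hits$snp_a, hits$snp_b))
  expect_true(all(hit_snps %in% unique(c(cand$pairs))))
})

test_that("forward selection recovers planted terms and nothing else", {
  fx <- model_fixture()
  hits <- fx$sc$hits[fx$sc$hits$cpg_id == "cg00002", ]
  cand <- assemble_candidates("cg00002", hits, fx$sim$discovery, 0.021)
  fs <- forward_select("cg00002", cand$mains, cand$pairs,
                       fx$sim$discovery, fx$sim$replication)
  kept_mains <- fs$terms$snp_a[fs$terms$kind == "main"]
  kept_ints <- fs$terms[fs$terms$kind == "interaction", ]
  expect_true(fx$main_snp %in% kept_mains)
  expect_true(any((kept_ints$snp_a == fx$pp[1] &
                     kept_ints$snp_b == fx$pp[2]) |
                    (kept_ints$snp_a == fx$pp[2] &
                       kept_ints$snp_b == fx$pp[1])))
  # every kept term satisfies the dual-cohort threshold
  expect_true(all(fs$terms$p_discovery < fs$threshold))
  expect_true(all(fs$terms$p_replication < fs$threshold))
  expect_equal(fs$threshold,
               0.05 / (length(cand$mains) + nrow(cand$pairs)))
})

test_that("no candidates yields the intercept-only model", {
  fx <- model_fixture()
  fs <- forward_select("cg00001", character(), NULL, fx$sim$discovery,
                       fx$sim$replication)
  expect_identical(nrow(fs$terms), 0L)
})

test_that("null candidates are almost never kept (dual-cohort control)", {
  fx <- model_fixture()
  # cg00004 carries no planted effect; offer it unrelated candidates
  map <- fx$sim$discovery$snp_map
  cand_mains <- map$snp_id[seq(1, 60, by = 6)]
  fs <- forward_select("cg00004", cand_mains, NULL, fx$sim$discovery,
                       fx$sim$replication)
  expect_lte(nrow(fs$terms), 1L)
})

test_that("classification separates LD-block pairs from epistatic ones", {
  fx <- model_fixture()
  hits <- fx$sc$hits[fx$sc$hits$cpg_id == "cg00002", ]
  cand <- assemble_candidates("cg00002", hits, fx$sim$discovery, 0.021)
  fs <- forward_select("cg00002", cand$mains, cand$pairs,
                       fx$sim$discovery, fx$sim$replication)
  fs <- classify_pairs(fs, fx$sim$discovery, ld_threshold = 0.021)
  ints <- fs$terms[fs$terms$kind == "interaction", ]
  expect_true(all(!is.na(ints$ld_r2)))
  expect_identical(ints$ld_class,
                   ifelse(ints$ld_r2 > 0.021, "ld_block", "epistatic"))
  # the planted cross-chromosome pair must be epistatic and trans/cis-labeled
  planted <- which((ints$snp_a == fx$pp[1] & ints$snp_b == fx$pp[2]) |
                     (ints$snp_a == fx$pp[2] & ints$snp_b == fx$pp[1]))
  expect_identical(ints$ld_class[planted], "epistatic")
  expect_true(ints$cis_trans[planted] %in%
                c("both_trans", "one_cis", "both_cis"))
})

test_that("variance decomposition recovers planted components", {
  fx <- model_fixture()
  hits <- fx$sc$hits[fx$sc$hits$cpg_id == "cg00002", ]
  cand <- assemble_candidates("cg00002", hits, fx$sim$discovery, 0.021)
  fs <- forward_select("cg00002", cand$mains, cand$pairs,
                       fx$sim$discovery, fx$sim$replication)
  vd <- variance_decomposition(fs, fx$sim$discovery)
  truth <- as.data.frame(fx$sim$truth)
  main_truth <- truth$realized_r2[truth$kind == "main_additive"]
  int_truth <- truth$realized_r2[truth$kind == "epistatic"]
  expect_lt(abs(vd$all_mains - main_truth), 0.1)
  expect_lt(abs(vd$interaction_contribution - int_truth), 0.05)
  # nested models: components non-decreasing
  expect_lte(vd$most_significant_main, vd$all_mains + 1e-10)
  expect_lte(vd$all_mains, vd$all_mains_plus_interactions + 1e-10)
  # decomposition is reproducible from scratch
  vd2 <- variance_decomposition(fs, fx$sim$discovery)
  expect_equal(vd$all_mains_plus_interactions,
               vd2$all_mains_plus_interactions, tolerance = 1e-10)
})

test_that("the proximal chain finds a planted cis main effect and interaction", {
  cfg <- sim_config(n_snps = 80, n_cpgs = 4, n_chromosomes = 2, seed = 72)
  map <- epimeth:::.simulate_snp_map(cfg)
  cmap <- epimeth:::.simulate_cpg_map(cfg, map)
  cg <- cmap$cpg_id[1]
  # two high-MAF SNPs within the window around this CpG
  win <- map$snp_id[map$chrom == cmap$chrom[1] &
                      abs(map$bp - cmap$bp[1]) <= 3.5e6 & map$maf > 0.4]
  s1 <- win[1]; s2 <- win[length(win)]
  effs <- list(planted_effect(cg, "main_additive", s1, 0.2),
               planted_effect(cg, "main_additive", s2, 0.1),
               planted_effect(cg, "epistatic", c(s1, s2), 0.12))
  sim <- simulate_cohorts(cfg, effs)
  mains <- proximal_main_scan(cg, sim$discovery, sim$replication)
  expect_true(all(c(s1, s2) %in% mains$snp_id))
  pairs <- proximal_interaction_scan(cg, mains, sim$discovery,
                                     sim$replication)
  expect_true(any((pairs$snp_a == s1 & pairs$snp_b == s2) |
                    (pairs$snp_a == s2 & pairs$snp_b == s1)))
  px <- proximal_search(cg, sim$discovery, sim$replication)
  expect_true(any(px$model$terms$kind == "interaction"))
  # a null CpG on the same chromosome yields (almost) nothing
  mains_null <- proximal_main_scan(cmap$cpg_id[2], sim$discovery,
                                   sim$replication)
  expect_lte(nrow(mains_null), 1L)
  expect_error(proximal_interaction_scan(cg, mains[1, , drop = FALSE],
                                         sim$discovery, sim$replication),
               "at least two")
})

test_that("window containing one SNP uses the unadjusted alpha", {
  cfg <- sim_config(n_snps = 20, n_cpgs = 3, n_chromosomes = 2, seed = 73)
  sim <- simulate_cohorts(cfg)
  cg <- sim$discovery$cpg_map$cpg_id[1]
  # shrink the window until at most one SNP remains
  map <- sim$discovery$snp_map
  cpos <- sim$discovery$cpg_map$bp[1]
  dists <- sort(abs(map$bp[map$chrom == sim$discovery$cpg_map$chrom[1]] -
                      cpos))
  win <- mean(dists[1:2])
  res <- proximal_main_scan(cg, sim$discovery, sim$replication,
                            window_bp = win)
  expect_lte(attr(res, "n_tested_discovery"), 1L)
})
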