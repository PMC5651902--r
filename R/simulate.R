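#' Simulation configuration for paired cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults emulate
#' the study design the rest of the package is built for: a discovery cohort
#' of 533 subjects and a replication cohort of 319, genotyped at blockwise-LD
#' SNPs and assayed at CpGs whose methylation signal mixes genetic effects,
#' technical nuisance (plate/batch) and biological covariates (sex, age).
#'
#' @param n_discovery,n_replication Cohort sizes (subjects). Both must be at
#'   least 10.
#' @param n_snps,n_cpgs Numbers of SNPs and CpGs to simulate.
#' @param n_chromosomes Number of chromosomes the markers are spread over.
#' @param block_len_range Integer range (min, max) of SNPs per LD block;
#'   block lengths are drawn uniformly from this range.
#' @param block_rho Within-block AR(1) correlation of the latent Gaussian
#'   haplotype variables, in [0, 1).
#' @param maf_range Range of minor allele frequencies, within (0, 0.5].
#' @param plate_count Number of assay plates; samples are dealt to plates
#'   cyclically and plates are grouped pairwise into batches.
#' @param sex_fraction Expected fraction of female subjects.
#' @param age_range Age range in years (uniform integer draw).
#' @param noise_sd Residual standard deviation of the CpG signal on the
#'   M-value scale.
#' @param missing_rate Genotype missingness rate (missing completely at
#'   random).
#' @param plate_sd,batch_sd,sex_sd,age_sd Standard deviations of the per-CpG
#'   nuisance coefficients on the M-scale (plate/batch offsets, sex effect,
#'   per-year age slope).
#' @param seed Integer seed. The SNP/CpG maps are derived deterministically
#'   from it and are identical for both cohorts; cohort draws use derived
#'   streams so discovery and replication are independent.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_discovery = 533L, n_replication = 319L,
                       n_snps = 300L, n_cpgs = 50L, n_chromosomes = 4L,
                       block_len_range = c(2L, 10L), block_rho = 0.8,
                       maf_range = c(0.05, 0.5), plate_count = 4L,
                       sex_fraction = 0.5, age_range = c(18L, 35L),
                       noise_sd = 1, missing_rate = 0.002,
                       plate_sd = 0.3, batch_sd = 0.2, sex_sd = 0.2,
                       age_sd = 0.02, seed = 1L) {
  cfg <- list(n_discovery = as.integer(n_discovery),
              n_replication = as.integer(n_replication),
              n_snps = as.integer(n_snps), n_cpgs = as.integer(n_cpgs),
              n_chromosomes = as.integer(n_chromosomes),
              block_len_range = as.integer(block_len_range),
              block_rho = block_rho, maf_range = maf_range,
              plate_count = as.integer(plate_count),
              sex_fraction = sex_fraction, age_range = age_range,
              noise_sd = noise_sd, missing_rate = missing_rate,
              plate_sd = plate_sd, batch_sd = batch_sd, sex_sd = sex_sd,
              age_sd = age_sd, seed = as.integer(seed))
  if (cfg$n_discovery < 10L || cfg$n_replication < 10L)
    stop("cohort sizes must be >= 10")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("block_rho must lie in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$n_chromosomes < 1L || cfg$n_snps < 1L || cfg$n_cpgs < 1L)
    stop("n_chromosomes, n_snps and n_cpgs must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic SNP map shared by both cohorts: chromosome assignment,
# positions, per-SNP MAF and LD-block id. Uses its own RNG stream.
.simulate_snp_map <- function(config) {
  set.seed(config$seed)
  m <- config$n_snps
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  bp <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bp[idx] <- cumsum(sample(5000:30000, length(idx), replace = TRUE))
  }
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  # LD blocks: runs of consecutive SNPs, never crossing a chromosome
  block <- integer(m)
  b <- 0L
  i <- 1L
  while (i <= m) {
    b <- b + 1L
    len <- sample(config$block_len_range[1]:config$block_len_range[2], 1L)
    j <- min(i + len - 1L, m)
    j <- min(j, max(which(chrom == chrom[i])))
    block[i:j] <- b
    i <- j + 1L
  }
  data.frame(snp_id = sprintf("snp%05d", seq_len(m)), chrom = chrom,
             bp = bp, maf = maf, block = block,
             allele_ref = "A", allele_alt = "B",
             stringsAsFactors = FALSE)
}

.simulate_cpg_map <- function(config, snp_map) {
  set.seed(config$seed + 7L)
  k <- config$n_cpgs
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), k))
  bp <- integer(k)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    hi <- max(snp_map$bp[snp_map$chrom == ch])
    bp[idx] <- sort(sample(seq(1000L, hi + 10000L), length(idx)))
  }
  data.frame(cpg_id = sprintf("cg%05d", seq_len(k)), chrom = chrom, bp = bp,
             stringsAsFactors = FALSE)
}

.role_offset <- function(role) switch(role, discovery = 101L,
                                      replication = 202L,
                                      stop("unknown role: ", role))

#' Simulate blockwise-LD genotypes for one cohort
#'
#' Genotypes are generated per haplotype by thresholding latent Gaussian
#' variables with AR(1) correlation `block_rho` inside each LD block at the
#' quantile implied by the SNP's minor allele frequency; the two haplotypes
#' are summed to a 0/1/2 minor-allele dosage. Both cohorts share the same SNP
#' map and MAFs but use independent draws. Missing genotypes are injected
#' completely at random at `config$missing_rate`.
#'
#' @param config A [sim_config()] object.
#' @param role `"discovery"` or `"replication"`.
#' @return A list with `genotypes` (samples x SNPs integer matrix, `NA` for
#'   missing) and `snp_map` (data frame sorted by chromosome and position).
#' @export
simulate_genotypes <- function(config, role = c("discovery", "replication")) {
  role <- match.arg(role)
  stopifnot(inherits(config, "sim_config"))
  snp_map <- .simulate_snp_map(config)
  n <- if (role == "discovery") config$n_discovery else config$n_replication
  set.seed(config$seed + .role_offset(role))
  m <- config$n_snps
  G <- matrix(0L, n, m)
  thr <- qnorm(snp_map$maf)
  for (blk in split(seq_len(m), snp_map$block)) {
    L <- length(blk)
    for (h in 1:2) {
      Z <- matrix(rnorm(n * L), n, L)
      if (L > 1 && config$block_rho > 0) {
        w <- sqrt(1 - config$block_rho^2)
        for (l in 2:L) Z[, l] <- config$block_rho * Z[, l - 1] + w * Z[, l]
      }
      G[, blk] <- G[, blk] + (Z < rep(thr[blk], each = n))
    }
  }
  storage.mode(G) <- "integer"
  if (config$missing_rate > 0) {
    nmiss <- rbinom(1L, n * m, config$missing_rate)
    if (nmiss > 0) G[sample(n * m, nmiss)] <- NA_integer_
  }
  dimnames(G) <- list(sprintf("%s%04d", substr(role, 1, 1), seq_len(n)),
                      snp_map$snp_id)
  list(genotypes = G, snp_map = snp_map)
}

#' Simulate per-sample covariates for one cohort
#'
#' @inheritParams simulate_genotypes
#' @return Data frame with `sample_id`, `sex` (0/1), `age` (years), `plate`
#'   and `batch` (plates grouped pairwise).
#' @export
simulate_covariates <- function(config, role = c("discovery", "replication")) {
  role <- match.arg(role)
  n <- if (role == "discovery") config$n_discovery else config$n_replication
  set.seed(config$seed + .role_offset(role) + 13L)
  plate <- rep_len(seq_len(config$plate_count), n)
  data.frame(sample_id = sprintf("%s%04d", substr(role, 1, 1), seq_len(n)),
             sex = rbinom(n, 1L, config$sex_fraction),
             age = sample(config$age_range[1]:config$age_range[2], n, TRUE),
             plate = plate,
             batch = (plate + 1L) %/% 2L,
             stringsAsFactors = FALSE)
}

#' Describe a planted genetic effect on one CpG
#'
#' @param cpg_id Target CpG identifier.
#' @param kind One of `"main_additive"`, `"main_dominance"`, `"epistatic"`,
#'   `"spurious_ld_triad"`, `"probe_artifact"`.
#' @param snp_ids One to three SNP identifiers (two for `epistatic`).
#' @param target_r2 Intended fraction of CpG signal variance, in [0, 1).
#' @param delta Optional 3x3 deviation matrix (M-value units) for epistatic
#'   effects; it is re-orthogonalized against the marginal genotype
#'   frequencies before use so that the planted pattern carries no main
#'   effect. The default concentrates the deviation on the double
#'   rare-homozygote cell, the canonical two-locus epistasis architecture
#'   in which a phenotypic shift appears only when both loci carry two
#'   minor alleles.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(cpg_id, kind, snp_ids, target_r2, delta = NULL) {
  kind <- match.arg(kind, c("main_additive", "main_dominance", "epistatic",
                            "spurious_ld_triad", "probe_artifact"))
  if (target_r2 < 0 || target_r2 >= 1) stop("target_r2 must lie in [0, 1)")
  if (kind == "epistatic" && length(snp_ids) != 2L)
    stop("epistatic effects need exactly two SNPs")
  if (kind == "epistatic" && is.null(delta))
    delta <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 1), 3, 3)
  structure(list(cpg_id = cpg_id, kind = kind, snp_ids = snp_ids,
                 target_r2 = target_r2, delta = delta),
            class = "planted_effect")
}

#' Orthogonalize a 3x3 interaction pattern against genotype margins
#'
#' Removes the frequency-weighted row and column means of `delta` so that,
#' under the given expected genotype frequencies, the pattern induces no
#' additive or dominance main effect at either locus -- the planted signal is
#' interaction-only, exactly the quantity a 4-df deviation test targets.
#'
#' @param delta 3x3 numeric matrix (rows: genotype 0/1/2 of SNP a).
#' @param freq_a,freq_b Expected genotype frequencies (length-3, summing
#'   to 1) of the two SNPs.
#' @return The orthogonalized 3x3 matrix.
#' @export
orthogonalize_delta <- function(delta, freq_a, freq_b) {
  stopifnot(length(freq_a) == 3L, length(freq_b) == 3L)
  freq_a <- freq_a / sum(freq_a)
  freq_b <- freq_b / sum(freq_b)
  r <- as.vector(delta %*% freq_b)          # weighted row means
  cm <- as.vector(crossprod(delta, freq_a)) # weighted column means
  g <- sum(freq_a * r)
  sweep(sweep(delta, 1, r), 2, cm) + g
}

.hwe_freqs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# Evaluate a planted effect as a per-sample M-scale term (unscaled).
# Missing genotypes contribute the term's mean (i.e. no signal).
.effect_term <- function(effect, genotypes, snp_map) {
  ids <- effect$snp_ids
  if (!all(ids[seq_len(min(2, length(ids)))] %in% colnames(genotypes)))
    stop("planted effect references unknown SNP(s): ",
         paste(setdiff(ids, colnames(genotypes)), collapse = ", "))
  g1 <- genotypes[, ids[1]]
  term <- switch(effect$kind,
    main_additive = ,
    spurious_ld_triad = as.numeric(g1),
    main_dominance = as.numeric(g1 == 1L),
    epistatic = {
      g2 <- genotypes[, ids[2]]
      maf1 <- snp_map$maf[match(ids[1], snp_map$snp_id)]
      maf2 <- snp_map$maf[match(ids[2], snp_map$snp_id)]
      d <- orthogonalize_delta(effect$delta, .hwe_freqs(maf1),
                               .hwe_freqs(maf2))
      d[cbind(g1 + 1L, g2 + 1L)]
    },
    probe_artifact = NULL)
  if (!is.null(term)) {
    mu <- mean(term, na.rm = TRUE)
    term[is.na(term)] <- mu
    term <- term - mu
  }
  term
}

#' Simulate methylation signals with planted genetic effects
#'
#' Builds each CpG signal on the M-value scale as the sum of planted genetic
#' terms, covariate/nuisance terms (plate and batch offsets, sex, age) and
#' Gaussian noise, then maps it to a beta-value via the inverse M-transform.
#' Planted terms are rescaled so that their realized variance fraction in the
#' generated data tracks `target_r2`; the achieved fractions are measured on
#' the discovery-scale data and returned in a truth registry.
#'
#' @param genotypes Samples x SNPs dosage matrix (from
#'   [simulate_genotypes()]).
#' @param snp_map SNP map matching `genotypes`.
#' @param cpg_map CpG map (one row per simulated CpG).
#' @param effects List of [planted_effect()] objects. Per-CpG target
#'   fractions must sum to < 1.
#' @param covariates Covariate data frame from [simulate_covariates()].
#' @param config The [sim_config()].
#' @param role Cohort role; drives the RNG stream for noise and nuisance.
#' @return List with `methylation_beta` (samples x CpGs, strictly inside
#'   (0,1)), `truth` (a `truth_registry`), and `probe_dosages` (named list of
#'   per-CpG dosage matrices for planted probe artifacts).
#' @export
simulate_methylation <- function(genotypes, snp_map, cpg_map, effects = list(),
                                 covariates, config,
                                 role = c("discovery", "replication")) {
  role <- match.arg(role)
  n <- nrow(genotypes)
  k <- nrow(cpg_map)
  targets <- vapply(effects, function(e) e$target_r2, 0)
  for (cg in unique(vapply(effects, function(e) e$cpg_id, ""))) {
    if (sum(targets[vapply(effects, function(e) e$cpg_id, "") == cg]) >= 1)
      stop("target_r2 values for ", cg, " sum to >= 1")
  }
  # Per-CpG nuisance coefficients are map-level properties: derive them from
  # the base seed so both cohorts share the same biology.
  set.seed(config$seed + 31L)
  base_mu <- runif(k, -2.5, 2.5)
  sex_coef <- rnorm(k, 0, config$sex_sd)
  age_coef <- rnorm(k, 0, config$age_sd)
  plate_off <- matrix(rnorm(config$plate_count * k, 0, config$plate_sd),
                      config$plate_count, k)
  nb <- max(1L, (config$plate_count + 1L) %/% 2L)
  batch_off <- matrix(rnorm(nb * k, 0, config$batch_sd), nb, k)

  set.seed(config$seed + .role_offset(role) + 57L)
  M <- matrix(rnorm(n * k, 0, config$noise_sd), n, k)
  M <- M + rep(base_mu, each = n)
  M <- M + outer(covariates$sex - mean(covariates$sex), sex_coef)
  M <- M + outer(covariates$age - mean(covariates$age), age_coef)
  M <- M + plate_off[covariates$plate, , drop = FALSE]
  M <- M + batch_off[covariates$batch, , drop = FALSE]
  colnames(M) <- cpg_map$cpg_id
  rownames(M) <- rownames(genotypes)

  probe_dosages <- list()
  realized <- rep(NA_real_, length(effects))
  scaled_terms <- vector("list", length(effects))
  if (length(effects)) {
    cpg_of <- vapply(effects, function(e) e$cpg_id, "")
    for (cg in unique(cpg_of)) {
      jj <- match(cg, cpg_map$cpg_id)
      if (is.na(jj)) stop("planted effect on unknown CpG: ", cg)
      idx <- which(cpg_of == cg)
      base_var <- var(M[, jj])  # nuisance + noise variance before planting
      tsum <- sum(targets[idx])
      for (i in idx) {
        e <- effects[[i]]
        if (e$kind == "probe_artifact") {
          set.seed(config$seed + .role_offset(role) + 400L + i)
          maf <- runif(1, 0.1, 0.4)
          d <- rbinom(n, 2L, maf) + runif(n, -0.1, 0.1)
          d <- pmin(pmax(d, 0), 2)
          probe_dosages[[cg]] <- cbind(probe_dosages[[cg]],
                                       setNames(data.frame(d), "probe_var1"))
          term <- d - mean(d)
        } else {
          term <- .effect_term(e, genotypes, snp_map)
        }
        vt <- var(term)
        if (vt <= 0) stop("planted term for ", cg, " has zero variance")
        sc <- sqrt((e$target_r2 / (1 - tsum)) * base_var / vt)
        term <- term * sc
        M[, jj] <- M[, jj] + term
        scaled_terms[[i]] <- term
      }
      for (i in idx) {
        fit_r2 <- function(t) {
          ss <- sum((t - mean(t)) * M[, jj])^2 / sum((t - mean(t))^2)
          ss / sum((M[, jj] - mean(M[, jj]))^2)
        }
        realized[i] <- fit_r2(scaled_terms[[i]])
      }
    }
    probe_dosages <- lapply(probe_dosages, as.matrix)
  }

  beta <- m_to_beta(M)
  truth <- structure(list(effects = effects, realized_r2 = realized,
                          role = role),
                     class = "truth_registry")
  list(methylation_beta = beta, truth = truth, probe_dosages = probe_dosages)
}

#' Assemble one simulated cohort
#'
#' @inheritParams simulate_methylation
#' @return An object of class `cohort`: role, genotypes, snp_map,
#'   methylation_beta, cpg_map, covariates, probe_dosages, truth.
#' @export
simulate_cohort <- function(config, role = c("discovery", "replication"),
                            effects = list()) {
  role <- match.arg(role)
  geno <- simulate_genotypes(config, role)
  cpg_map <- .simulate_cpg_map(config, geno$snp_map)
  cov <- simulate_covariates(config, role)
  meth <- simulate_methylation(geno$genotypes, geno$snp_map, cpg_map, effects,
                               cov, config, role)
  structure(list(role = role, genotypes = geno$genotypes,
                 snp_map = geno$snp_map,
                 methylation_beta = meth$methylation_beta, cpg_map = cpg_map,
                 covariates = cov, probe_dosages = meth$probe_dosages,
                 truth = meth$truth),
            class = "cohort")
}

#' Simulate a paired discovery/replication cohort set
#'
#' Both cohorts share the SNP map, CpG map, MAFs and planted-effect
#' coefficients; subject-level draws are independent.
#'
#' @inheritParams simulate_cohort
#' @return List with elements `discovery`, `replication` (class `cohort`) and
#'   `truth` (the discovery-side `truth_registry`, whose `realized_r2` is
#'   measured in the generated discovery cohort).
#' @export
simulate_cohorts <- function(config, effects = list()) {
  disc <- simulate_cohort(config, "discovery", effects)
  repl <- simulate_cohort(config, "replication", effects)
  list(discovery = disc, replication = repl, truth = disc$truth)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort role=%s: %d samples, %d SNPs, %d CpGs>\n", x$role,
              nrow(x$genotypes), ncol(x$genotypes),
              ncol(x$methylation_beta)))
  invisible(x)
}

#' @export
print.truth_registry <- function(x, ...) {
  cat(sprintf("<truth_registry: %d planted effects (%s cohort)>\n",
              length(x$effects), x$role))
  if (length(x$effects)) print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.truth_registry <- function(x, ...) {
  if (!length(x$effects))
    return(data.frame(cpg_id = character(), kind = character(),
                      snp_ids = character(), target_r2 = numeric(),
                      realized_r2 = numeric()))
  data.frame(cpg_id = vapply(x$effects, function(e) e$cpg_id, ""),
             kind = vapply(x$effects, function(e) e$kind, ""),
             snp_ids = vapply(x$effects,
                              function(e) paste(e$snp_ids, collapse = ";"),
                              ""),
             target_r2 = vapply(x$effects, function(e) e$target_r2, 0),
             realized_r2 = x$realized_r2,
             stringsAsFactors = FALSE)
}
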