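#' Methylation preprocessing configuration
#'
#' @param n_pcs_discovery,n_pcs_replication Number of principal-component
#'   axes regressed out of the M-value matrix in each cohort (defaults 8
#'   and 7).
#' @param probe_r2_min Variance fraction above which a CpG signal is
#'   residualized on the dosages of variants inside its 50-mer probe
#'   sequence (strictly greater than; default 0.001, i.e. 0.1 percent).
#' @param dosage_maf_min Minimum MAF of a probe-sequence variant dosage for
#'   it to enter the correction model (default 0.0003, i.e. 0.03 percent).
#' @param cpg_miss_max Maximum per-CpG missing rate (exclusive).
#' @param exclusion_list CpG ids excluded a priori (e.g. cross-hybridizing
#'   probes, polymorphic CpG sites).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(n_pcs_discovery = 8L, n_pcs_replication = 7L,
                              probe_r2_min = 0.001,
                              dosage_maf_min = 0.0003, cpg_miss_max = 0.01,
                              exclusion_list = character()) {
  cfg <- list(n_pcs_discovery = as.integer(n_pcs_discovery),
              n_pcs_replication = as.integer(n_pcs_replication),
              probe_r2_min = probe_r2_min, dosage_maf_min = dosage_maf_min,
              cpg_miss_max = cpg_miss_max, exclusion_list = exclusion_list)
  stopifnot(cfg$n_pcs_discovery >= 0L, cfg$n_pcs_replication >= 0L,
            cfg$probe_r2_min >= 0, cfg$probe_r2_min < 1,
            cfg$dosage_maf_min >= 0, cfg$dosage_maf_min < 1,
            cfg$cpg_miss_max >= 0, cfg$cpg_miss_max < 1)
  class(cfg) <- "preprocess_config"
  cfg
}

#' Beta-value to M-value transform
#'
#' `M = log2(beta / (1 - beta))`, the standard logit (base 2) analysis scale
#' for methylation fractions.
#'
#' @param beta Numeric vector or matrix with values strictly inside (0, 1);
#'   `NA` entries pass through.
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta-values must lie strictly inside (0, 1)")
  log2(beta / (1 - beta))
}

#' Inverse M-transform (M-value to beta-value)
#'
#' Beta-values are clipped to `[1e-6, 1 - 1e-6]` so the forward transform
#' stays finite.
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values of the same shape.
#' @export
m_to_beta <- function(m) {
  b <- 2^m / (1 + 2^m)
  b[!is.na(b) & b < 1e-6] <- 1e-6
  b[!is.na(b) & b > 1 - 1e-6] <- 1 - 1e-6
  b
}

#' Z-transform each CpG within each plate
#'
#' Centers and scales every CpG column to zero mean and unit variance within
#' each plate, removing plate and batch offsets. Missing entries are
#' ignored. Columns with zero variance inside a plate are set to 0 there and
#' flagged in the `"zero_variance"` attribute.
#'
#' @param M Samples x CpGs M-value matrix.
#' @param plates Plate label per sample (each plate needs >= 2 samples).
#' @return The transformed matrix.
#' @export
zscore_by_plate <- function(M, plates) {
  stopifnot(length(plates) == nrow(M))
  if (any(table(plates) < 2L)) stop("each plate needs at least 2 samples")
  flagged <- character()
  for (pl in unique(plates)) {
    rows <- which(plates == pl)
    sub <- M[rows, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    s <- apply(sub, 2, sd, na.rm = TRUE)
    zero <- !is.na(s) & s == 0
    s[zero | is.na(s)] <- 1
    M[rows, ] <- sweep(sweep(sub, 2, mu), 2, s, "/")
    if (any(zero)) {
      M[rows, zero] <- 0
      flagged <- union(flagged, colnames(M)[zero])
    }
  }
  attr(M, "zero_variance") <- flagged
  M
}

.mean_impute <- function(M) {
  na <- is.na(M)
  if (any(na)) {
    mu <- colMeans(M, na.rm = TRUE)
    M[na] <- rep(mu, each = nrow(M))[na]
  }
  list(M = M, na = na)
}

.residualize <- function(M, X) {
  imp <- .mean_impute(M)
  R <- qr.resid(qr(X), imp$M)
  R[imp$na] <- NA
  R
}

#' Regress principal-component axes out of the methylation matrix
#'
#' The top `k` principal components are computed from the CpG columns with
#' no missing values; the resulting per-sample scores are regressed out of
#' every column. Columns with missing entries are mean-imputed for the
#' regression and re-masked afterwards. `k = 0` returns the input unchanged.
#'
#' @param M Samples x CpGs M-value matrix.
#' @param k Number of components to remove.
#' @return The residualized matrix, with the removed scores in the
#'   `"scores"` attribute.
#' @export
pca_residualize <- function(M, k) {
  stopifnot(k >= 0)
  if (k == 0) return(M)
  complete <- which(colSums(is.na(M)) == 0L)
  if (length(complete) < k)
    stop("fewer complete CpG columns (", length(complete),
         ") than requested components (", k, ")")
  pr <- prcomp(M[, complete, drop = FALSE], center = TRUE, scale. = FALSE)
  if (ncol(pr$x) < k) stop("requested components exceed available rank")
  scores <- pr$x[, seq_len(k), drop = FALSE]
  R <- .residualize(M, cbind(1, scores))
  attr(R, "scores") <- scores
  R
}

#' Regress sex and age out of every CpG column
#'
#' Per-CpG least-squares residuals from intercept + sex + age. A constant
#' covariate is dropped from the design with a message. When `extra` is
#' supplied (e.g. the principal-component scores removed in the previous
#' step), the projection is joint, which keeps the residuals orthogonal to
#' both covariate sets and makes the adjustment chain idempotent.
#'
#' @param M Samples x CpGs M-value matrix.
#' @param sex,age Complete covariate vectors.
#' @param extra Optional additional design columns for a joint projection.
#' @return The residualized matrix.
#' @export
regress_out_covariates <- function(M, sex, age, extra = NULL) {
  stopifnot(!anyNA(sex), !anyNA(age), length(sex) == nrow(M),
            length(age) == nrow(M))
  X <- cbind(intercept = 1, sex = sex, age = age)
  const <- apply(X[, -1, drop = FALSE], 2, function(x) var(x) == 0)
  if (any(const)) {
    message("dropping constant covariate(s): ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  if (!is.null(extra)) X <- cbind(X, extra)
  .residualize(M, X)
}

#' Correct one CpG signal for variants in its 50-mer probe sequence
#'
#' The CpG signal is regressed jointly on the dosages of the variants lying
#' inside the probe sequence (after dropping dosage columns with MAF below
#' `dosage_maf_min`). If the model explains strictly more than `probe_r2_min`
#' of the signal variance, the residuals replace the signal; otherwise the
#' input is returned unchanged. Applied independently per cohort.
#'
#' @param m CpG signal vector (M scale).
#' @param dosages Matrix of per-sample variant dosages in [0, 2], or `NULL`.
#' @param probe_r2_min,dosage_maf_min See [preprocess_config()].
#' @return List with `signal`, `corrected` flag and the model `r2`.
#' @export
probe_variant_correction <- function(m, dosages, probe_r2_min = 0.001,
                                     dosage_maf_min = 0.0003) {
  if (is.null(dosages) || ncol(as.matrix(dosages)) == 0L)
    return(list(signal = m, corrected = FALSE, r2 = 0))
  D <- as.matrix(dosages)
  if (any(D < 0 | D > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  maf <- pmin(colMeans(D, na.rm = TRUE) / 2,
              1 - colMeans(D, na.rm = TRUE) / 2)
  D <- D[, maf >= dosage_maf_min, drop = FALSE]
  if (ncol(D) == 0L) return(list(signal = m, corrected = FALSE, r2 = 0))
  fit <- lm(m ~ D)
  r2 <- summary(fit)$r.squared
  if (r2 > probe_r2_min)
    list(signal = as.numeric(residuals(fit)), corrected = TRUE, r2 = r2)
  else
    list(signal = m, corrected = FALSE, r2 = r2)
}

#' Filter CpGs on missingness and the exclusion list, in both cohorts
#'
#' @param discovery,replication `cohort` objects (or beta matrices) sharing
#'   a CpG map.
#' @param config A [preprocess_config()].
#' @return Character vector of kept CpG ids.
#' @export
filter_cpgs <- function(discovery, replication,
                        config = preprocess_config()) {
  Bd <- if (inherits(discovery, "cohort")) discovery$methylation_beta
        else discovery
  Br <- if (inherits(replication, "cohort")) replication$methylation_beta
        else replication
  stopifnot(identical(colnames(Bd), colnames(Br)))
  miss_d <- colMeans(is.na(Bd))
  miss_r <- colMeans(is.na(Br))
  keep <- miss_d < config$cpg_miss_max & miss_r < config$cpg_miss_max &
    !(colnames(Bd) %in% config$exclusion_list)
  colnames(Bd)[keep]
}

#' Run the full methylation preprocessing chain on one cohort
#'
#' Applies, in order: (1) the M-transform, (2) per-plate z-scoring,
#' (3) removal of the top principal-component axes, (4) regression on sex
#' and age, and (5) the 50-mer probe-variant correction for CpGs with
#' planted probe dosages. Returns the adjusted M-scale signal used by all
#' association stages.
#'
#' @param cohort A `cohort` object.
#' @param config A [preprocess_config()].
#' @return List with `M` (adjusted samples x CpGs matrix) and
#'   `correction_log` (per-CpG probe-correction flag and r2).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  stopifnot(inherits(cohort, "cohort"))
  k <- if (cohort$role == "discovery") config$n_pcs_discovery
       else config$n_pcs_replication
  M <- beta_to_m(cohort$methylation_beta)
  M <- zscore_by_plate(M, cohort$covariates$plate)
  k <- min(k, max(0L, sum(colSums(is.na(M)) == 0L) - 1L))
  M <- pca_residualize(M, k)
  M <- regress_out_covariates(M, cohort$covariates$sex,
                              cohort$covariates$age,
                              extra = attr(M, "scores"))
  log_rows <- list()
  for (cg in names(cohort$probe_dosages)) {
    if (!cg %in% colnames(M)) next
    res <- probe_variant_correction(M[, cg], cohort$probe_dosages[[cg]],
                                    config$probe_r2_min,
                                    config$dosage_maf_min)
    M[, cg] <- res$signal
    log_rows[[cg]] <- data.frame(cpg_id = cg, corrected = res$corrected,
                                 r2 = res$r2, stringsAsFactors = FALSE)
  }
  list(M = M,
       correction_log = if (length(log_rows)) do.call(rbind, log_rows)
                        else data.frame(cpg_id = character(),
                                        corrected = logical(),
                                        r2 = numeric()))
}
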