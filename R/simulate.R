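#' Specify a synthetic control cohort
#'
#' Defines the generative model for a synthetic regional-uptake cohort:
#' per-region SUVr means and standard deviations, a block-structured
#' region-by-region correlation matrix, and linear age/sex covariate
#' effects. Subjects are drawn from a multivariate normal around the
#' covariate-adjusted regional means.
#'
#' The default emulates an FDOPA-like 83-region parcellation: a densely
#' inter-correlated subcortical/monoaminergic core (regions 1-40, with a
#' tighter striatal sub-block in regions 1-12), three cortical lobe blocks,
#' homologous left/right region pairs with very high correlation, and a
#' positive background correlation everywhere (regional SUVr shares the
#' reference-region scaling, so no region pair is truly independent).
#' Striatal-like regions default to mean 2.5 SUVr, the rest to 1.2.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_regions Number of regions (default 83).
#' @param block_structure List of `list(regions = <integer indices>,
#'   rho = <correlation>)` entries, applied in order on top of the
#'   background correlation (later entries overwrite earlier ones).
#'   `NULL` uses the packaged default structure (83 regions only).
#' @param between_block_correlation Background correlation for region pairs
#'   not covered by any block.
#' @param region_means,region_sds Per-region SUVr means and standard
#'   deviations (recycled if scalar). Defaults: means 2.5 for the striatal
#'   block, 1.2 elsewhere; sds 0.25 and 0.15.
#' @param age_slope Additive SUVr change per year of age (per region,
#'   recycled). Default -0.004 (mild age-related decline).
#' @param sex_offset Additive SUVr offset for male subjects (sex coded
#'   0 = female, 1 = male). Default 0.05.
#' @param age_range Length-2 numeric; ages drawn uniformly over it.
#' @param sex_ratio Fraction of male subjects.
#' @param seed Integer seed making the cohort draw reproducible.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [simulate_patients()]
#' @export
cohort_spec <- function(n_subjects,
                        n_regions = 83,
                        block_structure = NULL,
                        between_block_correlation = 0.2,
                        region_means = NULL,
                        region_sds = NULL,
                        age_slope = -0.004,
                        sex_offset = 0.05,
                        age_range = c(20, 65),
                        sex_ratio = 0.5,
                        seed = NULL) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (is.null(block_structure)) {
    if (n_regions == 83) {
      block_structure <- default_block_structure()
    } else {
      block_structure <- list()
    }
  }
  for (b in block_structure) {
    if (!all(b$regions >= 1 & b$regions <= n_regions))
      stop("block region indices out of range")
    if (abs(b$rho) > 1) stop("block correlations must lie in [-1, 1]")
  }
  if (abs(between_block_correlation) > 1)
    stop("between_block_correlation must lie in [-1, 1]")
  striatal <- if (n_regions == 83) 1:12 else seq_len(min(4, n_regions))
  if (is.null(region_means)) {
    region_means <- rep(1.2, n_regions)
    region_means[striatal] <- 2.5
  }
  if (is.null(region_sds)) {
    region_sds <- rep(0.15, n_regions)
    region_sds[striatal] <- 0.25
  }
  region_means <- rep_len(region_means, n_regions)
  region_sds <- rep_len(region_sds, n_regions)
  if (any(region_sds <= 0)) stop("region_sds must be positive")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must lie in [0, 1]")
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    n_regions = as.integer(n_regions),
    block_structure = block_structure,
    between_block_correlation = between_block_correlation,
    region_means = region_means,
    region_sds = region_sds,
    age_slope = rep_len(age_slope, n_regions),
    sex_offset = rep_len(sex_offset, n_regions),
    age_range = age_range,
    sex_ratio = sex_ratio,
    seed = seed
  ), class = "cohort_spec")
  # build (and if necessary repair) the target correlation now so an
  # invalid structure fails at spec time, not at draw time
  spec$correlation <- target_correlation(spec)
  spec
}

#' Default 83-region block structure
#'
#' The correlation overlay used by [cohort_spec()] for 83 regions:
#' subcortical core (1-40) at 0.75, striatal sub-block (1-12) at 0.85,
#' cortical lobe blocks at 0.4-0.5, homologous left/right pairs
#' (consecutive odd/even indices) at 0.9.
#'
#' @return List of blocks as documented in [cohort_spec()].
#' @export
default_block_structure <- function() {
  blocks <- list(
    list(regions = 1:40, rho = 0.75),
    list(regions = 1:12, rho = 0.85),
    list(regions = 41:54, rho = 0.45),
    list(regions = 55:68, rho = 0.40),
    list(regions = 69:82, rho = 0.50)
  )
  for (k in seq(1, 81, by = 2)) {
    blocks[[length(blocks) + 1]] <- list(regions = c(k, k + 1), rho = 0.9)
  }
  blocks
}

# Target correlation matrix implied by a cohort_spec, repaired to the
# nearest positive semi-definite matrix by eigenvalue clipping when needed
# (attribute "repaired" records that this happened).
target_correlation <- function(spec) {
  m <- spec$n_regions
  R <- matrix(spec$between_block_correlation, m, m)
  for (b in spec$block_structure) {
    R[b$regions, b$regions] <- b$rho
  }
  diag(R) <- 1
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(d)
    diag(R) <- 1
    repaired <- TRUE
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("correlation structure is not positive semi-definite even after repair")
    warning("target correlation matrix was not positive semi-definite; ",
            "repaired by eigenvalue clipping")
  }
  attr(R, "repaired") <- repaired
  R
}

# Covariance Cholesky factor for a spec (upper triangular, for X %*% L).
cohort_chol <- function(spec) {
  S <- spec$correlation * tcrossprod(spec$region_sds)
  chol(S + diag(1e-12, nrow(S)))
}

# Draw covariates for n subjects (assumes RNG already seeded).
draw_covariates <- function(spec, n, prefix) {
  data.frame(
    subject_id = sprintf("%s%03d", prefix, seq_len(n)),
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sex = rbinom(n, 1, spec$sex_ratio),
    stringsAsFactors = FALSE
  )
}

# Deterministic mean surface for given covariates.
mean_surface <- function(spec, cov) {
  n <- nrow(cov)
  mid_age <- mean(spec$age_range)
  matrix(spec$region_means, n, spec$n_regions, byrow = TRUE) +
    outer(cov$age - mid_age, spec$age_slope) +
    outer(cov$sex, spec$sex_offset)
}

#' Simulate a control cohort
#'
#' Draws `spec$n_subjects` subjects from the cohort's generative model:
#' region means plus linear age and sex effects plus correlated Gaussian
#' noise with the spec's block-structured covariance. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param prefix Subject-id prefix (default "C").
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list with `uptake` (numeric matrix, subjects x regions, with
#'   subject-id rownames and region-label colnames) and `covariates`
#'   (data.frame with subject_id, age, sex).
#' @examples
#' hc <- simulate_cohort(cohort_spec(20, n_regions = 6, seed = 1))
#' dim(hc$uptake)
#' @export
simulate_cohort <- function(spec, prefix = "C", seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- if (is.null(seed)) spec$seed else seed
  with_seed(seed, {
    cov <- draw_covariates(spec, spec$n_subjects, prefix)
    L <- cohort_chol(spec)
    noise <- matrix(rnorm(spec$n_subjects * spec$n_regions),
                    spec$n_subjects, spec$n_regions) %*% L
    values <- mean_surface(spec, cov) + noise
    rownames(values) <- cov$subject_id
    colnames(values) <- default_region_labels(spec$n_regions)
    list(uptake = values, covariates = cov)
  })
}

#' Specify a patient-group network perturbation
#'
#' Patients are drawn from the control cohort's distribution and then
#' displaced in regional-uptake space so that, when each patient perturbs
#' the reference network, the affected block's edges deviate in a
#' controlled direction.
#'
#' With `mode = "axis_shift"` (default) the displacement lies along an
#' eigenvector of the affected block's covariance: the leading axis for
#' `direction = "strengthen"` (a subject displaced along the dominant
#' covariance pattern reinforces the block's correlations, giving positive
#' deviation z-scores) and the trailing (minor) axis for `"weaken"` (a
#' displacement that contradicts the covariance pattern drags the block's
#' correlations down, giving negative z-scores). The displacement length is
#' `magnitude` times the mean regional SD of the affected block. Note that
#' reversing the sign of a leading-axis shift does not weaken correlations
#' (edge perturbations are even in the displacement), which is why the
#' weakening displacement uses the minor axis.
#'
#' With `mode = "rescale"` the patients are drawn from a modified
#' distribution in which the affected block's within-block correlations are
#' moved towards 0.97 (strengthen) or towards 0 (weaken) by the fraction
#' `min(magnitude, 1)`.
#'
#' @param affected_regions Integer indices of the affected regions.
#' @param direction `"strengthen"` or `"weaken"`.
#' @param magnitude Non-negative scalar, in units of the affected block's
#'   mean regional SD; 0 means patients are drawn from the unmodified
#'   cohort distribution. The default 5 emulates a clinically overt
#'   perturbation (on the order of the 40-50% striatal FDOPA signal
#'   change seen in Parkinsonian neurodegeneration).
#' @param mode `"axis_shift"` (default) or `"rescale"`.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(affected_regions = 1:12,
                              direction = c("strengthen", "weaken"),
                              magnitude = 5,
                              mode = c("axis_shift", "rescale")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (length(affected_regions) == 0 && magnitude > 0)
    stop("affected_regions is empty but magnitude > 0")
  structure(list(affected_regions = as.integer(affected_regions),
                 direction = direction, magnitude = magnitude, mode = mode),
            class = "perturbation_spec")
}

# Displacement vector (length n_regions) for an axis_shift perturbation.
perturbation_delta <- function(spec, pert) {
  delta <- numeric(spec$n_regions)
  if (pert$magnitude == 0 || pert$mode != "axis_shift") return(delta)
  blk <- pert$affected_regions
  S <- (spec$correlation * tcrossprod(spec$region_sds))[blk, blk, drop = FALSE]
  e <- eigen(S, symmetric = TRUE)
  u <- if (pert$direction == "strengthen") e$vectors[, 1] else e$vectors[, ncol(e$vectors)]
  if (sum(u) < 0) u <- -u
  delta[blk] <- pert$magnitude * mean(spec$region_sds[blk]) * u
  delta
}

# cohort_spec with the affected block's correlations rescaled.
rescaled_spec <- function(spec, pert) {
  if (pert$magnitude == 0) return(spec)
  f <- min(pert$magnitude, 1)
  blk <- pert$affected_regions
  R <- spec$correlation
  target <- if (pert$direction == "strengthen") 0.97 else 0
  sub <- R[blk, blk]
  sub <- sub + f * (target - sub)
  R[blk, blk] <- sub
  diag(R) <- 1
  spec2 <- spec
  spec2$correlation <- R
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- 1 / sqrt(diag(R))
    spec2$correlation <- R * tcrossprod(d)
    diag(spec2$correlation) <- 1
  }
  spec2
}

#' Simulate a perturbed patient group
#'
#' Draws `n_patients` subjects from the cohort distribution of `spec` and
#' applies the network perturbation described by `pert`. With magnitude 0
#' the patients are indistinguishable from held-out controls.
#'
#' @param spec A [cohort_spec()] describing the underlying population.
#' @param pert A [perturbation_spec()].
#' @param n_patients Number of patients.
#' @param seed Integer seed.
#' @param prefix Subject-id prefix (default "P").
#' @return A list with `uptake` and `covariates`, as [simulate_cohort()].
#' @export
simulate_patients <- function(spec, pert, n_patients, seed = NULL,
                              prefix = "P") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(pert, "perturbation_spec"))
  if (!all(pert$affected_regions <= spec$n_regions))
    stop("affected_regions outside the spec's regions")
  gen_spec <- if (pert$mode == "rescale") rescaled_spec(spec, pert) else spec
  with_seed(seed, {
    cov <- draw_covariates(spec, n_patients, prefix)
    L <- cohort_chol(gen_spec)
    noise <- matrix(rnorm(n_patients * spec$n_regions),
                    n_patients, spec$n_regions) %*% L
    values <- mean_surface(spec, cov) + noise
    if (pert$mode == "axis_shift") {
      delta <- perturbation_delta(spec, pert)
      values <- sweep(values, 2, delta, "+")
    }
    rownames(values) <- cov$subject_id
    colnames(values) <- default_region_labels(spec$n_regions)
    list(uptake = values, covariates = cov)
  })
}

#' Specify a longitudinal (baseline/follow-up) design
#'
#' @param stability_rho Within-subject correlation of the subject-specific
#'   noise component across timepoints, in `[0, 1]`.
#' @param treatment_shrink Factor in `[0, 1]` applied to the perturbation
#'   displacement at follow-up (1 = unchanged, 0 = fully normalised).
#' @param noise_sd Additional independent measurement noise (SUVr) added at
#'   follow-up.
#' @return An object of class `longitudinal_spec`.
#' @export
longitudinal_spec <- function(stability_rho = 0.7, treatment_shrink = 0.5,
                              noise_sd = 0.02) {
  if (stability_rho < 0 || stability_rho > 1)
    stop("stability_rho must lie in [0, 1]")
  if (treatment_shrink < 0 || treatment_shrink > 1)
    stop("treatment_shrink must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(stability_rho = stability_rho,
                 treatment_shrink = treatment_shrink,
                 noise_sd = noise_sd),
            class = "longitudinal_spec")
}

#' Simulate paired baseline/follow-up patient scans
#'
#' Generates a patient group at baseline (cohort draw plus perturbation
#' displacement) together with a follow-up scan per subject. The
#' subject-specific noise component is shared across timepoints with
#' correlation `stability_rho`; the perturbation displacement is scaled by
#' `treatment_shrink` at follow-up; independent measurement noise of SD
#' `noise_sd` is added at follow-up. With `stability_rho = 1`,
#' `treatment_shrink = 1` and `noise_sd = 0` the follow-up equals the
#' baseline exactly.
#'
#' Only `mode = "axis_shift"` perturbations carry a well-defined
#' displacement to shrink; other modes are rejected.
#'
#' @param spec A [cohort_spec()].
#' @param pert A [perturbation_spec()] with `mode = "axis_shift"`.
#' @param n_pairs Number of subjects scanned twice.
#' @param lspec A [longitudinal_spec()].
#' @param seed Integer seed.
#' @param prefix Subject-id prefix (default "L").
#' @return A list with `baseline` and `followup` uptake matrices (same
#'   subject ids) and the shared `covariates`.
#' @export
simulate_longitudinal <- function(spec, pert, n_pairs, lspec, seed = NULL,
                                  prefix = "L") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(pert, "perturbation_spec"),
            inherits(lspec, "longitudinal_spec"))
  if (pert$mode != "axis_shift")
    stop("simulate_longitudinal requires an axis_shift perturbation")
  with_seed(seed, {
    cov <- draw_covariates(spec, n_pairs, prefix)
    L <- cohort_chol(spec)
    m <- spec$n_regions
    Eb <- matrix(rnorm(n_pairs * m), n_pairs, m) %*% L
    Ef <- lspec$stability_rho * Eb +
      sqrt(1 - lspec$stability_rho^2) * (matrix(rnorm(n_pairs * m), n_pairs, m) %*% L)
    delta <- perturbation_delta(spec, pert)
    mu <- mean_surface(spec, cov)
    base <- mu + sweep(Eb, 2, delta, "+")
    fup <- mu + sweep(Ef, 2, lspec$treatment_shrink * delta, "+")
    if (lspec$noise_sd > 0)
      fup <- fup + matrix(rnorm(n_pairs * m, 0, lspec$noise_sd), n_pairs, m)
    labs <- default_region_labels(m)
    dimnames(base) <- dimnames(fup) <- list(cov$subject_id, labs)
    list(baseline = base, followup = fup, covariates = cov)
  })
}
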