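# Small synthetic fixtures shared across tests.

# Compact cohort spec: m regions, one correlated block in the first half,
# cheap to simulate many times.
small_spec <- function(n, m = 10, seed = 1, rho = 0.6, ...) {
  cohort_spec(n, n_regions = m,
              block_structure = list(list(regions = seq_len(m %/% 2), rho = rho)),
              between_block_correlation = 0.1,
              region_means = 1.5, region_sds = 0.2,
              seed = seed, ...)
}

# Independent brute-force deviation z-matrix: two separate network builds
# plus the variance formula, sharing no code with perturb_network.
brute_force_z <- function(ref_values, ref_cov, subj_values, subj_cov) {
  resid_bf <- function(V, cv) {
    D <- cbind(1, cv)
    V - D %*% solve(crossprod(D), crossprod(D, V))
  }
  cv0 <- if (is.null(ref_cov)) NULL else as.matrix(ref_cov)
  r0 <- if (is.null(cv0)) scale(ref_values, scale = FALSE) else resid_bf(ref_values, cv0)
  p0 <- stats::cor(r0)
  aug <- rbind(ref_values, subj_values)
  cv1 <- if (is.null(ref_cov)) NULL else rbind(cv0, as.matrix(subj_cov))
  r1 <- if (is.null(cv1)) scale(aug, scale = FALSE) else resid_bf(aug, cv1)
  p1 <- stats::cor(r1)
  n <- nrow(ref_values)
  z <- (p1 - p0) * (n - 1) / (1 - p0^2)
  diag(z) <- 0
  z
}

# Random labelled uptake matrix.
random_uptake <- function(n, m, seed = 1, prefix = "S") {
  set.seed(seed)
  vals <- matrix(rnorm(n * m, mean = 1.5, sd = 0.2), n, m)
  rownames(vals) <- sprintf("%s%03d", prefix, seq_len(n))
  colnames(vals) <- sprintf("region_%03d", seq_len(m))
  vals
}

# Covariate table matching an uptake matrix.
random_covariates <- function(uptake, seed = 1) {
  set.seed(seed)
  n <- nrow(uptake)
  data.frame(subject_id = rownames(uptake),
             age = runif(n, 20, 65),
             sex = rep_len(c(0, 1), n),
             stringsAsFactors = FALSE)
}

# Wrap a plain z matrix as a deviation_matrix object.
as_deviation <- function(z, id = "subject") {
  if (is.null(dimnames(z)))
    dimnames(z) <- list(sprintf("r%02d", seq_len(nrow(z))),
                        sprintf("r%02d", seq_len(nrow(z))))
  structure(list(z = z, subject_id = id, n_ref = NA_integer_,
                 region_labels = colnames(z)),
            class = "deviation_matrix")
}

# Random symmetric zero-diagonal matrix.
random_symmetric <- function(m, seed = 1, scale = 3) {
  set.seed(seed)
  z <- matrix(rnorm(m * m, sd = scale), m, m)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}
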