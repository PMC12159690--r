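#' Perturb the reference network with a single subject
#'
#' Adds one subject to the reference cohort, rebuilds the partial
#' correlation network on the augmented sample (covariates refitted on all
#' n + 1 subjects), and standardizes the edge-wise change in correlation.
#' For an edge with reference partial correlation `r` estimated from `n`
#' subjects, the change `d = r_perturbed - r` is referred to its null
#' scale `(1 - r^2) / (n - 1)`, giving the deviation z-score
#' `z = d * (n - 1) / (1 - r^2)`. The z-matrix is symmetric with a zero
#' diagonal and quantifies, edge by edge, how abnormal the subject's
#' regional profile is relative to the reference covariance structure.
#'
#' Subject covariates outside the reference cohort's observed range are
#' allowed but flagged with an extrapolation warning.
#'
#' @param ref A fitted [reference_network()].
#' @param subject_values Numeric vector of length m (one value per
#'   region). If named, names must match the reference region labels.
#' @param subject_cov One-row data frame (or named list/vector) with `age`
#'   and `sex`; required when the reference network was fitted with
#'   covariates.
#' @param subject_id Identifier stored in the result.
#' @return An object of class `deviation_matrix`: list with `z` (m x m),
#'   `subject_id`, `n_ref`, `region_labels`.
#' @examples
#' hc <- simulate_cohort(cohort_spec(30, n_regions = 8, seed = 1))
#' ref <- reference_network(hc$uptake, hc$covariates)
#' pat <- simulate_patients(cohort_spec(30, n_regions = 8, seed = 1),
#'                          perturbation_spec(1:4, magnitude = 2), 1, seed = 2)
#' dev <- perturb_network(ref, pat$uptake[1, ], pat$covariates[1, ])
#' dev
#' @export
perturb_network <- function(ref, subject_values, subject_cov = NULL,
                            subject_id = "subject") {
  stopifnot(inherits(ref, "reference_network"))
  m <- length(ref$region_labels)
  subject_values <- unlist(subject_values)
  if (length(subject_values) != m)
    stop(sprintf("subject has %d regions, reference has %d",
                 length(subject_values), m))
  if (!is.null(names(subject_values)) &&
      !identical(names(subject_values), ref$region_labels))
    stop("subject region labels do not match the reference network")
  if (any(!is.finite(subject_values)))
    stop("subject has missing or non-finite regional values")

  has_cov <- length(ref$covariate_names) > 0
  if (has_cov) {
    if (is.null(subject_cov)) stop("reference network uses covariates; subject_cov is required")
    sc <- as.list(subject_cov)
    if (!all(c("age", "sex") %in% names(sc)))
      stop("subject_cov must provide age and sex")
    ref_age <- range(ref$covariates$age)
    if (sc$age < ref_age[1] || sc$age > ref_age[2])
      warning(sprintf("subject age %.1f outside reference range [%.1f, %.1f]; extrapolating covariate adjustment",
                      sc$age, ref_age[1], ref_age[2]))
    aug_cov <- rbind(ref$covariates[, c("age", "sex")],
                     data.frame(age = as.numeric(sc$age), sex = as.numeric(sc$sex)))
    cv <- cbind(age = aug_cov$age, sex = aug_cov$sex)
    cv <- cv[, colnames(cv) %in% ref$covariate_names, drop = FALSE]
  } else cv <- NULL

  aug <- rbind(ref$uptake, subject_values)
  res <- residualize_covariates(aug, cv)
  pcc1 <- stats::cor(res)
  n <- ref$n_ref
  denom_n <- if (isTRUE(ref$dof_adjust)) n - 1 - length(ref$covariate_names) else n - 1
  z <- (pcc1 - ref$pcc) * denom_n / (1 - ref$pcc^2)
  diag(z) <- 0
  dimnames(z) <- dimnames(ref$pcc)
  structure(list(z = z, subject_id = subject_id, n_ref = n,
                 region_labels = ref$region_labels),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  zl <- x$z[lower.tri(x$z)]
  cat(sprintf("Deviation z-matrix for subject '%s' (%d regions, reference n = %d)\n",
              x$subject_id, length(x$region_labels), x$n_ref))
  cat(sprintf("Edge z: median %.2f, range [%.2f, %.2f]; %d edges with |z| > 4.13\n",
              stats::median(zl), min(zl), max(zl), sum(abs(zl) > 4.13)))
  invisible(x)
}

#' Deviation matrices for new subjects
#'
#' Applies [perturb_network()] to every row of a new uptake table,
#' returning one deviation z-matrix per subject.
#'
#' @param object A fitted [reference_network()].
#' @param newdata Numeric matrix, subjects x regions, with dimnames.
#' @param newcov Covariate data frame aligned to `newdata` by
#'   `subject_id` (required if the network was fitted with covariates).
#' @param ... Unused.
#' @return Named list of `deviation_matrix` objects, one per row of
#'   `newdata`.
#' @export
predict.reference_network <- function(object, newdata, newcov = NULL, ...) {
  check_uptake(newdata, require_variance = FALSE)
  if (!identical(colnames(newdata), object$region_labels))
    stop("region labels of newdata do not match the reference network")
  cov_al <- if (is.null(newcov)) NULL else align_covariates(newdata, newcov)
  out <- vector("list", nrow(newdata))
  names(out) <- rownames(newdata)
  for (i in seq_len(nrow(newdata))) {
    out[[i]] <- perturb_network(
      object, newdata[i, ],
      subject_cov = if (is.null(cov_al)) NULL else cov_al[i, ],
      subject_id = rownames(newdata)[i])
  }
  out
}

#' Edge-wise p-values for a deviation matrix
#'
#' Two-tailed standard-normal tail probabilities of the deviation
#' z-scores. Symmetric; diagonal set to 1.
#'
#' @param dev A `deviation_matrix` (or a bare z matrix).
#' @return Matrix of p-values.
#' @export
edge_pvalues <- function(dev) {
  z <- if (inherits(dev, "deviation_matrix")) dev$z else dev
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- 1
  p
}
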