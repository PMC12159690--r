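#' Residualize regional values against covariates
#'
#' Replaces each region column by its least-squares residual against an
#' intercept plus the given covariate columns. This is the adjustment
#' underlying the partial Pearson correlations of the reference network:
#' correlating residualized columns equals partial correlation given the
#' covariates.
#'
#' @param values Numeric matrix, subjects x regions.
#' @param covariates Numeric matrix (subjects x k), or `NULL` for
#'   intercept-only (mean-centering).
#' @return Matrix of residuals with the same dimensions/dimnames.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' age <- rnorm(10)
#' r <- residualize_covariates(x, cbind(age = age))
#' max(abs(crossprod(r, age)))  # orthogonal to the covariate
#' @export
residualize_covariates <- function(values, covariates = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  D <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates and values have different row counts")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    D <- cbind(D, covariates)
  }
  if (n <= ncol(D)) stop("need more subjects than covariates (plus intercept)")
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  values - D %*% qr.coef(qrD, values)
}

#' Fit a covariate-adjusted partial-correlation reference network
#'
#' Estimates the group-level molecular covariance network of a reference
#' (control) cohort: every region column is residualized against age and
#' sex (or any supplied covariates), and edges are the Pearson
#' correlations of the residualized columns — i.e. partial correlations
#' given the covariates. The fitted object retains the reference data so
#' that new subjects can perturb the network via [predict.reference_network()].
#'
#' @param uptake Numeric matrix, subjects x regions, with subject-id
#'   rownames and region-label colnames. At least 4 subjects.
#' @param covariates Data frame with columns `subject_id`, `age`, `sex`
#'   aligned to `uptake` rows by id, or `NULL` for no adjustment.
#' @param on_constant What to do when a covariate column is constant
#'   across the (sub)cohort: `"error"` (default) or `"drop"` the column.
#'   Dropping is used by [reference_stability()], where small random
#'   subsamples can be single-sex.
#' @param dof_adjust If `TRUE`, the deviation z-score denominator uses
#'   `n - 1 - k` (k = number of covariates) instead of `n - 1`. Off by
#'   default: the perturbation variance formula is used verbatim.
#' @return An object of class `reference_network` with components `pcc`
#'   (m x m partial-correlation matrix), `n_ref`, `region_labels`,
#'   `covariate_names`, and the retained data.
#' @examples
#' hc <- simulate_cohort(cohort_spec(30, n_regions = 8, seed = 1))
#' ref <- reference_network(hc$uptake, hc$covariates)
#' ref
#' @export
reference_network <- function(uptake, covariates = NULL,
                              on_constant = c("error", "drop"),
                              dof_adjust = FALSE) {
  on_constant <- match.arg(on_constant)
  check_uptake(uptake)
  if (nrow(uptake) < 4) stop("need at least 4 reference subjects")
  covariates <- align_covariates(uptake, covariates)
  cv <- covariate_matrix(covariates, on_constant)
  res <- residualize_covariates(uptake, cv)
  rv <- apply(res, 2, stats::var)
  if (any(rv < .Machine$double.eps))
    stop("zero-variance residual column(s): ",
         paste(colnames(uptake)[rv < .Machine$double.eps], collapse = ", "))
  pcc <- stats::cor(res)
  off <- abs(pcc[lower.tri(pcc)])
  if (any(off >= 1 - 1e-12)) {
    idx <- which(lower.tri(pcc), arr.ind = TRUE)
    bad <- idx[off >= 1 - 1e-12, , drop = FALSE][1, ]
    stop(sprintf("degenerate edge: |partial correlation| ~ 1 between '%s' and '%s' (duplicate or collinear regions)",
                 colnames(uptake)[bad[2]], colnames(uptake)[bad[1]]))
  }
  structure(list(
    pcc = pcc,
    n_ref = nrow(uptake),
    region_labels = colnames(uptake),
    covariate_names = colnames(cv),
    dof_adjust = dof_adjust,
    uptake = uptake,
    covariates = covariates
  ), class = "reference_network")
}

# Build the numeric covariate matrix from an aligned covariate data frame.
covariate_matrix <- function(covariates, on_constant = "error") {
  if (is.null(covariates)) return(NULL)
  cv <- cbind(age = covariates$age, sex = covariates$sex)
  const <- apply(cv, 2, function(x) length(unique(x)) <= 1)
  if (any(const)) {
    if (on_constant == "error")
      stop("constant covariate column(s): ",
           paste(colnames(cv)[const], collapse = ", "),
           " (use on_constant = \"drop\" to drop them)")
    cv <- cv[, !const, drop = FALSE]
    if (ncol(cv) == 0) return(NULL)
  }
  cv
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("Partial-correlation reference network: %d regions, %d reference subjects\n",
              length(x$region_labels), x$n_ref))
  if (length(x$covariate_names))
    cat("Covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  else cat("Covariates: none\n")
  e <- x$pcc[lower.tri(x$pcc)]
  cat(sprintf("Edges: %d; partial correlations median %.3f, range [%.3f, %.3f]\n",
              length(e), stats::median(e), min(e), max(e)))
  invisible(x)
}

#' @export
summary.reference_network <- function(object, ...) {
  e <- object$pcc[lower.tri(object$pcc)]
  out <- list(
    n_regions = length(object$region_labels),
    n_ref = object$n_ref,
    n_edges = length(e),
    covariates = object$covariate_names,
    edge_quantiles = stats::quantile(e, c(0, 0.25, 0.5, 0.75, 1))
  )
  class(out) <- "summary.reference_network"
  out
}

#' @export
print.summary.reference_network <- function(x, ...) {
  cat(sprintf("Reference network: %d regions (%d edges), n = %d\n",
              x$n_regions, x$n_edges, x$n_ref))
  cat("Covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "none", "\n")
  cat("Edge partial-correlation quantiles:\n")
  print(round(x$edge_quantiles, 3))
  invisible(x)
}

#' @export
coef.reference_network <- function(object, ...) object$pcc

#' @export
residuals.reference_network <- function(object, ...) {
  residualize_covariates(object$uptake,
                         covariate_matrix(object$covariates, "drop"))
}

#' Heatmap of the reference network
#' @param x A `reference_network`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.reference_network <- function(x, ...) {
  m <- length(x$region_labels)
  graphics::image(seq_len(m), seq_len(m), t(x$pcc[m:1, ]),
                  zlim = c(-1, 1), xlab = "region", ylab = "region",
                  main = "partial-correlation reference network",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' Simulate subjects from a fitted reference network
#'
#' Draws synthetic subjects from the Gaussian model implied by the fit:
#' covariate rows are resampled from the reference cohort, the mean
#' surface is the fitted covariate regression, and noise is drawn from
#' the sample covariance of the residuals.
#'
#' @param object A `reference_network`.
#' @param nsim Number of subjects to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list with `uptake` and `covariates` as [simulate_cohort()].
#' @export
simulate.reference_network <- function(object, nsim = 1, seed = NULL, ...) {
  cv <- covariate_matrix(object$covariates, "drop")
  with_seed(seed, {
    idx <- sample.int(object$n_ref, nsim, replace = TRUE)
    D <- cbind(1, cv)
    beta <- qr.coef(qr(D), object$uptake)
    res <- object$uptake - D %*% beta
    S <- stats::cov(res)
    L <- chol(S + diag(1e-12, ncol(S)))
    mu <- D[idx, , drop = FALSE] %*% beta
    vals <- mu + matrix(rnorm(nsim * ncol(S)), nsim, ncol(S)) %*% L
    rownames(vals) <- sprintf("S%03d", seq_len(nsim))
    colnames(vals) <- object$region_labels
    cov_out <- if (is.null(object$covariates)) NULL else {
      out <- object$covariates[idx, , drop = FALSE]
      out$subject_id <- rownames(vals)
      rownames(out) <- NULL
      out
    }
    list(uptake = vals, covariates = cov_out)
  })
}
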