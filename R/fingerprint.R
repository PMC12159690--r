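#' Connectome fingerprinting across timepoints
#'
#' For every baseline subject, finds the most similar follow-up subject
#' by Pearson correlation of the strict-lower-triangle vectors of their
#' deviation matrices. Identification succeeds when the best match is the
#' same subject; accuracy is the fraction of successful identifications.
#' Argmax ties are broken by lowest follow-up index (a measure-zero event
#' with continuous data, made deterministic for testing).
#'
#' @param base,follow Lists of `deviation_matrix` objects with identical
#'   subject-id sets (order may differ; matched by id).
#' @return An object of class `fingerprint_result`: `similarity`
#'   (baseline x follow-up Pearson matrix), `matches` (named character
#'   vector of best-match ids), `accuracy`.
#' @export
fingerprint_identify <- function(base, follow) {
  ids_b <- vapply(base, function(d) d$subject_id, character(1))
  ids_f <- vapply(follow, function(d) d$subject_id, character(1))
  if (length(ids_b) < 2) stop("need at least 2 subjects")
  if (!setequal(ids_b, ids_f) || anyDuplicated(ids_b) || anyDuplicated(ids_f))
    stop("baseline and follow-up subject-id sets differ")
  follow <- follow[match(ids_b, ids_f)]
  Vb <- vapply(base, vectorize_lower_triangle,
               numeric(length(vectorize_lower_triangle(base[[1]]))))
  Vf <- vapply(follow, vectorize_lower_triangle, numeric(nrow(Vb)))
  sim <- stats::cor(Vb, Vf)
  dimnames(sim) <- list(ids_b, ids_b)
  best <- apply(sim, 1, which.max)  # which.max takes the first (lowest index) on ties
  matches <- colnames(sim)[best]
  names(matches) <- ids_b
  structure(list(similarity = sim, matches = matches,
                 accuracy = mean(matches == ids_b)),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  n <- nrow(x$similarity)
  cat(sprintf("Connectome fingerprinting: %d/%d identified (accuracy %.1f%%)\n",
              round(x$accuracy * n), n, 100 * x$accuracy))
  invisible(x)
}

#' Reference-network stability under subsampling
#'
#' Measures how stable the reference network is as a function of cohort
#' size: for each size, random subsets are drawn without replacement,
#' the network is rebuilt with the same covariate model, and the Pearson
#' correlation between the strict lower triangles of the subsampled and
#' full-cohort networks is recorded. (The diagonal is constant 1 and is
#' excluded so it cannot inflate the correlation.) Default grid: sizes 8
#' to 64 in steps of 4, 20 repetitions each.
#'
#' A subsample can be single-sex by chance; constant covariate columns
#' are dropped for that rebuild rather than aborting the resampling.
#'
#' @param uptake Subjects x regions matrix (full reference cohort).
#' @param covariates Covariate data frame (or `NULL`).
#' @param sizes Increasing vector of subsample sizes (max <= number of
#'   subjects; each must exceed the covariate count + 2).
#' @param reps Repetitions per size (default 20).
#' @param seed Master seed; each (size, rep) cell uses an independent
#'   substream derived from it.
#' @return An object of class `stability_curve`: `sizes`, `correlations`
#'   (sizes x reps matrix), `mean_correlation` (per size).
#' @export
reference_stability <- function(uptake, covariates = NULL,
                                sizes = seq(8, 64, by = 4), reps = 20,
                                seed = NULL) {
  check_uptake(uptake)
  n <- nrow(uptake)
  if (any(diff(sizes) <= 0)) stop("sizes must be strictly increasing")
  if (max(sizes) > n) stop("largest subsample size exceeds the cohort size")
  k <- if (is.null(covariates)) 0 else 2
  if (min(sizes) <= k + 2)
    stop(sprintf("smallest size %d too small for the covariate model (need > %d)",
                 min(sizes), k + 2))
  covariates <- align_covariates(uptake, covariates)
  full <- reference_network(uptake, covariates)
  full_l <- full$pcc[lower.tri(full$pcc)]
  cors <- matrix(NA_real_, length(sizes), reps,
                 dimnames = list(size = sizes, rep = seq_len(reps)))
  for (si in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      idx <- with_seed(substream_seed(if (is.null(seed)) 0 else seed, sizes[si], r),
                       sample.int(n, sizes[si]))
      sub_cov <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
      net <- reference_network(uptake[idx, , drop = FALSE], sub_cov,
                               on_constant = "drop")
      cors[si, r] <- stats::cor(net$pcc[lower.tri(net$pcc)], full_l)
    }
  }
  structure(list(sizes = sizes, correlations = cors,
                 mean_correlation = rowMeans(cors), reps = reps, seed = seed),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat("Reference-network stability (subsample vs full-cohort correlation):\n")
  df <- data.frame(size = x$sizes, mean = round(x$mean_correlation, 3),
                   min = round(apply(x$correlations, 1, min), 3),
                   max = round(apply(x$correlations, 1, max), 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.stability_curve <- function(x, ...) {
  graphics::plot(rep(x$sizes, x$reps), as.vector(x$correlations),
                 xlab = "subsample size", ylab = "correlation with full network",
                 pch = 16, col = "#00000040", ...)
  graphics::lines(x$sizes, x$mean_correlation, lwd = 2, col = "firebrick")
  invisible(x)
}

#' Long-format export of a stability curve
#' @param x A `stability_curve`.
#' @param path CSV output path (columns size, rep, correlation).
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(x, path) {
  df <- expand.grid(rep = seq_len(ncol(x$correlations)), size = x$sizes)
  df <- df[, c("size", "rep")]
  df$correlation <- as.vector(t(x$correlations))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
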