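#' Threshold a deviation matrix at the extreme-deviation level
#'
#' Zeroes every edge with `|z| <= tau`; surviving entries keep their
#' signed z value. The default threshold 4.13 corresponds to a
#' Bonferroni-corrected two-tailed significance level of 0.05 over the
#' edges of an 83-region network and is kept as a fixed constant (it is
#' not recomputed for other region counts). The inequality is strict: an
#' entry exactly at the threshold is zeroed.
#'
#' @param dev A `deviation_matrix` from [perturb_network()], or a bare
#'   square z matrix.
#' @param tau Positive threshold (default 4.13).
#' @return An object of class `thresholded_deviation`: list with `zt`
#'   (thresholded matrix), `tau`, `subject_id`.
#' @examples
#' z <- matrix(c(0, 5, 5, 0), 2, 2)
#' threshold_deviation(z)$zt
#' @export
threshold_deviation <- function(dev, tau = 4.13) {
  if (tau <= 0) stop("tau must be positive")
  z <- if (inherits(dev, "deviation_matrix")) dev$z else as.matrix(dev)
  sid <- if (inherits(dev, "deviation_matrix")) dev$subject_id else "subject"
  zt <- z
  zt[abs(zt) <= tau] <- 0
  structure(list(zt = zt, tau = tau, subject_id = sid),
            class = "thresholded_deviation")
}

#' Subject extreme deviations (SED)
#'
#' Summarises one subject's thresholded deviation matrix as
#' `SED = T / C`, where `T` is the sum of absolute thresholded z-scores
#' over the strict lower triangle and `C = m(m-1)/2` is the number of
#' edges. Because `T` sums magnitudes (each exceeding the threshold), SED
#' can exceed 1; it is 0 exactly when no edge survives the threshold.
#'
#' A count-based variant (`count = TRUE`) divides the *number* of
#' surviving edges by `C` instead, giving a true proportion.
#'
#' @param t A `thresholded_deviation` (or bare thresholded matrix).
#' @param count If `TRUE`, count surviving edges instead of summing
#'   magnitudes.
#' @return A single non-negative number.
#' @export
sed <- function(t, count = FALSE) {
  zt <- if (inherits(t, "thresholded_deviation")) t$zt else as.matrix(t)
  m <- nrow(zt)
  if (m < 2) stop("need at least 2 regions")
  lower <- zt[lower.tri(zt)]
  C <- m * (m - 1) / 2
  if (count) sum(lower != 0) / C else sum(abs(lower)) / C
}

#' Regional extreme deviations (RED)
#'
#' Stacks per-subject regional deviation scores into a subjects x regions
#' matrix. For subject j and region i the score is the row mean of the
#' thresholded deviation matrix, `(1/m) * sum_k |zt[i, k]|`; the zero
#' diagonal contributes nothing but the divisor stays m. By default
#' absolute values are used, making RED non-negative and comparable
#' across groups whose deviations have opposite signs; `signed = TRUE`
#' averages the raw signed thresholded z-scores instead.
#'
#' @param ts A list of `thresholded_deviation` objects (all sharing the
#'   same regions), e.g. built from the output of
#'   [predict.reference_network()].
#' @param signed Use signed z-scores instead of absolute values.
#' @return Numeric matrix, subjects x regions, rownames = subject ids.
#' @export
red <- function(ts, signed = FALSE) {
  if (inherits(ts, "thresholded_deviation")) ts <- list(ts)
  if (!length(ts)) stop("empty subject list")
  labs <- colnames(ts[[1]]$zt)
  m <- nrow(ts[[1]]$zt)
  rows <- lapply(ts, function(t) {
    if (nrow(t$zt) != m || !identical(colnames(t$zt), labs))
      stop("subjects have inconsistent region labels")
    if (signed) rowSums(t$zt) / m else rowSums(abs(t$zt)) / m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(ts, function(t) t$subject_id, character(1))
  if (!is.null(labs)) colnames(out) <- labs
  out
}

#' Deviation metrics for a set of subjects
#'
#' Convenience wrapper: thresholds each subject's deviation matrix and
#' returns the SED vector and RED matrix.
#'
#' @param devs List of `deviation_matrix` objects.
#' @param tau Threshold passed to [threshold_deviation()].
#' @param signed_red Passed to [red()].
#' @return List with `sed` (named numeric vector) and `red` (matrix).
#' @export
deviation_metrics <- function(devs, tau = 4.13, signed_red = FALSE) {
  ts <- lapply(devs, threshold_deviation, tau = tau)
  sed_v <- vapply(ts, sed, numeric(1))
  names(sed_v) <- vapply(ts, function(t) t$subject_id, character(1))
  list(sed = sed_v, red = red(ts, signed = signed_red))
}

#' Write SED values / RED matrix as CSV
#'
#' SED: two columns (subject_id, sed). RED: subject rows, region columns.
#'
#' @param sed_values Named numeric vector of SED values.
#' @param red_matrix Subjects x regions RED matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sed_csv <- function(sed_values, path) {
  df <- data.frame(subject_id = names(sed_values),
                   sed = signif17(unname(sed_values)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sed_csv
#' @export
write_red_csv <- function(red_matrix, path) {
  df <- data.frame(subject_id = rownames(red_matrix),
                   signif17(red_matrix), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
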