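#' Unpaired two-group comparison (rank-sum + effect size)
#'
#' Wilcoxon rank-sum test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise, as implemented by
#' [stats::wilcox.test()]) together with Cohen's d computed with the plain
#' pooled standard deviation. The sign of d follows `mean(a) - mean(b)`.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An object of class `group_comparison`: list with `statistic`,
#'   `p_value`, `effect_size_d`, `alternative`, `n_a`, `n_b`.
#' @examples
#' compare_unpaired(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_unpaired <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 values")
  if (length(unique(c(a, b))) <= 1) stop("combined sample is constant")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
  structure(list(statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 effect_size_d = cohens_d(a, b),
                 alternative = alternative,
                 n_a = length(a), n_b = length(b),
                 test = "Wilcoxon rank-sum"),
            class = "group_comparison")
}

#' Paired one-tailed comparison (signed-rank)
#'
#' Wilcoxon signed-rank test of the hypothesis that values decrease from
#' baseline to follow-up (alternative: `after < before`). Zero
#' differences are dropped before ranking (Wilcoxon's original
#' treatment); ties among the remaining absolute differences are
#' mid-ranked. For up to 14 informative pairs the p-value is exact,
#' computed by enumerating all sign patterns of the (mid-ranked)
#' differences — this stays exact under ties, where the classical exact
#' tables do not apply; larger samples use the normal approximation.
#'
#' @param before,after Numeric vectors of equal length.
#' @return A `group_comparison` object (with `n_informative` pairs).
#' @examples
#' compare_paired(c(5, 6, 7, 8, 9), c(4, 5, 6, 7, 8))  # p = 1/32
#' @export
compare_paired <- function(before, after) {
  if (length(before) != length(after)) stop("before/after lengths differ")
  d <- before - after
  informative <- d != 0
  if (!any(informative)) stop("all paired differences are zero")
  if (sum(informative) < 5)
    warning("fewer than 5 informative pairs; signed-rank p is coarse")
  di <- d[informative]
  n_inf <- length(di)
  r <- rank(abs(di))
  wplus <- sum(r[di > 0])  # positive differences support "after < before"
  if (n_inf <= 14) {
    # exact conditional null: all 2^n sign assignments of the midranks
    masks <- seq_len(2^n_inf) - 1L
    wdist <- vapply(masks, function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, seq_len(n_inf) - 1L)) != 0])
    }, numeric(1))
    p <- mean(wdist >= wplus)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(after[informative], before[informative],
                         paired = TRUE, alternative = "less"))
    p <- wt$p.value
  }
  structure(list(statistic = wplus,
                 p_value = p,
                 effect_size_d = cohens_d(before, after),
                 alternative = "after < before",
                 n_a = length(before), n_b = length(after),
                 n_informative = sum(informative),
                 test = "Wilcoxon signed-rank (one-tailed)"),
            class = "group_comparison")
}

# Cohen's d with plain pooled SD (no small-sample correction).
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(0)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s\n", x$test, x$statistic,
              x$p_value, significance_marker(x$p_value)))
  cat(sprintf("Cohen's d = %.3f (alternative: %s; n = %d, %d)\n",
              x$effect_size_d, x$alternative, x$n_a, x$n_b))
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Omnibus Kruskal-Wallis test (with tie correction) across three or more
#' groups, followed by Dunn's pairwise z-tests on the pooled ranks with
#' two-sided normal p-values, FDR-adjusted across the pairs. Cohen's d is
#' reported per pair.
#'
#' @param groups Named list of numeric vectors (>= 3 values each).
#' @return An object of class `omnibus_report`: `kw_statistic` (chi-square),
#'   `kw_df`, `kw_p`, and `pairwise` (data frame with pair, dunn_z,
#'   raw_p, adj_p, cohen_d).
#' @examples
#' omnibus_groups(list(a = c(1, 3, 4), b = c(2, 5, 7), c = c(10, 11, 12)))
#' @export
omnibus_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("groups must be a list of at least 3 numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 3)) stop("each group needs at least 3 values")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) <= 1) stop("pooled sample is constant")
  kw <- stats::kruskal.test(groups)

  # Dunn's test on pooled mid-ranks with tie correction
  g <- rep(names(groups), lengths(groups))
  r <- rank(pooled)
  N <- length(pooled)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)[names(groups)]
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    za <- pr[1]; zb <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[za]] + 1 / ns[[zb]]))
    z <- (mean_ranks[[za]] - mean_ranks[[zb]]) / se
    c(dunn_z = z, raw_p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                         dunn_z = pw["dunn_z", ],
                         raw_p = pw["raw_p", ],
                         adj_p = fdr_adjust(pw["raw_p", ]),
                         cohen_d = apply(pairs, 2, function(pr)
                           cohens_d(groups[[pr[1]]], groups[[pr[2]]])),
                         stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  structure(list(kw_statistic = unname(kw$statistic),
                 kw_df = unname(kw$parameter),
                 kw_p = kw$p.value,
                 pairwise = pairwise),
            class = "omnibus_report")
}

#' @export
print.omnibus_report <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-square = %.3f (df = %d), p = %.4g %s\n",
              x$kw_statistic, x$kw_df, x$kw_p, significance_marker(x$kw_p)))
  cat("Dunn's post-hoc comparisons (FDR-adjusted):\n")
  pw <- x$pairwise
  pw$marker <- vapply(pw$adj_p, significance_marker, character(1))
  print(pw, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Region-wise group comparison of RED matrices
#'
#' Tests every region's RED values between two groups with a two-sided
#' Wilcoxon rank-sum test and adjusts across regions by FDR. A region
#' that is constant across both groups gets p = 1 (flagged in the report)
#' rather than aborting the scan.
#'
#' @param red_a,red_b RED matrices (subjects x regions) with matching
#'   region labels.
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return A data frame of class `regionwise_report` with columns
#'   `region`, `raw_p`, `adj_p`, `significant`, `effect_size_d`,
#'   `degenerate`.
#' @export
regionwise_tests <- function(red_a, red_b, alpha = 0.05) {
  if (!identical(colnames(red_a), colnames(red_b)))
    stop("region labels differ between the two RED matrices")
  m <- ncol(red_a)
  raw_p <- numeric(m); d <- numeric(m); degen <- logical(m)
  for (i in seq_len(m)) {
    a <- red_a[, i]; b <- red_b[, i]
    if (length(unique(c(a, b))) <= 1) {
      raw_p[i] <- 1; d[i] <- 0; degen[i] <- TRUE
    } else {
      ct <- compare_unpaired(a, b)
      raw_p[i] <- ct$p_value; d[i] <- ct$effect_size_d
    }
  }
  adj_p <- fdr_adjust(raw_p)
  out <- data.frame(region = colnames(red_a), raw_p = raw_p, adj_p = adj_p,
                    significant = adj_p < alpha, effect_size_d = d,
                    degenerate = degen, stringsAsFactors = FALSE)
  class(out) <- c("regionwise_report", "data.frame")
  out
}

#' Top regions by mean RED
#'
#' Ranks regions by their column mean in a RED matrix and returns the top
#' fraction (default 10%, i.e. `floor(0.10 * m)` regions; 8 of 83) in
#' descending order. Ties at the cutoff are broken deterministically by
#' region index (first occurrence wins).
#'
#' @param red_matrix Subjects x regions RED matrix.
#' @param fraction Fraction of regions to keep (default 0.10).
#' @return Character vector of region labels, highest mean first.
#' @export
top_regions <- function(red_matrix, fraction = 0.10) {
  if (nrow(red_matrix) < 1) stop("need at least one subject")
  mu <- colMeans(red_matrix)
  k <- max(1L, floor(fraction * length(mu)))
  ord <- order(-mu, seq_along(mu))
  colnames(red_matrix)[ord[seq_len(k)]]
}

#' Significance marker for a p-value
#'
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p A p-value.
#' @return Character marker.
#' @export
significance_marker <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Write a region-wise report as CSV plus a text summary
#' @param report A `regionwise_report`.
#' @param path CSV output path; a `.txt` summary is written alongside.
#' @return `path`, invisibly.
#' @export
write_regionwise_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  sig <- report[report$significant, ]
  lines <- c(sprintf("%d of %d regions significant after FDR (p < 0.05)",
                     nrow(sig), nrow(report)),
             sprintf("  %s %s adj p = %.4g", sig$region,
                     vapply(sig$adj_p, significance_marker, character(1)),
                     sig$adj_p))
  writeLines(lines, txt)
  invisible(path)
}
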