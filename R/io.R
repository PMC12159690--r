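#' Packaged region labels
#'
#' Returns region labels for an `n`-region parcellation. For `n = 83` the
#' packaged atlas-style names are used (41 homologous left/right pairs
#' plus brainstem); for other sizes generic `region_###` labels are
#' generated. All algorithms in the package treat labels as opaque
#' strings, so any parcellation works.
#'
#' @param n Number of regions.
#' @return Character vector of length `n`.
#' @export
default_region_labels <- function(n = 83) {
  if (n == 83) {
    path <- system.file("extdata", "region_labels_83.csv", package = "molpert")
    if (nzchar(path)) return(read.csv(path, stringsAsFactors = FALSE)$region_label)
  }
  sprintf("region_%03d", seq_len(n))
}

# Validate a subjects-x-regions uptake matrix: finite, named, non-degenerate.
check_uptake <- function(values, require_variance = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("uptake must be a numeric matrix (subjects x regions)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("uptake matrix needs subject-id rownames and region-label colnames")
  if (anyDuplicated(colnames(values))) stop("region labels must be unique")
  if (anyDuplicated(rownames(values))) stop("subject ids must be unique")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("missing or non-finite value at subject '%s', region '%s' (no imputation is performed)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  if (require_variance) {
    v <- apply(values, 2, stats::var)
    if (any(v == 0))
      stop("zero-variance region(s): ",
           paste(colnames(values)[v == 0], collapse = ", "))
  }
  invisible(values)
}

# Align a covariate table to an uptake matrix; errors list the symmetric
# difference of the id sets.
align_covariates <- function(values, covariates) {
  if (is.null(covariates)) return(NULL)
  if (!all(c("subject_id", "age", "sex") %in% names(covariates)))
    stop("covariates must have columns subject_id, age, sex")
  ids <- rownames(values)
  missing_cov <- setdiff(ids, covariates$subject_id)
  extra_cov <- setdiff(covariates$subject_id, ids)
  if (length(missing_cov) || length(extra_cov))
    stop("subject ids differ between uptake and covariates; ",
         "missing from covariates: {", paste(missing_cov, collapse = ", "),
         "}; not in uptake: {", paste(extra_cov, collapse = ", "), "}")
  covariates[match(ids, covariates$subject_id), , drop = FALSE]
}

#' Read and write regional uptake tables
#'
#' The canonical on-disk form is a UTF-8 CSV with a header row of region
#' labels and a first `subject_id` column. TSV input is accepted (the
#' delimiter is sniffed from the header line). Values are written with 17
#' significant digits so that write/read round-trips are exact in double
#' precision. Missing cells are an error: the analysis performs no
#' imputation.
#'
#' @param path File path.
#' @param table Subjects-x-regions numeric matrix with dimnames.
#' @return `read_uptake_csv` returns the uptake matrix;
#'   `write_uptake_csv` returns `path` invisibly.
#' @export
read_uptake_csv <- function(path) {
  sep <- sniff_sep(path)
  df <- utils::read.csv(path, check.names = FALSE, sep = sep,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    stop("first column of an uptake table must be 'subject_id'")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$subject_id
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("empty or non-numeric cell at line %d, column '%s'",
                 bad[1, 1] + 1L, colnames(vals)[bad[1, 2]]))
  vals
}

#' @rdname read_uptake_csv
#' @export
write_uptake_csv <- function(table, path) {
  check_uptake(table, require_variance = FALSE)
  df <- data.frame(subject_id = rownames(table),
                   signif17(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write covariate tables
#'
#' CSV with columns `subject_id`, `age`, `sex` (0 = female, 1 = male).
#'
#' @param path File path.
#' @param covariates Data frame with subject_id, age, sex.
#' @return `read_covariates_csv` returns the data frame;
#'   `write_covariates_csv` returns `path` invisibly.
#' @export
read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, sep = sniff_sep(path), stringsAsFactors = FALSE)
  if (!all(c("subject_id", "age", "sex") %in% names(df)))
    stop("covariate table must have columns subject_id, age, sex")
  if (any(is.na(df$age)) || any(is.na(df$sex)))
    stop("missing covariate values")
  if (!all(df$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  df
}

#' @rdname read_covariates_csv
#' @export
write_covariates_csv <- function(covariates, path) {
  df <- covariates
  df$age <- signif17(df$age)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a deviation matrix as CSV
#'
#' Square matrix with region labels as header row and first column.
#'
#' @param dev A deviation matrix from [perturb_network()] (or any square
#'   labelled matrix).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_deviation_csv <- function(dev, path) {
  z <- if (inherits(dev, "deviation_matrix")) dev$z else dev
  df <- data.frame(region = rownames(z), signif17(z), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deviation matrix CSV written by [write_deviation_csv()]
#' @param path File path.
#' @return Square numeric matrix with region dimnames.
#' @export
read_deviation_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- df[[1]]
  storage.mode(z) <- "double"
  z
}

sniff_sep <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

# Format numerics at 17 significant digits (exact double round-trip).
signif17 <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) formatC(col, digits = 17, format = "g"))
    dimnames(out) <- dimnames(x)
    out
  } else formatC(x, digits = 17, format = "g")
}

#' Extract regional SUVr values from a parametric image
#'
#' Computes, for one subject, the mean voxel activity within each atlas
#' region of a parametric PET image divided by the mean activity within
#' the reference-region label set (e.g. cerebellum), yielding one row of a
#' regional uptake table. Requires the RNifti package.
#'
#' @param image_path Path to a parametric NIfTI-1 image.
#' @param label_path Path to an integer NIfTI-1 label image on the same
#'   voxel grid.
#' @param region_ids Integer label values, in output order.
#' @param region_labels Character labels for the output (defaults to
#'   `region_<id>`).
#' @param reference_ids Integer label values forming the reference region.
#' @return Named numeric vector of SUVr values, one per region.
#' @export
extract_regional_suvr <- function(image_path, label_path, region_ids,
                                  reference_ids,
                                  region_labels = sprintf("region_%d", region_ids)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("extract_regional_suvr requires the RNifti package")
  img <- as.numeric(RNifti::readNifti(image_path))
  lab <- as.integer(round(as.numeric(RNifti::readNifti(label_path))))
  if (length(img) != length(lab))
    stop("parametric and label images are on different voxel grids")
  if (length(intersect(region_ids, reference_ids)) > 0)
    stop("reference label ids must be disjoint from analysis region ids")
  ref_mask <- lab %in% reference_ids
  if (!any(ref_mask)) stop("reference region mask is empty")
  ref_mean <- mean(img[ref_mask])
  if (ref_mean == 0) stop("reference region has zero mean activity; cannot form SUVr")
  out <- vapply(region_ids, function(id) {
    mask <- lab == id
    if (!any(mask)) stop(sprintf("empty mask for region id %d", id))
    mean(img[mask]) / ref_mean
  }, numeric(1))
  names(out) <- region_labels
  out
}
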