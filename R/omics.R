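#' Feature-by-sample omics matrix with sample metadata
#'
#' The common carrier for both metabolome (continuous, strictly positive
#' abundances) and transcriptome (non-negative integer counts) data: a numeric
#' matrix with features in rows and samples in columns, plus a metadata table
#' describing each sample's genotype, temperature and replicate.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids). All entries must be finite and
#'   non-negative; for `role = "transcriptome"` they must be whole numbers.
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `genotype`, `temperature_C`, `replicate`. Rows are matched
#'   to `colnames(values)` by `sample_id` and reordered to agree.
#' @param role `"metabolome"` or `"transcriptome"`; controls the integrality
#'   check and is carried along for downstream defaults.
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `metadata` and `role`.
#' @export
omics_matrix <- function(values, metadata, role = c("metabolome", "transcriptome")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique")
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  if (any(values < 0))
    stop("`values` must be non-negative")
  if (role == "transcriptome" && any(values != round(values)))
    stop("transcriptome values must be integral counts")

  req <- c("sample_id", "genotype", "temperature_C", "replicate")
  if (!is.data.frame(metadata) || !all(req %in% names(metadata)))
    stop("`metadata` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (anyNA(metadata[req]))
    stop("`metadata` has missing entries")
  if (!setequal(metadata$sample_id, colnames(values)))
    stop("metadata sample_id set does not match matrix column names")
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL

  structure(list(values = values, metadata = metadata, role = role),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix (%s): %d features x %d samples\n",
              x$role, nrow(x$values), ncol(x$values)))
  md <- x$metadata
  cat("  genotypes:    ", paste(sort(unique(md$genotype)), collapse = ", "), "\n")
  cat("  temperatures: ", paste(sort(unique(md$temperature_C)), collapse = ", "),
      "degC\n")
  cat("  replicates:   ", length(unique(md$replicate)),
      "per genotype x temperature\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by sample
#'
#' @param x an [omics_matrix()].
#' @param keep logical or integer index over samples, or a character vector of
#'   sample ids.
#' @return An `omics_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(x, keep) {
  stopifnot(inherits(x, "omics_matrix"))
  if (is.character(keep)) keep <- match(keep, colnames(x$values))
  omics_matrix(x$values[, keep, drop = FALSE],
               x$metadata[keep, , drop = FALSE], role = x$role)
}

#' Restrict an omics matrix to one genotype
#'
#' @param x an [omics_matrix()].
#' @param genotype genotype label to keep.
#' @export
subset_genotype <- function(x, genotype) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!genotype %in% x$metadata$genotype)
    stop("genotype '", genotype, "' not present in metadata")
  subset_samples(x, x$metadata$genotype == genotype)
}

#' Write / read an omics matrix as a pair of TSV files
#'
#' The on-disk layout is the pipeline's interchange format: an abundance TSV
#' (feature_id column followed by one column per sample) and a metadata TSV
#' (sample_id, genotype, temperature_C, replicate).
#'
#' @param x an [omics_matrix()].
#' @param matrix_path,metadata_path file paths for the two TSVs.
#' @return `write_omics_tsv` returns the paths invisibly; `read_omics_tsv`
#'   returns an `omics_matrix`.
#' @export
write_omics_tsv <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' @rdname write_omics_tsv
#' @param role passed through to [omics_matrix()].
#' @export
read_omics_tsv <- function(matrix_path, metadata_path,
                           role = c("metabolome", "transcriptome")) {
  role <- match.arg(role)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  md <- utils::read.delim(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  md$sample_id <- as.character(md$sample_id)
  omics_matrix(values, md, role = role)
}

# log2 with a pseudo-count of half the smallest positive value; keeps
# fold-changes finite when group means hit zero.
log2_safe <- function(x) {
  pos <- x[x > 0]
  eps <- if (length(pos)) min(pos) / 2 else 0.5
  log2(x + eps)
}
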