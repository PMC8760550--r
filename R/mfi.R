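#' MFI matrix container
#'
#' Bundles a samples x antibodies intensity matrix with its sample annotation
#' table (one row per sample, in matrix row order). All normalization, QC and
#' clustering steps consume and return this container. Raw and normalized
#' matrices are on the linear MFI scale (`scale = "linear"`, strictly positive
#' values); covariate-residualized matrices are on the log scale
#' (`scale = "log"`) where positivity no longer applies.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   antibodies in columns (colnames = antibody ids).
#' @param samples data.frame with at least `sample_id` and `plate_id`;
#'   typically the full sample record table from [generate_cohort()]. Rows are
#'   matched to `values` by `sample_id`.
#' @param scale `"linear"` (positive MFI) or `"log"` (adjusted values).
#' @return An object of class `mfi_matrix`: a list with elements `values`,
#'   `samples` and `scale`.
#' @export
mfi_matrix <- function(values, samples, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample ids as rownames and antibody ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated antibody ids")
  if (!all(is.finite(values))) stop("non-finite values in MFI matrix")
  if (scale == "linear" && any(values <= 0)) {
    stop("MFI values must be strictly positive on the linear scale")
  }
  if (!is.data.frame(samples) || !all(c("sample_id", "plate_id") %in% names(samples))) {
    stop("`samples` must be a data.frame with sample_id and plate_id columns")
  }
  miss <- setdiff(rownames(values), samples$sample_id)
  if (length(miss)) {
    stop("samples table lacks annotation for: ", paste(head(miss, 5), collapse = ", "))
  }
  samples <- samples[match(rownames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, scale = scale),
            class = "mfi_matrix")
}

#' @export
print.mfi_matrix <- function(x, ...) {
  cat(sprintf("mfi_matrix: %d samples x %d antibodies (%s scale), %d plate(s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              length(unique(x$samples$plate_id))))
  if ("role" %in% names(x$samples)) {
    print(table(x$samples$role))
  }
  invisible(x)
}

#' @export
dim.mfi_matrix <- function(x) dim(x$values)

#' Extract the intensity matrix or sample table
#'
#' @param x an `mfi_matrix`.
#' @return `mfi_values()` the numeric matrix; `mfi_samples()` the annotation
#'   data.frame; `mfi_plates()` the plate id per sample.
#' @export
mfi_values <- function(x) x$values

#' @rdname mfi_values
#' @export
mfi_samples <- function(x) x$samples

#' @rdname mfi_values
#' @export
mfi_plates <- function(x) x$samples$plate_id

# subset keeping container semantics
mfi_subset <- function(x, i = NULL, j = NULL) {
  v <- x$values
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  mfi_matrix(v, x$samples[x$samples$sample_id %in% rownames(v), , drop = FALSE],
             scale = x$scale)
}

#' Read / write an MFI matrix as CSV
#'
#' The CSV layout has `sample_id` in the first column and one column per
#' antibody, matching the files written by [write_simulation()].
#'
#' @param mfi_file path to the intensity CSV.
#' @param samples either a data.frame or the path of a sample-annotation CSV.
#' @param scale value scale of the stored matrix.
#' @return an [mfi_matrix()].
#' @export
read_mfi_csv <- function(mfi_file, samples, scale = "linear") {
  d <- read.csv(mfi_file, check.names = FALSE)
  v <- as.matrix(d[, -1, drop = FALSE])
  rownames(v) <- d[[1]]
  if (is.character(samples)) samples <- read.csv(samples)
  mfi_matrix(v, samples, scale = scale)
}

#' @rdname read_mfi_csv
#' @param x an `mfi_matrix` to write.
#' @param file output path.
#' @export
write_mfi_csv <- function(x, file) {
  d <- data.frame(sample_id = rownames(x$values), x$values,
                  check.names = FALSE)
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}
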