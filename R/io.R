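#' Construct a per-subject cell table
#'
#' @param subject_id Subject identifier.
#' @param matrix Numeric cells x markers matrix (no missing values).
#' @param marker_names Optional marker names; defaults to `colnames(matrix)`.
#' @return A `cell_table` object.
#' @export
cell_table <- function(subject_id, matrix, marker_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 1) stop("cell table must contain at least one cell")
  if (anyNA(matrix)) stop("cell table contains missing values")
  if (is.null(marker_names)) stop("marker names are required")
  if (anyDuplicated(marker_names)) stop("duplicate marker names")
  colnames(matrix) <- marker_names
  structure(list(subject_id = as.character(subject_id), matrix = matrix,
                 marker_names = marker_names),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table: subject", x$subject_id, "-", nrow(x$matrix), "cells x",
      ncol(x$matrix), "markers\n")
  invisible(x)
}

#' Read a per-subject cell table
#'
#' CSV is the required dialect: one header row of marker names, one row per
#' cell, dot decimal separator regardless of locale. Columns are reordered to
#' the panel; unknown or missing markers are an error naming the offenders.
#'
#' @param path Input file.
#' @param panel Ordered character vector of expected marker names.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @param format `"csv"` (supported) or `"fcs"` (not available in this
#'   build; reserved for a flow-standard reader).
#' @return A [cell_table()].
#' @export
read_cells <- function(path, panel, subject_id = NULL,
                       format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (format == "fcs")
    stop("FCS input is not supported by this build; export to CSV instead")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "numeric")
  if (nrow(df) == 0) stop("empty cell file: ", path)
  missing <- setdiff(panel, names(df))
  if (length(missing))
    stop("missing marker column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), panel)
  if (length(extra))
    stop("unknown marker column(s): ", paste(extra, collapse = ", "))
  cell_table(subject_id %||% sub("\\.[^.]*$", "", basename(path)),
             as.matrix(df[, panel, drop = FALSE]))
}

#' Write a cell table to CSV
#'
#' @param ct A [cell_table()].
#' @param path Output path.
#' @param space `"transformed"` writes values as stored; `"raw"` inverts the
#'   arcsinh transform (`sinh(x) * cofactor`) so the file mimics raw
#'   instrument intensities.
#' @param cofactor Cofactor used for the raw-space inversion.
#' @return `path`, invisibly.
#' @export
write_cells <- function(ct, path, space = c("transformed", "raw"),
                        cofactor = 5) {
  stopifnot(inherits(ct, "cell_table"))
  space <- match.arg(space)
  m <- ct$matrix
  if (space == "raw") m <- sinh(m) * cofactor
  write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Arcsinh transform of raw intensities
#'
#' The standard variance-stabilising cytometry transform
#' `x -> asinh(x / cofactor)`; monotone, hence rank-preserving per marker.
#'
#' @param x A [cell_table()] or numeric matrix of raw intensities.
#' @param cofactor Positive scale cofactor (mass-cytometry convention: 5).
#' @return Same type as `x`, transformed.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("cofactor must be a single positive number")
  if (inherits(x, "cell_table")) {
    x$matrix <- asinh(x$matrix / cofactor)
    return(x)
  }
  asinh(x / cofactor)
}

#' Read / write subject metadata
#'
#' Metadata has one row per subject with columns `subject_id`, `group`,
#' `sex`, optional scalar biomarker and covariate columns.
#'
#' @param meta Data frame of subject metadata.
#' @param path File path.
#' @return `read_subject_meta` returns the data frame; `write_subject_meta`
#'   returns `path` invisibly.
#' @export
write_subject_meta <- function(meta, path) {
  stopifnot(is.data.frame(meta), all(c("subject_id", "group") %in% names(meta)))
  write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_meta
#' @export
read_subject_meta <- function(path) {
  meta <- read.csv(path, check.names = FALSE)
  if (!all(c("subject_id", "group") %in% names(meta)))
    stop("metadata must contain subject_id and group columns")
  if (anyDuplicated(meta$subject_id)) stop("duplicate subject_id values")
  meta
}
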