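#' Per-subject tiered abundance features
#'
#' For every abundance group (all tiers) and every subject, the fraction of
#' that subject's cells annotated to the group: leaves directly, tier-1/2
#' groups as sums over their descendant leaves. Fractions are of total
#' annotated cells per subject (the stand-in for proportions of the CD45+
#' population).
#'
#' @param assignment An annotated `cluster_assignment` (needs `cell_leaf`
#'   and `subject`).
#' @param taxonomy A `subtype_taxonomy`.
#' @param subjects Optional ordered subject ids; defaults to order of first
#'   appearance.
#' @return Subjects x groups matrix of fractions.
#' @export
compute_abundances <- function(assignment, taxonomy, subjects = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (is.null(assignment$cell_leaf))
    stop("assignment must be annotated first (annotate_clusters)")
  if (is.null(assignment$subject))
    stop("assignment carries no per-cell subject ids")
  subjects <- subjects %||% unique(assignment$subject)
  leaf <- factor(assignment$cell_leaf, levels = taxonomy$tier3$name)
  subj <- factor(assignment$subject, levels = subjects)
  if (anyNA(subj)) stop("cells with subject ids outside `subjects`")
  counts <- table(subj, leaf)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("subject(s) with zero cells: ",
         paste(subjects[totals == 0], collapse = ", "))
  leaf_frac <- sweep(unclass(counts), 1, totals, "/")
  groups <- taxonomy_groups(taxonomy)
  out <- sapply(groups, function(g)
    rowSums(leaf_frac[, descendant_leaves(taxonomy, g), drop = FALSE]))
  out <- matrix(out, nrow = length(subjects),
                dimnames = list(subjects, groups))
  out
}

#' Per-subject per-leaf marker summary features
#'
#' For each subject, leaf subtype and feature marker, the median (or mean)
#' transformed intensity over that subject's cells in that leaf. A leaf with
#' no cells for a subject yields a missing value imputed with the cohort
#' median of that feature, and the imputation is recorded.
#'
#' @param assignment Annotated `cluster_assignment`.
#' @param pooled Pooled cell matrix aligned with the assignment (e.g. from
#'   [pool_cells()]).
#' @param taxonomy A `subtype_taxonomy`.
#' @param subjects Optional ordered subject ids.
#' @param stat Summary statistic, `"median"` (default) or `"mean"`.
#' @return Subjects x (leaves x feature markers) matrix, leaf-major column
#'   order, names `"<leaf>__<marker>"`; attribute `imputed` holds a logical
#'   matrix of imputed entries.
#' @export
compute_marker_summaries <- function(assignment, pooled, taxonomy,
                                     subjects = NULL,
                                     stat = c("median", "mean")) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  stat <- match.arg(stat)
  fun <- if (stat == "median") median else mean
  if (is.list(pooled) && !is.null(pooled$matrix)) pooled <- pooled$matrix
  if (nrow(pooled) != length(assignment$cell_leaf))
    stop("pooled matrix and assignment disagree on cell count")
  subjects <- subjects %||% unique(assignment$subject)
  leaves <- taxonomy$tier3$name
  fm <- taxonomy$feature_markers
  X <- pooled[, fm, drop = FALSE]
  out <- matrix(NA_real_, length(subjects), length(leaves) * length(fm),
                dimnames = list(subjects, as.vector(t(outer(
                  leaves, fm, paste, sep = "__")))))
  key <- paste(assignment$subject, assignment$cell_leaf, sep = "\r")
  groups <- split(seq_len(nrow(X)), key)
  for (g in names(groups)) {
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    if (!(parts[1] %in% subjects) || !(parts[2] %in% leaves)) next
    rows <- groups[[g]]
    cols <- paste(parts[2], fm, sep = "__")
    out[parts[1], cols] <- apply(X[rows, , drop = FALSE], 2, fun)
  }
  imputed <- is.na(out)
  if (any(imputed)) {
    for (j in which(colSums(imputed) > 0)) {
      med <- median(out[, j], na.rm = TRUE)
      if (is.na(med)) med <- 0   # leaf absent for every subject
      out[imputed[, j], j] <- med
    }
  }
  attr(out, "imputed") <- imputed
  out
}

#' Assemble and normalise the immune feature matrix
#'
#' Binds the tiered abundance block and the leaf-major marker summary block
#' into one subjects x features matrix and z-scores each feature across
#' subjects (zero-variance features become all-zero columns and are
#' flagged). For the default taxonomy (39 groups, 41 feature markers, 29
#' leaves) the matrix has 39 + 41 x 29 = 1228 features.
#'
#' @param abundance Subjects x groups matrix from [compute_abundances()].
#' @param marker_summaries Subjects x (leaves x markers) matrix from
#'   [compute_marker_summaries()].
#' @param taxonomy The `subtype_taxonomy` the blocks were built from.
#' @param normalization `"zscore"` (default) or `"none"`.
#' @return An `immune_feature_matrix`: list with `values` (subjects x
#'   features), `features` (descriptor data frame: `name`, `kind`, `tier`,
#'   `subtype`, `marker`), `subjects`, `normalization`, `center`, `scale`,
#'   `degenerate` (features with zero variance).
#' @export
build_feature_matrix <- function(abundance, marker_summaries, taxonomy,
                                 normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  if (!identical(rownames(abundance), rownames(marker_summaries)))
    stop("abundance and marker summary blocks disagree on subjects")
  groups <- taxonomy_groups(taxonomy)
  tiers <- c(rep(1L, length(taxonomy$tier1)), rep(2L, nrow(taxonomy$tier2)),
             rep(3L, nrow(taxonomy$tier3)))
  ms_names <- colnames(marker_summaries)
  parts <- strsplit(ms_names, "__", fixed = TRUE)
  features <- rbind(
    data.frame(name = groups, kind = "abundance", tier = tiers,
               subtype = groups, marker = NA_character_),
    data.frame(name = ms_names, kind = "marker_summary", tier = NA_integer_,
               subtype = vapply(parts, `[[`, "", 1),
               marker = vapply(parts, `[[`, "", 2)))
  values <- cbind(abundance[, groups, drop = FALSE], marker_summaries)
  attr(values, "imputed") <- NULL
  center <- scale_ <- rep(NA_real_, ncol(values))
  degenerate <- rep(FALSE, ncol(values))
  if (normalization == "zscore") {
    center <- colMeans(values)
    scale_ <- apply(values, 2, sd)
    degenerate <- !is.finite(scale_) | scale_ == 0
    scale_[degenerate] <- 1
    values <- sweep(sweep(values, 2, center, "-"), 2, scale_, "/")
    values[, degenerate] <- 0
    if (any(degenerate))
      message(sum(degenerate), " zero-variance feature(s) set to 0")
  }
  structure(list(values = values, features = features,
                 subjects = rownames(values), normalization = normalization,
                 center = center, scale = scale_, degenerate = degenerate),
            class = "immune_feature_matrix")
}

#' One-call feature matrix from an annotated assignment
#'
#' Convenience wrapper running [compute_abundances()],
#' [compute_marker_summaries()] and [build_feature_matrix()].
#'
#' @inheritParams compute_marker_summaries
#' @inheritParams build_feature_matrix
#' @return An `immune_feature_matrix`.
#' @export
featurize <- function(assignment, pooled, taxonomy, subjects = NULL,
                      stat = "median", normalization = "zscore") {
  subjects <- subjects %||% unique(assignment$subject)
  ab <- compute_abundances(assignment, taxonomy, subjects)
  ms <- compute_marker_summaries(assignment, pooled, taxonomy, subjects,
                                 stat = stat)
  build_feature_matrix(ab, ms, taxonomy, normalization = normalization)
}

#' @export
print.immune_feature_matrix <- function(x, ...) {
  cat("immune_feature_matrix:", nrow(x$values), "subjects x",
      ncol(x$values), "features (",
      sum(x$features$kind == "abundance"), "abundance,",
      sum(x$features$kind == "marker_summary"), "marker summaries );",
      "normalization:", x$normalization, "\n")
  invisible(x)
}

#' Export / import a feature matrix
#'
#' Values go to CSV (subjects in rows); feature descriptors and
#' normalisation parameters go to a YAML sidecar so raw values can be
#' reconstructed exactly.
#'
#' @param fm An `immune_feature_matrix`.
#' @param path CSV path; the sidecar is `<path>.meta.yaml`.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the `immune_feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "immune_feature_matrix"))
  df <- data.frame(subject_id = fm$subjects, fm$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(normalization = fm$normalization,
               center = as.list(fm$center), scale = as.list(fm$scale),
               degenerate = as.list(fm$degenerate),
               features = lapply(seq_len(nrow(fm$features)), function(i)
                 lapply(fm$features[i, ], function(v)
                   if (is.na(v)) NULL else unname(v))))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$subject_id
  feats <- do.call(rbind, lapply(meta$features, function(f)
    data.frame(name = f$name, kind = f$kind,
               tier = f$tier %||% NA_integer_,
               subtype = f$subtype %||% NA_character_,
               marker = f$marker %||% NA_character_)))
  structure(list(values = values, features = feats,
                 subjects = df$subject_id,
                 normalization = meta$normalization,
                 center = as.numeric(unlist(meta$center)),
                 scale = as.numeric(unlist(meta$scale)),
                 degenerate = as.logical(unlist(meta$degenerate))),
            class = "immune_feature_matrix")
}
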