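#' Pool per-subject cell tables for cohort-level clustering
#'
#' @param cells List of [cell_table()] objects sharing one panel.
#' @return List with `matrix` (all cells stacked) and `subject` (subject id
#'   per row).
#' @export
pool_cells <- function(cells) {
  stopifnot(length(cells) >= 1)
  panel <- cells[[1]]$marker_names
  for (ct in cells)
    if (!identical(ct$marker_names, panel))
      stop("all cell tables must share the same marker panel")
  list(matrix = do.call(rbind, lapply(cells, `[[`, "matrix")),
       subject = rep(vapply(cells, `[[`, "", "subject_id"),
                     vapply(cells, function(ct) nrow(ct$matrix), 0L)))
}

# blockwise brute-force k nearest neighbours (Euclidean); returns n x k index
knn_index <- function(X, k, block_size = 2048L) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of cells")
  sq <- rowSums(X^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(X[rows, , drop = FALSE], X)
    for (i in seq_along(rows)) {
      d2[i, rows[i]] <- Inf            # exclude self
      ord <- order(d2[i, ])[seq_len(k)]
      idx[rows[i], ] <- ord
    }
  }
  idx
}

#' Graph-based clustering of pooled cells
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance in transformed
#' space) over all pooled cells and partitions it by Leiden modularity
#' community detection — the kNN-graph/community-partitioning strategy used
#' for cytometry phenotyping. If the partition yields fewer communities than
#' `min_communities`, the resolution is doubled up to three times.
#'
#' @param pooled A matrix of pooled cells, or the result of [pool_cells()].
#' @param k Neighbour count for the kNN graph.
#' @param resolution Leiden resolution parameter (> 0).
#' @param seed RNG seed; the partition is deterministic given the seed.
#' @param min_communities Optional lower bound on the number of communities.
#' @return A `cluster_assignment`: per-cell `cluster` (integer), per-cluster
#'   `medians` (clusters x markers), `params`, and (after
#'   [annotate_clusters()]) the per-cluster `leaf` mapping.
#' @export
cluster_cells <- function(pooled, k = 30, resolution = 1, seed,
                          min_communities = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  subject <- NULL
  if (is.list(pooled) && !is.null(pooled$matrix)) {
    subject <- pooled$subject
    pooled <- pooled$matrix
  }
  X <- as.matrix(pooled)
  n <- nrow(X)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  if (resolution <= 0) stop("resolution must be > 0")
  nn <- knn_index(X, k)
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  res <- resolution
  for (attempt in 0:3) {
    set.seed(derive_seed(seed, attempt))
    comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = res, n_iterations = 5)
    cl <- igraph::membership(comm)
    if (is.null(min_communities) || length(unique(cl)) >= min_communities)
      break
    res <- res * 2
  }
  if (!is.null(min_communities) && length(unique(cl)) < min_communities)
    stop("could not reach ", min_communities,
         " communities after doubling resolution 3 times (got ",
         length(unique(cl)), ")")
  cl <- as.integer(cl)
  meds <- t(vapply(sort(unique(cl)), function(cid)
    apply(X[cl == cid, , drop = FALSE], 2, median),
    numeric(ncol(X))))
  rownames(meds) <- sort(unique(cl))
  colnames(meds) <- colnames(X)
  structure(list(cluster = cl, medians = meds, subject = subject,
                 leaf = NULL, similarity = NULL,
                 params = list(k = k, resolution = res, seed = seed)),
            class = "cluster_assignment")
}

#' Annotate clusters against taxonomy leaf signatures
#'
#' Each cluster is assigned the leaf subtype maximising cosine similarity
#' between the cluster's median marker vector and the leaf signature over
#' the taxonomy's signature markers. Ties break deterministically to the
#' lexicographically smallest leaf name (with a warning); assignments with
#' similarity below `flag_threshold` are flagged.
#'
#' @param assignment A `cluster_assignment` from [cluster_cells()].
#' @param taxonomy A `subtype_taxonomy`.
#' @param flag_threshold Similarity below which an assignment is flagged.
#' @return The assignment with `leaf` (per-cluster), `similarity`,
#'   `flagged`, and `cell_leaf` (per-cell leaf label) filled in.
#' @export
annotate_clusters <- function(assignment, taxonomy, flag_threshold = 0.5) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(taxonomy, "subtype_taxonomy"))
  sm <- taxonomy$signature_markers
  if (!all(sm %in% colnames(assignment$medians)))
    stop("cluster medians lack signature marker(s): ",
         paste(setdiff(sm, colnames(assignment$medians)), collapse = ", "))
  sig <- taxonomy$signatures[, sm, drop = FALSE]
  leaves <- rownames(sig)[order(rownames(sig))]     # lexicographic tie order
  sig <- sig[leaves, , drop = FALSE]
  meds <- assignment$medians[, sm, drop = FALSE]
  leaf <- character(nrow(meds)); simv <- numeric(nrow(meds))
  for (i in seq_len(nrow(meds))) {
    sims <- apply(sig, 1, cosine_sim, a = meds[i, ])
    best <- max(sims)
    hits <- which(sims >= best - 1e-12)
    if (length(hits) > 1)
      warning("similarity tie for cluster ", rownames(meds)[i],
              "; taking lexicographically smallest leaf")
    leaf[i] <- leaves[hits[1]]
    simv[i] <- best
  }
  names(leaf) <- rownames(meds); names(simv) <- rownames(meds)
  flagged <- simv < flag_threshold
  if (any(flagged))
    message(sum(flagged), " cluster(s) annotated below similarity ",
            flag_threshold)
  missing_leaves <- setdiff(taxonomy$tier3$name, leaf)
  if (length(missing_leaves))
    message("leaf subtype(s) receiving no cluster: ",
            paste(missing_leaves, collapse = ", "))
  assignment$leaf <- leaf
  assignment$similarity <- simv
  assignment$flagged <- flagged
  assignment$cell_leaf <- unname(leaf[as.character(assignment$cluster)])
  assignment
}

#' Bypass clustering with ground-truth labels
#'
#' Builds a `cluster_assignment` directly from a synthetic cohort's true
#' per-cell leaf labels, so downstream stages can be tested in isolation
#' from clustering error.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @return An annotated `cluster_assignment` (one cluster per true leaf).
#' @export
oracle_assign <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  labels <- unlist(cohort$truth$cell_labels, use.names = FALSE)
  if (length(labels) == 0) stop("cohort carries no ground-truth labels")
  pooled <- pool_cells(cohort$cells)
  leaves <- sort(unique(labels))
  cl <- match(labels, leaves)
  meds <- t(vapply(leaves, function(l)
    apply(pooled$matrix[labels == l, , drop = FALSE], 2, median),
    numeric(ncol(pooled$matrix))))
  rownames(meds) <- seq_along(leaves)
  structure(list(cluster = cl, medians = meds, subject = pooled$subject,
                 leaf = setNames(leaves, seq_along(leaves)),
                 similarity = setNames(rep(1, length(leaves)),
                                       seq_along(leaves)),
                 flagged = setNames(rep(FALSE, length(leaves)),
                                    seq_along(leaves)),
                 cell_leaf = labels,
                 params = list(oracle = TRUE)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$cluster), "cells,",
      nrow(x$medians), "clusters")
  if (!is.null(x$leaf)) cat(",", length(unique(x$leaf)), "annotated leaves")
  cat("\n")
  invisible(x)
}
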