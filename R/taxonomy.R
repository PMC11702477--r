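#' Load a three-tier immune subtype taxonomy
#'
#' Reads a YAML taxonomy describing the marker panel, the three tiers of
#' immune subtypes (major lineages, intermediate subsets, leaf subtypes), a
#' mean marker signature per leaf, and the marker subsets used for
#' annotation (`signature_markers`) and feature extraction
#' (`feature_markers`). The shipped default has 4 tier-1 lineages (T, B, NK,
#' Myeloid), 6 tier-2 subsets and 29 leaves — 39 abundance groups in all —
#' with a 42-marker panel of which 41 are feature markers (CD45 defines the
#' denominator population and is excluded).
#'
#' The taxonomy is a strict tree: every leaf names exactly one parent, which
#' is either a tier-2 subset or a tier-1 lineage, and every tier-2 subset
#' names its tier-1 parent.
#'
#' @param path Path to a taxonomy YAML file.
#' @return An object of class `subtype_taxonomy`: a list with elements
#'   `panel`, `signature_markers`, `feature_markers`, `tier1` (character),
#'   `tier2` (data.frame `name`, `parent`), `tier3` (data.frame `name`,
#'   `parent`, `tier1`), and `signatures` (leaves x panel matrix).
#' @seealso [default_taxonomy()], [taxonomy_groups()]
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (f in c("panel", "tier1", "tier3"))
    if (is.null(raw[[f]])) stop("taxonomy is missing field '", f, "'")
  panel <- as.character(unlist(raw$panel))
  if (anyDuplicated(panel)) stop("duplicate marker names in panel")
  tier1 <- as.character(unlist(raw$tier1))
  tier2 <- if (length(raw$tier2)) {
    data.frame(name = vapply(raw$tier2, `[[`, "", "name"),
               parent = vapply(raw$tier2, `[[`, "", "parent"))
  } else data.frame(name = character(), parent = character())
  leaves <- vapply(raw$tier3, `[[`, "", "name")
  parents <- vapply(raw$tier3, `[[`, "", "parent")
  all_names <- c(tier1, tier2$name, leaves)
  if (anyDuplicated(all_names))
    stop("duplicate subtype name(s): ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  bad <- !(tier2$parent %in% tier1)
  if (any(bad))
    stop("tier-2 subtype(s) with unknown tier-1 parent: ",
         paste(tier2$name[bad], collapse = ", "))
  bad <- !(parents %in% c(tier1, tier2$name))
  if (any(bad))
    stop("leaf subtype(s) with unknown parent: ",
         paste(leaves[bad], collapse = ", "))
  # resolve each leaf's tier-1 ancestor through the (optional) tier-2 parent
  t1_of <- function(p) if (p %in% tier1) p else tier2$parent[match(p, tier2$name)]
  tier3 <- data.frame(name = leaves, parent = parents,
                      tier1 = vapply(parents, t1_of, ""))
  sig <- t(vapply(raw$tier3, function(l) {
    v <- as.numeric(unlist(l$signature))
    if (length(v) != length(panel))
      stop("signature length mismatch for leaf '", l$name, "': ",
           length(v), " values for a ", length(panel), "-marker panel")
    v
  }, numeric(length(panel))))
  dimnames(sig) <- list(leaves, panel)
  sig_markers <- as.character(unlist(raw$signature_markers %||% panel))
  feat_markers <- as.character(unlist(raw$feature_markers %||% panel))
  if (!all(sig_markers %in% panel) || !all(feat_markers %in% panel))
    stop("signature_markers / feature_markers must be subsets of the panel")
  structure(list(panel = panel, signature_markers = sig_markers,
                 feature_markers = feat_markers, tier1 = tier1,
                 tier2 = tier2, tier3 = tier3, signatures = sig),
            class = "subtype_taxonomy")
}

#' Default shipped taxonomy
#'
#' @return The packaged default `subtype_taxonomy` (4 + 6 + 29 groups,
#'   42-marker panel, 41 feature markers).
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy_default.yaml",
                            package = "cytoien", mustWork = TRUE))
}

#' Number and names of abundance groups in a taxonomy
#'
#' The abundance groups are all subtypes across the three tiers; for the
#' default taxonomy that is 4 + 6 + 29 = 39.
#'
#' @param taxonomy A `subtype_taxonomy`.
#' @return Character vector of group names in tier order.
#' @export
taxonomy_groups <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "subtype_taxonomy"))
  c(taxonomy$tier1, taxonomy$tier2$name, taxonomy$tier3$name)
}

# leaves that descend from a given group (the group itself if it is a leaf)
descendant_leaves <- function(taxonomy, group) {
  t3 <- taxonomy$tier3
  if (group %in% t3$name) return(group)
  if (group %in% taxonomy$tier2$name) return(t3$name[t3$parent == group])
  if (group %in% taxonomy$tier1) return(t3$name[t3$tier1 == group])
  stop("unknown group: ", group)
}

#' @export
print.subtype_taxonomy <- function(x, ...) {
  cat("subtype_taxonomy:", length(x$tier1), "tier-1 /", nrow(x$tier2),
      "tier-2 /", nrow(x$tier3), "leaf subtypes (",
      length(taxonomy_groups(x)), "abundance groups )\n")
  cat("panel:", length(x$panel), "markers;", length(x$feature_markers),
      "feature markers;", length(x$signature_markers), "signature markers\n")
  invisible(x)
}
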