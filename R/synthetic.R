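#' Configuration for a synthetic cytometry cohort
#'
#' Defines the study conditions for [generate_cohort()]: group sizes, cells
#' per subject, marker panel, baseline leaf-subtype composition, planted
#' group effects on composition and on within-subtype marker levels, and the
#' nuisance variability knobs. Defaults emulate a three-group dementia
#' cohort: 14 + 25 + 18 subjects (AD, DLB, HC), a 42-marker panel, 29 leaf
#' subtypes with tier-1 proportions of roughly 53% T, 21% myeloid, 18% NK
#' and 8% B cells.
#'
#' Marker values are generated directly in arcsinh-transformed space, where
#' all downstream computation happens; [write_cells()] can invert the
#' transform when a raw-space export is wanted.
#'
#' @param n_subjects_per_group Named integer vector of subjects per group.
#' @param groups Ordered group labels (defaults to the names of
#'   `n_subjects_per_group`).
#' @param n_cells_per_subject Cells per subject (study scale: each subject
#'   contributes millions of live cells; the default 3000 is a desk-scale
#'   stand-in).
#' @param base_fractions Named baseline leaf composition summing to 1;
#'   `NULL` uses the packaged default matched to the default taxonomy.
#' @param abundance_effects Data frame `group`, `subtype`, `multiplier`:
#'   multiplicative shifts applied to baseline leaf fractions of that group
#'   (a tier-1/2 subtype scales all its descendant leaves), renormalised.
#' @param marker_effects Data frame `group`, `subtype`, `marker`, `shift`
#'   and optional `sex`: additive shifts (transformed units) to the leaf
#'   signature mean for that group (and sex, if given).
#' @param noise_sd Per-cell Gaussian marker noise sd (transformed units).
#' @param subject_sd Between-subject random-effect sd per subject x leaf x
#'   marker (transformed units); the marker-level analogue of the Dirichlet
#'   composition jitter.
#' @param dirichlet_concentration Concentration multiplier for the per-subject
#'   Dirichlet composition jitter (`alpha = concentration * fraction`);
#'   larger is less between-subject variation.
#' @param sex_ratio Proportion of males per group; `NULL` alternates M/F
#'   deterministically within group.
#' @param seed Mandatory RNG seed; identical seed + config reproduce the
#'   cohort bit-identically.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects_per_group = c(AD = 14, DLB = 25, HC = 18),
                          groups = names(n_subjects_per_group),
                          n_cells_per_subject = 3000,
                          base_fractions = NULL,
                          abundance_effects = NULL,
                          marker_effects = NULL,
                          noise_sd = 0.5,
                          subject_sd = 0.2,
                          dirichlet_concentration = 200,
                          sex_ratio = NULL,
                          seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(groups)) stop("groups must be named or given explicitly")
  if (length(n_subjects_per_group) != length(groups))
    stop("n_subjects_per_group must have one entry per group")
  names(n_subjects_per_group) <- groups
  if (any(n_subjects_per_group < 1)) stop("each group needs >= 1 subject")
  if (noise_sd < 0 || subject_sd < 0) stop("noise sds must be >= 0")
  if (dirichlet_concentration <= 0) stop("dirichlet_concentration must be > 0")
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 groups = groups,
                 n_cells_per_subject = as.integer(n_cells_per_subject),
                 base_fractions = base_fractions,
                 abundance_effects = abundance_effects,
                 marker_effects = marker_effects,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 dirichlet_concentration = dirichlet_concentration,
                 sex_ratio = sex_ratio, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default baseline leaf composition for the shipped taxonomy
#'
#' Tier-1 totals match the reported cohort-wide proportions (53.0% T,
#' 21.2% myeloid, 18.3% NK, 7.5% B), spread over leaves.
#'
#' @return Named numeric vector over the 29 default leaves, summing to 1.
#' @export
default_base_fractions <- function() {
  c(T01 = 0.100, T02 = 0.030, T03 = 0.045, T04 = 0.025, T05 = 0.040,
    T06 = 0.020, T07 = 0.050, T08 = 0.020, T09 = 0.035, T10 = 0.020,
    T11 = 0.030, T12 = 0.015, T13 = 0.020, T14 = 0.010, T15 = 0.025,
    T16 = 0.010, T17 = 0.020, T18 = 0.015,
    B01 = 0.045, B02 = 0.030,
    NK01 = 0.080, NK02 = 0.050, NK03 = 0.028, NK04 = 0.025,
    M01 = 0.100, M02 = 0.045, M03 = 0.032, M04 = 0.020, M05 = 0.015)
}

# validate effect tables against the taxonomy/panel, returning normalised
# data frames (possibly empty)
validate_effects <- function(config, taxonomy) {
  groups <- taxonomy_groups(taxonomy)
  ab <- config$abundance_effects
  if (is.null(ab)) ab <- data.frame(group = character(), subtype = character(),
                                    multiplier = numeric())
  bad <- !(ab$subtype %in% groups)
  if (any(bad))
    stop("abundance effect references unknown subtype(s): ",
         paste(unique(ab$subtype[bad]), collapse = ", "))
  bad <- !(ab$group %in% config$groups)
  if (any(bad))
    stop("abundance effect references unknown group(s): ",
         paste(unique(ab$group[bad]), collapse = ", "))
  if (any(ab$multiplier <= 0)) stop("abundance multipliers must be > 0")
  mk <- config$marker_effects
  if (is.null(mk)) mk <- data.frame(group = character(), subtype = character(),
                                    marker = character(), shift = numeric())
  if (is.null(mk$sex)) mk$sex <- rep(NA_character_, nrow(mk))
  bad <- !(mk$subtype %in% taxonomy$tier3$name)
  if (any(bad))
    stop("marker effect references unknown leaf subtype(s): ",
         paste(unique(mk$subtype[bad]), collapse = ", "))
  bad <- !(mk$marker %in% taxonomy$panel)
  if (any(bad))
    stop("marker effect references unknown marker(s): ",
         paste(unique(mk$marker[bad]), collapse = ", "))
  bad <- !(mk$group %in% config$groups)
  if (any(bad))
    stop("marker effect references unknown group(s): ",
         paste(unique(mk$group[bad]), collapse = ", "))
  list(abundance = ab, marker = mk)
}

#' Generate a synthetic single-cell cohort with ground truth
#'
#' Per subject, leaf-subtype counts are drawn multinomially from an
#' effect-adjusted, Dirichlet-jittered fraction vector; each cell's marker
#' vector is the leaf signature mean plus a per-subject random effect
#' (`subject_sd`) plus per-cell Gaussian noise (`noise_sd`), all in
#' arcsinh-transformed space. Group effects on composition and on
#' within-leaf marker levels are planted exactly as configured and recorded
#' in the returned ground truth.
#'
#' @param config A [cohort_config()].
#' @param taxonomy A `subtype_taxonomy`; defaults to [default_taxonomy()].
#' @return A list of class `synthetic_cohort`:
#'   `cells` (list of [cell_table()]), `meta` (subject metadata data frame),
#'   `truth` (per-cell leaf labels per subject, per-subject true group
#'   fraction vectors over all tiers, and the planted effect tables).
#' @export
generate_cohort <- function(config, taxonomy = default_taxonomy()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(taxonomy, "subtype_taxonomy"))
  leaves <- taxonomy$tier3$name
  if (length(leaves) < 1) stop("taxonomy has no leaf subtypes")
  base <- config$base_fractions %||% default_base_fractions()
  if (!setequal(names(base), leaves))
    stop("base_fractions must cover exactly the taxonomy leaves")
  base <- base[leaves]
  if (any(base <= 0) || abs(sum(base) - 1) > 1e-8)
    stop("base fractions must be positive and sum to 1")
  eff <- validate_effects(config, taxonomy)

  # per-group effect-adjusted baseline compositions
  group_fracs <- lapply(config$groups, function(g) {
    f <- base
    ge <- eff$abundance[eff$abundance$group == g, , drop = FALSE]
    for (i in seq_len(nrow(ge))) {
      lv <- descendant_leaves(taxonomy, ge$subtype[i])
      f[lv] <- f[lv] * ge$multiplier[i]
    }
    if (any(f <= 0))
      stop("abundance effects drive fraction(s) to <= 0 in group ", g)
    f / sum(f)
  })
  names(group_fracs) <- config$groups

  set.seed(config$seed)
  n_per <- config$n_subjects_per_group
  subj_group <- rep(config$groups, n_per)
  ids <- sprintf("S%03d", seq_along(subj_group))
  sex <- unlist(lapply(config$groups, function(g) {
    n <- n_per[[g]]
    if (is.null(config$sex_ratio)) rep_len(c("M", "F"), n)
    else c(rep("M", round(config$sex_ratio * n)),
           rep("F", n - round(config$sex_ratio * n)))
  }), use.names = FALSE)

  n_cells <- config$n_cells_per_subject
  panel <- taxonomy$panel
  cells <- vector("list", length(ids))
  labels <- vector("list", length(ids))
  true_frac <- matrix(0, length(ids), length(leaves),
                      dimnames = list(ids, leaves))
  for (s in seq_along(ids)) {
    g <- subj_group[s]
    alpha <- config$dirichlet_concentration * group_fracs[[g]]
    gam <- rgamma(length(alpha), shape = alpha)
    frac <- gam / sum(gam)
    true_frac[s, ] <- frac
    counts <- as.integer(rmultinom(1, n_cells, frac))
    lab <- rep(leaves, counts)
    mu <- taxonomy$signatures[lab, , drop = FALSE]
    mk <- eff$marker[eff$marker$group == g &
                       (is.na(eff$marker$sex) | eff$marker$sex == sex[s]), ,
                     drop = FALSE]
    # subject-level random effect per (leaf, marker), then planted shifts
    if (config$subject_sd > 0) {
      re <- matrix(rnorm(length(leaves) * length(panel),
                         sd = config$subject_sd),
                   length(leaves), length(panel),
                   dimnames = list(leaves, panel))
      mu <- mu + re[lab, , drop = FALSE]
    }
    for (i in seq_len(nrow(mk)))
      mu[lab == mk$subtype[i], mk$marker[i]] <-
        mu[lab == mk$subtype[i], mk$marker[i]] + mk$shift[i]
    x <- mu
    if (config$noise_sd > 0)
      x <- x + matrix(rnorm(length(mu), sd = config$noise_sd),
                      nrow(mu), ncol(mu))
    colnames(x) <- panel
    rownames(x) <- NULL
    cells[[s]] <- cell_table(ids[s], x)
    labels[[s]] <- lab
  }

  meta <- data.frame(subject_id = ids, group = subj_group, sex = sex,
                     stringsAsFactors = FALSE)
  truth <- list(cell_labels = setNames(labels, ids),
                leaf_fractions = true_frac,
                group_fractions = true_group_fractions(true_frac, taxonomy),
                abundance_effects = eff$abundance,
                marker_effects = eff$marker)
  structure(list(cells = setNames(cells, ids), meta = meta, truth = truth,
                 config = config, taxonomy = taxonomy),
            class = "synthetic_cohort")
}

# roll true leaf fractions up the taxonomy to all 39 groups
true_group_fractions <- function(leaf_frac, taxonomy) {
  groups <- taxonomy_groups(taxonomy)
  out <- sapply(groups, function(g)
    rowSums(leaf_frac[, descendant_leaves(taxonomy, g), drop = FALSE]))
  rownames(out) <- rownames(leaf_frac)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$cells), "subjects (",
      paste(sprintf("%s=%d", names(x$config$n_subjects_per_group),
                    x$config$n_subjects_per_group), collapse = ", "),
      "),", x$config$n_cells_per_subject, "cells/subject\n")
  invisible(x)
}

#' Add simulated scalar plasma biomarkers to subject metadata
#'
#' Adds two scalar biomarker columns (defaults named after plasma p-Tau181
#' and neurofilament light) drawn `N(0, 1)` in the reference group and
#' `N(effect_size, 1)` in the case group; other groups draw from the
#' reference distribution.
#'
#' @param meta Subject metadata with a `group` column.
#' @param effect_size Standardised mean difference between the two groups.
#' @param case_group,reference_group Group labels receiving the shifted and
#'   the null distribution.
#' @param names Biomarker column names.
#' @param seed RNG seed.
#' @return `meta` with the biomarker columns appended.
#' @export
generate_biomarkers <- function(meta, effect_size,
                                case_group = meta$group[1],
                                reference_group = NULL,
                                names = c("pTau181", "NFL"), seed) {
  stopifnot(is.data.frame(meta), "group" %in% colnames(meta))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  shift <- ifelse(meta$group == case_group, effect_size, 0)
  for (nm in names) meta[[nm]] <- rnorm(nrow(meta)) + shift
  meta
}

#' Plant marker effects at a target standardised effect size
#'
#' Converts a standardised (subject-level) effect size into additive shifts
#' in transformed units, accounting for the between-subject sd of a median
#' summary feature: `sd = sqrt(subject_sd^2 + pi * noise_sd^2 /
#' (2 * n_cells))`.
#'
#' @param config A [cohort_config()] to extend.
#' @param subtypes,markers Equal-length vectors naming the leaf/marker pairs.
#' @param group Group receiving the shift.
#' @param effect_size Standardised effect size (Cohen's d at subject level).
#' @param sex Optional sex restriction per effect (NA = both).
#' @return The config with `marker_effects` filled in.
#' @export
plant_marker_effects <- function(config, subtypes, markers, group,
                                 effect_size, sex = NA_character_) {
  stopifnot(inherits(config, "cohort_config"),
            length(subtypes) == length(markers))
  sd_subj <- sqrt(config$subject_sd^2 +
                    pi * config$noise_sd^2 / (2 * config$n_cells_per_subject))
  eff <- data.frame(group = group, subtype = subtypes, marker = markers,
                    shift = effect_size * sd_subj,
                    sex = rep_len(sex, length(subtypes)))
  config$marker_effects <- rbind(config$marker_effects, eff)
  config
}

#' Write a synthetic cohort to disk
#'
#' One CSV per subject (cells x markers) plus a cohort-level metadata CSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param space Passed to [write_cells()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, space = "transformed") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ct in cohort$cells)
    write_cells(ct, file.path(dir, paste0(ct$subject_id, ".csv")),
                space = space)
  write_subject_meta(cohort$meta, file.path(dir, "subjects.csv"))
  invisible(dir)
}
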