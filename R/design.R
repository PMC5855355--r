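#' Design matrix for the clustered two-species multi-part experiment
#'
#' One indicator column per individual (absorbing species main effects, which
#' are confounded with housing and deliberately not estimable), shared
#' brain-part effect columns relative to a reference part, and species-by-part
#' interaction columns carrying the difference of part effects in the second
#' species. On the full 2 x 5 x 6 layout this gives 10 + 5 + 5 = 20 columns of
#' full rank.
#'
#' @param samples a [sample_table()].
#' @param reference_part reference brain-part level (default: first level).
#' @return An object of class `design_matrix`: list with the model `matrix`,
#'   the `samples` table, `reference_part`, `part_levels`, `species_levels`,
#'   and column bookkeeping used by the contrast builders.
#' @export
build_design <- function(samples, reference_part = NULL) {
  samples <- sample_table(samples)
  parts <- levels(samples$brain_part)
  species <- levels(samples$species)
  individuals <- levels(samples$individual)
  if (length(parts) < 2L) abort("need at least two brain parts")
  if (anyNA(samples$brain_part)) abort("unknown brain_part level in samples")
  if (is.null(reference_part)) reference_part <- parts[1]
  if (!reference_part %in% parts) {
    abort(paste0("reference_part ", reference_part, " is not a part level"))
  }
  # parts per individual: the part effects need within-individual replication
  ppi <- tapply(samples$brain_part, samples$individual,
                function(z) length(unique(z)))
  if (any(ppi < 2L)) {
    abort("every individual needs samples from at least two brain parts")
  }
  n <- nrow(samples)
  nonref <- setdiff(parts, reference_part)
  ind_cols <- paste0("ind_", individuals)
  part_cols <- paste0("part_", nonref)
  has_interaction <- length(species) >= 2L
  int_cols <- if (has_interaction) paste0("sp2_part_", nonref) else character()
  X <- matrix(0, n, length(ind_cols) + length(part_cols) + length(int_cols),
              dimnames = list(samples$sample_id,
                              c(ind_cols, part_cols, int_cols)))
  for (i in seq_along(individuals)) {
    X[samples$individual == individuals[i], ind_cols[i]] <- 1
  }
  for (p in nonref) {
    X[samples$brain_part == p, paste0("part_", p)] <- 1
    if (has_interaction) {
      X[samples$brain_part == p & samples$species == species[2],
        paste0("sp2_part_", p)] <- 1
    }
  }
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; non-estimable coefficient(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(matrix = X, samples = samples, reference_part = reference_part,
         part_levels = parts, species_levels = species,
         individual_cols = ind_cols, part_cols = setNames(part_cols, nonref),
         interaction_cols = if (has_interaction) setNames(int_cols, nonref)
                            else setNames(character(), character()),
         rank = dec$rank),
    class = "design_matrix"
  )
}

#' @exportS3Method base::print
print.design_matrix <- function(x, ...) {
  cat("design_matrix: ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " coefficients (rank ", x$rank, ")\n", sep = "")
  cat("reference part:", x$reference_part, "\n")
  invisible(x)
}

# coefficient-space representation of the expression effect of `part` in
# `species` (relative to the reference part in the first species)
part_effect_weights <- function(design, part, species) {
  w <- setNames(numeric(ncol(design$matrix)), colnames(design$matrix))
  if (part != design$reference_part) {
    w[design$part_cols[[part]]] <- w[design$part_cols[[part]]] + 1
    if (length(design$interaction_cols) &&
        species == design$species_levels[2]) {
      w[design$interaction_cols[[part]]] <- w[design$interaction_cols[[part]]] + 1
    }
  }
  w
}

new_contrast_set <- function(mat, family) {
  structure(mat, family = family, class = "contrast_set")
}

#' Within-species part-versus-average contrasts
#'
#' One contrast per species and brain part: the part's expression effect minus
#' the mean effect of the remaining parts within that species. With 6 parts
#' and 2 species this yields the 12 contrasts of the first hypothesis family
#' (e.g. `CE-avg_Na`).
#'
#' @param design a [build_design()] result.
#' @return A `contrast_set`: coefficient x contrast matrix whose columns are
#'   the contrast weight vectors, with a per-column `family` attribute
#'   (`"within_species"`).
#' @export
within_species_contrasts <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  parts <- design$part_levels
  if (length(parts) < 2L) abort("need at least two parts for contrasts")
  cols <- list()
  for (s in design$species_levels) {
    for (p in parts) {
      others <- setdiff(parts, p)
      w <- part_effect_weights(design, p, s)
      for (q in others) {
        w <- w - part_effect_weights(design, q, s) / length(others)
      }
      cols[[paste0(p, "-avg_", s)]] <- w
    }
  }
  mat <- do.call(cbind, cols)
  new_contrast_set(mat, rep("within_species", ncol(mat)))
}

#' Between-species interaction contrasts
#'
#' One contrast per unordered pair of brain parts: the part-pair expression
#' difference in the first species minus the same difference in the second
#' species. With 6 parts this yields the 15 contrasts of the second hypothesis
#' family (e.g. `BSvCE_Na-BSvCE_Ve`). Each reduces to a +/-1 combination of
#' interaction columns.
#'
#' @param design a [build_design()] result.
#' @return A `contrast_set` with `family = "interaction"` columns; with a
#'   single species, an empty set with a warning.
#' @export
interaction_contrasts <- function(design) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(design$species_levels) < 2L) {
    warn("single species: no interaction contrasts")
    mat <- matrix(0, ncol(design$matrix), 0,
                  dimnames = list(colnames(design$matrix), character()))
    return(new_contrast_set(mat, character()))
  }
  parts <- design$part_levels
  s1 <- design$species_levels[1]
  s2 <- design$species_levels[2]
  cols <- list()
  for (i in seq_len(length(parts) - 1)) {
    for (j in (i + 1):length(parts)) {
      pi <- parts[i]
      pj <- parts[j]
      w <- (part_effect_weights(design, pi, s1) -
              part_effect_weights(design, pj, s1)) -
           (part_effect_weights(design, pi, s2) -
              part_effect_weights(design, pj, s2))
      cols[[paste0(pi, "v", pj, "_", s1, "-", pi, "v", pj, "_", s2)]] <- w
    }
  }
  mat <- do.call(cbind, cols)
  new_contrast_set(mat, rep("interaction", ncol(mat)))
}
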