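# broom-style tidiers for the result objects.

#' Tidy an array scan into its spot table
#'
#' @param x An [array_scan()].
#' @param ... Unused.
#' @return The spot tibble, with the scan identity as columns.
#' @method tidy array_scan
#' @export
tidy.array_scan <- function(x, ...) {
  mutate(x$spots, scan_id = x$scan_id, rna_id = x$rna_id, strand = x$strand,
         .before = 1)
}

#' One-row summary of an array scan
#'
#' @param x An [array_scan()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance array_scan
#' @export
glance.array_scan <- function(x, ...) {
  sp <- x$spots
  tibble(
    scan_id = x$scan_id, rna_id = x$rna_id, strand = x$strand,
    n_spots = nrow(sp), n_blocks = x$n_blocks,
    n_proteins = length(unique(sp$protein_id[!sp$is_control])),
    n_control_spots = sum(sp$is_control),
    n_flagged = sum(sp$flag < 0)
  )
}

#' Tidy a hit table
#'
#' @param x A `hit_table` from [call_hits()].
#' @param ... Unused.
#' @return A plain tibble of the hits with the scan identity as columns.
#' @method tidy hit_table
#' @export
tidy.hit_table <- function(x, ...) {
  out <- as_tibble(x)
  mutate(out, rna_id = attr(x, "rna_id"), strand = attr(x, "strand"),
         .before = 1)
}

#' One-row summary of a hit table
#'
#' @param x A `hit_table`.
#' @param ... Unused.
#' @return A one-row tibble with counts and the thresholds used.
#' @method glance hit_table
#' @export
glance.hit_table <- function(x, ...) {
  tibble(
    rna_id = attr(x, "rna_id"), strand = attr(x, "strand"),
    sense_specific = isTRUE(attr(x, "antisense_subtracted")),
    n_hits = nrow(x), n_tested = attr(x, "n_tested"),
    z_min = attr(x, "z_min"), fold_min = attr(x, "fold_min")
  )
}

#' Tidy an interaction matrix into long form
#'
#' @param x An `interaction_matrix` from [build_matrix()].
#' @param ... Unused.
#' @return Tibble `protein_id`, `rna_id`, `bound` (0/1).
#' @method tidy interaction_matrix
#' @export
tidy.interaction_matrix <- function(x, ...) {
  m <- x$matrix
  out <- tibble(
    protein_id = rep(rownames(m), times = ncol(m)),
    rna_id = rep(colnames(m), each = nrow(m)),
    bound = as.integer(m)
  )
  out
}

#' One-row summary of an interaction matrix
#'
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance interaction_matrix
#' @export
glance.interaction_matrix <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$matrix), n_rnas = ncol(x$matrix),
    n_interactions = sum(x$matrix), clustered = x$clustered
  )
}

#' One-row summary of a pipeline run
#'
#' @param x An `rbp_screen` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble of the headline counts.
#' @method glance rbp_screen
#' @export
glance.rbp_screen <- function(x, ...) {
  s <- x$summary
  tibble(
    n_incubations = s$n_incubations,
    n_proteins_tested = s$n_proteins_tested,
    n_any_binders = s$n_any_binders,
    n_sense_specific_interactions = s$n_sense_specific_interactions,
    n_common_binders = s$n_common_binders,
    z_min = x$params$z_min, fold_min = x$params$fold_min,
    min_frac = x$params$min_frac
  )
}
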