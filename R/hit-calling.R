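#' Call significant RNA-protein interactions on one scan
#'
#' Applies the dual filter used throughout the screen: a protein is a hit when
#' each of its duplicate spots shows signal over background at or above
#' `fold_min` (i.e. the minimum duplicate ratio passes) and its mean ratio
#' lies at least `z_min` standard deviations above the global array mean.
#' Both comparisons are inclusive.
#'
#' @param stats A `protein_stats` tibble with Z-scores set
#'   (see [quantify_scan()]).
#' @param z_min Z-score threshold (default 3.0).
#' @param fold_min Fold threshold on the minimum duplicate ratio (default 2.5).
#' @param rna_id,strand Scan identity; defaults to the attributes carried by
#'   `stats`.
#' @return A `hit_table`: the rows of `stats` passing both filters, with the
#'   thresholds, scan identity and number of proteins tested attached as
#'   attributes.
#' @seealso [sense_specific()], [build_matrix()], [common_binders()]
#' @export
#' @examples
#' s <- tibble::tibble(
#'   protein_id = c("STAU1", "weak"), protein_name = c("Staufen1", "weak"),
#'   n_spots = 2L, ratios = list(c(3.0, 3.38), c(1, 1.1)),
#'   mean_ratio = c(3.19, 1.05), min_ratio = c(3.0, 1.0),
#'   zscore = c(4.24, 0.1)
#' )
#' call_hits(s, rna_id = "TP53", strand = "sense")
call_hits <- function(stats, z_min = 3.0, fold_min = 2.5,
                      rna_id = NULL, strand = NULL) {
  check_number(z_min, "z_min", min = 0, strict = TRUE)
  check_number(fold_min, "fold_min", min = 0, strict = TRUE)
  if (!inherits(stats, "data.frame") ||
      !all(c("protein_id", "min_ratio", "zscore") %in% names(stats))) {
    stop_input("`stats` must have `protein_id`, `min_ratio` and `zscore` columns.")
  }
  if (anyNA(stats$zscore)) {
    stop_input("Z-scores are unset; run add_zscores() first.")
  }
  hits <- stats[stats$min_ratio >= fold_min & stats$zscore >= z_min, , drop = FALSE]
  structure(
    as_tibble(hits),
    class = c("hit_table", "tbl_df", "tbl", "data.frame"),
    rna_id = as.character(rna_id %||% attr(stats, "rna_id") %||% NA_character_),
    strand = as.character(strand %||% attr(stats, "strand") %||% NA_character_),
    z_min = z_min,
    fold_min = fold_min,
    n_tested = nrow(stats),
    antisense_subtracted = FALSE
  )
}

hit_ids <- function(tab) as.character(tab$protein_id)

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf(
    "<hit_table> rna: %s (%s)%s  %d hits / %d tested  [fold >= %g, Z >= %g]\n",
    attr(x, "rna_id"), attr(x, "strand"),
    if (isTRUE(attr(x, "antisense_subtracted"))) " sense-specific" else "",
    nrow(x), attr(x, "n_tested"), attr(x, "fold_min"), attr(x, "z_min")
  ))
  NextMethod()
}

#' Subtract antisense hits to keep sense-specific interactions
#'
#' Probing the antisense transcript of the same locus flags proteins that bind
#' RNA without sequence specificity; removing them from the sense hit list
#' leaves strand-specific interactions. Both tables must come from the same
#' RNA locus and have been called at the same thresholds.
#'
#' @param sense,antisense `hit_table`s for the two strands of one locus.
#' @return A `hit_table` with `sense`'s hits minus any protein present in
#'   `antisense`.
#' @export
sense_specific <- function(sense, antisense) {
  for (t in list(sense, antisense)) {
    if (!inherits(t, "hit_table")) stop_input("inputs must be hit_tables.")
  }
  ra <- attr(sense, "rna_id"); rb <- attr(antisense, "rna_id")
  if (!is.na(ra) && !is.na(rb) && ra != rb) {
    stop_input(sprintf("RNA locus mismatch: sense is '%s', antisense is '%s'.", ra, rb),
               class = "rbpscreen_pairing_error")
  }
  if (!identical(attr(sense, "z_min"), attr(antisense, "z_min")) ||
      !identical(attr(sense, "fold_min"), attr(antisense, "fold_min"))) {
    stop_input("sense and antisense tables were called at different thresholds.",
               class = "rbpscreen_pairing_error")
  }
  keep <- !hit_ids(sense) %in% hit_ids(antisense)
  out <- sense[keep, , drop = FALSE]
  attributes(out)[c("rna_id", "strand", "z_min", "fold_min", "n_tested")] <-
    attributes(sense)[c("rna_id", "strand", "z_min", "fold_min", "n_tested")]
  attr(out, "antisense_subtracted") <- TRUE
  class(out) <- class(sense)
  out
}

#' Build the binary protein x RNA interaction matrix
#'
#' Rows are the union of hit proteins over all tables (lexicographic order
#' before clustering), columns one per RNA in input order; a cell is 1 when
#' the protein is a hit for that RNA. Only proteins with at least one
#' interaction appear, so no row is all zero.
#'
#' @param tables List of `hit_table`s (typically sense-specific), one per RNA.
#' @return An `interaction_matrix` object.
#' @seealso [cluster_matrix()], [autoplot.interaction_matrix()]
#' @export
build_matrix <- function(tables) {
  if (!is.list(tables) || length(tables) == 0 ||
      !all(vapply(tables, inherits, logical(1), "hit_table"))) {
    stop_input("`tables` must be a non-empty list of hit_tables.")
  }
  rnas <- vapply(tables, function(t) as.character(attr(t, "rna_id")), character(1))
  if (anyNA(rnas)) stop_input("every hit_table must carry an rna_id.")
  if (anyDuplicated(rnas) > 0) {
    stop_input(sprintf("duplicate rna_id across tables: %s",
                       rnas[duplicated(rnas)][1]))
  }
  proteins <- sort(unique(unlist(lapply(tables, hit_ids))))
  m <- matrix(0L, nrow = length(proteins), ncol = length(rnas),
              dimnames = list(proteins, rnas))
  for (j in seq_along(tables)) {
    m[hit_ids(tables[[j]]), j] <- 1L
  }
  names_map <- unique(bind_rows(lapply(tables, function(t) {
    as_tibble(t)[c("protein_id", "protein_name")]
  })))
  structure(
    list(matrix = m, protein_names = names_map,
         row_order = NULL, col_order = NULL,
         row_hclust = NULL, col_hclust = NULL, clustered = FALSE),
    class = "interaction_matrix"
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf(
    "<interaction_matrix> %d proteins x %d RNAs, %d interactions%s\n",
    nrow(x$matrix), ncol(x$matrix), sum(x$matrix),
    if (x$clustered) " (clustered)" else ""
  ))
  invisible(x)
}

#' Extract the binary matrix
#'
#' @param x An `interaction_matrix`.
#' @param clustered Reorder rows/columns by the clustering if available.
#' @return An integer 0/1 matrix with protein rows and RNA columns.
#' @export
as_matrix <- function(x, clustered = FALSE) {
  if (!inherits(x, "interaction_matrix")) {
    stop_input("`x` must be an interaction_matrix.")
  }
  m <- x$matrix
  if (clustered && x$clustered) {
    m <- m[x$row_order, x$col_order, drop = FALSE]
  }
  m
}

# Jaccard distance between binary rows of m; two empty profiles are at
# distance 0 (stats::dist(method = "binary") returns NaN there).
jaccard_dist <- function(m) {
  inter <- tcrossprod(m)
  size <- rowSums(m)
  union <- outer(size, size, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Hierarchically cluster the interaction matrix
#'
#' Agglomerative clustering of both protein rows and RNA columns using the
#' Jaccard distance between binary interaction profiles and average linkage.
#' The input order is lexicographic, so output is deterministic; a dimension
#' of size one keeps the identity order.
#'
#' @param x An `interaction_matrix` from [build_matrix()].
#' @return `x` with `row_order`/`col_order` (and the `hclust` trees) set.
#' @export
cluster_matrix <- function(x) {
  if (!inherits(x, "interaction_matrix")) {
    stop_input("`x` must be an interaction_matrix.")
  }
  m <- x$matrix
  if (nrow(m) == 0) stop_input("cannot cluster an empty matrix.")
  if (nrow(m) >= 2) {
    x$row_hclust <- hclust(jaccard_dist(m), method = "average")
    x$row_order <- x$row_hclust$order
  } else {
    x$row_order <- seq_len(nrow(m))
  }
  if (ncol(m) >= 2) {
    x$col_hclust <- hclust(jaccard_dist(t(m)), method = "average")
    x$col_order <- x$col_hclust$order
  } else {
    x$col_order <- seq_len(ncol(m))
  }
  x$clustered <- TRUE
  x
}

#' Rank proteins by how many incubations they bind
#'
#' A "common binder" is a protein called significant in a large fraction of
#' all incubations (sense and antisense alike): with 10 loci probed on both
#' strands, at least 15 of the 20 scans at the default 75% cutoff. Such
#' proteins bind RNA broadly rather than specifically.
#'
#' @param tables List of `hit_table`s, one per incubation; the denominator is
#'   `length(tables)`.
#' @param min_frac Minimum fraction of incubations bound (default 0.75).
#' @return Tibble `protein_id`, `protein_name`, `n_bound`, `n_tables`,
#'   `percent`, sorted by `percent` descending then `protein_id`.
#' @export
common_binders <- function(tables, min_frac = 0.75) {
  if (!is.list(tables) || length(tables) == 0 ||
      !all(vapply(tables, inherits, logical(1), "hit_table"))) {
    stop_input("`tables` must be a non-empty list of hit_tables.")
  }
  check_number(min_frac, "min_frac", min = 0, strict = TRUE)
  n_tables <- length(tables)
  counts <- bind_rows(lapply(tables, function(t) {
    as_tibble(t)[c("protein_id", "protein_name")]
  })) |>
    group_by(.data$protein_id) |>
    summarise(protein_name = first(.data$protein_name),
              n_bound = dplyr::n(), .groups = "drop") |>
    mutate(n_tables = n_tables,
           percent = 100 * .data$n_bound / n_tables)
  out <- counts |>
    filter(.data$percent >= 100 * min_frac - 1e-9) |>
    arrange(desc(.data$percent), .data$protein_id)
  out
}

#' Write a hit table as TSV
#'
#' @param tab A `hit_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(tab, path) {
  flat <- as_tibble(tab)[c("protein_id", "protein_name", "n_spots",
                           "mean_ratio", "min_ratio", "zscore")]
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Write an interaction matrix as TSV
#'
#' Rows are proteins, columns RNAs, cells 0/1. If the matrix is clustered the
#' clustered order is written; the original lexicographic order is used
#' otherwise.
#'
#' @param x An `interaction_matrix`.
#' @param path Output path.
#' @param clustered Write in clustered order when available.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, clustered = TRUE) {
  m <- as_matrix(x, clustered = clustered)
  df <- as_tibble(as.data.frame(m), rownames = "protein_id")
  readr::write_tsv(df, path)
  invisible(path)
}
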