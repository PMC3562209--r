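#' Concordance between technical replicate scans
#'
#' Pearson correlation of the per-protein mean signal-over-background ratios
#' between two scans of the same layout, over all non-control proteins usable
#' in both (not just hits). This is the standard check that independent
#' incubations of the same labeled RNA rank proteins the same way.
#'
#' @param a,b [array_scan()]s (or spot data frames) with a shared layout.
#' @param flag_min Spot-quality cutoff passed to [aggregate_spots()].
#' @return A one-row tibble: `r`, `r_squared`, `n_proteins`.
#' @export
replicate_concordance <- function(a, b, flag_min = 0L) {
  sa <- aggregate_spots(a, flag_min = flag_min)
  sb <- aggregate_spots(b, flag_min = flag_min)
  shared <- inner_join(
    as_tibble(sa)[c("protein_id", "mean_ratio")],
    as_tibble(sb)[c("protein_id", "mean_ratio")],
    by = "protein_id", suffix = c("_a", "_b")
  )
  if (nrow(shared) < 3) {
    stop_input(sprintf(
      "need at least 3 shared usable proteins, found %d.", nrow(shared)
    ), class = "rbpscreen_insufficient_data_error")
  }
  if (sd(shared$mean_ratio_a) == 0 || sd(shared$mean_ratio_b) == 0) {
    stop_degenerate("zero variance in one replicate; correlation undefined.")
  }
  r <- cor(shared$mean_ratio_a, shared$mean_ratio_b)
  tibble(r = r, r_squared = r^2, n_proteins = nrow(shared))
}

#' Significance of the overlap between two hit sets
#'
#' One-sided Fisher exact test for over-representation: the probability, under
#' random draws from a universe of `universe_n` proteins, of an overlap at
#' least as large as observed between two sets of the given sizes. This is
#' the hypergeometric upper tail `P(X >= |a intersect b|)`.
#'
#' @param hits_a,hits_b Character vectors of protein IDs, or `hit_table`s /
#'   data frames with a `protein_id` column.
#' @param universe_n Number of proteins in the universe (e.g. all non-control
#'   proteins spotted on the array).
#' @return A single p-value.
#' @export
#' @examples
#' overlap_significance(letters[1:5], letters[1:5], universe_n = 10) # 1/252
overlap_significance <- function(hits_a, hits_b, universe_n) {
  a <- as_protein_ids(hits_a, "hits_a")
  b <- as_protein_ids(hits_b, "hits_b")
  check_number(universe_n, "universe_n", min = 1)
  n_union <- length(union(a, b))
  if (universe_n < n_union) {
    stop_input(sprintf(
      "universe (%d) smaller than the union of the hit sets (%d).",
      universe_n, n_union
    ))
  }
  k <- length(intersect(a, b))
  hyper_upper_tail(k, K = length(a), n = length(b), N = universe_n)
}

# P(X >= k) for X ~ Hypergeometric(N, K, n).
hyper_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotation-term enrichment of a hit set
#'
#' For each annotation term (protein family domain, GO category, ...) tests
#' whether the hit proteins carry the term more often than expected from the
#' universe of all spotted proteins, using the one-sided hypergeometric upper
#' tail, with Benjamini-Hochberg correction across all tested terms. The
#' optional EASE variant removes one hit from the term overlap before taking
#' the tail, giving a more conservative score (the default of the DAVID
#' service).
#'
#' Annotation rows whose protein is not in the universe are dropped and
#' reported via the `"unmapped"` attribute; terms with no annotated universe
#' protein are skipped.
#'
#' @param hits Character vector of hit protein IDs (or a `hit_table`); must be
#'   a subset of `universe`.
#' @param universe Character vector of all spotted protein IDs.
#' @param annotations Tibble with columns `term_id`, `protein_id` and
#'   optionally `term_name` (see [read_annotation_map()]), or a named list of
#'   protein-ID vectors.
#' @param ease Use the EASE variant (k - 1) instead of the plain
#'   hypergeometric tail.
#' @return Tibble `term_id`, `term_name`, `k` (hits with term), `K` (universe
#'   proteins with term), `n` (hit-set size), `N` (universe size), `p`,
#'   `p_adj`; sorted by `p` then `term_id`.
#' @export
term_enrichment <- function(hits, universe, annotations, ease = FALSE) {
  hits <- as_protein_ids(hits, "hits")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop_input("`universe` is empty.")
  extra <- setdiff(hits, universe)
  if (length(extra) > 0) {
    stop_input(sprintf("hits not in the universe: %s", compact_ids(extra)))
  }
  ann <- normalize_annotations(annotations)
  unmapped <- ann[!ann$protein_id %in% universe, , drop = FALSE]
  ann <- ann[ann$protein_id %in% universe, , drop = FALSE]

  N <- length(universe)
  n <- length(hits)
  res <- ann |>
    group_by(.data$term_id) |>
    summarise(
      term_name = first(.data$term_name),
      K = length(unique(.data$protein_id)),
      k = length(unique(intersect(.data$protein_id, hits))),
      .groups = "drop"
    )
  res$n <- n
  res$N <- N
  k_eff <- if (ease) pmax(res$k - 1L, 0L) else res$k
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    hyper_upper_tail(k_eff[i], K = res$K[i], n = n, N = N)
  }, numeric(1))
  res <- arrange(res, .data$p, .data$term_id)
  res$p_adj <- benjamini_hochberg(res$p)
  out <- res[c("term_id", "term_name", "k", "K", "n", "N", "p", "p_adj")]
  attr(out, "unmapped") <- unmapped
  if (nrow(unmapped) > 0) {
    inform(sprintf("%d annotation row(s) dropped (protein not in universe).",
                   nrow(unmapped)))
  }
  out
}

normalize_annotations <- function(annotations) {
  if (inherits(annotations, "data.frame")) {
    if (!all(c("term_id", "protein_id") %in% names(annotations))) {
      stop_input("`annotations` must have `term_id` and `protein_id` columns.")
    }
    ann <- as_tibble(annotations)
    if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
    ann$term_id <- as.character(ann$term_id)
    ann$protein_id <- as.character(ann$protein_id)
    distinct(ann[c("term_id", "term_name", "protein_id")])
  } else if (is.list(annotations) && !is.null(names(annotations))) {
    bind_rows(lapply(names(annotations), function(t) {
      tibble(term_id = t, term_name = t,
             protein_id = as.character(annotations[[t]]))
    }))
  } else {
    stop_input("`annotations` must be a data frame or a named list.")
  }
}

#' Read an annotation map from TSV
#'
#' The map is a two-column tab-separated table (`term_id`, `protein_id`), one
#' row per term membership — the flat form of a GMT gene-set file. An optional
#' second table supplies human-readable term labels.
#'
#' @param path Path to the 2-column TSV (a header row `term_id<TAB>protein_id`
#'   is detected and honoured).
#' @param labels_path Optional 2-column TSV (`term_id`, `term_name`).
#' @return Tibble `term_id`, `protein_id`, `term_name`.
#' @export
read_annotation_map <- function(path, labels_path = NULL) {
  ann <- readr::read_tsv(path, col_names = c("term_id", "protein_id"),
                         col_types = "cc", progress = FALSE)
  if (nrow(ann) > 0 && identical(tolower(ann$term_id[1]), "term_id")) {
    ann <- ann[-1, , drop = FALSE]
  }
  ann$term_name <- ann$term_id
  if (!is.null(labels_path)) {
    lab <- readr::read_tsv(labels_path, col_names = c("term_id", "term_name"),
                           col_types = "cc", progress = FALSE)
    if (nrow(lab) > 0 && identical(tolower(lab$term_id[1]), "term_id")) {
      lab <- lab[-1, , drop = FALSE]
    }
    ann$term_name <- NULL
    ann <- left_join(ann, lab, by = "term_id")
    ann$term_name <- dplyr::coalesce(ann$term_name, ann$term_id)
  }
  ann
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; input order is preserved.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the same order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
benjamini_hochberg <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop_input("p-values must be numbers in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}
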