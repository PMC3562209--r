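normalize_manifest <- function(manifest) {
  if (!inherits(manifest, "data.frame") || nrow(manifest) == 0) {
    stop_input("`manifest` must be a non-empty data frame.")
  }
  m <- as_tibble(manifest)
  if (!all(c("rna_id", "strand") %in% names(m))) {
    stop_input("`manifest` needs `rna_id` and `strand` columns.")
  }
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  if (!any(c("path", "scan") %in% names(m))) {
    stop_input("`manifest` needs a `path` or `scan` column.")
  }
  if (!all(m$strand %in% c("sense", "antisense"))) {
    stop_input('manifest `strand` must be "sense" or "antisense".')
  }
  key <- paste(m$rna_id, m$strand, m$replicate)
  if (anyDuplicated(key) > 0) {
    stop_input(sprintf("duplicate manifest entry: %s", key[duplicated(key)][1]))
  }
  no_sense <- setdiff(unique(m$rna_id), m$rna_id[m$strand == "sense"])
  if (length(no_sense) > 0) {
    stop_input(sprintf("locus without a sense scan: %s", compact_ids(no_sense)))
  }
  m
}

load_manifest_scan <- function(row, control_patterns) {
  scan <- if ("scan" %in% names(row) && !is.null(row$scan[[1]])) {
    row$scan[[1]]
  } else {
    if (!file.exists(row$path)) {
      stop_input(sprintf("scan file not readable: %s", row$path))
    }
    read_gpr(row$path, control_patterns = control_patterns)
  }
  if (!is_array_scan(scan)) stop_input("manifest `scan` entries must be array_scans.")
  # manifest identity wins over whatever the file header says
  scan$rna_id <- as.character(row$rna_id)
  scan$strand <- as.character(row$strand)
  scan
}

#' Run the screen pipeline end to end
#'
#' Reads (or receives) one scan per incubation, quantifies
#' signal-over-background per protein, calls hits with the dual fold/Z
#' filter, subtracts antisense hits per locus, assembles and clusters the
#' binary interaction matrix, and ranks common binders across all
#' incubations. Technical replicates of the same (locus, strand) contribute
#' replicate concordance and overlap significance; the lowest replicate tag
#' is used for hit calling.
#'
#' @param manifest Tibble with columns `rna_id`, `strand`
#'   (`"sense"`/`"antisense"`), one of `path` (GPR file) or `scan`
#'   (list-column of [array_scan()]s), and optionally `replicate`.
#'   Every locus needs a sense entry; a locus without an antisense scan keeps
#'   its raw sense hits with a warning.
#' @param z_min,fold_min Hit-calling thresholds (defaults 3.0 and 2.5).
#' @param min_frac Common-binder fraction (default 0.75).
#' @param control_patterns Passed to [read_gpr()].
#' @param annotations Optional annotation map (see [term_enrichment()]);
#'   when given, enrichment is computed for the set of proteins binding at
#'   least one incubation against the spotted-protein universe.
#' @param ease Use the EASE variant for enrichment.
#' @param out_dir Optional directory; when given, hit tables, the matrix,
#'   common binders and a JSON summary are written there.
#' @return An `rbp_screen` list: `hit_tables` (per incubation),
#'   `sense_specific` (per locus), `matrix` (clustered
#'   `interaction_matrix`), `common_binders`, `concordance`, `enrichment`,
#'   `stats` (per-incubation `protein_stats`), `params` and `summary`.
#' @export
run_pipeline <- function(manifest, z_min = 3.0, fold_min = 2.5,
                         min_frac = 0.75,
                         control_patterns = default_control_patterns(),
                         annotations = NULL, ease = FALSE, out_dir = NULL) {
  m <- normalize_manifest(manifest)
  m <- arrange(m, .data$rna_id, .data$strand, .data$replicate)

  stats_list <- list()
  hit_list <- list()
  for (i in seq_len(nrow(m))) {
    row <- m[i, , drop = FALSE]
    scan <- load_manifest_scan(row, control_patterns)
    key <- paste(row$rna_id, row$strand, row$replicate, sep = "_")
    st <- quantify_scan(scan, on_degenerate = "zero")
    stats_list[[key]] <- st
    hit_list[[key]] <- call_hits(st, z_min = z_min, fold_min = fold_min,
                                 rna_id = row$rna_id, strand = row$strand)
  }

  # primary table per incubation = lowest replicate tag
  prim <- m |>
    group_by(.data$rna_id, .data$strand) |>
    summarise(replicate = min(.data$replicate), .groups = "drop")
  prim_keys <- paste(prim$rna_id, prim$strand, prim$replicate, sep = "_")
  primary <- setNames(hit_list[prim_keys], paste(prim$rna_id, prim$strand, sep = "_"))

  # replicate concordance / overlap where a (locus, strand) has >= 2 scans
  concordance <- NULL
  rep_groups <- m |> count(.data$rna_id, .data$strand) |> filter(.data$n >= 2)
  if (nrow(rep_groups) > 0) {
    concordance <- bind_rows(lapply(seq_len(nrow(rep_groups)), function(i) {
      g <- m[m$rna_id == rep_groups$rna_id[i] & m$strand == rep_groups$strand[i], ]
      g <- arrange(g, .data$replicate)
      s1 <- load_manifest_scan(g[1, ], control_patterns)
      s2 <- load_manifest_scan(g[2, ], control_patterns)
      cc <- replicate_concordance(s1, s2)
      k1 <- paste(g$rna_id[1], g$strand[1], g$replicate[1], sep = "_")
      k2 <- paste(g$rna_id[2], g$strand[2], g$replicate[2], sep = "_")
      universe_n <- attr(hit_list[[k1]], "n_tested")
      tibble(
        rna_id = g$rna_id[1], strand = g$strand[1],
        r = cc$r, r_squared = cc$r_squared, n_proteins = cc$n_proteins,
        overlap = length(intersect(hit_ids(hit_list[[k1]]), hit_ids(hit_list[[k2]]))),
        overlap_p = overlap_significance(hit_list[[k1]], hit_list[[k2]], universe_n)
      )
    }))
  }

  # antisense subtraction per locus
  loci <- unique(prim$rna_id)
  sense_tables <- list()
  for (rna in loci) {
    s_key <- paste(rna, "sense", sep = "_")
    a_key <- paste(rna, "antisense", sep = "_")
    if (a_key %in% names(primary)) {
      sense_tables[[rna]] <- sense_specific(primary[[s_key]], primary[[a_key]])
    } else {
      warn(sprintf("locus %s has no antisense scan; using raw sense hits.", rna),
           class = "rbpscreen_no_antisense_warning")
      sense_tables[[rna]] <- primary[[s_key]]
    }
  }

  mat <- build_matrix(unname(sense_tables))
  if (nrow(mat$matrix) > 0) mat <- cluster_matrix(mat)
  binders <- common_binders(unname(primary), min_frac = min_frac)

  enrichment <- NULL
  if (!is.null(annotations)) {
    universe <- stats_list[[1]]$protein_id
    any_binders <- sort(unique(unlist(lapply(primary, hit_ids))))
    enrichment <- term_enrichment(any_binders, universe, annotations, ease = ease)
  }

  res <- structure(list(
    hit_tables = primary,
    all_hit_tables = hit_list,
    sense_specific = sense_tables,
    matrix = mat,
    common_binders = binders,
    concordance = concordance,
    enrichment = enrichment,
    stats = stats_list,
    params = list(z_min = z_min, fold_min = fold_min, min_frac = min_frac,
                  control_patterns = control_patterns, ease = ease)
  ), class = "rbp_screen")
  res$summary <- report_summary(res)

  if (!is.null(out_dir)) write_screen(res, out_dir)
  res
}

#' @export
print.rbp_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<rbp_screen> %d incubations, %d proteins tested\n",
           "  any-RNA binders: %d, sense-specific interactions: %d, ",
           "common binders (>= %g%%): %d\n"),
    s$n_incubations, s$n_proteins_tested, s$n_any_binders,
    s$n_sense_specific_interactions, 100 * x$params$min_frac, s$n_common_binders
  ))
  invisible(x)
}

#' Summarise a pipeline run
#'
#' Bookkeeping totals of a finished run: proteins tested, hits per
#' incubation, the number of proteins binding at least one incubation, the
#' sense-specific interaction count (the sum of the binary matrix), common
#' binders, and the thresholds used. The list is JSON-ready.
#'
#' @param res An `rbp_screen` from [run_pipeline()].
#' @param path Optional path; when given the summary is also written as JSON.
#' @return A named list, invisibly when `path` is given.
#' @export
report_summary <- function(res, path = NULL) {
  if (!inherits(res, "rbp_screen")) stop_input("`res` must be an rbp_screen.")
  hits_per_scan <- vapply(res$hit_tables, nrow, integer(1))
  out <- list(
    n_incubations = length(res$hit_tables),
    n_proteins_tested = attr(res$hit_tables[[1]], "n_tested"),
    hits_per_scan = as.list(hits_per_scan),
    n_any_binders = length(unique(unlist(lapply(res$hit_tables, hit_ids)))),
    n_sense_specific_interactions = sum(res$matrix$matrix),
    n_sense_specific_proteins = nrow(res$matrix$matrix),
    n_common_binders = nrow(res$common_binders),
    thresholds = res$params[c("z_min", "fold_min", "min_frac")]
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

write_screen <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(res$hit_tables)) {
    write_hit_table(res$hit_tables[[key]],
                    file.path(out_dir, paste0("hits_", key, ".tsv")))
  }
  for (rna in names(res$sense_specific)) {
    write_hit_table(res$sense_specific[[rna]],
                    file.path(out_dir, paste0("sense_specific_", rna, ".tsv")))
  }
  write_matrix(res$matrix, file.path(out_dir, "interaction_matrix.tsv"))
  readr::write_tsv(res$common_binders, file.path(out_dir, "common_binders.tsv"))
  if (!is.null(res$concordance)) {
    readr::write_tsv(res$concordance, file.path(out_dir, "replicate_concordance.tsv"))
  }
  if (!is.null(res$enrichment)) {
    readr::write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  report_summary(res, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension) with fields `manifest` (list of records with
#' `rna_id`, `strand`, `path`, optional `replicate`), optional `thresholds`
#' (`z_min`, `fold_min`, `min_frac`), `control_patterns`, `annotation_path`,
#' `annotation_labels_path` and `out_dir`.
#'
#' @param path Path to the config file.
#' @return A list with a `manifest` tibble and the remaining settings, ready
#'   to splice into [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading YAML configs requires the 'yaml' package.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (is.null(cfg$manifest)) stop_input("config must contain a `manifest`.")
  manifest <- as_tibble(if (inherits(cfg$manifest, "data.frame")) {
    cfg$manifest
  } else {
    bind_rows(lapply(cfg$manifest, as_tibble))
  })
  th <- cfg$thresholds %||% list()
  list(
    manifest = manifest,
    z_min = th$z_min %||% 3.0,
    fold_min = th$fold_min %||% 2.5,
    min_frac = th$min_frac %||% 0.75,
    control_patterns = unlist(cfg$control_patterns) %||% default_control_patterns(),
    annotation_path = cfg$annotation_path,
    annotation_labels_path = cfg$annotation_labels_path,
    out_dir = cfg$out_dir
  )
}
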