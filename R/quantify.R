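#' Signal-over-background ratio of a spot
#'
#' The primary quantity of the screen: the 635 nm foreground median divided by
#' the local background median. Non-binding proteins sit near 1; RNA-bound
#' features are elevated.
#'
#' @param f635,b635 Numeric vectors of foreground and background intensities.
#' @return `f635 / b635`.
#' @export
#' @examples
#' spot_ratio(2500, 1000)
spot_ratio <- function(f635, b635) {
  if (!is.numeric(f635) || !is.numeric(b635)) {
    stop_input("`f635` and `b635` must be numeric.")
  }
  if (any(!is.finite(b635)) || any(b635 <= 0)) {
    stop_degenerate("background intensity must be > 0 to form a ratio.")
  }
  if (any(!is.finite(f635)) || any(f635 < 0)) {
    stop_input("`f635` must be finite and >= 0.")
  }
  f635 / b635
}

#' Aggregate duplicate spots into per-protein statistics
#'
#' Computes one signal-over-background ratio per usable spot (quality flag
#' >= `flag_min` and positive background) and summarises each non-control
#' protein by the arithmetic mean and the minimum over its duplicates. The
#' minimum is what the dual significance filter thresholds ("each duplicate"
#' above the fold cutoff); the mean is what the Z-score standardizes.
#'
#' Spots excluded by flag or degenerate background, and proteins left with no
#' usable spot, are recorded in the `"report"` attribute.
#'
#' @param scan An [array_scan()] or spot data frame.
#' @param flag_min Minimum scanner flag for a spot to be used (default 0:
#'   negative-flagged spots are dropped).
#' @return A `protein_stats` tibble: `protein_id`, `protein_name`, `n_spots`,
#'   `ratios` (list-column), `mean_ratio`, `min_ratio`, `zscore` (`NA` until
#'   [add_zscores()]).
#' @seealso [add_zscores()], [quantify_scan()]
#' @export
aggregate_spots <- function(scan, flag_min = 0L) {
  sp <- scan_spots(scan, "scan")
  sp <- sp[!sp$is_control, , drop = FALSE]
  if (nrow(sp) == 0) stop_input("scan contains no non-control protein spots.")
  usable <- sp$flag >= flag_min & sp$b635 > 0
  report <- list(
    flagged_spots = sp[sp$flag < flag_min, c("protein_id", "block", "row", "column", "flag")],
    degenerate_background = sp[sp$flag >= flag_min & sp$b635 <= 0,
                               c("protein_id", "block", "row", "column", "b635")]
  )
  all_ids <- unique(sp$protein_id)
  sp <- sp[usable, , drop = FALSE]
  dropped <- setdiff(all_ids, unique(sp$protein_id))
  report$dropped_proteins <- dropped
  if (length(dropped) > 0) {
    warn(sprintf("%d protein(s) dropped (no usable spot): %s",
                 length(dropped), compact_ids(dropped)),
         class = "rbpscreen_dropped_warning")
  }
  if (nrow(sp) == 0) stop_input("no usable spots remain after filtering.")

  sp <- arrange(sp, .data$protein_id, .data$block, .data$row, .data$column)
  sp$ratio <- spot_ratio(sp$f635, sp$b635)
  # rows are sorted by protein, so grouped summaries reduce to split/rowsum
  grp <- factor(sp$protein_id, levels = unique(sp$protein_id))
  ratios <- split(sp$ratio, grp)
  n_spots <- lengths(ratios)
  first_row <- !duplicated(sp$protein_id)
  stats <- tibble(
    protein_id = sp$protein_id[first_row],
    protein_name = sp$protein_name[first_row],
    n_spots = as.integer(n_spots),
    ratios = unname(ratios),
    mean_ratio = unname(as.vector(rowsum(sp$ratio, grp, reorder = FALSE)) / n_spots),
    min_ratio = unname(vapply(ratios, min, numeric(1))),
    zscore = NA_real_
  )
  structure(
    stats,
    class = c("protein_stats", class(stats)),
    scan_id = if (is_array_scan(scan)) scan$scan_id else NA_character_,
    rna_id = if (is_array_scan(scan)) scan$rna_id else NA_character_,
    strand = if (is_array_scan(scan)) scan$strand else NA_character_,
    report = report
  )
}

#' Standardize mean ratios into global Z-scores
#'
#' The Z-score of a protein is the number of standard deviations its mean
#' signal-over-background ratio lies from the global mean over all spotted
#' (non-control) proteins on the same array: `z = (mean_ratio - mu) / s` with
#' `s` the sample (n-1) standard deviation. By construction the scores have
#' mean 0 and sample SD 1.
#'
#' @param stats A `protein_stats` tibble from [aggregate_spots()].
#' @param on_degenerate What to do when all mean ratios are equal (`s` = 0):
#'   `"error"` (default) or `"zero"`, which sets all Z-scores to 0 with a
#'   warning so that a perfectly flat null array flows through hit calling
#'   and yields no hits.
#' @return `stats` with `zscore` filled in; the global mean and SD are
#'   attached as attributes `"mu"` and `"sigma"`.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   protein_id = letters[1:4], protein_name = letters[1:4], n_spots = 2L,
#'   ratios = as.list(c(1, 1, 1, 4)), mean_ratio = c(1, 1, 1, 4),
#'   min_ratio = c(1, 1, 1, 4), zscore = NA_real_
#' )
#' add_zscores(s)$zscore
add_zscores <- function(stats, on_degenerate = c("error", "zero")) {
  on_degenerate <- match.arg(on_degenerate)
  if (!inherits(stats, "data.frame") || !"mean_ratio" %in% names(stats)) {
    stop_input("`stats` must be a protein_stats data frame with `mean_ratio`.")
  }
  x <- stats$mean_ratio
  if (length(x) < 2) stop_input("need at least 2 proteins to standardize.")
  mu <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    if (on_degenerate == "error") {
      stop_degenerate("all mean ratios are equal; Z-scores are undefined (SD = 0).")
    }
    warn("all mean ratios are equal; Z-scores set to 0.",
         class = "rbpscreen_degenerate_warning")
    z <- rep(0, length(x))
  } else {
    z <- (x - mu) / s
  }
  out <- stats
  out$zscore <- z
  attr(out, "mu") <- mu
  attr(out, "sigma") <- s
  out
}

#' Quantify one scan: ratios, duplicate aggregation, Z-scores
#'
#' Convenience wrapper: [aggregate_spots()] followed by [add_zscores()].
#'
#' @inheritParams aggregate_spots
#' @inheritParams add_zscores
#' @return A `protein_stats` tibble with Z-scores set.
#' @export
quantify_scan <- function(scan, flag_min = 0L,
                          on_degenerate = c("error", "zero")) {
  add_zscores(aggregate_spots(scan, flag_min = flag_min),
              on_degenerate = on_degenerate)
}

#' Export per-protein statistics as TSV
#'
#' Flattens the duplicate ratios into `ratio_spot1`, `ratio_spot2`, ...
#' columns and writes a tab-separated table.
#'
#' @param stats A `protein_stats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_stats <- function(stats, path) {
  k <- max(stats$n_spots)
  wide <- as_tibble(stats[c("protein_id", "protein_name", "n_spots")])
  for (i in seq_len(k)) {
    wide[[paste0("ratio_spot", i)]] <-
      vapply(stats$ratios, function(r) if (length(r) >= i) r[i] else NA_real_,
             numeric(1))
  }
  wide$mean_ratio <- stats$mean_ratio
  wide$min_ratio <- stats$min_ratio
  wide$zscore <- stats$zscore
  readr::write_tsv(wide, path)
  invisible(path)
}
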