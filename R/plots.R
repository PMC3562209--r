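# ggplot2 figures for the three result views a screen report needs:
# the per-array ratio distribution, the replicate scatter, and the binary
# interaction heat map.

#' Plot the signal-over-background distribution of one array
#'
#' Histogram of per-protein mean ratios with the global mean, the Z-score
#' threshold line (mean + z_min * sd) and the fold cutoff marked. The bulk of
#' non-binding proteins sits at ratio ~1; hits live in the sparse right tail.
#'
#' @param stats A `protein_stats` tibble with Z-scores
#'   (see [quantify_scan()]).
#' @param z_min,fold_min Thresholds to mark (defaults 3.0 and 2.5).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_ratio_distribution <- function(stats, z_min = 3.0, fold_min = 2.5,
                                    bins = 100) {
  mu <- attr(stats, "mu") %||% mean(stats$mean_ratio)
  s <- attr(stats, "sigma") %||% sd(stats$mean_ratio)
  ggplot2::ggplot(as_tibble(stats), ggplot2::aes(x = .data$mean_ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = mu, colour = "blue") +
    ggplot2::geom_vline(xintercept = mu + z_min * s, colour = "blue",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = fold_min, colour = "red") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(
      x = "mean signal / background ratio",
      y = "proteins",
      title = "Per-protein ratio distribution",
      subtitle = sprintf("mean %.3f; dashed: Z = %g; red: %g-fold cutoff",
                         mu, z_min, fold_min)
    )
}

#' Scatter plot of two technical replicates
#'
#' Per-protein mean ratios of one scan against the other, annotated with the
#' Pearson r-squared over all shared usable proteins.
#'
#' @param a,b [array_scan()]s of the same layout.
#' @return A ggplot object.
#' @export
plot_replicate_concordance <- function(a, b) {
  sa <- aggregate_spots(a)
  sb <- aggregate_spots(b)
  shared <- inner_join(
    as_tibble(sa)[c("protein_id", "mean_ratio")],
    as_tibble(sb)[c("protein_id", "mean_ratio")],
    by = "protein_id", suffix = c("_a", "_b")
  )
  cc <- replicate_concordance(a, b)
  ggplot2::ggplot(shared, ggplot2::aes(x = .data$mean_ratio_a,
                                       y = .data$mean_ratio_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::annotate("text", x = Inf, y = -Inf, hjust = 1.1, vjust = -0.5,
                      label = sprintf("r² = %.3f", cc$r_squared)) +
    ggplot2::labs(x = "replicate 1 mean ratio", y = "replicate 2 mean ratio",
                  title = "Replicate concordance")
}

#' Binary heat map of the interaction matrix
#'
#' Proteins in rows, RNAs in columns, filled where the protein is a
#' sense-specific hit; rows and columns follow the clustering order when the
#' matrix has been through [cluster_matrix()].
#'
#' @param object An `interaction_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_matrix
#' @export
autoplot.interaction_matrix <- function(object, ...) {
  m <- as_matrix(object, clustered = TRUE)
  long <- tidy.interaction_matrix(list(matrix = m))
  long$protein_id <- factor(long$protein_id, levels = rev(rownames(m)))
  long$rna_id <- factor(long$rna_id, levels = colnames(m))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rna_id, y = .data$protein_id,
                                     fill = factor(.data$bound))) +
    ggplot2::geom_tile(colour = NA) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "red3"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d sense-specific interactions",
                                  sum(m))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   panel.grid = ggplot2::element_blank())
}
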