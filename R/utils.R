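# Internal helpers: error classes, seed derivation, small checks.

stop_format <- function(msg, class = NULL) {
  abort(msg, class = c(class, "rbpscreen_format_error"))
}

stop_input <- function(msg, class = NULL) {
  abort(msg, class = c(class, "rbpscreen_input_error"))
}

stop_param <- function(msg, class = NULL) {
  abort(msg, class = c(class, "rbpscreen_parameter_error"))
}

stop_degenerate <- function(msg, class = NULL) {
  abort(msg, class = c(class, "rbpscreen_degenerate_error"))
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > min else x >= min
  if (!ok) {
    stop_param(sprintf(
      "`%s` must be %s %s (got %g).", name, if (strict) ">" else ">=", min, x
    ))
  }
  invisible(x)
}

# Deterministic 31-bit seed from a base seed and a character tag, so each
# simulated scan has its own reproducible random substream. All arithmetic
# stays well below 2^53, and the result below 2^31.
derive_seed <- function(seed, tag) {
  m <- 2147483563
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m + h * 97) %% m)
}

compact_ids <- function(ids, max_show = 8L) {
  if (length(ids) <= max_show) return(paste(ids, collapse = ", "))
  paste0(paste(head(ids, max_show), collapse = ", "),
         ", ... (", length(ids), " total)")
}

as_protein_ids <- function(x, arg = "hits") {
  if (inherits(x, "data.frame")) {
    if (!"protein_id" %in% names(x)) {
      stop_input(sprintf("`%s` data frame must have a `protein_id` column.", arg))
    }
    unique(as.character(x$protein_id))
  } else if (is.character(x)) {
    unique(x)
  } else {
    stop_input(sprintf("`%s` must be a character vector or a data frame with `protein_id`.", arg))
  }
}
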