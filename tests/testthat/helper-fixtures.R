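# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A hand-written 8-spot GPR file: 3 proteins in duplicate + 2 control spots.
gpr_fixture_lines <- function() {
  c(
    "ATF\t1.0",
    "2\t8",
    '"Type=GenePix Results 3"',
    '"Scanner=test"',
    paste('"Block"', '"Row"', '"Column"', '"ID"', '"Name"',
          '"F635 Median"', '"B635 Median"', '"Flags"', sep = "\t"),
    "1\t1\t1\t\"P1\"\t\"protein one\"\t900\t300\t0",
    "1\t1\t2\t\"P1\"\t\"protein one\"\t960\t320\t0",
    "1\t1\t3\t\"P2\"\t\"protein two\"\t510\t500\t0",
    "1\t1\t4\t\"P2\"\t\"protein two\"\t490\t490\t0",
    "1\t2\t1\t\"P3\"\t\"protein three\"\t2500\t1000\t0",
    "1\t2\t2\t\"P3\"\t\"protein three\"\t2600\t1000\t-100",
    "1\t2\t3\t\"CTRL1\"\t\"Positive Control\"\t60000\t400\t0",
    "1\t2\t4\t\"CTRL1\"\t\"Positive Control\"\t60000\t410\t0"
  )
}

write_gpr_fixture <- function(lines = gpr_fixture_lines()) {
  path <- withr::local_tempfile(fileext = ".gpr",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# protein_stats row builder for hit-calling tests
make_stats <- function(ratios_list, zscores = NULL, ids = NULL) {
  n <- length(ratios_list)
  ids <- ids %||% sprintf("P%02d", seq_len(n))
  tibble::tibble(
    protein_id = ids,
    protein_name = ids,
    n_spots = lengths(ratios_list),
    ratios = ratios_list,
    mean_ratio = vapply(ratios_list, mean, numeric(1)),
    min_ratio = vapply(ratios_list, min, numeric(1)),
    zscore = zscores %||% rep(NA_real_, n)
  )
}

make_hit_table <- function(ids, rna_id, strand = "sense",
                           z_min = 3, fold_min = 2.5, n_tested = 100L) {
  stats <- make_stats(rep(list(c(5, 5)), length(ids)),
                      zscores = rep(10, length(ids)), ids = ids)
  call_hits(stats, z_min = z_min, fold_min = fold_min,
            rna_id = rna_id, strand = strand)
}

# a scan built directly from per-protein duplicate ratios (background 100)
scan_from_ratios <- function(ratios, rna_id = "TP53", strand = "sense",
                             scan_id = "fx") {
  n <- length(ratios)
  ids <- names(ratios) %||% sprintf("P%02d", seq_len(n))
  spots <- tibble::tibble(
    block = 1L,
    row = rep(seq_len(n), each = 2),
    column = rep(1:2, n),
    protein_id = rep(ids, each = 2),
    protein_name = rep(ids, each = 2),
    f635 = 100 * rep(unname(ratios), each = 2),
    b635 = 100,
    flag = 0L,
    is_control = FALSE
  )
  array_scan(spots, scan_id = scan_id, rna_id = rna_id, strand = strand)
}

# tiny simulation config used wherever full scale is not the point
small_sim_config <- function(seed = 42, ...) {
  sim_config(n_proteins = 400, n_blocks = 4, n_rnas = 3,
             n_planted = 12, n_shared = 5, shared_loci_range = c(2, 3),
             seed = seed, ...)
}

manifest_from_experiment <- function(ex) {
  tibble::tibble(
    rna_id = vapply(ex$scans, function(s) s$rna_id, character(1)),
    strand = vapply(ex$scans, function(s) s$strand, character(1)),
    scan = unname(ex$scans)
  )
}

interactions_of <- function(res) {
  df <- tidy(res$matrix)
  df[df$bound == 1, , drop = FALSE]
}

# brute-force hypergeometric upper tail via log-binomials (independent oracle)
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- k:hi
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}
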