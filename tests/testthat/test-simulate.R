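no_truth <- function(...) {
  small_sim_config(
    planted = tibble::tibble(protein_id = character(0), rna_id = character(0),
                             strand = character(0), fold = numeric(0)),
    shared_nonspecific = tibble::tibble(protein_id = character(0),
                                        rna_id = character(0),
                                        fold = numeric(0)),
    ...
  )
}

test_that("a noise-free null scan has every non-control ratio exactly 1", {
  cfg <- no_truth(nonspecific_log_sd = 0, duplicate_log_sd = 0)
  sim <- simulate_scan(cfg, "TP53", "sense")
  st <- aggregate_spots(sim$scan)
  expect_true(all(vapply(st$ratios, function(r) all(r == 1), logical(1))))
  # flows through hit calling with zero hits
  expect_warning(z <- add_zscores(st, on_degenerate = "zero"),
                 class = "rbpscreen_degenerate_warning")
  expect_equal(nrow(call_hits(z, rna_id = "TP53", strand = "sense")), 0)
  expect_equal(sim$expected_hits, character(0))
})

test_that("a single planted interaction is the sole hit at low noise", {
  cfg <- no_truth(nonspecific_log_sd = 0.02, duplicate_log_sd = 0)
  cfg$planted <- tibble::tibble(protein_id = "PROT_00042", rna_id = "TP53",
                                strand = "sense", fold = 8)
  sense <- simulate_scan(cfg, "TP53", "sense")
  hits <- call_hits(quantify_scan(sense$scan), rna_id = "TP53", strand = "sense")
  expect_equal(hits$protein_id, "PROT_00042")
  expect_equal(sense$expected_hits, "PROT_00042")
  # the antisense scan of the same locus is clean
  anti <- simulate_scan(cfg, "TP53", "antisense")
  expect_equal(anti$expected_hits, character(0))
})

test_that("simulation is deterministic: same seed gives byte-identical GPR", {
  cfg <- small_sim_config()
  p1 <- withr::local_tempfile(fileext = ".gpr")
  p2 <- withr::local_tempfile(fileext = ".gpr")
  write_gpr(simulate_scan(cfg, "TP53", "sense")$scan, p1)
  write_gpr(simulate_scan(cfg, "TP53", "sense")$scan, p2)
  expect_identical(readLines(p1), readLines(p2))
  # different strand or replicate -> different noise
  s_rep <- simulate_scan(cfg, "TP53", "sense", replicate = 2)$scan
  expect_false(identical(s_rep$spots$f635,
                         simulate_scan(cfg, "TP53", "sense")$scan$spots$f635))
})

test_that("planted config validation catches out-of-range proteins and folds", {
  expect_error(
    small_sim_config(planted = tibble::tibble(
      protein_id = "PROT_99999", rna_id = "TP53", strand = "sense", fold = 4
    )),
    class = "rbpscreen_parameter_error"
  )
  expect_error(
    small_sim_config(planted = tibble::tibble(
      protein_id = "PROT_00001", rna_id = "TP53", strand = "sense", fold = 0.9
    )),
    class = "rbpscreen_parameter_error"
  )
})

test_that("shared non-specific binders appear on both strands and cancel out", {
  cfg <- no_truth(nonspecific_log_sd = 0.02)
  cfg$planted <- tibble::tibble(protein_id = "PROT_00010", rna_id = "MYC",
                                strand = "sense", fold = 6)
  cfg$shared_nonspecific <- tibble::tibble(protein_id = "PROT_00020",
                                           rna_id = "MYC", fold = 6)
  ex <- simulate_experiment(cfg)
  res <- run_pipeline(manifest_from_experiment(ex))
  found <- interactions_of(res)
  expect_equal(found$protein_id, "PROT_00010")
  expect_equal(found$rna_id, "MYC")
  # the shared binder was a hit on both strands before subtraction
  expect_true("PROT_00020" %in% res$hit_tables[["MYC_sense"]]$protein_id)
  expect_true("PROT_00020" %in% res$hit_tables[["MYC_antisense"]]$protein_id)
})

test_that("a protein planted on both strands is absent from the matrix", {
  cfg <- no_truth(nonspecific_log_sd = 0.02)
  cfg$planted <- tibble::tibble(
    protein_id = c("PROT_00010", "PROT_00010"), rna_id = "MYC",
    strand = c("sense", "antisense"), fold = 6
  )
  ex <- simulate_experiment(cfg)
  expect_equal(nrow(ex$truth$interactions), 0)
  res <- run_pipeline(manifest_from_experiment(ex))
  expect_equal(nrow(interactions_of(res)), 0)
})

test_that("planted folds are recoverable from mean ratios at low noise", {
  cfg <- small_sim_config(nonspecific_log_sd = 0.05, duplicate_log_sd = 0.05)
  cfg <- rbpscreen:::materialize_truth(cfg)
  sense_truth <- cfg$planted[cfg$planted$rna_id == "TP53" &
                               cfg$planted$strand == "sense", ]
  st <- aggregate_spots(simulate_scan(cfg, "TP53", "sense")$scan)
  est <- st$mean_ratio[match(sense_truth$protein_id, st$protein_id)]
  rel_err <- abs(est - sense_truth$fold) / sense_truth$fold
  expect_true(median(rel_err) < 0.10)
  expect_true(mean(rel_err < 0.10) >= 0.75)
})

test_that("two simulated technical replicates are strongly concordant", {
  cfg <- sim_config(n_proteins = 2000, n_blocks = 12, n_rnas = 3,
                    n_planted = 40, n_shared = 8, shared_loci_range = c(2, 3),
                    nonspecific_log_sd = 0.1, seed = 19)
  r1 <- simulate_scan(cfg, "HRAS", "sense", replicate = 1)$scan
  r2 <- simulate_scan(cfg, "HRAS", "sense", replicate = 2)$scan
  cc <- replicate_concordance(r1, r2)
  expect_gt(cc$r_squared, 0.8)
})

test_that("null Z-score exceedances match the tail mass of the ratio distribution", {
  # with nothing planted, the fraction of proteins with Z >= 3 should equal
  # the mass of the pooled mean-ratio distribution beyond mu + 3 sd
  ratios <- c()
  n_exceed <- 0
  for (seed in 1:20) {
    cfg <- no_truth(seed = seed)
    st <- quantify_scan(simulate_scan(cfg, "TP53", "sense")$scan)
    ratios <- c(ratios, st$mean_ratio)
    n_exceed <- n_exceed + sum(st$zscore >= 3)
  }
  pooled_tail <- mean(ratios >= mean(ratios) + 3 * sd(ratios))
  frac_exceed <- n_exceed / length(ratios)
  se <- sqrt(pooled_tail * (1 - pooled_tail) / length(ratios))
  expect_lt(abs(frac_exceed - pooled_tail), 4 * se + 1e-4)
})

test_that("write_experiment emits readable GPRs, a truth table and a manifest", {
  cfg <- no_truth(nonspecific_log_sd = 0.02)
  cfg$planted <- tibble::tibble(protein_id = "PROT_00005", rna_id = "TP53",
                                strand = "sense", fold = 5)
  dir <- withr::local_tempdir()
  manifest <- write_experiment(simulate_experiment(cfg), dir)
  expect_equal(nrow(manifest), 6)  # 3 loci x 2 strands
  back <- read_gpr(manifest$path[manifest$rna_id == "TP53" &
                                   manifest$strand == "sense"])
  expect_equal(back$rna_id, "TP53")
  expect_equal(nrow(back$spots),
               2 * (cfg$n_proteins + cfg$n_blocks * cfg$controls_per_block))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(truth$protein_id, "PROT_00005")
  # and the pipeline runs off the files on disk
  res <- run_pipeline(manifest)
  expect_equal(interactions_of(res)$protein_id, "PROT_00005")
})
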