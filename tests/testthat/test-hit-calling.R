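test_that("the dual filter requires every duplicate >= fold and Z >= cutoff", {
  st <- make_stats(
    list(c(3.0, 3.38),   # the validated interaction profile: mean 3.19
         c(2.4, 9.0),    # one duplicate below fold
         c(5.0, 5.0),    # Z below cutoff
         c(2.5, 2.5)),   # exactly at both thresholds: inclusive
    zscores = c(4.24, 10, 2.9, 3.0),
    ids = c("STAU1", "loud_single", "low_z", "boundary")
  )
  hits <- call_hits(st, rna_id = "TP53", strand = "sense")
  expect_setequal(hits$protein_id, c("STAU1", "boundary"))
  expect_equal(attr(hits, "z_min"), 3.0)
  expect_equal(attr(hits, "fold_min"), 2.5)
  expect_equal(attr(hits, "n_tested"), 4)

  expect_error(call_hits(st, z_min = 0), class = "rbpscreen_parameter_error")
  expect_error(call_hits(st, fold_min = -1), class = "rbpscreen_parameter_error")
  expect_error(call_hits(make_stats(list(c(1, 1)))),
               regexp = "Z-scores", class = "rbpscreen_input_error")
})

test_that("raising either threshold never adds a hit (monotonicity)", {
  set.seed(5)
  st <- make_stats(lapply(1:60, function(i) runif(2, 0.5, 6)),
                   zscores = rnorm(60, 0, 3))
  base <- call_hits(st)
  for (dz in c(0.5, 1, 2)) {
    expect_true(all(call_hits(st, z_min = 3 + dz)$protein_id %in% base$protein_id))
    expect_true(all(call_hits(st, fold_min = 2.5 + dz)$protein_id %in% base$protein_id))
  }
})

test_that("antisense subtraction keeps sense-only hits", {
  sense <- make_hit_table(c("A", "B", "C"), rna_id = "MYC")
  anti <- make_hit_table("B", rna_id = "MYC", strand = "antisense")
  ss <- sense_specific(sense, anti)
  expect_setequal(ss$protein_id, c("A", "C"))
  expect_true(attr(ss, "antisense_subtracted"))
  expect_equal(attr(ss, "strand"), "sense")

  # antisense empty -> unchanged; sense subset of antisense -> empty
  empty <- make_hit_table(character(0), rna_id = "MYC", strand = "antisense")
  expect_setequal(sense_specific(sense, empty)$protein_id, c("A", "B", "C"))
  all_anti <- make_hit_table(c("A", "B", "C", "D"), rna_id = "MYC",
                             strand = "antisense")
  expect_equal(nrow(sense_specific(sense, all_anti)), 0)
  # self-subtraction is empty
  expect_equal(nrow(sense_specific(sense, sense)), 0)

  # mismatched locus or thresholds refuse to pair
  other <- make_hit_table("B", rna_id = "HRAS", strand = "antisense")
  expect_error(sense_specific(sense, other), class = "rbpscreen_pairing_error")
  loose <- make_hit_table("B", rna_id = "MYC", strand = "antisense", z_min = 2)
  expect_error(sense_specific(sense, loose), class = "rbpscreen_pairing_error")
})

test_that("the binary matrix unions hits with no all-zero rows", {
  t1 <- make_hit_table(c("A", "B"), rna_id = "R1")
  t2 <- make_hit_table(c("B", "C"), rna_id = "R2")
  im <- build_matrix(list(t1, t2))
  m <- as_matrix(im)
  expect_equal(dim(m), c(3, 2))
  expect_equal(sum(m), 4)
  expect_equal(rownames(m), c("A", "B", "C"))  # lexicographic before clustering
  expect_equal(unname(m["B", ]), c(1L, 1L))
  expect_true(all(rowSums(m) >= 1))
  # column sums = per-RNA hit counts
  expect_equal(unname(colSums(m)), c(2, 2))

  empty <- build_matrix(list(make_hit_table(character(0), rna_id = "R1")))
  expect_equal(dim(as_matrix(empty)), c(0, 1))

  expect_error(build_matrix(list(t1, make_hit_table("X", rna_id = "R1"))),
               regexp = "duplicate", class = "rbpscreen_input_error")
  expect_error(build_matrix(list()), class = "rbpscreen_input_error")
})

test_that("clustering orders identical profiles together, deterministically", {
  tabs <- list(
    make_hit_table(c("A", "B", "Z"), rna_id = "R1"),
    make_hit_table(c("A", "B"), rna_id = "R2"),
    make_hit_table(c("Q"), rna_id = "R3")
  )
  im <- cluster_matrix(build_matrix(tabs))
  expect_true(im$clustered)
  m <- as_matrix(im, clustered = TRUE)
  # A and B have identical profiles -> adjacent after clustering
  expect_equal(abs(diff(match(c("A", "B"), rownames(m)))), 1)
  # identical input -> identical output
  im2 <- cluster_matrix(build_matrix(tabs))
  expect_equal(im2$row_order, im$row_order)
  expect_equal(im2$col_order, im$col_order)

  # permuting the table order permutes columns but yields the same clustering
  im3 <- cluster_matrix(build_matrix(tabs[c(2, 3, 1)]))
  m3 <- as_matrix(im3, clustered = TRUE)
  expect_equal(m3[rownames(m), colnames(m)], m)

  # distinct orthogonal rows: all merge heights positive
  expect_true(all(im$row_hclust$height[im$row_hclust$height > 0] > 0))
  ortho <- cluster_matrix(build_matrix(list(
    make_hit_table("A", rna_id = "R1"), make_hit_table("B", rna_id = "R2")
  )))
  expect_true(all(ortho$row_hclust$height > 0))

  # single row: identity order
  single <- cluster_matrix(build_matrix(list(make_hit_table("A", rna_id = "R1"))))
  expect_equal(single$row_order, 1L)
})

test_that("common binders are ranked by the fraction of incubations bound", {
  # protein X hit in 15 of 20 tables (75%), Y in 14 (70%), Z in all 20
  tabs <- lapply(1:20, function(i) {
    ids <- c(if (i <= 15) "X", if (i <= 14) "Y", "Z")
    make_hit_table(ids, rna_id = paste0("R", (i + 1) %/% 2),
                   strand = if (i %% 2) "sense" else "antisense")
  })
  cb <- common_binders(tabs)
  expect_equal(cb$protein_id, c("Z", "X"))
  expect_equal(cb$percent, c(100, 75))
  expect_false("Y" %in% cb$protein_id)
  # ties break lexicographically
  tabs2 <- lapply(1:4, function(i) {
    make_hit_table(c("B", "A"), rna_id = paste0("R", i))
  })
  expect_equal(common_binders(tabs2)$protein_id, c("A", "B"))
  expect_error(common_binders(list()), class = "rbpscreen_input_error")
})
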