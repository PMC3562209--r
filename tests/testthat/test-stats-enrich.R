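test_that("replicate concordance is the Pearson r over shared mean ratios", {
  a <- scan_from_ratios(c(A = 1, B = 2, C = 3, D = 1.5))
  expect_equal(replicate_concordance(a, a)$r_squared, 1)

  b <- scan_from_ratios(c(A = 2, B = 4, C = 6, D = 3))
  cc <- replicate_concordance(a, b)
  expect_equal(cc$r, 1)
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$n_proteins, 4)

  # closed-form zero correlation
  x <- scan_from_ratios(c(A = 1, B = 0, C = 1, D = 0))
  y <- scan_from_ratios(c(A = 1, B = 0, C = 0, D = 1))
  expect_equal(replicate_concordance(x, y)$r, 0)

  # affine transform of one vector leaves r unchanged
  z <- scan_from_ratios(c(A = 1.2, B = 3.4, C = 0.8, D = 2.2))
  r1 <- replicate_concordance(a, z)$r
  z2 <- scan_from_ratios(c(A = 1.2, B = 3.4, C = 0.8, D = 2.2) * 3 + 0.5)
  expect_equal(replicate_concordance(a, z2)$r, r1, tolerance = 1e-12)

  expect_error(replicate_concordance(scan_from_ratios(c(A = 1, B = 2)),
                                     scan_from_ratios(c(A = 1, B = 2))),
               class = "rbpscreen_insufficient_data_error")
  flat <- scan_from_ratios(c(A = 1, B = 1, C = 1, D = 1))
  expect_error(replicate_concordance(a, flat),
               class = "rbpscreen_degenerate_error")
})

test_that("overlap significance is the hypergeometric upper tail", {
  # full overlap of two 5-sets in a 10-universe: 1 / C(10,5)
  expect_equal(overlap_significance(letters[1:5], letters[1:5], 10),
               1 / 252, tolerance = 1e-12)
  # no overlap -> P(X >= 0) = 1
  expect_equal(overlap_significance(c("a", "b"), c("c", "d"), 100), 1)
  expect_error(overlap_significance(letters[1:5], letters[6:10], 8),
               class = "rbpscreen_input_error")

  # random tables match brute-force enumeration
  set.seed(21)
  universe <- sprintf("u%02d", 1:30)
  for (i in 1:25) {
    a <- sample(universe, sample(0:20, 1))
    b <- sample(universe, sample(0:20, 1))
    p <- overlap_significance(a, b, 30)
    expect_equal(p, hyper_tail_oracle(length(intersect(a, b)),
                                      length(a), length(b), 30),
                 tolerance = 1e-12)
  }
})

test_that("term enrichment matches enumeration, EASE is more conservative", {
  universe <- sprintf("u%02d", 1:20)
  ann <- tibble::tibble(term_id = "T", protein_id = universe[1:5])
  hits <- c(universe[1:3], universe[10])  # k = 3, K = 5, n = 4, N = 20
  res <- term_enrichment(hits, universe, ann)
  expect_equal(res$k, 3)
  expect_equal(res$K, 5)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p_adj, res$p)

  res_ease <- term_enrichment(hits, universe, ann, ease = TRUE)
  expect_equal(res_ease$p, hyper_tail_oracle(2, 5, 4, 20), tolerance = 1e-12)
  expect_gt(res_ease$p, res$p)

  # hits exactly the carriers of T -> minimal possible p for T
  res_min <- term_enrichment(universe[1:5], universe, ann)
  expect_equal(res_min$p, 1 / choose(20, 5), tolerance = 1e-12)

  # empty hit set: all p = 1
  expect_equal(term_enrichment(character(0), universe, ann)$p, 1)

  # overlap_significance agrees with term_enrichment when the term is hits_b
  ann2 <- tibble::tibble(term_id = "B", protein_id = universe[3:9])
  p_term <- term_enrichment(universe[1:4], universe, ann2)$p
  p_olap <- overlap_significance(universe[1:4], universe[3:9], 20)
  expect_equal(p_term, p_olap, tolerance = 1e-12)
})

test_that("enrichment drops unmapped annotations and sorts by p", {
  universe <- sprintf("u%02d", 1:20)
  ann <- tibble::tibble(
    term_id = c(rep("strong", 4), rep("weak", 6), "ghost"),
    protein_id = c(universe[1:4], universe[c(1, 6:10)], "not_on_array")
  )
  expect_message(res <- term_enrichment(universe[1:4], universe, ann))
  expect_equal(res$term_id, c("strong", "weak"))  # ghost term skipped (K = 0)
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$p_adj >= res$p))
  expect_equal(nrow(attr(res, "unmapped")), 1)
  expect_error(term_enrichment("not_in_universe", universe, ann),
               class = "rbpscreen_input_error")
})

test_that("Benjamini-Hochberg step-up adjustment with order preserved", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # order preserved, output >= input, <= 1, monotone in rank
  set.seed(9)
  p <- runif(40)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_true(!is.unsorted(adj[order(p)]))
  # hand step-up on a scrambled vector
  p2 <- c(0.9, 0.005, 0.04, 0.03)
  # sorted: .005 .03 .04 .9 -> *4/i: .02 .06 .0533 .9 -> cummin from top: .02 .0533 .0533 .9
  expect_equal(benjamini_hochberg(p2), c(0.9, 0.02, 16 / 300, 16 / 300))
  expect_error(benjamini_hochberg(c(0.2, 1.3)), class = "rbpscreen_input_error")
  expect_error(benjamini_hochberg(c(0.2, NA)), class = "rbpscreen_input_error")
})
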