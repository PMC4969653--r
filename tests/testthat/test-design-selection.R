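test_that("the Bayes risk envelope solves a two-line toy exactly", {
  # lines T(q): (n=10, e=8) -> 2q + 8 and (n=12, e=7) -> 5q + 7 cross at
  # q = 1/3; the cheaper-ESS0 design wins below, the smaller-MSS above
  tab <- ph2adapt:::envelope_table(c(10L, 12L), c(8, 7),
                                   list(`10` = NULL, `12` = NULL))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n, c(12L, 10L))
  expect_equal(tab$q_lo, c(0, 1/3), tolerance = 1e-12)
  expect_equal(tab$q_hi, c(1/3, 1), tolerance = 1e-12)
})

test_that("envelope handles a single candidate and merges duplicates", {
  tab <- ph2adapt:::envelope_table(10L, 8, list(`10` = NULL))
  expect_equal(nrow(tab), 1L)
  expect_equal(c(tab$q_lo, tab$q_hi), c(0, 1))
  # three lines, middle one never on the envelope
  tab3 <- ph2adapt:::envelope_table(c(10L, 11L, 12L), c(8, 7.9, 7),
                                    list(a = NULL, b = NULL, c = NULL))
  expect_true(all(diff(tab3$n) <= 0))       # n non-increasing in q
  expect_true(all(diff(tab3$ess0) >= 0))    # ess0 non-decreasing in q
  expect_equal(tab3$q_lo[1], 0)
  expect_equal(tab3$q_hi[nrow(tab3)], 1)
})

test_that("minimax adaptive design dominates the fixed-stage-2 minimax designs", {
  # module-level spot check; the full >= 10-spec grid runs with the
  # acceptance suite
  specs <- list(design_spec(0.05, 0.2, 0.7, 0.9),
                design_spec(0.1, 0.2, 0.6, 0.8),
                design_spec(0.1, 0.2, 0.5, 0.7))
  for (spec in specs) {
    simon <- search_simon(spec, "minimax")
    ef <- search_minimax_ef(spec, n_max = simon$n)
    ad <- find_minimax_adaptive(spec)
    expect_true(ad$certified)
    expect_lte(ef$n, simon$n)
    expect_lte(ad$metrics$mss, ef$n)
    expect_true(is_feasible(ad$metrics, spec))
    validate_adaptive_design(ad$design)
    if (ad$metrics$mss == ef$n)
      expect_lte(ad$metrics$ess0, attr(ef, "metrics")$ess0 + 1e-9)
    if (ad$metrics$mss == simon$n)
      expect_lte(ad$metrics$ess0, evaluate_design(simon, spec)$ess0 + 1e-9)
  }
})

test_that("optimal adaptive search never loses to the minimax adaptive design", {
  spec <- design_spec(0.05, 0.2, 0.7, 0.9)
  mm <- find_minimax_adaptive(spec)
  opt <- find_optimal_adaptive(spec)
  expect_lte(opt$metrics$ess0, mm$metrics$ess0 + 1e-9)
  expect_true(is_feasible(opt$metrics, spec))
  # admissible envelope connects the two
  tab <- admissible_designs(spec)
  expect_s3_class(tab, "admissible_table")
  expect_equal(tab$n[nrow(tab)], mm$metrics$mss)
  expect_equal(tab$ess0[1], opt$metrics$ess0, tolerance = 1e-9)
  expect_true(all(attr(tab, "lines")$n - attr(tab, "lines")$ess0 > 0))
})
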