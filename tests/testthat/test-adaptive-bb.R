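test_that("omega space enumerates the candidate triangle", {
  spec <- design_spec(0.2, 0.3, 0.3, 0.7)
  om <- build_omega(3, 4, spec)
  expect_length(om, 4)
  # S = 0 is the forced futility stop
  expect_equal(om[[1]]$is_stop, "futility")
  # raw triangle r - S <= n2 <= 4 has 14 pairs; kept candidates are those
  # with conditional null error strictly inside (0, 1): j <= n2 - 1
  expect_equal(sum(seq_len(4) + 1), 14)
  cand <- om[[2]][om[[2]]$is_stop == "none", ]
  expect_equal(nrow(cand), sum(seq_len(4)))
  expect_true(all(cand$ce_null > 0 & cand$ce_null < 1))
  # sorted by n2 ascending then ce_null ascending
  expect_true(!is.unsorted(cand$n2))
  for (k in unique(cand$n2))
    expect_true(!is.unsorted(cand$ce_null[cand$n2 == k]))
  # single-patient stage 2: the only candidate has r = s, ce_null = pi_u
  om1 <- build_omega(2, 1, spec)
  c1 <- om1[[2]][om1[[2]]$is_stop == "none", ]
  expect_equal(c1$r, 1)
  expect_equal(c1$ce_null, spec$pi_u)
})

test_that("branch-and-bound equals exhaustive enumeration on tiny designs", {
  cases <- list(
    list(n1 = 3, n = 6, spec = design_spec(0.2, 0.3, 0.3, 0.7)),
    list(n1 = 3, n = 7, spec = design_spec(0.15, 0.2, 0.25, 0.7)),
    list(n1 = 4, n = 7, spec = design_spec(0.2, 0.3, 0.3, 0.7)),
    list(n1 = 4, n = 7, spec = design_spec(0.3, 0.3, 0.4, 0.8)))
  for (cs in cases) for (exact in c(FALSE, TRUE)) {
    oracle <- enumerate_best_ess0(cs$n1, cs$n, cs$spec, exact_mss = exact)
    got <- bb_search(cs$n1, cs$n, cs$spec, exact_mss = exact)
    expect_equal(got$feasible, oracle$feasible,
                 info = sprintf("n1=%d n=%d exact=%d", cs$n1, cs$n, exact))
    if (oracle$feasible)
      expect_equal(got$metrics$ess0, oracle$best_ess0, tolerance = 1e-9,
                   info = sprintf("n1=%d n=%d exact=%d", cs$n1, cs$n, exact))
  }
})

test_that("returned schedules are monotone, feasible and exact-MSS when asked", {
  specs <- list(design_spec(0.2, 0.3, 0.3, 0.7),
                design_spec(0.3, 0.3, 0.4, 0.8))
  args <- list(c(4, 7), c(4, 7))
  for (i in seq_along(specs)) {
    res <- bb_search(args[[i]][1], args[[i]][2], specs[[i]],
                     exact_mss = TRUE)
    expect_true(res$feasible)
    sch <- res$design$schedule
    cont <- sch$n2[sch$kind == "continue"]
    expect_true(all(diff(cont) <= 0))
    expect_equal(max(sch$n2), args[[i]][2] - args[[i]][1])
    expect_true(is_feasible(res$metrics, specs[[i]]))
    validate_adaptive_design(res$design)
  }
})

test_that("a worse incumbent never changes the optimum", {
  spec <- design_spec(0.2, 0.3, 0.3, 0.7)
  base <- bb_search(4, 8, spec)
  worse <- bb_search(4, 8, spec, incumbent_ess0 = base$metrics$ess0 + 3)
  expect_equal(worse$metrics$ess0, base$metrics$ess0)
  expect_equal(worse$design$schedule, base$design$schedule)
})

test_that("infeasible size pairs return a result, not an error", {
  res <- bb_search(2, 4, design_spec(0.01, 0.05, 0.4, 0.5))
  expect_false(res$feasible)
  expect_type(res$stats$nodes, "double")
})

test_that("restricting to a constant stage-2 size recovers the EF optimum", {
  # with exact_mss the first continuation is pinned at n - n1; an EF
  # design is such a schedule with constant n2, so bb_search can only
  # improve on the best EF design at the same (n1, n)
  spec <- design_spec(0.05, 0.2, 0.7, 0.9)
  ef <- search_minimax_ef(spec)
  res <- bb_search(ef$n1, ef$n, spec, exact_mss = TRUE,
                   incumbent_ess0 = attr(ef, "metrics")$ess0 + 1e-6)
  expect_true(res$feasible)
  expect_lte(res$metrics$ess0, attr(ef, "metrics")$ess0 + 1e-6)
})
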