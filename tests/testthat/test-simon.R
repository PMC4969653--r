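# Brute-force Simon design search without pruning, for small n: direct
# term-by-term evaluation of the two-stage error sums for every
# (n1, r1, n, r) quadruple.  Independent of the vectorised production
# search machinery.
brute_simon <- function(spec, criterion, n_max) {
  best <- NULL
  for (n in 2:n_max) for (n1 in 1:(n - 1)) for (r1 in 0:(n1 - 1)) {
    n2 <- n - n1
    s <- (r1 + 1):n1
    b0 <- dbinom(s, n1, spec$pi_u)
    ba <- dbinom(s, n1, spec$pi_a)
    ess0 <- n1 + (1 - pbinom(r1, n1, spec$pi_u)) * n2
    for (r in r1:n) {
      al <- sum(b0 * (1 - pbinom(r - s, n2, spec$pi_u)))
      if (al > spec$alpha + 1e-12) next
      pw <- sum(ba * (1 - pbinom(r - s, n2, spec$pi_a)))
      if (pw < 1 - spec$beta - 1e-12) next
      key <- if (criterion == "minimax") c(n, ess0) else c(ess0, n)
      if (is.null(best) || key[1] < best$key[1] - 1e-12 ||
          (abs(key[1] - best$key[1]) <= 1e-12 && key[2] < best$key[2] - 1e-12))
        best <- list(design = simon_design(n1, r1, n, r), key = key,
                     ess0 = ess0)
    }
  }
  best
}

test_that("search_simon agrees with brute-force enumeration on small problems", {
  grid <- list(design_spec(0.1, 0.2, 0.2, 0.6),
               design_spec(0.15, 0.25, 0.3, 0.7),
               design_spec(0.1, 0.3, 0.4, 0.8))
  for (spec in grid) {
    bf <- brute_simon(spec, "minimax", 20)
    got <- search_simon(spec, "minimax", n_max = 20)
    expect_equal(got$n, bf$design$n)
    expect_equal(attr(got, "metrics")$ess0, bf$ess0, tolerance = 1e-9)
    bf_o <- brute_simon(spec, "optimal", 20)
    got_o <- search_simon(spec, "optimal", n_max = 20)
    expect_equal(attr(got_o, "metrics")$ess0, bf_o$ess0, tolerance = 1e-9)
  }
})

test_that("Simon searches reproduce the urothelial trial designs", {
  spec <- design_spec(0.1, 0.2, 0.35, 0.5)
  mm <- search_simon(spec, "minimax")
  expect_equal(unlist(mm[c("r1", "n1", "r", "n")]),
               c(r1 = 10, n1 = 31, r = 21, n = 49))
  expect_equal(round(attr(mm, "metrics")$ess0, 1), 40.8)
  opt <- search_simon(spec, "optimal")
  expect_equal(unlist(opt[c("r1", "n1", "r", "n")]),
               c(r1 = 7, n1 = 20, r = 24, n = 58))
  expect_equal(round(attr(opt, "metrics")$ess0, 1), 35.2)
})

test_that("returned designs are feasible and criteria are ordered", {
  specs <- list(design_spec(0.05, 0.2, 0.7, 0.9),
                design_spec(0.1, 0.2, 0.6, 0.8))
  for (spec in specs) {
    mm <- search_simon(spec, "minimax")
    op <- search_simon(spec, "optimal")
    m_mm <- evaluate_design(mm, spec)
    m_op <- evaluate_design(op, spec)
    expect_true(is_feasible(m_mm, spec))
    expect_true(is_feasible(m_op, spec))
    expect_lte(m_op$ess0, m_mm$ess0 + 1e-9)
    expect_lte(mm$n, op$n)
  }
})

test_that("an impossible error target reports infeasibility explicitly", {
  expect_error(search_simon(design_spec(0.01, 0.05, 0.45, 0.5), n_max = 30),
               "infeasible under n_max")
})
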