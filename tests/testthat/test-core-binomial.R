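spec <- design_spec(0.1, 0.2, 0.35, 0.5)

test_that("design_spec validates its inputs", {
  expect_s3_class(spec, "design_spec")
  expect_error(design_spec(0, 0.2, 0.35, 0.5), "alpha")
  expect_error(design_spec(0.1, 1, 0.35, 0.5), "beta")
  expect_error(design_spec(0.1, 0.2, 0.5, 0.35), "pi_u < pi_a")
})

test_that("binomial pmf and cdf match an independent summation oracle", {
  expect_equal(binom_pmf(0, 5, 0), 1)
  expect_equal(binom_pmf(2, 2, 0.5), 0.25)
  expect_equal(binom_pmf(4, 18, 0.2), oracle_binom_pmf(4, 18, 0.2))
  expect_equal(binom_pmf(4, 18, 0.2), 0.2153, tolerance = 1e-3)
  expect_error(binom_pmf(6, 5, 0.2), "0..n")

  expect_equal(binom_cdf(-1, 10, 0.3), 0)
  expect_equal(binom_cdf(10, 10, 0.3), 1)
  expect_equal(binom_cdf(4, 18, 0.2), oracle_binom_cdf(4, 18, 0.2))
  expect_equal(binom_cdf(4, 18, 0.2), 0.7164, tolerance = 1e-4)
})

test_that("conditional error handles crossed and unreachable boundaries", {
  expect_equal(conditional_error(22, 21, 5, 0.35), 1)
  expect_equal(conditional_error(0, 10, 5, 0.35), 0)
  # continue region of the urothelial adaptive schedule, S = 12
  expect_equal(conditional_error(12, 21, 21, 0.35),
               1 - oracle_binom_cdf(9, 21, 0.35))
})

test_that("conditional error is monotone in p and in the critical value", {
  p <- seq(0.05, 0.95, by = 0.05)
  ce <- conditional_error(5, 12, 15, p)
  expect_true(all(diff(ce) >= 0))
  r <- 5:20
  ce_r <- conditional_error(5, r, 15, 0.4)
  expect_true(all(diff(ce_r) <= 0))
})

test_that("evaluate_design reproduces the urothelial designs exactly", {
  simon <- simon_design(n1 = 31, r1 = 10, n = 49, r = 21)
  m <- evaluate_design(simon, spec)
  expect_equal(round(m$ess0, 1), 40.8)
  expect_lte(m$type1, 0.1)
  expect_gte(m$power, 0.8)
  expect_equal(m$mss, 49)
  expect_equal(m$pet0, pbinom(10, 31, 0.35))

  tab1 <- read_schedule(system.file("extdata",
                                    "urothelial_minimax_adaptive.csv",
                                    package = "ph2adapt"))
  ma <- evaluate_design(tab1, spec)
  expect_equal(round(ma$ess0, 1), 38.9)
  expect_equal(ma$mss, 49)
  expect_lte(ma$type1, 0.1)
  expect_gte(ma$power, 0.8)
})

test_that("a design that always stops for futility never rejects", {
  d <- adaptive_design(5, data.frame(S = 0:5, kind = "futility",
                                     n2 = 0L, r = 0L))
  m <- evaluate_design(d, spec)
  expect_equal(m$type1, 0)
  expect_equal(m$power, 0)
  expect_equal(m$ess0, 5)
  expect_equal(m$pet0, 1)
})

test_that("schedule validation names the violated rule", {
  sch <- data.frame(S = 0:4, kind = c("futility", "continue", "continue",
                                      "efficacy", "efficacy"),
                    n2 = c(0L, 5L, 6L, 0L, 0L), r = c(0L, 3L, 4L, 0L, 0L))
  expect_error(adaptive_design(4, sch), "non-increasing")
  sch$n2 <- c(0L, 6L, 5L, 0L, 0L)
  expect_s3_class(adaptive_design(4, sch), "adaptive_design")
  sch2 <- sch
  sch2$kind[1] <- "continue"; sch2$n2[1] <- 3L
  expect_error(adaptive_design(4, sch2), "S = 0")
  sch3 <- sch
  sch3$kind[4] <- "futility"
  expect_error(adaptive_design(4, sch3), "prefix")
})

test_that("EF designs evaluate identically through the direct two-boundary formula", {
  # alpha = P(X1 > r2) + sum_{s=r1+1}^{r2} b(s) P(X2 > r - s)
  for (par in list(c(32, 11, 16, 49, 21), c(25, 15, 20, 45, 32))) {
    d <- ef_design(par[1], par[2], par[3], par[4], par[5])
    for (p in c(0.35, 0.5, 0.6, 0.8)) {
      s <- (par[2] + 1):par[3]
      direct <- 1 - pbinom(par[3], par[1], p) +
        sum(dbinom(s, par[1], p) * (1 - pbinom(par[5] - s, par[4] - par[1], p)))
      sp <- design_spec(0.05, 0.1, p, min(p + 0.1, 0.99))
      m <- evaluate_design(d, sp)
      expect_lt(abs(m$type1 - direct), 1e-12)
    }
  }
})

test_that("early termination and continuation probabilities normalise", {
  d <- read_schedule(system.file("extdata", "urothelial_minimax_ef.csv",
                                 package = "ph2adapt"))
  m <- evaluate_design(d, spec)
  cont <- d$schedule$kind == "continue"
  expect_equal(m$pet0 + sum(dbinom(d$schedule$S[cont], d$n1, spec$pi_u)), 1)
})

test_that("exact metrics agree with Monte-Carlo simulation within 3 SE", {
  set.seed(421)
  tab1 <- read_schedule(system.file("extdata",
                                    "urothelial_minimax_adaptive.csv",
                                    package = "ph2adapt"))
  m <- evaluate_design(tab1, spec)
  for (p in c(spec$pi_u, spec$pi_a)) {
    sim <- simulate_design(tab1, p, nsim = 2e5)
    exact <- if (p == spec$pi_u) m$type1 else m$power
    expect_lt(abs(sim$reject - exact), 3 * sim$reject_se + 1e-12)
  }
  sim0 <- simulate_design(tab1, spec$pi_u, nsim = 2e5)
  expect_lt(abs(sim0$mean_n - m$ess0), 3 * sim0$mean_n_se)
})
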