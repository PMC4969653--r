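# Exhaustive enumeration oracle for tiny adaptive-design searches.
# Enumerates every monotone schedule at fixed (n1, n) directly in R --
# futility prefix, efficacy suffix, non-increasing n2 over the
# continuation region, every critical value r in s..s+n2 -- evaluates each
# with evaluate_design(), and returns the feasible minimum-ESS0 value.
# Completely independent of the branch-and-bound engine.
enumerate_best_ess0 <- function(n1, n, spec, exact_mss = FALSE) {
  n2max <- n - n1
  best <- Inf
  count <- 0L
  recurse <- function(s, rows, limit, started) {
    if (s > n1) {
      if (!started) {
        if (exact_mss) return(invisible())
      } else if (exact_mss && max(vapply(rows, `[[`, 0L, "n2")) != n2max) {
        return(invisible())
      }
      sch <- do.call(rbind, lapply(rows, as.data.frame))
      d <- adaptive_design(n1, sch)
      m <- evaluate_design(d, spec)
      count <<- count + 1L
      if (is_feasible(m, spec) && m$ess0 < best) best <<- m$ess0
      return(invisible())
    }
    if (!started && s > 0) {
      # keep the futility prefix open
      recurse(s + 1L, c(rows, list(list(S = s, kind = "futility", n2 = 0L,
                                        r = 0L))), n2max, FALSE)
    }
    if (s == 0L) {
      recurse(1L, list(list(S = 0L, kind = "futility", n2 = 0L, r = 0L)),
              n2max, FALSE)
      return(invisible())
    }
    # efficacy suffix from s on
    suffix <- lapply(s:n1, function(t)
      list(S = t, kind = "efficacy", n2 = 0L, r = 0L))
    recurse(n1 + 1L, c(rows, suffix), limit, started)
    # continuations
    for (k in seq_len(limit)) for (j in 0:k) {
      recurse(s + 1L,
              c(rows, list(list(S = s, kind = "continue", n2 = k,
                                r = s + j))), k, TRUE)
    }
  }
  recurse(0L, list(), n2max, FALSE)
  list(best_ess0 = best, feasible = is.finite(best), n_schedules = count)
}

# Independent arbitrary-precision binomial oracle via Rmpfr-free exact
# rational arithmetic on small cases: uses sums of choose() terms, which
# are exact in double for the tiny n used in tests.
oracle_binom_pmf <- function(x, n, p) choose(n, x) * p^x * (1 - p)^(n - x)
oracle_binom_cdf <- function(x, n, p) {
  if (x < 0) return(0)
  sum(oracle_binom_pmf(0:min(x, n), n, p))
}
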