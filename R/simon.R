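#' Simon two-stage design
#'
#' Classical futility-only two-stage design: enrol `n1` patients, stop and
#' accept \eqn{H_0} if at most `r1` respond; otherwise enrol `n - n1` more
#' and reject \eqn{H_0} iff the total response count exceeds `r`.
#'
#' @param n1,r1 First-stage sample size and futility boundary.
#' @param n,r Total sample size and final critical value (reject if `x > r`).
#' @return An object of class `simon_design`.
#' @export
simon_design <- function(n1, r1, n, r) {
  if (!(n1 >= 1 && n1 < n)) stop("need 1 <= n1 < n")
  if (!(r1 >= 0 && r1 <= n1)) stop("need 0 <= r1 <= n1")
  if (!(r >= r1 && r <= n)) stop("need r1 <= r <= n")
  structure(list(n1 = as.integer(n1), r1 = as.integer(r1),
                 n = as.integer(n), r = as.integer(r)),
            class = "simon_design")
}

#' @export
print.simon_design <- function(x, ...) {
  cat(sprintf("Simon two-stage design: (r1/n1, r/n) = (%d/%d, %d/%d)\n",
              x$r1, x$n1, x$r, x$n))
  invisible(x)
}

# Most powerful level-alpha test with n observations (randomised
# Neyman-Pearson threshold test on the total response count).  Any
# two-stage design with maximum sample size n is a test on at most n
# Bernoulli outcomes, so its power cannot exceed this bound; used to skip
# total sample sizes that cannot possibly meet the power requirement.
np_power_bound <- function(n, spec) {
  tail0 <- 1 - pbinom(-1:n, n, spec$pi_u)  # P(X > r) for r = -1..n
  r <- which(tail0 <= spec$alpha + .ph2_ctol)[1] - 2L  # smallest feasible r
  gamma <- if (r >= 0) {
    (spec$alpha - tail0[r + 2L]) / dbinom(r, n, spec$pi_u)
  } else 0
  1 - pbinom(r, n, spec$pi_a) + gamma * dbinom(max(r, 0), n, spec$pi_a)
}

# All feasible (r1, r) boundary pairs at fixed (n1, n), with the attained
# errors and ESS0, returned as a data frame (possibly empty).  Exact
# binomial computation vectorised over the whole (r1, r) grid.  The
# design's power is at most P(X_n > r | pi_a) (its rejection region is a
# subset of {x > r}), so critical values with that tail below the power
# target are skipped.
simon_feasible_at <- function(n1, n, spec) {
  n2 <- n - n1
  s <- 0:n1
  r_hi <- which(1 - pbinom(0:n, n, spec$pi_a) >=
                  1 - spec$beta - .ph2_ctol)
  if (!length(r_hi)) return(NULL)
  r_hi <- max(r_hi) - 1L
  b0 <- dbinom(s, n1, spec$pi_u)
  ba <- dbinom(s, n1, spec$pi_a)
  rs <- outer(s, 0:r_hi, function(s, r) r - s)  # (s, r) -> r - s
  t0 <- b0 * (1 - pbinom(rs, n2, spec$pi_u)) # mass rejecting via stage 2
  ta <- ba * (1 - pbinom(rs, n2, spec$pi_a))
  # column k: critical value r = k - 1; alpha(r1) = sum_{s > r1} t0[s]
  revcum <- function(m) apply(m, 2, function(col) rev(cumsum(rev(col))))
  A <- revcum(t0)  # A[i, k] = sum_{s >= i-1} -> alpha for r1 = i - 2
  P <- revcum(ta)
  out <- vector("list", n1)
  pet0 <- pbinom(s, n1, spec$pi_u)
  for (r1 in 0:(n1 - 1L)) {
    al <- A[r1 + 2L, ]
    pw <- P[r1 + 2L, ]
    ok <- which(al <= spec$alpha + .ph2_ctol &
                pw >= 1 - spec$beta - .ph2_ctol)
    if (!length(ok)) next
    k <- ok[1L]  # smallest feasible critical value (maximal power)
    out[[r1 + 1L]] <- data.frame(
      n1 = n1, r1 = r1, n = n, r = k - 1L,
      type1 = al[k], power = pw[k],
      ess0 = n1 + (1 - pet0[r1 + 1L]) * n2)
  }
  do.call(rbind, out)
}

#' Exact search for Simon's minimax or optimal two-stage design
#'
#' Enumerates all designs `(n1, r1, n, r)` with exact type I error at most
#' `spec$alpha` and exact power at least `1 - spec$beta`.  The *minimax*
#' criterion returns the design with the smallest total sample size `n`
#' (ties broken by smallest expected sample size under the null); the
#' *optimal* criterion returns the smallest \eqn{ESS_0} (ties broken by
#' smallest `n`).  Remaining ties are broken by smallest `n1`, then
#' smallest `r1`, for deterministic output.
#'
#' The scan runs `n` upward from 2.  Once the first feasible `n` (the
#' minimax MSS) is found, the optimal criterion keeps scanning up to 35
#' beyond it, a margin that comfortably covers the spread between minimax
#' and optimal total sample sizes in practice.
#'
#' @param spec A [design_spec()].
#' @param criterion `"minimax"` or `"optimal"`.
#' @param n_max Largest total sample size to consider (`NULL` for the
#'   automatic rule above).
#' @return A `simon_design` with attributes `metrics` (its
#'   [evaluate_design()] result) carried along.
#' @examples
#' \donttest{
#' search_simon(design_spec(0.1, 0.2, 0.35, 0.5), "minimax")  # (10/31, 21/49)
#' }
#' @export
search_simon <- function(spec, criterion = c("minimax", "optimal"),
                         n_max = NULL) {
  spec <- as_design_spec(spec)
  criterion <- match.arg(criterion)
  hard_cap <- if (is.null(n_max)) 500L else as.integer(n_max)
  if (hard_cap < 2) stop("'n_max' must be at least 2")
  first_feasible_n <- NA_integer_
  cand <- list()
  n <- 2L
  repeat {
    lim <- hard_cap
    if (!is.na(first_feasible_n)) {
      lim <- min(lim, if (criterion == "minimax") first_feasible_n
                      else first_feasible_n + 35L)
    }
    if (n > lim) break
    if (np_power_bound(n, spec) >= 1 - spec$beta - .ph2_ctol) {
      rows <- lapply(1:(n - 1L), simon_feasible_at, n = n, spec = spec)
      rows <- do.call(rbind, rows)
      if (!is.null(rows) && nrow(rows)) {
        if (is.na(first_feasible_n)) first_feasible_n <- n
        cand[[length(cand) + 1L]] <- rows
      }
    }
    n <- n + 1L
  }
  if (!length(cand))
    stop(sprintf("no feasible Simon design with n <= %d (infeasible under n_max)",
                 hard_cap))
  all <- do.call(rbind, cand)
  ord <- if (criterion == "minimax") {
    order(all$n, all$ess0, all$n1, all$r1)
  } else {
    order(all$ess0, all$n, all$n1, all$r1)
  }
  b <- all[ord[1L], ]
  d <- simon_design(b$n1, b$r1, b$n, b$r)
  attr(d, "metrics") <- evaluate_design(d, spec)
  d
}
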