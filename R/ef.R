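#' Two-stage design with first-stage stopping for futility or efficacy
#'
#' The Mander-Thompson extension of Simon's design: after `n1` patients the
#' trial stops for futility if `x1 <= r1`, stops *and rejects* for efficacy
#' if `x1 > r2`, and otherwise continues to `n` patients with final
#' rejection iff `x > r`.  Setting `r2 = n1` recovers futility-only
#' stopping.
#'
#' @param n1 First-stage sample size.
#' @param r1,r2 Futility and efficacy boundaries, `0 <= r1 < r2 <= n1`.
#' @param n,r Total sample size and final critical value.
#' @return An object of class `ef_design`.
#' @export
ef_design <- function(n1, r1, r2, n, r) {
  if (!(n1 >= 1 && n1 < n)) stop("need 1 <= n1 < n")
  if (!(r1 >= 0 && r1 < r2 && r2 <= n1)) stop("need 0 <= r1 < r2 <= n1")
  if (r > n) stop("need r <= n")
  structure(list(n1 = as.integer(n1), r1 = as.integer(r1),
                 r2 = as.integer(r2), n = as.integer(n), r = as.integer(r)),
            class = "ef_design")
}

#' @export
print.ef_design <- function(x, ...) {
  cat(sprintf("Minimax-EF two-stage design: ((r1,r2)/n1, r/n) = ((%d,%d)/%d, %d/%d)\n",
              x$r1, x$r2, x$n1, x$r, x$n))
  invisible(x)
}

#' Probability of early termination of an EF design
#'
#' The probability that the trial stops at the first stage, for futility or
#' efficacy: \eqn{B(r_1; n_1, p) + 1 - B(r_2; n_1, p)}.
#'
#' @param design An `ef_design`.  `r1 = -1` may be passed through a raw
#'   list to encode "no futility stopping".
#' @param p Response probability.
#' @return The early-termination probability.
#' @export
pet_ef <- function(design, p) {
  pbinom(design$r1, design$n1, p) + 1 - pbinom(design$r2, design$n1, p)
}

# Best feasible EF boundaries at fixed (n1, n): returns a one-row data
# frame (or NULL) minimising ESS0 = n1 + P(r1 < X1 <= r2 | pi_u) * n2.
# For each (r, r2) the feasible futility boundaries r1 form an interval;
# the largest feasible r1 minimises ESS0, so only interval endpoints are
# inspected.  Ties at equal ESS0 are broken by largest r1 then smallest
# r2 (and smallest r), for deterministic output.
ef_best_at <- function(n1, n, spec) {
  n2 <- n - n1
  s <- 0:n1
  b0 <- dbinom(s, n1, spec$pi_u)
  ba <- dbinom(s, n1, spec$pi_a)
  F0 <- pbinom(s, n1, spec$pi_u)
  tail0 <- 1 - F0                       # P(X1 > r2) at pi_u, index r2 + 1
  taila <- 1 - pbinom(s, n1, spec$pi_a)
  best <- NULL
  for (r in 0:n) {
    t0 <- b0 * conditional_error(s, r, n2, spec$pi_u)
    ta <- ba * conditional_error(s, r, n2, spec$pi_a)
    C0 <- cumsum(t0)                    # sum_{s <= k}, index k + 1
    Ca <- cumsum(ta)
    r2 <- 1:n1
    # alpha(r1, r2) = tail0[r2] + C0[r2] - C0[r1]; feasibility in r1:
    lo_v <- tail0[r2 + 1L] + C0[r2 + 1L] - spec$alpha - .ph2_ctol
    hi_v <- taila[r2 + 1L] + Ca[r2 + 1L] - (1 - spec$beta) + .ph2_ctol
    # smallest r1 with C0[r1] >= lo_v ; largest r1 with Ca[r1] <= hi_v
    r1_lo <- findInterval(lo_v, C0, left.open = TRUE)      # 0-based r1
    r1_hi <- findInterval(hi_v, Ca) - 1L
    r1_hi <- pmin(r1_hi, r2 - 1L)
    ok <- which(r1_lo <= r1_hi & r1_hi >= 0L)
    if (!length(ok)) next
    r1 <- r1_hi[ok]
    ess <- n1 + (F0[r2[ok] + 1L] - F0[r1 + 1L]) * n2
    o <- order(ess, -r1, r2[ok])[1L]
    row <- data.frame(n1 = n1, r1 = r1[o], r2 = r2[ok][o], n = n, r = r,
                      ess0 = ess[o])
    if (is.null(best) || row$ess0 < best$ess0 - .ph2_ttol ||
        (abs(row$ess0 - best$ess0) <= .ph2_ttol &&
         (row$r1 > best$r1 || (row$r1 == best$r1 && row$r2 < best$r2))))
      best <- row
  }
  best
}

#' Exact search for the minimax-EF design
#'
#' Finds the design with exact type I error at most `spec$alpha` and power
#' at least `1 - spec$beta` that minimises the total sample size `n`;
#' among those, the smallest expected sample size under the null,
#' \eqn{ESS_0 = n_1 + P(r_1 < X_1 \le r_2 \mid \pi_u)(n - n_1)}.  Ties at
#' equal `(n, ESS0)` are broken by smallest `n1`, then largest `r1`, then
#' smallest `r2`; any such tie is reported via a warning listing the
#' co-optimal designs.
#'
#' The scan runs `n` upward from the smallest value passing the
#' Neyman-Pearson power bound; Simon's minimax design (an EF design with
#' `r2 = n1`) guarantees feasibility by its MSS, which is the default cap.
#'
#' @param spec A [design_spec()].
#' @param n_max Largest total sample size to consider (`NULL`: the MSS of
#'   Simon's minimax design).
#' @return An `ef_design` with attribute `metrics`.
#' @examples
#' \donttest{
#' search_minimax_ef(design_spec(0.1, 0.2, 0.35, 0.5))  # ((11,16)/32, 21/49)
#' }
#' @export
search_minimax_ef <- function(spec, n_max = NULL) {
  spec <- as_design_spec(spec)
  if (is.null(n_max)) n_max <- search_simon(spec, "minimax")$n
  n <- 2L
  while (n <= n_max) {
    if (np_power_bound(n, spec) >= 1 - spec$beta - .ph2_ctol) {
      rows <- lapply(1:(n - 1L), ef_best_at, n = n, spec = spec)
      rows <- do.call(rbind, rows)
      if (!is.null(rows) && nrow(rows)) {
        ord <- order(rows$ess0, rows$n1, -rows$r1, rows$r2)
        b <- rows[ord[1L], ]
        co <- which(abs(rows$ess0 - b$ess0) <= .ph2_ttol)
        if (length(co) > 1L)
          warning(sprintf(
            "minimax-EF tie at n = %d, ESS0 = %.6f; co-optimal: %s (kept first by n1, -r1, r2)",
            n, b$ess0,
            paste(sprintf("((%d,%d)/%d, %d/%d)", rows$r1[co], rows$r2[co],
                          rows$n1[co], rows$r[co], rows$n[co]),
                  collapse = ", ")))
        d <- ef_design(b$n1, b$r1, b$r2, b$n, b$r)
        attr(d, "metrics") <- evaluate_design(d, spec)
        return(d)
      }
    }
    n <- n + 1L
  }
  stop(sprintf("no feasible EF design with n <= %d (infeasible under n_max)",
               n_max))
}
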