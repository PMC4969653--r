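#' Exact binomial probability mass
#'
#' Thin, argument-checked wrapper around [stats::dbinom()] used throughout
#' the design evaluations: \eqn{b(x; n, p) = \binom{n}{x} p^x (1-p)^{n-x}}.
#'
#' @param x Number of successes; must lie in `0..n`.
#' @param n Number of trials.
#' @param p Success probability in \[0, 1\].
#' @return `P(X = x)` for `X ~ Binomial(n, p)`.
#' @seealso [binom_cdf()], [conditional_error()]
#' @export
binom_pmf <- function(x, n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  if (any(x < 0 | x > n)) stop("'x' must lie in 0..n")
  dbinom(x, n, p)
}

#' Exact binomial cumulative probability
#'
#' Returns \eqn{B(x; n, p) = P(X \le x)}.  Unlike [binom_pmf()], `x` may be
#' negative (probability 0) or exceed `n` (probability 1); boundary
#' crossings in conditional error computations rely on this.
#'
#' @inheritParams binom_pmf
#' @param x Threshold; any integer, possibly outside `0..n`.
#' @return `P(X <= x)` for `X ~ Binomial(n, p)`.
#' @export
binom_cdf <- function(x, n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  pbinom(x, n, p)
}

#' Conditional error function of a two-stage design
#'
#' Given `s` responses among the first-stage patients, a second stage of
#' `n2_s` patients and a critical value `r_s` on the *cumulative* response
#' count (reject \eqn{H_0} iff total responses exceed `r_s`), the
#' conditional probability of rejection at the end of the trial is
#' \deqn{P(s \mid r(s), n_2(s), \pi) = 1 - B(r(s) - s;\, n_2(s), \pi).}
#' The value is 1 when `r_s - s < 0` (the boundary is already crossed at
#' the interim) and 0 when `r_s - s >= n2_s` (the boundary is unreachable).
#'
#' @param s First-stage response count(s).
#' @param r_s Critical value(s) on the cumulative response count.
#' @param n2_s Second-stage sample size(s); 0 is allowed and yields 0 or 1.
#' @param p Response probability at which the error is evaluated.
#' @return Rejection probability/ies conditional on `s`.
#' @examples
#' conditional_error(12, 21, 21, 0.35)  # continue region of a real schedule
#' conditional_error(22, 21, 5, 0.35)   # boundary already crossed -> 1
#' @export
conditional_error <- function(s, r_s, n2_s, p) {
  stopifnot(all(s >= 0), all(n2_s >= 0), p >= 0, p <= 1)
  1 - pbinom(r_s - s, n2_s, p)
}
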