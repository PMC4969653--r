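#' Exact operating characteristics of a two-stage design
#'
#' Computes, by exact binomial summation over the first-stage response
#' count `s`, the attained type I error
#' \deqn{\alpha = \sum_{s=0}^{n_1} P(s \mid r(s), n_2(s), \pi_u)\, b(s; n_1, \pi_u),}
#' the power (same sum at \eqn{\pi_a}), the expected sample size under the
#' null \eqn{ESS_0 = \sum_s (n_1 + n_2(s))\, b(s; n_1, \pi_u)}, the
#' probability of early termination (PET, stopping at stage 1 for futility
#' or efficacy) under both rates, and the maximum sample size
#' \eqn{MSS = n_1 + \max_s n_2(s)}.  The conditional rejection probability
#' is 0 for a futility stop and 1 for an efficacy stop.
#'
#' @param design An [adaptive_design()], or a `simon_design`/`ef_design`
#'   (converted via [as_adaptive_design()]).
#' @param spec A [design_spec()].
#' @return An object of class `design_metrics`: a list with elements
#'   `type1`, `power`, `ess0`, `pet0`, `pet_a`, `mss`.
#' @examples
#' spec <- design_spec(0.1, 0.2, 0.35, 0.5)
#' simon <- simon_design(n1 = 31, r1 = 10, n = 49, r = 21)
#' evaluate_design(simon, spec)   # ESS0 40.8, the urothelial trial design
#' @export
evaluate_design <- function(design, spec) {
  design <- as_adaptive_design(design)
  validate_adaptive_design(design)
  spec <- as_design_spec(spec)
  sch <- design$schedule
  n1 <- design$n1
  s <- sch$S
  ce_at <- function(p) {
    ce <- conditional_error(s, sch$r, sch$n2, p)
    ce[sch$kind == "futility"] <- 0
    ce[sch$kind == "efficacy"] <- 1
    ce
  }
  b0 <- dbinom(s, n1, spec$pi_u)
  ba <- dbinom(s, n1, spec$pi_a)
  stopped <- sch$kind != "continue"
  structure(list(
    type1 = sum(ce_at(spec$pi_u) * b0),
    power = sum(ce_at(spec$pi_a) * ba),
    ess0  = sum((n1 + sch$n2) * b0),
    pet0  = sum(b0[stopped]),
    pet_a = sum(ba[stopped]),
    mss   = n1 + max(sch$n2)
  ), class = "design_metrics")
}

#' @export
print.design_metrics <- function(x, ...) {
  cat(sprintf(
    "  type I error %.4f | power %.4f | ESS0 %.2f | PET0 %.3f | PETa %.3f | MSS %d\n",
    x$type1, x$power, x$ess0, x$pet0, x$pet_a, x$mss))
  invisible(x)
}

#' Does a design meet its nominal error bounds?
#'
#' Feasibility is judged in the conservative direction with a slack of
#' `1e-12`: attained type I error at most `alpha + 1e-12` and attained type
#' II error at most `beta + 1e-12`.
#'
#' @param metrics A `design_metrics` object.
#' @param spec A [design_spec()].
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(metrics, spec) {
  spec <- as_design_spec(spec)
  metrics$type1 <= spec$alpha + .ph2_ctol &&
    metrics$power >= 1 - spec$beta - .ph2_ctol
}

#' Simulate trials under a two-stage design
#'
#' Monte-Carlo companion to [evaluate_design()]: simulates `nsim` trials at
#' response probability `p` and reports the empirical rejection rate and
#' mean sample size with standard errors.  Used to cross-check the exact
#' computations; all design searches themselves are fully deterministic.
#'
#' @param design A design accepted by [as_adaptive_design()].
#' @param p True response probability to simulate under.
#' @param nsim Number of simulated trials.
#' @return A list with `reject`, `reject_se`, `mean_n`, `mean_n_se`,
#'   `pet`, and `nsim`.
#' @export
simulate_design <- function(design, p, nsim = 1e5) {
  design <- as_adaptive_design(design)
  sch <- design$schedule
  n1 <- design$n1
  x1 <- rbinom(nsim, n1, p)
  kind <- sch$kind[x1 + 1L]
  n2 <- sch$n2[x1 + 1L]
  r <- sch$r[x1 + 1L]
  x2 <- integer(nsim)
  cont <- kind == "continue"
  x2[cont] <- rbinom(sum(cont), n2[cont], p)
  reject <- kind == "efficacy" | (cont & (x1 + x2) > r)
  ntot <- n1 + n2
  list(reject = mean(reject),
       reject_se = sqrt(mean(reject) * (1 - mean(reject)) / nsim),
       mean_n = mean(ntot),
       mean_n_se = stats::sd(ntot) / sqrt(nsim),
       pet = mean(!cont),
       nsim = nsim)
}
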