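#' Branch-and-bound search for the best monotone adaptive schedule at
#' fixed (n1, n)
#'
#' Minimises the expected sample size under the null over all adaptive
#' schedules with first-stage size `n1` and second-stage sizes at most
#' `n - n1`, subject to exact type I error at most `spec$alpha`, exact
#' power at least `1 - spec$beta`, futility stop at `S = 0`, a futility
#' prefix and efficacy suffix, and `n2(S)` non-increasing over the
#' continuation region.  With `exact_mss = TRUE` the first continuation is
#' forced to `n2 = n - n1`, so the maximum sample size equals `n` exactly
#' (it may then recur at several `S`).
#'
#' The search is depth-first over `S = 0, 1, ..., n1`, choosing one
#' element of the candidate space per `S` in sorted order (see
#' [build_omega()]).  Branches are pruned when the accumulated type I mass
#' exceeds `alpha`, when the undecided suffix cannot recover the power
#' target, when the partial-ESS0 lower bound meets the incumbent, and by a
#' Lagrangian-dual power bound; all prunes are conservative, so the result
#' equals exhaustive enumeration.
#'
#' @param n1 First-stage sample size, `2 <= n1 <= n - 2`.
#' @param n Total (maximum) sample size.
#' @param spec A [design_spec()].
#' @param exact_mss Force the maximum sample size to equal `n` exactly.
#' @param incumbent_ess0 Optional known-achievable ESS0; schedules not
#'   beating it are pruned (the optimum, when returned, is unaffected).
#' @return A list with `feasible`; when feasible also `design` (an
#'   [adaptive_design()]), `metrics` ([evaluate_design()] output) and
#'   `stats` (node and prune counters).  Infeasibility is a regular
#'   result, not an error.
#' @param max_nodes Internal exploration cap used by the drivers' warm-up
#'   pass; when hit, the result carries `stats$aborted = TRUE` and is only
#'   a (possibly missing) upper bound, not the exact optimum.
#' @param ess_lower Internal: a previously *proven* statement that no
#'   feasible design at this configuration has ESS0 below this value;
#'   subtrees entirely below it are skipped.  Only the drivers' bisection
#'   supplies it.
#' @export
bb_search <- function(n1, n, spec, exact_mss = FALSE, incumbent_ess0 = NULL,
                      max_nodes = Inf, ess_lower = -Inf) {
  spec <- as_design_spec(spec)
  n1 <- as.integer(n1); n <- as.integer(n)
  if (!(n1 >= 2 && n1 <= n - 2))
    stop("need 2 <= n1 <= n - 2")
  inc <- if (is.null(incumbent_ess0)) Inf else as.numeric(incumbent_ess0)
  res <- .bb_search_cpp(n1, n, spec$alpha, spec$beta, spec$pi_u, spec$pi_a,
                        exact_mss, inc, max_nodes, ess_lower)
  if (!res$feasible)
    return(list(feasible = FALSE, stats = res$stats))
  kinds <- c("futility", "continue", "efficacy")
  design <- adaptive_design(n1, data.frame(
    S = 0:n1, kind = kinds[res$kind + 1L], n2 = res$n2, r = res$r))
  metrics <- evaluate_design(design, spec)
  # re-validate the engine's bookkeeping against the independent evaluator
  stopifnot(abs(metrics$type1 - res$alpha) < 1e-9,
            abs(metrics$power - res$power) < 1e-9,
            abs(metrics$ess0 - res$ess0) < 1e-9)
  if (res$stats$ties > 0)
    message(sprintf("bb_search(n1 = %d, n = %d): %d co-optimal schedule(s) within 1e-9 of ESS0 = %.6f; first in branch order kept",
                    n1, n, as.integer(res$stats$ties), res$ess0))
  list(feasible = TRUE, design = design, metrics = metrics,
       stats = res$stats)
}
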