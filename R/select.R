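#' Minimax adaptive two-stage design
#'
#' Backward maximum-sample-size scan for the adaptive design with the
#' smallest MSS, and the smallest \eqn{ESS_0} at that MSS.  The scan
#' starts at the MSS of the minimax-EF design (a special case of the
#' adaptive design, so feasibility there is guaranteed), runs
#' [bb_search()] with the exact-MSS constraint over every first-stage size
#' `n1` in `2..MSS-2` (enrolling a single patient, or all but one, in the
#' first stage is excluded as impractical), decrements the MSS, and stops
#' once three consecutive MSS values admit no feasible design.  The design
#' at the smallest feasible MSS is returned.
#'
#' Within one MSS level the incumbent ESS0 is seeded with the best EF
#' design at that total sample size (when one exists) and shared across
#' the `n1` scan, which only accelerates pruning.
#'
#' @param spec A [design_spec()].
#' @param verbose Report per-MSS progress via `message()`.
#' @param node_budget Cap on branch-and-bound nodes explored per MSS
#'   level.  The default (`Inf`) certifies the exact optimum.  With a
#'   finite budget the search reports the best design found and sets
#'   `certified = FALSE` once any level exhausts its budget; values are
#'   then upper bounds on the exact optima.
#' @return A list with `design` (the [adaptive_design()]), `metrics`,
#'   `search` (a data frame logging each MSS level: feasibility, best
#'   `n1`, ESS0, node counts), and `certified`.
#' @examples
#' \donttest{
#' res <- find_minimax_adaptive(design_spec(0.1, 0.2, 0.35, 0.5))
#' res$metrics  # MSS 49, ESS0 38.89
#' }
#' @export
find_minimax_adaptive <- function(spec, verbose = FALSE,
                                  node_budget = Inf) {
  spec <- as_design_spec(spec)
  ef <- search_minimax_ef(spec)
  n_t <- ef$n
  best <- NULL
  log <- list()
  n <- n_t
  consec_fail <- 0L
  certified <- TRUE
  while (consec_fail < 3L && n >= 4L) {
    lev <- bb_best_at_mss(n, spec, exact_mss = TRUE,
                          node_budget = node_budget)
    certified <- certified && lev$certified
    log[[length(log) + 1L]] <- data.frame(
      mss = n, feasible = lev$feasible,
      n1 = if (lev$feasible) lev$design$n1 else NA_integer_,
      ess0 = if (lev$feasible) lev$metrics$ess0 else NA_real_,
      nodes = lev$nodes, certified = lev$certified)
    if (lev$feasible) {
      best <- lev
      consec_fail <- 0L
    } else {
      consec_fail <- consec_fail + 1L
    }
    if (verbose)
      message(sprintf("MSS %d: %s%s", n,
                      if (lev$feasible) "feasible" else "infeasible",
                      if (lev$feasible)
                        sprintf(" (n1 = %d, ESS0 = %.4f)", lev$design$n1,
                                lev$metrics$ess0) else ""))
    n <- n - 1L
  }
  if (!certified)
    message("node budget reached: reporting the best design found; optimality (and level infeasibility) not certified")
  list(design = best$design, metrics = best$metrics,
       search = do.call(rbind, log), certified = certified)
}


# Best two-level schedule across all n1 at a level: incumbent seeding for
# the bisection (published optima are predominantly of this shape).
two_level_seed <- function(n, spec, exact_mss, upper, n1s) {
  best <- NULL
  kinds <- c("futility", "continue", "efficacy")
  for (n1 in n1s) {
    tl <- .two_level_best_cpp(n1, n, spec$alpha, spec$beta, spec$pi_u,
                              spec$pi_a, exact_mss, upper)
    if (!isTRUE(tl$feasible)) next
    d <- adaptive_design(n1, data.frame(S = 0:n1, kind = kinds[tl$kind + 1L],
                                        n2 = tl$n2, r = tl$r))
    m <- evaluate_design(d, spec)
    if (is_feasible(m, spec) && m$ess0 < upper - .ph2_ttol) {
      best <- list(feasible = TRUE, design = d, metrics = m)
      upper <- m$ess0
    }
  }
  best
}

# Best adaptive design at one MSS level: bisection on the attainable ESS0
# over the scan n1 = 2..n-2.  A sweep at threshold T searches every n1
# with incumbent T; if no schedule with ESS0 < T - 1e-9 exists anywhere,
# T becomes a *proven* lower bound that later sweeps exploit by skipping
# subtrees lying entirely below it.  Sweeps below the optimum are cheap
# (the relaxation bounds reject everything), so the bisection closes in
# on the optimum from both sides and the confirming sweep runs over a
# hairline band.  The best feasible EF design at total sample size n
# seeds the upper end and serves as a fallback witness.
bb_best_at_mss <- function(n, spec, exact_mss = TRUE, node_budget = Inf) {
  best <- NULL
  upper <- Inf
  ef_rows <- do.call(rbind, lapply(1:(n - 1L), ef_best_at, n = n, spec = spec))
  if (!is.null(ef_rows) && nrow(ef_rows)) {
    b <- ef_rows[order(ef_rows$ess0, ef_rows$n1, -ef_rows$r1, ef_rows$r2)[1L], ]
    d <- as_adaptive_design(ef_design(b$n1, b$r1, b$r2, b$n, b$r))
    best <- list(feasible = TRUE, design = d,
                 metrics = evaluate_design(d, spec))
    upper <- best$metrics$ess0
  }
  nodes <- 0
  certified <- TRUE
  n1s <- 2:(n - 2L)
  seed <- two_level_seed(n, spec, exact_mss, upper, n1s)
  if (!is.null(seed)) {
    best <- seed
    upper <- seed$metrics$ess0
  }
  # one sweep = a node-capped discovery pass (cheaply harvesting any
  # schedule below the threshold) followed by an exact pass over the n1
  # whose discovery hit the cap, with the tightest incumbent seen.  A
  # finite node budget caps the exact pass as well; a capped run that
  # proves nothing is treated as infeasible but drops the certificate.
  sweep <- function(threshold, lo) {
    found <- NULL
    inc <- threshold
    todo <- rep(TRUE, length(n1s))
    for (pass in 1:2) {
      for (i in seq_along(n1s)) {
        if (!todo[i]) next
        left <- node_budget - nodes
        if (left <= 0) { certified <<- FALSE; return(found) }
        res <- bb_search(n1s[i], n, spec, exact_mss = exact_mss,
                         incumbent_ess0 = inc, ess_lower = lo,
                         max_nodes = if (pass == 1L) min(3e5, left) else left)
        nodes <<- nodes + res$stats$nodes
        todo[i] <- pass == 1L && isTRUE(res$stats$aborted)
        if (pass == 2L && isTRUE(res$stats$aborted)) certified <<- FALSE
        if (res$feasible && res$metrics$ess0 < inc - .ph2_ttol) {
          found <- res
          inc <- res$metrics$ess0
        }
      }
      if (!any(todo)) break
    }
    found
  }
  if (!is.finite(upper)) {
    # no EF witness: bisect against the trivial ceiling (ESS0 < n for
    # every valid schedule), so an infeasible level is refuted by the
    # same cheap below-threshold sweeps
    upper <- n + 1
  }
  lo <- 0
  while (upper - lo > 1e-7 && lo <= n && nodes < node_budget) {
    # biased low: infeasible sweeps are cheap, so approach from below and
    # keep the band above the optimum narrow when a sweep finally crosses
    mid <- lo + 0.25 * (upper - lo)
    got <- sweep(mid, lo)
    if (is.null(got)) {
      lo <- mid - .ph2_ttol
    } else {
      best <- got
      upper <- got$metrics$ess0
    }
  }
  repeat {   # confirm over the remaining hairline band
    got <- sweep(upper, lo)
    if (is.null(got)) break
    best <- got
    upper <- got$metrics$ess0
  }
  if (is.null(best))
    return(list(feasible = FALSE, nodes = nodes, certified = certified))
  list(feasible = TRUE, design = best$design, metrics = best$metrics,
       nodes = nodes, certified = certified)
}

#' Optimal (minimum-ESS0) monotone adaptive design
#'
#' Minimises the expected sample size under the null over all monotone
#' adaptive designs with maximum sample size at most `n_upper`, by running
#' [bb_search()] without the exact-MSS constraint at `n = n_upper` for
#' every `n1`.  An upper bound on the sample size must be set for this
#' criterion; the default is the total sample size of Simon's optimal
#' design, a natural cap since the adaptive optimum dominates Simon's
#' optimal design (a special case) and pushing the worst case beyond it
#' buys little expected-size saving.  Simon's optimal design also seeds
#' the incumbent.
#'
#' @param spec A [design_spec()].
#' @param n_upper Cap on the maximum sample size (`NULL`: Simon optimal `n`).
#' @param verbose Report per-`n1` progress.
#' @param node_budget Cap on branch-and-bound nodes (see
#'   [find_minimax_adaptive()]); `Inf` certifies exactness.
#' @return A list with `design`, `metrics` (note `metrics$mss` is the MSS
#'   of the returned design, typically below `n_upper`), `n_upper`, and
#'   `certified`.
#' @export
find_optimal_adaptive <- function(spec, n_upper = NULL, verbose = FALSE,
                                  node_budget = Inf) {
  spec <- as_design_spec(spec)
  simon_opt <- search_simon(spec, "optimal")
  if (is.null(n_upper)) n_upper <- simon_opt$n
  n_upper <- as.integer(n_upper)
  if (n_upper < 4L) stop("'n_upper' too small for a two-stage design")
  best <- NULL
  inc <- Inf
  if (simon_opt$n <= n_upper) {
    d <- as_adaptive_design(simon_opt)
    best <- list(design = d, metrics = evaluate_design(d, spec))
    inc <- best$metrics$ess0
  }
  n1s <- 2:(n_upper - 2L)
  seed <- two_level_seed(n_upper, spec, FALSE, inc, n1s)
  if (!is.null(seed)) {
    best <- seed[c("design", "metrics")]
    inc <- seed$metrics$ess0
  }
  nodes <- 0
  certified <- TRUE
  sweep <- function(threshold, lo) {
    found <- NULL
    thr <- threshold
    todo <- rep(TRUE, length(n1s))
    for (pass in 1:2) {
      for (i in seq_along(n1s)) {
        if (!todo[i]) next
        left <- node_budget - nodes
        if (left <= 0) { certified <<- FALSE; return(found) }
        res <- bb_search(n1s[i], n_upper, spec, exact_mss = FALSE,
                         incumbent_ess0 = thr, ess_lower = lo,
                         max_nodes = if (pass == 1L) min(3e5, left) else left)
        nodes <<- nodes + res$stats$nodes
        todo[i] <- pass == 1L && isTRUE(res$stats$aborted)
        if (pass == 2L && isTRUE(res$stats$aborted)) certified <<- FALSE
        if (res$feasible && res$metrics$ess0 < thr - .ph2_ttol) {
          found <- res
          thr <- res$metrics$ess0
        }
      }
      if (!any(todo)) break
    }
    found
  }
  lo <- 0
  while (inc - lo > 1e-7 && nodes < node_budget) {
    mid <- lo + 0.25 * (inc - lo)
    got <- sweep(mid, lo)
    if (is.null(got)) {
      lo <- mid - .ph2_ttol
    } else {
      best <- got[c("design", "metrics")]
      inc <- got$metrics$ess0
    }
    if (verbose)
      message(sprintf("bisection: ESS0 in (%.5f, %.5f]", lo, inc))
  }
  repeat {
    got <- sweep(inc, lo)
    if (is.null(got)) break
    best <- got[c("design", "metrics")]
    inc <- got$metrics$ess0
  }
  if (is.null(best))
    stop(sprintf("no feasible adaptive design with MSS <= %d", n_upper))
  if (!certified)
    message("node budget reached: reporting the best design found; optimality not certified")
  list(design = best$design, metrics = best$metrics, n_upper = n_upper,
       certified = certified)
}

#' Admissible adaptive designs from the Bayes risk lower envelope
#'
#' For a weight `q` on the maximum sample size, the Bayes risk of a design
#' is \eqn{T = q n + (1 - q) ESS_0}, a line in `q` with slope
#' \eqn{n - ESS_0 > 0} and intercept \eqn{ESS_0}.  Candidates are the
#' minimum-ESS0 designs with MSS exactly `n` for every `n` between the
#' MSS of the minimax adaptive design (`n_min`) and of the optimal
#' adaptive design (`n_opt`).  The admissible design for a given `q` is
#' the candidate minimising `T`; the partition of \[0, 1\] is obtained
#' from the pairwise line intersections (those inside (0, 1), merged when
#' closer than `1e-9`).  Near `q = 0` the optimal design is admissible,
#' near `q = 1` the minimax design.
#'
#' @param spec A [design_spec()].
#' @param n_upper Cap used for the optimal-design search
#'   (see [find_optimal_adaptive()]).
#' @param verbose Report progress per MSS level.
#' @param node_budget Cap on branch-and-bound nodes per search phase
#'   (see [find_minimax_adaptive()]); `Inf` certifies exactness.
#' @return An object of class `admissible_table`: a data frame with
#'   columns `q_lo`, `q_hi`, `n`, `ess0`, and attributes `designs` (list
#'   of the candidate [adaptive_design()]s indexed by `n`) and
#'   `intersections` (the in-range crossing points, a diagnostic).
#' @export
admissible_designs <- function(spec, n_upper = NULL, verbose = FALSE,
                               node_budget = Inf) {
  spec <- as_design_spec(spec)
  mm <- find_minimax_adaptive(spec, verbose = verbose,
                              node_budget = node_budget)
  n_min <- mm$metrics$mss
  opt <- find_optimal_adaptive(spec, n_upper = n_upper,
                               node_budget = node_budget)
  n_opt <- opt$metrics$mss
  ns <- n_min:n_opt
  cand <- vector("list", length(ns))
  names(cand) <- as.character(ns)
  cand[[1L]] <- mm[c("design", "metrics")]
  if (n_opt > n_min) {
    cand[[length(cand)]] <- opt[c("design", "metrics")]
    if (n_opt > n_min + 1L) {
      for (i in seq_along(ns)[-c(1L, length(ns))]) {
        lev <- bb_best_at_mss(ns[i], spec, exact_mss = TRUE,
                              node_budget = node_budget)
        if (!lev$feasible)
          stop(sprintf("no design with MSS exactly %d between n_min and n_opt",
                       ns[i]))
        cand[[i]] <- lev[c("design", "metrics")]
        if (verbose)
          message(sprintf("MSS %d: ESS0 = %.4f", ns[i], lev$metrics$ess0))
      }
    }
  }
  ess <- vapply(cand, function(x) x$metrics$ess0, numeric(1))
  envelope_table(ns, ess, lapply(cand, `[[`, "design"))
}

# Lower envelope of the Bayes risk lines T_n(q) = (n - e_n) q + e_n.
envelope_table <- function(ns, ess, designs) {
  stopifnot(all(ns - ess > 0))  # ESS0 < n: T strictly increasing in q
  slope <- ns - ess
  k <- length(ns)
  xs <- numeric(0)
  if (k > 1L) {
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      q <- (ess[i] - ess[j]) / (slope[j] - slope[i])
      if (is.finite(q) && q > 0 && q < 1) xs <- c(xs, q)
    }
  }
  xs <- sort(xs)
  if (length(xs)) xs <- xs[c(TRUE, diff(xs) > .ph2_ttol)]  # merge close
  brk <- c(0, xs, 1)
  mids <- (head(brk, -1) + brk[-1]) / 2
  pick <- vapply(mids, function(q) {
    t <- slope * q + ess
    o <- which(t <= min(t) + .ph2_ttol)
    o[which.min(ns[o])]  # at exact ties prefer the smaller MSS
  }, integer(1))
  starts <- which(c(TRUE, diff(pick) != 0L))
  ends <- c(starts[-1L] - 1L, length(mids))
  idx <- pick[starts]
  out <- data.frame(q_lo = brk[starts], q_hi = brk[ends + 1L],
                    n = ns[idx], ess0 = ess[idx])
  structure(out, class = c("admissible_table", "data.frame"),
            designs = designs, intersections = xs,
            lines = data.frame(n = ns, ess0 = ess))
}

#' @export
print.admissible_table <- function(x, ...) {
  cat("Admissible adaptive designs (Bayes risk T = q*n + (1-q)*ESS0):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  q in [%.3f, %.3f] : n = %d, ESS0 = %.2f%s\n",
                x$q_lo[i], x$q_hi[i], x$n[i], x$ess0[i],
                if (i == 1L) "  (optimal end)"
                else if (i == nrow(x)) "  (minimax end)" else ""))
  invisible(x)
}
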