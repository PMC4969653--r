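#' Specify the testing problem for a two-stage phase II trial
#'
#' A design specification fixes the hypotheses \eqn{H_0: \pi \le \pi_u}
#' versus \eqn{H_a: \pi \ge \pi_a} for the response probability \eqn{\pi} of
#' a single-arm trial, together with the nominal error bounds: type I error
#' at most `alpha` (evaluated at `pi_u`) and type II error at most `beta`
#' (power at least `1 - beta` at `pi_a`).
#'
#' @param alpha Nominal one-sided type I error bound, in (0, 1).
#' @param beta Nominal type II error bound, in (0, 1).
#' @param pi_u Unacceptable (null) response rate, in (0, 1).
#' @param pi_a Acceptable (target) response rate; must exceed `pi_u`.
#'
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(0.1, 0.2, 0.35, 0.5)
#' @export
design_spec <- function(alpha, beta, pi_u, pi_a) {
  for (nm in c("alpha", "beta", "pi_u", "pi_a")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie strictly between 0 and 1")
  if (beta <= 0 || beta >= 1) stop("'beta' must lie strictly between 0 and 1")
  if (pi_u <= 0 || pi_a >= 1 || pi_u >= pi_a)
    stop("response rates must satisfy 0 < pi_u < pi_a < 1")
  structure(list(alpha = alpha, beta = beta, pi_u = pi_u, pi_a = pi_a),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Two-stage phase II design spec: H0 pi <= %.3g vs Ha pi >= %.3g (alpha = %.3g, power = %.3g)\n",
    x$pi_u, x$pi_a, x$alpha, 1 - x$beta))
  invisible(x)
}

as_design_spec <- function(x) {
  if (inherits(x, "design_spec")) return(x)
  if (is.numeric(x) && length(x) == 4L)
    return(design_spec(x[[1]], x[[2]], x[[3]], x[[4]]))
  stop("cannot interpret 'spec'; use design_spec(alpha, beta, pi_u, pi_a)")
}
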