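#' Adaptive two-stage design with a per-response second-stage schedule
#'
#' An adaptive design is a first-stage sample size `n1` together with one
#' stage-two decision for every possible first-stage response count
#' `S = 0, ..., n1`: stop for futility, stop for efficacy, or continue with
#' `n2(S)` further patients and reject at the end iff the cumulative
#' response count exceeds \code{r(S)}.  Valid schedules stop for futility at
#' `S = 0`, have a futility prefix and an efficacy suffix, and have `n2(S)`
#' non-increasing over the continuation region (the monotonicity property
#' that makes such designs usable in practice).
#'
#' @param n1 First-stage sample size.
#' @param schedule A data frame with one row per `S = 0..n1` and columns
#'   `S`, `kind` (one of `"futility"`, `"continue"`, `"efficacy"`), `n2`
#'   (second-stage size; 0 for stopped rows) and `r` (critical value on the
#'   cumulative response count; 0 for stopped rows).
#' @return An object of class `adaptive_design`.
#' @seealso [evaluate_design()], [read_schedule()], [write_schedule()]
#' @export
adaptive_design <- function(n1, schedule) {
  schedule <- as.data.frame(schedule)
  if (!all(c("S", "kind", "n2", "r") %in% names(schedule)))
    stop("'schedule' needs columns S, kind, n2, r")
  schedule <- schedule[order(schedule$S), c("S", "kind", "n2", "r")]
  schedule$kind <- as.character(schedule$kind)
  schedule$n2 <- as.integer(schedule$n2)
  schedule$r <- as.integer(schedule$r)
  rownames(schedule) <- NULL
  x <- structure(list(n1 = as.integer(n1), schedule = schedule),
                 class = "adaptive_design")
  validate_adaptive_design(x)
  x
}

#' Validate an adaptive design's schedule
#'
#' Checks the structural invariants and stops with an error naming the
#' first violated rule.
#'
#' @param design An [adaptive_design()].
#' @return `design`, invisibly, if valid.
#' @export
validate_adaptive_design <- function(design) {
  n1 <- design$n1
  sch <- design$schedule
  fail <- function(rule) stop("invalid adaptive design: ", rule, call. = FALSE)
  if (!is.numeric(n1) || n1 < 1) fail("n1 must be a positive count")
  if (!identical(sch$S, 0:n1))
    fail("schedule must define every S in 0..n1 exactly once")
  if (!all(sch$kind %in% c("futility", "continue", "efficacy")))
    fail("kind must be one of futility/continue/efficacy")
  if (sch$kind[1] != "futility")
    fail("S = 0 must stop for futility (no responses observed)")
  stopped <- sch$kind != "continue"
  if (any(sch$n2[stopped] != 0L)) fail("stopped rows must have n2 = 0")
  cont <- which(!stopped)
  if (length(cont)) {
    if (any(sch$n2[cont] < 1L)) fail("continue rows must have n2 >= 1")
    if (any(sch$r[cont] < 0L)) fail("continue rows must have r >= 0")
    if (is.unsorted(rev(sch$n2[cont])))
      fail("n2 must be non-increasing over the continuation region")
  }
  fut <- which(sch$kind == "futility")
  if (!identical(fut, seq_along(fut)))
    fail("futility rows must form a prefix of 0..n1")
  eff <- which(sch$kind == "efficacy")
  if (length(eff) && !identical(eff, seq.int(n1 + 2L - length(eff), n1 + 1L)))
    fail("efficacy rows must form a suffix of 0..n1")
  invisible(design)
}

#' @export
print.adaptive_design <- function(x, ...) {
  sch <- x$schedule
  cat(sprintf("Adaptive two-stage design: n1 = %d, MSS = %d\n",
              x$n1, x$n1 + max(sch$n2)))
  fut <- sum(sch$kind == "futility")
  eff <- sum(sch$kind == "efficacy")
  if (fut) cat(sprintf("  S <= %-2d : stop, futility\n", fut - 1L))
  cont <- sch[sch$kind == "continue", , drop = FALSE]
  if (nrow(cont)) {
    for (i in seq_len(nrow(cont)))
      cat(sprintf("  S  = %-2d : continue, n2 = %2d (n = %2d), reject if x > %d\n",
                  cont$S[i], cont$n2[i], x$n1 + cont$n2[i], cont$r[i]))
  }
  if (eff) cat(sprintf("  S >= %-2d : stop, efficacy\n", x$n1 + 1L - eff))
  invisible(x)
}

#' Convert classical designs to the adaptive representation
#'
#' Simon and minimax-EF designs are special cases of the adaptive design
#' (constant `n2` over the continuation region); encoding them as
#' [adaptive_design()] objects lets one evaluator compute every design's
#' operating characteristics.
#'
#' @param x A `simon_design`, `ef_design` or `adaptive_design`.
#' @param ... Unused.
#' @return An [adaptive_design()].
#' @export
as_adaptive_design <- function(x, ...) UseMethod("as_adaptive_design")

#' @export
as_adaptive_design.adaptive_design <- function(x, ...) x

#' @export
as_adaptive_design.simon_design <- function(x, ...) {
  S <- 0:x$n1
  kind <- ifelse(S <= x$r1, "futility", "continue")
  n2 <- ifelse(S <= x$r1, 0L, x$n - x$n1)
  r <- ifelse(S <= x$r1, 0L, x$r)
  adaptive_design(x$n1, data.frame(S = S, kind = kind, n2 = n2, r = r))
}

#' @export
as_adaptive_design.ef_design <- function(x, ...) {
  S <- 0:x$n1
  kind <- ifelse(S <= x$r1, "futility",
                 ifelse(S > x$r2, "efficacy", "continue"))
  n2 <- ifelse(kind == "continue", x$n - x$n1, 0L)
  r <- ifelse(kind == "continue", x$r, 0L)
  adaptive_design(x$n1, data.frame(S = S, kind = kind, n2 = n2, r = r))
}
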