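#' Candidate conditional-error space for the adaptive design search
#'
#' For each first-stage response count `S`, the branch-and-bound search
#' chooses one element of the candidate space Omega: the futility stop
#' (conditional rejection probability 0), the efficacy stop (probability
#' 1), or a continuation `(n2, r)` with `n2` second-stage patients and a
#' critical value `r` on the cumulative count.  Only continuations whose
#' conditional type I error is strictly between 0 and 1 are kept, i.e.
#' \code{r - S} between 0 and \code{n2 - 1}; \code{r - S <= n2} spans the full triangle of
#' achievable stage-2 boundaries.  Elements are sorted by `n2` ascending
#' (which serves the monotonicity constraint) and conditional null error
#' ascending; duplicated `(ce_null, ce_alt)` pairs at the same `n2` are
#' reduced to the representative with the smallest `r`.  `S = 0` always
#' stops for futility, so its list contains only that element.
#'
#' This R-level constructor mirrors the candidate table used internally by
#' the compiled search engine and exists for inspection and testing.
#'
#' @param n1 First-stage sample size.
#' @param n2_max Largest admissible second-stage size.
#' @param spec A [design_spec()].
#' @return A list of `n1 + 1` data frames (one per `S = 0..n1`) with
#'   columns `s`, `is_stop` (`"futility"`, `"efficacy"`, `"none"`), `n2`,
#'   `r`, `ce_null`, `ce_alt`.
#' @export
build_omega <- function(n1, n2_max, spec) {
  spec <- as_design_spec(spec)
  stopifnot(n2_max >= 1, n1 >= 1)
  n2 <- rep.int(seq_len(n2_max), seq_len(n2_max))
  j <- unlist(lapply(seq_len(n2_max), function(k) (k - 1L):0L))
  ce0 <- conditional_error(0L, j, n2, spec$pi_u)
  cea <- conditional_error(0L, j, n2, spec$pi_a)
  keep <- !duplicated(data.frame(n2, ce0, cea), fromLast = TRUE) &
    ce0 > 0 & ce0 < 1  # fromLast: the smallest r represents a duplicate pair
  n2 <- n2[keep]; j <- j[keep]; ce0 <- ce0[keep]; cea <- cea[keep]
  # within each n2 block j runs downward, so ce_null is already ascending;
  # blocks are in ascending n2 order by construction
  lapply(0:n1, function(s) {
    if (s == 0L) {
      return(data.frame(s = 0L, is_stop = "futility", n2 = 0L, r = 0L,
                        ce_null = 0, ce_alt = 0))
    }
    rbind(
      data.frame(s = s, is_stop = c("futility", "efficacy"),
                 n2 = 0L, r = 0L, ce_null = c(0, 1), ce_alt = c(0, 1)),
      data.frame(s = s, is_stop = "none", n2 = n2, r = s + j,
                 ce_null = ce0, ce_alt = cea))
  })
}
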