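#' Step plot of total sample size against first-stage responses
#'
#' Plots `n(S) = n1 + n2(S)` as a function of the first-stage response
#' count for one or more designs, the standard way to compare a constant
#' second stage (Simon, minimax-EF) with an adaptive one.
#'
#' @param ... Named designs (anything [as_adaptive_design()] accepts),
#'   e.g. `Simon = simon, Adaptive = ad`.
#' @return A `ggplot` object (requires the ggplot2 package).
#' @export
plot_design_sizes <- function(...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_design_sizes() needs the 'ggplot2' package")
  designs <- list(...)
  if (is.null(names(designs)) || any(names(designs) == ""))
    names(designs) <- paste0("design", seq_along(designs))
  df <- do.call(rbind, lapply(names(designs), function(nm) {
    d <- as_adaptive_design(designs[[nm]])
    data.frame(design = nm, S = d$schedule$S,
               n_total = d$n1 + d$schedule$n2)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = S, y = n_total,
                                   colour = design)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "first-stage responses S", y = "n(S)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bayes risk lines and their lower envelope
#'
#' Plots `T(q) = q n + (1 - q) ESS0` for each candidate design of an
#' [admissible_designs()] table, with the admissible (lower-envelope)
#' segments emphasised.
#'
#' @param x An `admissible_table`.
#' @return A `ggplot` object (requires the ggplot2 package).
#' @export
plot_bayes_risk <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_bayes_risk() needs the 'ggplot2' package")
  stopifnot(inherits(x, "admissible_table"))
  ln <- attr(x, "lines")
  lines <- do.call(rbind, lapply(seq_len(nrow(ln)), function(i) {
    data.frame(n = ln$n[i], q = c(0, 1), T = c(ln$ess0[i], ln$n[i]))
  }))
  env <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    q <- c(x$q_lo[i], x$q_hi[i])
    data.frame(n = x$n[i], q = q, T = (x$n[i] - x$ess0[i]) * q + x$ess0[i])
  }))
  ggplot2::ggplot(lines, ggplot2::aes(x = q, y = T,
                                      group = n)) +
    ggplot2::geom_line(colour = "grey65", linewidth = 0.4) +
    ggplot2::geom_line(data = env, ggplot2::aes(colour = factor(n)),
                       linewidth = 1.1) +
    ggplot2::labs(x = "weight q on the maximum sample size",
                  y = "Bayes risk T(q)", colour = "MSS n") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("S", "n_total", "design", "q", "T", "n"))
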