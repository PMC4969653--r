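#' Write an adaptive schedule to CSV or JSON
#'
#' The CSV layout mirrors the published presentation of adaptive
#' schedules: one explicit row per `S = 0..n1` with columns `S`, `n2`,
#' `n_total` (`= n1 + n2`) and `r`; stopped rows carry `n2 = 0` and
#' \code{r = 0}.  Futility rows are the `n2 = 0` prefix and efficacy rows the
#' `n2 = 0` suffix, so the stop kinds are recoverable as long as the
#' schedule has a continuation region; schedules without one can only be
#' serialised as JSON, which stores the decision kind (and optionally the
#' design spec) explicitly.
#'
#' @param design An [adaptive_design()] (or a design convertible via
#'   [as_adaptive_design()]).
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default: inferred from the
#'   extension, falling back to CSV).
#' @param spec Optional [design_spec()] embedded in JSON output.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(design, path, format = NULL, spec = NULL) {
  design <- as_adaptive_design(design)
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  sch <- design$schedule
  if (format == "csv") {
    if (!any(sch$kind == "continue"))
      stop("a schedule with no continuation region is ambiguous in CSV; use JSON")
    out <- data.frame(S = sch$S, n2 = sch$n2,
                      n_total = design$n1 + sch$n2, r = sch$r)
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(n1 = design$n1, schedule = sch)
    if (!is.null(spec)) obj$spec <- unclass(as_design_spec(spec))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read an adaptive schedule from CSV or JSON
#'
#' Inverse of [write_schedule()].  For CSV input the stop kinds are
#' reconstructed from the position of the `n2 = 0` rows relative to the
#' continuation region.
#'
#' @param path Input file path.
#' @return An [adaptive_design()]; for JSON input with an embedded spec,
#'   the spec is attached as attribute `"spec"`.
#' @export
read_schedule <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    d <- adaptive_design(obj$n1, as.data.frame(obj$schedule))
    if (!is.null(obj$spec))
      attr(d, "spec") <- do.call(design_spec, obj$spec)
    return(d)
  }
  tab <- read.csv(path)
  need <- c("S", "n2", "n_total", "r")
  if (!all(need %in% names(tab)))
    stop("schedule CSV needs columns S, n2, n_total, r")
  tab <- tab[order(tab$S), ]
  n1 <- max(tab$S)
  if (!all(tab$n_total == n1 + tab$n2))
    stop("inconsistent n_total column (must equal n1 + n2)")
  cont <- which(tab$n2 > 0)
  if (!length(cont))
    stop("schedule CSV has no continuation rows; stop kinds are ambiguous")
  kind <- ifelse(tab$n2 > 0, "continue",
                 ifelse(tab$S < tab$S[cont[1L]], "futility", "efficacy"))
  adaptive_design(n1, data.frame(S = tab$S, kind = kind, n2 = tab$n2,
                                 r = tab$r))
}
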