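#' Dissolution profile of one drug in one test medium
#'
#' Container for a measured dissolution profile: percent of dose dissolved at
#' sampling times, read in one of the two Japanese Pharmacopoeia dissolution
#' fluids (first fluid, pH 1.2, gastric-like; second fluid, pH 6.8,
#' intestinal-like).
#'
#' @param drug_id Character label for the drug/formulation.
#' @param time_min Numeric vector of sampling times in minutes; strictly
#'   increasing, non-negative, at least 3 points.
#' @param dissolved_pct Percent dissolved at each time. Values in \[0, 110\];
#'   small assay overshoot above 100 is tolerated, larger values are rejected.
#' @param medium `"pH1.2"` or `"pH6.8"`.
#' @return An object of class `dissolution_curve`: a list with the validated
#'   fields above.
#' @examples
#' dissolution_curve("amlodipine", c(5, 10, 15, 30, 45, 60),
#'                   c(53.6, 78.5, 90.0, 99.0, 99.9, 100), medium = "pH1.2")
#' @export
dissolution_curve <- function(drug_id, time_min, dissolved_pct, medium = c("pH1.2", "pH6.8")) {
  medium <- match.arg(medium)
  stopifnot(is.character(drug_id), length(drug_id) == 1L)
  time_min <- as.numeric(time_min)
  dissolved_pct <- as.numeric(dissolved_pct)
  if (length(time_min) != length(dissolved_pct))
    stop("time_min and dissolved_pct must have equal length")
  if (length(time_min) < 3L)
    stop("a dissolution curve needs at least 3 sampling points")
  if (any(!is.finite(time_min)) || any(!is.finite(dissolved_pct)))
    stop("non-finite values in dissolution curve")
  if (any(time_min < 0) || any(diff(time_min) <= 0))
    stop("times must be non-negative and strictly increasing")
  if (any(dissolved_pct < 0) || any(dissolved_pct > 110))
    stop("dissolved_pct must lie in [0, 110]")
  structure(
    list(drug_id = drug_id, medium = medium,
         time_min = time_min, dissolved_pct = dissolved_pct),
    class = "dissolution_curve"
  )
}

#' @export
print.dissolution_curve <- function(x, ...) {
  cat(sprintf("Dissolution curve: %s (%s), %d points over %g-%g min, last %g%%\n",
              x$drug_id, x$medium, length(x$time_min),
              min(x$time_min), max(x$time_min),
              x$dissolved_pct[length(x$dissolved_pct)]))
  invisible(x)
}

#' Plasma concentration-time profile after a single oral dose
#'
#' Container for graph-read plasma concentrations. Units of concentration are
#' arbitrary but must be consistent within a curve; the absorption rate
#' constant is invariant to uniform rescaling.
#'
#' @param drug_id Character label.
#' @param time_h Sampling times in hours post-dose; strictly increasing,
#'   non-negative, at least 5 points.
#' @param conc Concentrations, non-negative, at least one positive.
#' @return An object of class `plasma_curve`.
#' @examples
#' plasma_curve("x", c(0, 0.5, 1, 2, 4, 8, 12), c(0, 3.1, 4.4, 4.1, 2.6, 1.0, 0.4))
#' @export
plasma_curve <- function(drug_id, time_h, conc) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L)
  time_h <- as.numeric(time_h)
  conc <- as.numeric(conc)
  if (length(time_h) != length(conc))
    stop("time_h and conc must have equal length")
  if (length(time_h) < 5L)
    stop("a plasma curve needs at least 5 sampling points")
  if (any(!is.finite(time_h)) || any(!is.finite(conc)))
    stop("non-finite values in plasma curve")
  if (any(time_h < 0) || any(diff(time_h) <= 0))
    stop("times must be non-negative and strictly increasing")
  if (any(conc < 0))
    stop("concentrations must be non-negative")
  if (all(conc == 0))
    stop("at least one concentration must be positive")
  structure(list(drug_id = drug_id, time_h = time_h, conc = conc),
            class = "plasma_curve")
}

#' @export
print.plasma_curve <- function(x, ...) {
  cat(sprintf("Plasma curve: %s, %d points over %g-%g h, Cmax %g at %g h\n",
              x$drug_id, length(x$time_h), min(x$time_h), max(x$time_h),
              max(x$conc), x$time_h[which.max(x$conc)]))
  invisible(x)
}
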