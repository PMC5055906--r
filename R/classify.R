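#' Quadrant risk group from Rd and Ra
#'
#' Classifies a drug at a dosing interval into one of four interaction-risk
#' groups by comparing its theoretical dissolution and absorption rates to the
#' operating thresholds (equality on the at-or-above side):
#' group 1 (`Rd >= ThRd`, `Ra >= ThRa`): both fast, lowest risk;
#' group 2 (`Rd < ThRd`, `Ra >= ThRa`): slow dissolution only;
#' group 3 (`Rd >= ThRd`, `Ra < ThRa`): dissolved but unabsorbed drug exposed
#' to the adsorbent, warrants attention;
#' group 4 (both below): highest risk.
#'
#' @param rd,ra Rates in percent (vectorized, recycled).
#' @param th_rd,th_ra Operating thresholds in percent; the defaults (90, 30)
#'   are the round-number operating point inside the optimal region.
#' @return Integer group 1-4.
#' @examples
#' classify_risk(14.2, 1.0)   # 4
#' classify_risk(99.0, 26.8)  # 3
#' @export
classify_risk <- function(rd, ra, th_rd = 90, th_ra = 30) {
  stopifnot(all(rd >= 0 & rd <= 100), all(ra >= 0 & ra <= 100),
            length(th_rd) == 1L, length(th_ra) == 1L,
            th_rd >= 0, th_rd <= 100, th_ra >= 0, th_ra <= 100)
  d <- rd >= th_rd
  a <- ra >= th_ra
  ifelse(d & a, 1L, ifelse(!d & a, 2L, ifelse(d & !a, 3L, 4L)))
}

#' Rate-constant profile of one drug
#'
#' Bundles the fitted constants a drug needs for interval predictions: the
#' governing dissolution rate constant (larger of the two media, see
#' [select_medium_fit()]), its lag, and the absorption constant and lag.
#'
#' @param drug_id Character label.
#' @param kd_per_s Dissolution rate constant, s^-1.
#' @param tlagd_h Dissolution lag, hours.
#' @param ka_per_h Absorption rate constant, h^-1.
#' @param tlaga_h Absorption lag, hours.
#' @param dissolution_complete Whether complete dissolution was reached in at
#'   least one test medium; drugs where it was not cannot be scored.
#' @return An object of class `drug_profile`.
#' @export
drug_profile <- function(drug_id, kd_per_s, tlagd_h = 0, ka_per_h, tlaga_h = 0,
                         dissolution_complete = TRUE) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L,
            kd_per_s > 0, ka_per_h > 0, tlagd_h >= 0, tlaga_h >= 0)
  structure(
    list(drug_id = drug_id, kd_per_s = kd_per_s, tlagd_h = tlagd_h,
         ka_per_h = ka_per_h, tlaga_h = tlaga_h,
         dissolution_complete = isTRUE(dissolution_complete)),
    class = "drug_profile"
  )
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("Drug profile: %s  kd = %g x10^-4 s^-1 (Tlagd %g h), ka = %g h^-1 (Tlaga %g h)%s\n",
              x$drug_id, x$kd_per_s * 1e4, x$tlagd_h, x$ka_per_h, x$tlaga_h,
              if (x$dissolution_complete) "" else "  [dissolution incomplete]"))
  invisible(x)
}

#' Risk classification of one drug across dosing intervals
#'
#' Computes Rd and Ra at each candidate dosing interval from the drug's rate
#' constants and assigns the quadrant risk group. Because both rates are
#' non-decreasing in the interval, group-1 membership, once reached, persists
#' at all longer intervals.
#'
#' @param profile A [drug_profile()] (or list with the same fields).
#' @param intervals Dosing intervals in minutes; default
#'   `c(1, 30, 60, 90, 120, 240)` (1 encodes simultaneous administration).
#' @param th_rd,th_ra Operating thresholds (defaults 90 and 30 percent).
#' @param region Optional `threshold_region`; a warning is issued when the
#'   operating point lies outside it.
#' @return A data frame `drug_id, interval_min, rd_pct, ra_pct, group`.
#' @examples
#' amlo <- drug_profile("amlodipine", kd_per_s = 25.54e-4, ka_per_h = 0.62)
#' classify_profile(amlo, intervals = c(1, 30, 90, 240))
#' @export
classify_profile <- function(profile, intervals = c(1, 30, 60, 90, 120, 240),
                             th_rd = 90, th_ra = 30, region = NULL) {
  stopifnot(all(intervals > 0))
  if (!isTRUE(profile$dissolution_complete))
    stop(excluded_drug_error(profile$drug_id,
                             "complete dissolution not achieved in either fluid"))
  if (!is.null(region) && !region_contains(region, th_rd, th_ra))
    warning(sprintf("operating point (%g, %g) lies outside the optimal region",
                    th_rd, th_ra))
  rd <- dissolution_rate(profile$kd_per_s, intervals, tlagd_h = profile$tlagd_h)
  ra <- absorption_fraction(profile$ka_per_h, profile$tlaga_h, intervals)
  data.frame(drug_id = profile$drug_id, interval_min = intervals,
             rd_pct = rd, ra_pct = ra,
             group = classify_risk(rd, ra, th_rd, th_ra))
}

#' Smallest dosing interval reaching a target risk group
#'
#' Scans ascending candidate intervals and returns the first at which the
#' drug's risk group is at or below the target (group 1, or groups 1-2 when
#' `target = 2`). Monotonicity of Rd and Ra guarantees the qualifying set of
#' intervals is upward-closed, so the first qualifying candidate is minimal.
#'
#' @param profile A [drug_profile()].
#' @param target 1 or 2.
#' @param candidates Ascending candidate intervals in minutes.
#' @param th_rd,th_ra Operating thresholds.
#' @return The smallest qualifying candidate in minutes, or `NA` if none
#'   qualifies.
#' @export
min_interval_to_group <- function(profile, target = 1,
                                  candidates = c(1, 30, 60, 90, 120, 240),
                                  th_rd = 90, th_ra = 30) {
  stopifnot(target %in% c(1, 2), !is.unsorted(candidates, strictly = TRUE))
  cls <- classify_profile(profile, candidates, th_rd, th_ra)
  ok <- which(cls$group <= target)
  if (length(ok) == 0L) NA_real_ else candidates[ok[1L]]
}

#' Per-interval counts of drugs in each risk group
#'
#' @param assignments A data frame as returned by [classify_profile()]
#'   (possibly row-bound over drugs).
#' @return A data frame with one row per interval and columns `interval_min`,
#'   `group1`-`group4`, `n`; counts conserve the number of drugs classified at
#'   each interval. Zero rows yield a zero-row frame.
#' @export
group_counts <- function(assignments) {
  cols <- paste0("group", 1:4)
  if (is.null(assignments) || nrow(assignments) == 0L) {
    return(data.frame(interval_min = numeric(0), group1 = integer(0),
                      group2 = integer(0), group3 = integer(0),
                      group4 = integer(0), n = integer(0)))
  }
  tab <- table(interval = assignments$interval_min,
               group = factor(assignments$group, levels = 1:4))
  out <- data.frame(interval_min = as.numeric(rownames(tab)))
  out[cols] <- as.data.frame.matrix(tab)
  out$n <- rowSums(tab)
  rownames(out) <- NULL
  out[order(out$interval_min), , drop = FALSE]
}

#' Scatter display of drugs in the (Rd, Ra) plane with quadrant lines
#'
#' @param assignments A data frame from [classify_profile()] (row-bound over
#'   drugs), restricted to one interval per call for a clean panel.
#' @param th_rd,th_ra Thresholds drawn as quadrant lines.
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot_risk <- function(assignments, th_rd = 90, th_ra = 30, ...) {
  graphics::plot(assignments$rd_pct, assignments$ra_pct,
                 xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "Rd (%)", ylab = "Ra (%)",
                 pch = assignments$group, ...)
  graphics::abline(v = th_rd, h = th_ra, lty = 2)
  graphics::text(assignments$rd_pct, assignments$ra_pct,
                 labels = assignments$drug_id, pos = 3, cex = 0.7)
  invisible(assignments)
}
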