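#' Validate a table of interaction-study results
#'
#' An interaction-result table joins observed equivalence outcomes of human
#' interaction studies (E: exposure unchanged when co-dosed with AST-120;
#' NE: AUC or Cmax significantly changed) to the theoretical dissolution and
#' absorption rates at the studied dosing interval.
#'
#' @param x A data frame with columns `drug_id`, `interval_min` (simultaneous
#'   administration encoded as 1), `rd_pct`, `ra_pct` (percent, in
#'   \[0, 100\]), and `observed` (`"E"` or `"NE"`).
#' @return The validated data frame (invisibly classed `interaction_results`).
#' @export
as_interaction_results <- function(x) {
  x <- as.data.frame(x)
  need <- c("drug_id", "interval_min", "rd_pct", "ra_pct", "observed")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("interaction results must be non-empty")
  if (!all(x$observed %in% c("E", "NE")))
    stop("observed must be 'E' or 'NE'")
  if (any(x$interval_min < 1))
    stop("interval_min must be >= 1 (simultaneous is encoded as 1)")
  if (any(x$rd_pct < 0 | x$rd_pct > 100 | x$ra_pct < 0 | x$ra_pct > 100))
    stop("rd_pct and ra_pct must lie in [0, 100]")
  class(x) <- unique(c("interaction_results", class(x)))
  x
}

#' Predict equivalence from Rd/Ra against a threshold pair
#'
#' A co-administered drug's exposure is predicted unchanged (`"E"`) when both
#' its dissolution and absorption rates at the dosing interval reach the
#' thresholds (`Rd >= rdth` and `Ra >= rath`), predicted changed (`"NE"`)
#' when both fall strictly below, and `"MIXED"` otherwise (one above, one
#' below; always counted inconsistent). Equality falls on the equivalent side
#' of each comparison.
#'
#' @param rd,ra Rates in percent (vectorized, recycled against each other).
#' @param rdth,rath Thresholds in percent.
#' @return Character vector in `{"E", "NE", "MIXED"}`.
#' @examples
#' predict_equivalence(14.2, 1.0, 90, 30)  # "NE"
#' predict_equivalence(99.0, 26.8, 90, 30) # "MIXED"
#' @export
predict_equivalence <- function(rd, ra, rdth, rath) {
  stopifnot(length(rdth) == 1L, length(rath) == 1L,
            rdth >= 0, rdth <= 100, rath >= 0, rath <= 100,
            all(rd >= 0 & rd <= 100), all(ra >= 0 & ra <= 100))
  d <- rd >= rdth
  a <- ra >= rath
  ifelse(d & a, "E", ifelse(!d & !a, "NE", "MIXED"))
}

#' Consistency of a prediction with an observed study outcome
#'
#' @param prediction `"E"`, `"NE"` or `"MIXED"` (vectorized).
#' @param observed `"E"` or `"NE"`.
#' @return Logical; `MIXED` predictions are never consistent.
#' @export
is_consistent <- function(prediction, observed) {
  stopifnot(all(observed %in% c("E", "NE")),
            all(prediction %in% c("E", "NE", "MIXED")))
  prediction == observed
}

#' Predictive value of a threshold pair
#'
#' Percent of interaction-study results whose predicted equivalence matches
#' the observed outcome: `100 * n_consistent / n_results`.
#'
#' @param results An interaction-result table (see [as_interaction_results()]).
#' @param rdth,rath Thresholds in percent.
#' @return Predictive value in percent (full precision; reports conventionally
#'   round to one decimal).
#' @examples
#' fx <- load_fixtures()
#' predictive_value(fx$results, 90, 30)  # 85.71... (12 of 14)
#' @export
predictive_value <- function(results, rdth, rath) {
  results <- as_interaction_results(results)
  pred <- predict_equivalence(results$rd_pct, results$ra_pct, rdth, rath)
  100 * sum(is_consistent(pred, results$observed)) / nrow(results)
}

## Piecewise-constancy cells along one threshold axis. The indicator
## (value >= th) only changes as th crosses an observed value from below, so
## the predictive value is constant on [0, v_(1)], (v_(1), v_(2)], ...,
## (v_(k), 100]. Each cell is represented by one interior threshold; the
## representative of (v_(k), 100] sits eps above v_(k), with eps half the
## smallest nonzero gap between sorted observed values, capped at 0.05.
axis_cells <- function(vals) {
  u <- sort(unique(vals))
  k <- length(u)
  eps <- if (k > 1L) min(min(diff(u)) / 2, 0.05) else 0.05
  rep_ <- u
  low <- c(0, u[-k])
  low_open <- c(FALSE, rep(TRUE, k - 1L))
  high <- u
  if (u[k] < 100) {
    rep_ <- c(rep_, u[k] + min(eps, (100 - u[k]) / 2))
    low <- c(low, u[k])
    low_open <- c(low_open, TRUE)
    high <- c(high, 100)
  }
  data.frame(rep = rep_, low = low, low_open = low_open, high = high)
}

consistency_count <- function(results, rdth, rath) {
  pred <- predict_equivalence(results$rd_pct, results$ra_pct, rdth, rath)
  sum(is_consistent(pred, results$observed))
}

#' Optimal threshold region for equivalence prediction
#'
#' Finds all threshold pairs `(Rdth, Rath)` maximizing the predictive value
#' over the interaction results, by exact breakpoint search: the predictive
#' value is piecewise constant, changing only when a threshold crosses an
#' observed Rd or Ra value, so evaluating one representative per constancy
#' cell (at most `n + 2` per axis) covers `[0, 100]^2` exactly. Attaining
#' cells are merged into axis-aligned boxes whose open/closed bounds sit at
#' observed data values: since equality counts toward the equivalent side,
#' lower bounds strictly above a data value are open and upper bounds at a
#' data value are closed.
#'
#' @param results An interaction-result table (see [as_interaction_results()]).
#' @return An object of class `threshold_region`: `max_predictive_value`
#'   (percent, full precision), `n`, `n_consistent`, bounding per-axis
#'   intervals `rdth_low`/`rdth_high`/`rath_low`/`rath_high` with
#'   `rdth_low_open`/`rath_low_open` flags (upper bounds are always closed),
#'   `single_box`, and `rectangles` (a data frame of disjoint boxes jointly
#'   covering the attaining set).
#' @examples
#' fx <- load_fixtures()
#' optimal_region(fx$results)
#' @export
optimal_region <- function(results) {
  results <- as_interaction_results(results)
  crd <- axis_cells(results$rd_pct)
  cra <- axis_cells(results$ra_pct)
  n <- nrow(results)

  cnt <- matrix(0L, nrow(crd), nrow(cra))
  for (i in seq_len(nrow(crd)))
    for (j in seq_len(nrow(cra)))
      cnt[i, j] <- consistency_count(results, crd$rep[i], cra$rep[j])
  kmax <- max(cnt)
  attain <- cnt == kmax

  # merge attaining cells into boxes: per rd-cell, runs of contiguous ra-cells;
  # consecutive rd-cells with identical run sets merge along the rd axis
  row_runs <- lapply(seq_len(nrow(crd)), function(i) {
    r <- rle(attain[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  })
  sig <- vapply(row_runs, function(m) paste(m, collapse = ","), character(1))
  grp <- cumsum(c(TRUE, sig[-1L] != sig[-length(sig)]))

  rects <- do.call(rbind, lapply(split(seq_along(grp), grp), function(rows) {
    runs <- row_runs[[rows[1L]]]
    if (nrow(runs) == 0L) return(NULL)
    i1 <- rows[1L]; i2 <- rows[length(rows)]
    do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      j1 <- runs[r, "start"]; j2 <- runs[r, "end"]
      data.frame(
        rd_low = crd$low[i1], rd_low_open = crd$low_open[i1], rd_high = crd$high[i2],
        ra_low = cra$low[j1], ra_low_open = cra$low_open[j1], ra_high = cra$high[j2]
      )
    }))
  }))
  rownames(rects) <- NULL

  structure(
    list(max_predictive_value = 100 * kmax / n,
         n = n, n_consistent = kmax,
         rdth_low = min(rects$rd_low), rdth_high = max(rects$rd_high),
         rdth_low_open = rects$rd_low_open[which.min(rects$rd_low)[1L]],
         rath_low = min(rects$ra_low), rath_high = max(rects$ra_high),
         rath_low_open = rects$ra_low_open[which.min(rects$ra_low)[1L]],
         single_box = nrow(rects) == 1L,
         rectangles = rects),
    class = "threshold_region"
  )
}

#' Does a threshold pair lie inside the optimal region?
#'
#' @param region A `threshold_region` from [optimal_region()].
#' @param rdth,rath Threshold pair in percent (vectorized, recycled).
#' @return Logical, honoring the region's open/closed bounds.
#' @export
region_contains <- function(region, rdth, rath) {
  stopifnot(inherits(region, "threshold_region"))
  r <- region$rectangles
  out <- logical(max(length(rdth), length(rath)))
  rdth <- rep_len(rdth, length(out))
  rath <- rep_len(rath, length(out))
  for (i in seq_len(nrow(r))) {
    in_rd <- (if (r$rd_low_open[i]) rdth > r$rd_low[i] else rdth >= r$rd_low[i]) &
      rdth <= r$rd_high[i]
    in_ra <- (if (r$ra_low_open[i]) rath > r$ra_low[i] else rath >= r$ra_low[i]) &
      rath <= r$ra_high[i]
    out <- out | (in_rd & in_ra)
  }
  out
}

#' @export
print.threshold_region <- function(x, ...) {
  cat(sprintf("Optimal equivalence-prediction thresholds (%d results)\n", x$n))
  cat(sprintf("  maximum predictive value: %.1f %% (%d/%d)\n",
              x$max_predictive_value, x$n_consistent, x$n))
  cat(sprintf("  Rdth in %s%.1f, %.1f], Rath in %s%.1f, %.1f]%s\n",
              if (x$rdth_low_open) "(" else "[", x$rdth_low, x$rdth_high,
              if (x$rath_low_open) "(" else "[", x$rath_low, x$rath_high,
              if (x$single_box) "" else sprintf(" (bounding box of %d rectangles)",
                                                nrow(x$rectangles))))
  invisible(x)
}

#' Predictive-value surface over threshold grids
#'
#' Evaluates [predictive_value()] at every pair of grid thresholds, for
#' contour or perspective displays of the threshold landscape.
#'
#' @param results An interaction-result table.
#' @param rd_grid,ra_grid Ascending grids within \[0, 100\].
#' @return A numeric matrix (`length(rd_grid)` x `length(ra_grid)`) with the
#'   grids as dimnames.
#' @export
predictive_surface <- function(results, rd_grid, ra_grid) {
  results <- as_interaction_results(results)
  stopifnot(all(rd_grid >= 0 & rd_grid <= 100), all(ra_grid >= 0 & ra_grid <= 100),
            !is.unsorted(rd_grid), !is.unsorted(ra_grid))
  # prediction factorizes into per-axis indicators, so the count is a product
  # of two logical matrices per outcome class
  e <- results$observed == "E"
  Drd <- outer(results$rd_pct, rd_grid, ">=")
  Dra <- outer(results$ra_pct, ra_grid, ">=")
  m1 <- crossprod(Drd[e, , drop = FALSE], Dra[e, , drop = FALSE])
  m2 <- crossprod(!Drd[!e, , drop = FALSE], !Dra[!e, , drop = FALSE])
  out <- 100 * (m1 + m2) / nrow(results)
  dimnames(out) <- list(rd_grid, ra_grid)
  out
}

#' @export
plot.threshold_region <- function(x, results = NULL,
                                  rd_grid = seq(0, 100, by = 0.5),
                                  ra_grid = seq(0, 100, by = 0.5), ...) {
  if (is.null(results))
    stop("supply the interaction results used to compute the region")
  z <- predictive_surface(results, rd_grid, ra_grid)
  graphics::filled.contour(
    rd_grid, ra_grid, z,
    xlab = "Rdth (%)", ylab = "Rath (%)",
    main = sprintf("Predictive value (max %.1f %%)", x$max_predictive_value),
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      r <- x$rectangles
      graphics::rect(r$rd_low, r$ra_low, r$rd_high, r$ra_high, border = "red",
                     lwd = 2)
    }, ...)
  invisible(x)
}
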