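#' Lag time to 1 % dissolution
#'
#' The dissolution lag time is defined as the earliest time at which the
#' measured profile reaches 1 % dissolved (relevant for encapsulated and
#' enteric-coated formulations). The crossing is located by linear
#' interpolation between the bracketing sample points; if the first sample is
#' already at or above 1 % the lag is 0.
#'
#' @param curve A [dissolution_curve()].
#' @return Lag time in hours.
#' @examples
#' cv <- dissolution_curve("x", c(0, 30, 60), c(0, 0, 2))
#' estimate_lag_time(cv) # 0.75 h: 1 % is crossed halfway between 30 and 60 min
#' @export
estimate_lag_time <- function(curve) {
  stopifnot(inherits(curve, "dissolution_curve"))
  v <- curve$dissolved_pct
  t <- curve$time_min
  if (all(v < 1)) stop(no_dissolution_error(curve$drug_id))
  i <- which(v >= 1)[1L]
  if (i == 1L) return(0)
  j <- i - 1L
  t_cross <- t[j] + (1 - v[j]) / (v[i] - v[j]) * (t[i] - t[j])
  t_cross / 60
}

## Model mean: percent dissolved at time t (minutes) under the extended
## Noyes-Whitney solution x_e * {1 - exp(-kd (t - Tlagd))}, zero before the lag.
nw_mean <- function(time_min, kd_per_s, xe, tlagd_h) {
  ts <- time_min * 60 - tlagd_h * 3600
  ifelse(ts <= 0, 0, xe * (1 - exp(-kd_per_s * ts)))
}

#' Fit the extended Noyes-Whitney dissolution model
#'
#' Fits `xe * (1 - exp(-kd * (t - Tlagd)))` to a measured profile by bounded
#' Levenberg-Marquardt least squares. The lag time `Tlagd` is estimated from
#' the measured curve (time to 1 % dissolved, [estimate_lag_time()]) and held
#' fixed during fitting; `kd` and the equilibrium percent `xe` are free.
#' The dissolution rate constant is initialized from the slope of
#' `-log(1 - x/100)` against time over the rising part of the curve and the
#' optimizer is restarted from three log-spaced multiples of that value.
#'
#' A medium counts as reaching complete dissolution (`complete = TRUE`) when
#' the fitted `xe` is at least 95 % and the last measured point is at least
#' 95 %; only complete fits can be used for interaction prediction, and their
#' theoretical dissolution rate is evaluated with `xe` taken as exactly 100
#' (see [dissolution_rate()]).
#'
#' @param curve A [dissolution_curve()].
#' @param use_lag `NULL` (automatic: a lag is used iff the first measured
#'   value is below 1 % and the estimated lag exceeds 1 minute), or `TRUE` /
#'   `FALSE` to force the choice.
#' @return An object of class `dissolution_fit` with components `drug_id`,
#'   `medium`, `kd_per_s` (s^-1), `tlagd_h` (hours), `xe_pct`, `rss`
#'   (percent^2), `complete`, `fitted`, and the input `curve`.
#' @examples
#' cv <- generate_dissolution_curve(kd_per_s = 25.54e-4,
#'                                  times_min = c(5, 10, 15, 30, 45, 60))
#' fit <- fit_dissolution(cv)
#' coef(fit)
#' @seealso [select_medium_fit()], [dissolution_rate()]
#' @export
fit_dissolution <- function(curve, use_lag = NULL) {
  stopifnot(inherits(curve, "dissolution_curve"))
  t <- curve$time_min
  v <- curve$dissolved_pct
  if (sum(is.finite(v)) < 3L) stop("fewer than 3 usable points")

  if (is.null(use_lag)) {
    lag_try <- tryCatch(estimate_lag_time(curve), ast120_no_dissolution = function(e) NA_real_)
    use_lag <- !is.na(lag_try) && v[1L] < 1 && lag_try * 60 > 1
    tlagd_h <- if (use_lag) lag_try else 0
  } else if (isTRUE(use_lag)) {
    tlagd_h <- estimate_lag_time(curve)
  } else {
    tlagd_h <- 0
  }
  tlag_min <- tlagd_h * 60

  # initial kd (per minute) from the linearized rising phase
  idx <- which(v > 0.5 & v < 95 & t > tlag_min)
  kd0_min <- if (length(idx) >= 2L) {
    x <- t[idx] - tlag_min
    y <- -log(pmax(1 - v[idx] / 100, 1e-10))
    max(sum(x * y) / sum(x * x), 1e-8)
  } else if (length(idx) == 1L) {
    -log(pmax(1 - v[idx] / 100, 1e-10)) / (t[idx] - tlag_min)
  } else {
    0.05
  }
  xe0 <- min(110, max(max(v), 1))

  resid_fun <- function(par) nw_mean(t, par[1L] / 60, par[2L], tlagd_h) - v
  best <- NULL
  diags <- character(0)
  for (mult in c(0.1, 1, 10)) {
    start <- c(kd = kd0_min * mult, xe = xe0)
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fun,
        lower = c(1e-10, 1e-6), upper = c(Inf, 110),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15, gtol = 0)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) { diags <- c(diags, "optimizer error"); next }
    if (!(res$info %in% 1:4)) { diags <- c(diags, res$message); next }
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
  }
  if (is.null(best))
    stop(fitting_error(curve$drug_id, "dissolution fit",
                       paste(unique(diags), collapse = "; ")))

  kd_per_s <- unname(best$par[1L]) / 60
  xe_pct <- unname(best$par[2L])
  complete <- xe_pct >= 95 && v[length(v)] >= 95
  structure(
    list(drug_id = curve$drug_id, medium = curve$medium,
         kd_per_s = kd_per_s, tlagd_h = tlagd_h, xe_pct = xe_pct,
         rss = best$rss, complete = complete, use_lag = isTRUE(use_lag) || tlagd_h > 0,
         fitted = nw_mean(t, kd_per_s, xe_pct, tlagd_h), curve = curve),
    class = "dissolution_fit"
  )
}

#' Select the governing dissolution medium
#'
#' When complete dissolution is reached in both Pharmacopoeia fluids the fit
#' with the larger rate constant governs the interaction prediction; when only
#' one medium completes, that fit is used; when neither completes the drug is
#' excluded from prediction (classed error, see [is_excluded_signal()]).
#'
#' @param fit_ph12,fit_ph68 `dissolution_fit` objects (either may be `NULL`).
#' @return The selected `dissolution_fit`.
#' @export
select_medium_fit <- function(fit_ph12 = NULL, fit_ph68 = NULL) {
  fits <- Filter(Negate(is.null), list(fit_ph12, fit_ph68))
  if (length(fits) == 0L) stop("at least one fit must be supplied")
  stopifnot(all(vapply(fits, inherits, logical(1), "dissolution_fit")))
  complete <- vapply(fits, `[[`, logical(1), "complete")
  drug <- fits[[1L]]$drug_id
  if (!any(complete))
    stop(excluded_drug_error(drug, "complete dissolution not achieved in either fluid"))
  fits <- fits[complete]
  kd <- vapply(fits, `[[`, numeric(1), "kd_per_s")
  fits[[which.max(kd)]]
}

#' Theoretical dissolution rate Rd(t)
#'
#' Percent of the dose predicted dissolved at `t` minutes after intake,
#' `Rd = 100 * (1 - exp(-kd * (t - Tlagd)))`, clamped to \[0, 100\] and equal
#' to 0 at or before the lag time. For fitted curves the equilibrium percent
#' is taken as exactly 100, which is why only complete fits are admissible.
#'
#' @param fit A `dissolution_fit` (must be complete), or a numeric dissolution
#'   rate constant in s^-1 (then `tlagd_h` supplies the lag).
#' @param t_min Dosing interval(s) in minutes, positive. Simultaneous
#'   administration is encoded as 1 minute.
#' @param tlagd_h Lag time in hours; ignored when `fit` is a fit object.
#' @return Rd in percent, vectorized over `t_min`.
#' @examples
#' dissolution_rate(25.54e-4, 1)   # 14.2 % one minute after intake
#' dissolution_rate(17.59e-4, 30)  # 95.8 %
#' @export
dissolution_rate <- function(fit, t_min, tlagd_h = 0) {
  if (inherits(fit, "dissolution_fit")) {
    if (!fit$complete)
      stop(excluded_drug_error(fit$drug_id, "dissolution incomplete; Rd undefined"))
    kd <- fit$kd_per_s
    tlagd_h <- fit$tlagd_h
  } else {
    kd <- as.numeric(fit)
    stopifnot(length(kd) == 1L, kd > 0, tlagd_h >= 0)
  }
  stopifnot(all(t_min > 0))
  ts <- t_min * 60 - tlagd_h * 3600
  pmin(100, pmax(0, ifelse(ts <= 0, 0, 100 * (1 - exp(-kd * ts)))))
}

#' @export
print.dissolution_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Noyes-Whitney dissolution fit: %s (%s)\n", x$drug_id, x$medium))
  cat(sprintf("  kd = %s x10^-4 s^-1, Tlagd = %s h, xe = %s %%\n",
              format(x$kd_per_s * 1e4, digits = digits),
              format(x$tlagd_h, digits = digits),
              format(x$xe_pct, digits = digits)))
  cat(sprintf("  rss = %s, complete dissolution: %s\n",
              format(x$rss, digits = digits), if (x$complete) "yes" else "no"))
  invisible(x)
}

#' @export
coef.dissolution_fit <- function(object, ...) {
  c(kd_per_s = object$kd_per_s, tlagd_h = object$tlagd_h, xe_pct = object$xe_pct)
}

#' @export
predict.dissolution_fit <- function(object, time_min = NULL, ...) {
  if (is.null(time_min)) return(object$fitted)
  nw_mean(time_min, object$kd_per_s, object$xe_pct, object$tlagd_h)
}

#' @export
residuals.dissolution_fit <- function(object, ...) {
  object$curve$dissolved_pct - object$fitted
}

#' @export
summary.dissolution_fit <- function(object, ...) {
  out <- list(fit = object,
              n = length(object$curve$time_min),
              sigma = sqrt(object$rss / max(1, length(object$curve$time_min) - 2L)))
  class(out) <- "summary.dissolution_fit"
  out
}

#' @export
print.summary.dissolution_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  n = %d points, residual sd = %s %%\n", x$n, format(x$sigma, digits = 3)))
  invisible(x)
}

#' @export
plot.dissolution_fit <- function(x, ...) {
  t <- x$curve$time_min
  tt <- seq(min(t), max(t), length.out = 200)
  graphics::plot(t, x$curve$dissolved_pct, xlab = "Time (min)",
                 ylab = "Dissolved (%)", ylim = c(0, 105),
                 main = sprintf("%s (%s)", x$drug_id, x$medium), ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' @export
simulate.dissolution_fit <- function(object, nsim = 1, seed = NULL,
                                     noise_sd = NULL, ...) {
  if (is.null(noise_sd))
    noise_sd <- sqrt(object$rss / max(1, length(object$curve$time_min) - 2L))
  with_seed(seed, {
    lapply(seq_len(nsim), function(i)
      generate_dissolution_curve(
        drug_id = object$drug_id, medium = object$medium,
        kd_per_s = object$kd_per_s, xe = object$xe_pct,
        tlagd_h = object$tlagd_h, times_min = object$curve$time_min,
        noise_sd = noise_sd))
  })
}
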