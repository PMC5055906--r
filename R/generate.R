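#' Evaluate code under a temporary random seed
#'
#' Runs `expr` with the global random state set from `seed`, restoring the
#' previous state afterwards so callers' random streams are untouched. With
#' `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic dissolution curve from known constants
#'
#' Generates a dissolution profile from the extended Noyes-Whitney solution
#' `xe * (1 - exp(-kd * (t - Tlagd)))` plus Gaussian measurement noise,
#' clipped to the assay range \[0, 110\]. Used for parameter-recovery tests
#' and for [simulate()] methods; the noise level emulates the few-percent
#' scatter of graph-read dissolution data.
#'
#' @param drug_id,medium Labels for the generated curve.
#' @param kd_per_s True dissolution rate constant, s^-1.
#' @param xe True equilibrium percent.
#' @param tlagd_h True lag, hours.
#' @param times_min Sampling times in minutes.
#' @param noise_sd Gaussian noise standard deviation in percent (0 = exact
#'   model values).
#' @param seed Optional seed; the same seed reproduces the curve bit-for-bit.
#' @return A [dissolution_curve()].
#' @export
generate_dissolution_curve <- function(drug_id = "synthetic", medium = "pH1.2",
                                       kd_per_s, xe = 100, tlagd_h = 0,
                                       times_min = c(5, 10, 15, 30, 45, 60),
                                       noise_sd = 0, seed = NULL) {
  stopifnot(kd_per_s > 0, xe > 0, xe <= 110, tlagd_h >= 0, noise_sd >= 0)
  mu <- nw_mean(times_min, kd_per_s, xe, tlagd_h)
  v <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  dissolution_curve(drug_id, times_min, pmin(110, pmax(0, v)), medium)
}

#' Synthetic plasma curve from known compartmental parameters
#'
#' Generates concentrations from the one- or two-compartment oral solution
#' plus Gaussian noise scaled to the peak concentration, floored at 0.
#'
#' @param drug_id Label.
#' @param truth Named list: `model_order` (1 or 2), `ka`, `tlaga`, `scale`,
#'   and `ke` (one-compartment) or `alpha`, `beta`, `frac` (two-compartment).
#' @param times_h Sampling times in hours.
#' @param noise_sd Noise standard deviation as a fraction of the peak model
#'   concentration (0 = exact model values).
#' @param seed Optional seed.
#' @return A [plasma_curve()].
#' @export
generate_pk_curve <- function(drug_id = "synthetic", truth, times_h,
                              noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0, truth$model_order %in% c(1, 2))
  mu <- if (truth$model_order == 1) {
    conc_1cmt(times_h, truth$ka, truth$ke, truth$tlaga, truth$scale)
  } else {
    conc_2cmt(times_h, truth$ka, truth$alpha, truth$beta, truth$frac,
              truth$tlaga, truth$scale)
  }
  sd_abs <- noise_sd * max(mu)
  cc <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd_abs))
  plasma_curve(drug_id, times_h, pmax(0, cc))
}
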