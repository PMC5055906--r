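mk_fit1 <- function(ka, ke, tlaga = 0, scale = 1) {
  list(model_order = 1L, ka = ka, tlaga_h = tlaga,
       disposition = c(ke = ke), scale = scale)
}

test_that("concentration is 0 at the lag, peaks at the closed-form tmax", {
  f <- mk_fit1(1.55, 0.3, tlaga = 0.5)
  expect_equal(predict_concentration(f, 0.5), 0)
  expect_equal(predict_concentration(f, 0.2), 0)
  f0 <- mk_fit1(1.55, 0.3)
  tmax <- log(1.55 / 0.3) / (1.55 - 0.3)
  opt <- optimize(function(t) predict_concentration(f0, t),
                  interval = c(0, 24), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, tmax, tolerance = 1e-6)
})

test_that("the ka = ke degeneracy is continuous (analytic limit)", {
  ke <- 0.4
  at_limit <- predict_concentration(mk_fit1(ke, ke), c(0.5, 1, 2, 5))
  near <- predict_concentration(mk_fit1(ke * (1 + 1e-9), ke), c(0.5, 1, 2, 5))
  expect_equal(near, at_limit, tolerance = 1e-6)
  # bracketing from both sides
  below <- predict_concentration(mk_fit1(ke * (1 - 1e-6), ke), 2)
  above <- predict_concentration(mk_fit1(ke * (1 + 1e-6), ke), 2)
  mid <- predict_concentration(mk_fit1(ke, ke), 2)
  expect_true(min(below, above) <= mid && mid <= max(below, above))
})

test_that("noiseless compartmental truths are recovered", {
  cv1 <- generate_pk_curve(truth = list(model_order = 1, ka = 1.55, ke = 0.25,
                                        tlaga = 0, scale = 10),
                           times_h = seq(0.5, 24, length.out = 10))
  f1 <- fit_pk(cv1, 1)
  expect_lt(abs(f1$ka - 1.55) / 1.55, 1e-4)
  expect_lt(abs(f1$disposition[["ke"]] - 0.25) / 0.25, 1e-4)

  cv2 <- generate_pk_curve(truth = list(model_order = 2, ka = 2.49, alpha = 1.2,
                                        beta = 0.15, frac = 0.6, tlaga = 0.28,
                                        scale = 10),
                           times_h = c(0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 6, 8,
                                       12, 16, 20, 24))
  f2 <- fit_pk(cv2, 2)
  expect_lt(abs(f2$ka - 2.49) / 2.49, 1e-3)
  expect_lt(abs(f2$disposition[["alpha"]] - 1.2) / 1.2, 1e-3)
  expect_lt(abs(f2$disposition[["beta"]] - 0.15) / 0.15, 1e-3)
  expect_lt(abs(f2$tlaga_h - 0.28), 1e-3)
  expect_gt(f2$disposition[["alpha"]], f2$disposition[["beta"]])
})

test_that("flip-flop labelings are exchangeable and resolved toward ka >= ke", {
  # exchange symmetry of the model itself: (ka, ke, s) vs (ke, ka, s*ka/ke)
  t <- c(0.5, 1, 2, 4, 8, 16)
  a <- predict_concentration(mk_fit1(0.3, 1.5, scale = 10), t)
  b <- predict_concentration(mk_fit1(1.5, 0.3, scale = 10 * 0.3 / 1.5), t)
  expect_equal(a, b)
  # a flip-flop truth (ka < ke) is reported with the ka >= ke labeling
  cv <- generate_pk_curve(truth = list(model_order = 1, ka = 0.3, ke = 1.5,
                                       tlaga = 0, scale = 10),
                          times_h = pk_sampling_h)
  f <- fit_pk(cv, 1)
  expect_gte(f$ka, f$disposition[["ke"]])
  expect_lt(abs(f$ka - 1.5) / 1.5, 1e-4)
  expect_lt(abs(f$disposition[["ke"]] - 0.3) / 0.3, 1e-4)
})

test_that("rate constants are invariant to uniform concentration rescaling", {
  cv <- generate_pk_curve(truth = list(model_order = 1, ka = 1.55, ke = 0.25,
                                       tlaga = 0, scale = 10),
                          times_h = pk_sampling_h, noise_sd = 0.05, seed = 11)
  f <- fit_pk(cv, 1)
  cv_scaled <- plasma_curve(cv$drug_id, cv$time_h, cv$conc * 1000)
  fs <- fit_pk(cv_scaled, 1)
  expect_lt(abs(fs$ka - f$ka) / f$ka, 1e-8)
  expect_lt(abs(fs$disposition[["ke"]] - f$disposition[["ke"]]) /
              f$disposition[["ke"]], 1e-8)
  expect_equal(fs$scale / f$scale, 1000, tolerance = 1e-8)
})

test_that("information criterion selects the generating model order", {
  truth1 <- list(model_order = 1, ka = 1.55, ke = 0.25, tlaga = 0, scale = 10)
  sel1 <- vapply(1:100, function(s) {
    cv <- generate_pk_curve(truth = truth1, times_h = pk_sampling_h,
                            noise_sd = 0.05, seed = s)
    f1 <- fit_pk(cv, 1)
    f2 <- tryCatch(fit_pk(cv, 2), error = function(e) NULL)
    if (is.null(f2)) 1L else select_model(f1, f2)$model_order
  }, integer(1))
  expect_gte(mean(sel1 == 1L), 0.95)

  truth2 <- list(model_order = 2, ka = 5, alpha = 2, beta = 0.08, frac = 0.85,
                 tlaga = 0, scale = 10)
  t2 <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12, 16, 20, 24)
  sel2 <- vapply(1:50, function(s) {
    cv <- generate_pk_curve(truth = truth2, times_h = t2,
                            noise_sd = 0.03, seed = s)
    select_model(fit_pk(cv, 1), fit_pk(cv, 2))$model_order
  }, integer(1))
  expect_gt(mean(sel2 == 2L), 0.5)
})

test_that("criterion ties go to the one-compartment model", {
  f1 <- structure(list(model_order = 1L, aic = 10), class = "pk_fit")
  f2 <- structure(list(model_order = 2L, aic = 10), class = "pk_fit")
  expect_equal(select_model(f1, f2)$model_order, 1L)
  f2$aic <- 8.5  # within the 2-unit tie window
  expect_equal(select_model(f1, f2)$model_order, 1L)
  expect_equal(select_model(f2, f1)$model_order, 1L)  # argument order irrelevant
  f2$aic <- 7.5
  expect_equal(select_model(f1, f2)$model_order, 2L)
})

test_that("Ra is monotone, clamped below the lag, and saturates at 100", {
  t <- c(1, 5, 30, 60, 120, 240, 1e6)
  ra <- absorption_fraction(1.55, 0, t)
  expect_true(all(diff(ra) >= 0))
  expect_equal(ra[length(ra)], 100)
  expect_equal(absorption_fraction(17.34, 0.44, 1), 0)   # lag clamp
  expect_equal(absorption_fraction(2.49, 0.28, 1), 0)
})

test_that("printed Ra cells reproduce from the printed (ka, Tlaga)", {
  cells <- table2_ra_cells()
  ra <- round(mapply(function(ka, tl, t) absorption_fraction(ka, tl, t),
                     cells$ka, cells$tlaga_h, cells$t_min), 1)
  # two-decimal truncation of printed ka explains residuals up to ~0.3; for
  # nifedipine at 30 min the two-decimal rounding of ka AND Tlaga compounds
  # (computed 42.2 vs printed 41.6), so that one cell gets a wider band
  nif30 <- cells$ka == 2.49 & cells$t_min == 30
  expect_true(all(abs(ra[!nif30] - cells$printed[!nif30]) <= 0.3))
  expect_true(all(abs(ra[nif30] - cells$printed[nif30]) <= 0.65))
  # headline cells at printed precision
  expect_equal(round(absorption_fraction(1.55, 0, 60), 1), 78.8)
  expect_equal(round(absorption_fraction(2.49, 0.28, 120), 1), 98.6)
})

test_that("pk_fit methods are coherent and the lag clamp is observable", {
  cv <- generate_pk_curve(truth = list(model_order = 1, ka = 1.55, ke = 0.25,
                                       tlaga = 0, scale = 10),
                          times_h = pk_sampling_h, noise_sd = 0.05, seed = 5)
  f <- fit_pk(cv, 1)
  expect_gte(f$tlaga_h, 0)
  expect_true(is.numeric(f$tlaga_unclamped))
  expect_named(coef(f), c("ka", "tlaga_h", "ke", "scale"))
  expect_equal(predict(f), f$fitted)
  expect_equal(sum(residuals(f)^2), f$rss)
  expect_output(print(summary(f)), "Tlaga before clamping")
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_s3_class(sims[[2]], "plasma_curve")
  # insufficient points for the requested order
  short <- plasma_curve("s", c(0.5, 1, 2, 4, 8), c(3, 4, 3.5, 2, 1))
  expect_error(fit_pk(short, 2), "at least 6")
})
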