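test_that("bundled fixtures carry the 14 studies over 6 drugs, values as printed", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$results), 14L)
  expect_equal(length(unique(fx$results$drug_id)), 6L)
  expect_equal(nrow(fx$profiles), 6L)
  expect_true(all(fx$results$interval_min %in% c(1, 30, 60, 90, 120, 240)))
  # E labels exactly where the studies found no significant exposure change
  e_rows <- fx$results[fx$results$observed == "E", c("drug_id", "interval_min")]
  expect_equal(paste(e_rows$drug_id, e_rows$interval_min),
               c("amlodipine 90", "amlodipine 240", "bufferin 60",
                 "losartan 60", "nifedipine 1", "nifedipine 30", "nifedipine 120"))
  amlo1 <- fx$results[fx$results$drug_id == "amlodipine" & fx$results$interval_min == 1, ]
  expect_equal(c(amlo1$rd_pct, amlo1$ra_pct), c(14.2, 1.0))
  expect_equal(amlo1$observed, "NE")
  tri <- fx$results[fx$results$drug_id == "triazolam", ]
  expect_equal(tri$ra_pct, 0.0)
  # the governing kd is the larger of the two media
  expect_equal(fx$profiles$kd_per_s,
               pmax(fx$profiles$kd_ph12_per_s, fx$profiles$kd_ph68_per_s))
})

test_that("synthetic generators are exact at sd = 0 and seed-reproducible", {
  cv <- generate_dissolution_curve(kd_per_s = 17.59e-4,
                                   times_min = c(5, 15, 30, 60))
  expect_equal(cv$dissolved_pct, 100 * (1 - exp(-17.59e-4 * c(5, 15, 30, 60) * 60)))
  a <- generate_dissolution_curve(kd_per_s = 1e-3, times_min = c(5, 15, 30),
                                  noise_sd = 2, seed = 7)
  b <- generate_dissolution_curve(kd_per_s = 1e-3, times_min = c(5, 15, 30),
                                  noise_sd = 2, seed = 7)
  expect_identical(a$dissolved_pct, b$dissolved_pct)
  c_ <- generate_dissolution_curve(kd_per_s = 1e-3, times_min = c(5, 15, 30),
                                   noise_sd = 2, seed = 8)
  expect_false(identical(a$dissolved_pct, c_$dissolved_pct))
  expect_true(all(a$dissolved_pct >= 0 & a$dissolved_pct <= 110))

  tr <- list(model_order = 1, ka = 1.55, ke = 0.25, tlaga = 0, scale = 10)
  p0 <- generate_pk_curve(truth = tr, times_h = c(0.5, 1, 2, 4, 8))
  expect_equal(p0$conc, 10 * 1.55 / 1.3 * (exp(-0.25 * c(0.5, 1, 2, 4, 8)) -
                                             exp(-1.55 * c(0.5, 1, 2, 4, 8))))
  p1 <- generate_pk_curve(truth = tr, times_h = c(0.5, 1, 2, 4, 8),
                          noise_sd = 0.1, seed = 3)
  p2 <- generate_pk_curve(truth = tr, times_h = c(0.5, 1, 2, 4, 8),
                          noise_sd = 0.1, seed = 3)
  expect_identical(p1$conc, p2$conc)
  expect_true(all(p1$conc >= 0))
})

test_that("generators leave the caller's random stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_dissolution_curve(kd_per_s = 1e-3, times_min = c(5, 15, 30),
                                       noise_sd = 2, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("CSV readers validate schema, values and the simultaneous alias", {
  td <- withr::local_tempdir()
  # dissolution round trip
  dpath <- file.path(td, "dissolution.csv")
  write.csv(data.frame(drug_id = "d1", medium = "pH1.2",
                       time_min = c(5, 15, 30), dissolved_pct = c(10, 40, 80)),
            dpath, row.names = FALSE)
  curves <- read_dissolution_csv(dpath)
  expect_length(curves, 1)
  expect_equal(curves[[1]]$dissolved_pct, c(10, 40, 80))
  # bad medium
  write.csv(data.frame(drug_id = "d1", medium = "pH7.4",
                       time_min = c(5, 15, 30), dissolved_pct = c(10, 40, 80)),
            dpath, row.names = FALSE)
  expect_error(read_dissolution_csv(dpath), "medium")
  # missing column names the file
  write.csv(data.frame(drug_id = "d1", time_min = 5), dpath, row.names = FALSE)
  expect_error(read_dissolution_csv(dpath), "missing columns")
  # outcomes: simultaneous alias maps to 1
  opath <- file.path(td, "outcomes.csv")
  writeLines(c("drug_id,interval_min,observed",
               "a,simultaneous,NE", "a,30,E"), opath)
  outc <- read_outcomes_csv(opath)
  expect_equal(outc$interval_min, c(1, 30))
  writeLines(c("drug_id,interval_min,observed", "a,30,maybe"), opath)
  expect_error(read_outcomes_csv(opath), "observed")
})

test_that("fixture tables survive a write/read round trip exactly", {
  td <- withr::local_tempdir()
  fx <- load_fixtures()
  ppath <- file.path(td, "profiles.csv")
  write.csv(fx$profiles[, c("drug_id", "kd_per_s", "tlagd_h", "ka_per_h",
                            "tlaga_h", "dissolution_complete")],
            ppath, row.names = FALSE)
  back <- read_profiles_csv(ppath)
  expect_equal(back$kd_per_s, fx$profiles$kd_per_s)
  expect_equal(back$dissolution_complete, fx$profiles$dissolution_complete)
  opath <- file.path(td, "outcomes.csv")
  write.csv(fx$results, opath, row.names = FALSE)
  expect_equal(as.data.frame(read_outcomes_csv(opath)),
               as.data.frame(fx$results))
})

test_that("pipeline runs end-to-end on the bundled set and is deterministic", {
  td <- withr::local_tempdir()
  fx <- load_fixtures()
  ppath <- file.path(td, "profiles.csv")
  write.csv(fx$profiles[, c("drug_id", "kd_per_s", "tlagd_h", "ka_per_h",
                            "tlaga_h", "dissolution_complete")],
            ppath, row.names = FALSE)
  opath <- file.path(td, "outcomes.csv")
  write.csv(fx$results, opath, row.names = FALSE)

  out1 <- file.path(td, "run1")
  res <- run_pipeline(profiles_csv = ppath, outcomes_csv = opath, out_dir = out1)
  expect_equal(round(res$region$max_predictive_value, 1), 85.7)
  expect_equal(res$predictive_value_at_operating_point, 100 * 12 / 14)
  expect_true(file.exists(file.path(out1, "risk.csv")))
  expect_true(file.exists(file.path(out1, "region.json")))
  risk <- read.csv(file.path(out1, "risk.csv"))
  expect_equal(sort(unique(risk$interval_min)), c(1, 30, 60, 90, 120, 240))
  expect_true(all(risk$group[risk$interval_min == 1] == 4L))
  reg_json <- jsonlite::read_json(file.path(out1, "region.json"))
  expect_equal(reg_json$max_predictive_value, 85.7)
  expect_equal(reg_json$rdth$low, 84.8)

  # byte-identical rerun
  out2 <- file.path(td, "run2")
  run_pipeline(profiles_csv = ppath, outcomes_csv = opath, out_dir = out2)
  for (f in c("risk.csv", "region.json", "run.log"))
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))

  # empty outcomes: classification-only run, no region
  epath <- file.path(td, "empty.csv")
  writeLines("drug_id,interval_min,observed", epath)
  res3 <- run_pipeline(profiles_csv = ppath, outcomes_csv = epath,
                       out_dir = file.path(td, "run3"))
  expect_null(res3$region)
  expect_true(file.exists(file.path(td, "run3", "risk.csv")))
})

test_that("pipeline fits raw curves, selects media, and flags excluded drugs", {
  td <- withr::local_tempdir()
  fx <- load_fixtures()
  # noiseless curves for two drugs from their published constants, both media,
  # plus one drug that plateaus below completeness in both media
  rows <- list()
  for (d in c("amlodipine", "nifedipine")) {
    pr <- fx$profiles[fx$profiles$drug_id == d, ]
    for (m in c("pH1.2", "pH6.8")) {
      kd <- if (m == "pH1.2") pr$kd_ph12_per_s else pr$kd_ph68_per_s
      tm <- c(0.2, 0.5, 1, 2, 3) / (kd * 60)
      rows[[paste(d, m)]] <- data.frame(drug_id = d, medium = m, time_min = tm,
                                        dissolved_pct = 100 * (1 - exp(-kd * tm * 60)))
    }
  }
  for (m in c("pH1.2", "pH6.8"))
    rows[[paste("stuck", m)]] <- data.frame(
      drug_id = "stuck", medium = m, time_min = c(5, 15, 30, 60, 120),
      dissolved_pct = 60 * (1 - exp(-2e-3 * c(5, 15, 30, 60, 120) * 60)))
  dpath <- file.path(td, "dissolution.csv")
  write.csv(do.call(rbind, rows), dpath, row.names = FALSE)

  pk_rows <- lapply(c("amlodipine", "nifedipine"), function(d) {
    pr <- fx$profiles[fx$profiles$drug_id == d, ]
    tr <- list(model_order = 1, ka = pr$ka_per_h, ke = pr$ka_per_h / 5,
               tlaga = pr$tlaga_h, scale = 10)
    cv <- generate_pk_curve(drug_id = d, truth = tr,
                            times_h = c(0.25, 0.5, 1, 2, 4, 8, 16))
    data.frame(drug_id = d, time_h = cv$time_h, conc = cv$conc)
  })
  kpath <- file.path(td, "pk.csv")
  write.csv(do.call(rbind, pk_rows), kpath, row.names = FALSE)

  out <- file.path(td, "fitrun")
  res <- run_pipeline(dissolution_csv = dpath, pk_csv = kpath, out_dir = out,
                      intervals = c(1, 30, 90, 240))
  expect_equal(res$unclassifiable, "stuck")
  # governing medium has the larger kd: pH1.2 for amlodipine
  expect_equal(res$profiles$amlodipine$kd_per_s,
               fx$profiles$kd_ph12_per_s[fx$profiles$drug_id == "amlodipine"],
               tolerance = 1e-6)
  expect_equal(res$profiles$nifedipine$ka_per_h,
               fx$profiles$ka_per_h[fx$profiles$drug_id == "nifedipine"],
               tolerance = 1e-4)
  # recovered constants reproduce the published classification path
  expect_equal(res$risk$group[res$risk$drug_id == "amlodipine"], c(4L, 3L, 1L, 1L))
  fits <- read.csv(file.path(out, "dissolution_fits.csv"))
  expect_equal(sum(fits$selected), 2L)
  expect_false(any(fits$complete[fits$drug_id == "stuck"]))
  log <- readLines(file.path(out, "run.log"))
  expect_true(any(grepl("excluded: stuck", log)))

  # outcome rows without a matching profile are an explicit error
  opath <- file.path(td, "orphan.csv")
  write.csv(data.frame(drug_id = "ghost", interval_min = 30, observed = "E"),
            opath, row.names = FALSE)
  expect_error(run_pipeline(profiles_csv = NULL, dissolution_csv = dpath,
                            pk_csv = kpath, outcomes_csv = opath,
                            out_dir = file.path(td, "x")),
               "ghost")
})
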