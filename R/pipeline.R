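#' End-to-end interaction-prediction pipeline
#'
#' Composes the four computation stages over CSV inputs: fit dissolution
#' curves per drug and medium and select the governing medium; fit one- and
#' two-compartment absorption models and keep the information-criterion
#' choice; evaluate Rd/Ra at the candidate dosing intervals and classify each
#' drug into a risk group; and, when interaction-study outcomes are supplied,
#' compute the optimal threshold region and the predictive value at the
#' operating point. All outputs are written to `out_dir`; reruns with
#' identical inputs produce byte-identical files.
#'
#' Rate constants can enter either as raw curves (`dissolution_csv`,
#' `pk_csv`) or pre-fitted (`profiles_csv`); when both are given the fitted
#' values take precedence and the profiles file fills in drugs without
#' curves. Outcome rows carrying their own `rd_pct`/`ra_pct` columns are used
#' as supplied; otherwise the rates are computed from the profiles, and
#' outcome rows without a matching profile are reported as an explicit error.
#' Drugs whose dissolution completes in neither medium are routed to
#' `unclassifiable` rather than dropped. A run log records medium selections,
#' model choices, clamp events (Rd/Ra/lag floors) and exclusions.
#'
#' @param dissolution_csv,pk_csv,profiles_csv,outcomes_csv Input paths (each
#'   optional, but dissolution+pk or profiles must identify at least one drug
#'   unless only outcomes with supplied rates are given).
#' @param out_dir Output directory, created if needed.
#' @param th_rd,th_ra Operating thresholds for classification (default 90/30).
#' @param intervals Dosing intervals in minutes (default
#'   `c(1, 30, 60, 90, 120, 240)`).
#' @param seed Optional seed recorded in the log (the pipeline itself is
#'   deterministic; the seed governs any [simulate()] calls made on the
#'   returned fits).
#' @return Invisibly, a list with `dissolution_fits`, `pk_fits`, `profiles`,
#'   `risk`, `region` (or `NULL`), `predictive_value_at_operating_point`,
#'   `unclassifiable`, and the output paths.
#' @export
run_pipeline <- function(dissolution_csv = NULL, pk_csv = NULL,
                         profiles_csv = NULL, outcomes_csv = NULL,
                         out_dir = ".", th_rd = 90, th_ra = 30,
                         intervals = c(1, 30, 60, 90, 120, 240), seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("ast120di pipeline run",
                 sprintf("thresholds: ThRd = %g, ThRa = %g", th_rd, th_ra),
                 sprintf("intervals (min): %s", paste(intervals, collapse = ", ")),
                 sprintf("seed: %s", if (is.null(seed)) "none" else seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  paths <- list()

  # --- dissolution fits -----------------------------------------------------
  disso_fits <- list()
  selected_disso <- list()   # drug_id -> governing dissolution_fit
  unclassifiable <- character(0)
  if (!is.null(dissolution_csv)) {
    curves <- read_dissolution_csv(dissolution_csv)
    disso_fits <- lapply(curves, fit_dissolution)
    for (drug in unique(vapply(disso_fits, `[[`, character(1), "drug_id"))) {
      of_drug <- Filter(function(f) f$drug_id == drug, disso_fits)
      f12 <- Filter(function(f) f$medium == "pH1.2", of_drug)
      f68 <- Filter(function(f) f$medium == "pH6.8", of_drug)
      sel <- tryCatch(
        select_medium_fit(if (length(f12)) f12[[1L]] else NULL,
                          if (length(f68)) f68[[1L]] else NULL),
        ast120_excluded_drug = function(e) e
      )
      if (is_excluded_signal(sel)) {
        unclassifiable <- c(unclassifiable, drug)
        note("excluded: %s (complete dissolution in neither fluid)", drug)
      } else {
        selected_disso[[drug]] <- sel
        note("medium selected for %s: %s (kd = %g x10^-4 s^-1)",
             drug, sel$medium, sel$kd_per_s * 1e4)
        if (sel$tlagd_h > 0) note("lag used for %s: Tlagd = %g h", drug, sel$tlagd_h)
      }
    }
    paths$dissolution_fits <- file.path(out_dir, "dissolution_fits.csv")
    write_dissolution_fits(
      disso_fits, paths$dissolution_fits,
      selected = vapply(selected_disso, function(f)
        paste(f$drug_id, f$medium, sep = "."), character(1))
    )
  }

  # --- absorption fits ------------------------------------------------------
  pk_fits <- list()
  if (!is.null(pk_csv)) {
    pcurves <- read_pk_csv(pk_csv)
    pk_fits <- lapply(pcurves, function(cv) {
      f1 <- fit_pk(cv, 1L)
      f2 <- if (length(cv$time_h) >= 6L)
        tryCatch(fit_pk(cv, 2L), error = function(e) NULL) else NULL
      sel <- if (is.null(f2)) f1 else select_model(f1, f2)
      note("model selected for %s: %d-compartment (AICc %.2f vs %.2f)",
           cv$drug_id, sel$model_order, f1$aic, if (is.null(f2)) NA_real_ else f2$aic)
      if (sel$tlaga_unclamped < 0)
        note("clamp: %s Tlaga %.4f h -> 0", cv$drug_id, sel$tlaga_unclamped)
      sel
    })
    paths$pk_fits <- file.path(out_dir, "pk_fits.csv")
    write_pk_fits(pk_fits, paths$pk_fits)
  }

  # --- assemble profiles ----------------------------------------------------
  prof <- list()
  for (drug in names(selected_disso)) {
    if (!is.null(pk_fits[[drug]])) {
      prof[[drug]] <- drug_profile(
        drug, kd_per_s = selected_disso[[drug]]$kd_per_s,
        tlagd_h = selected_disso[[drug]]$tlagd_h,
        ka_per_h = pk_fits[[drug]]$ka, tlaga_h = pk_fits[[drug]]$tlaga_h
      )
    } else {
      note("no absorption fit for %s; dropped from classification", drug)
    }
  }
  if (!is.null(profiles_csv)) {
    ptab <- read_profiles_csv(profiles_csv)
    for (i in seq_len(nrow(ptab))) {
      drug <- ptab$drug_id[i]
      if (!is.null(prof[[drug]])) next
      if (!isTRUE(ptab$dissolution_complete[i])) {
        unclassifiable <- c(unclassifiable, drug)
        note("excluded: %s (profile marked dissolution-incomplete)", drug)
        next
      }
      prof[[drug]] <- drug_profile(drug, ptab$kd_per_s[i], ptab$tlagd_h[i],
                                   ptab$ka_per_h[i], ptab$tlaga_h[i])
    }
  }

  # --- risk classification --------------------------------------------------
  risk <- NULL
  if (length(prof) > 0L) {
    risk <- do.call(rbind, lapply(prof[order(names(prof))], classify_profile,
                                  intervals = intervals, th_rd = th_rd,
                                  th_ra = th_ra))
    rownames(risk) <- NULL
    paths$risk <- file.path(out_dir, "risk.csv")
    utils::write.csv(risk, paths$risk, row.names = FALSE)
  }

  # --- threshold optimization against outcomes ------------------------------
  region <- NULL
  pv_op <- NULL
  if (!is.null(outcomes_csv)) {
    outc <- read_outcomes_csv(outcomes_csv)
    if (nrow(outc) == 0L) {
      note("outcomes file empty; classification-only run")
    } else {
      if (!all(c("rd_pct", "ra_pct") %in% names(outc))) {
        missing_prof <- setdiff(unique(outc$drug_id), names(prof))
        if (length(missing_prof) > 0L)
          stop("outcome rows without profiles: ",
               paste(missing_prof, collapse = ", "))
        outc$rd_pct <- mapply(function(d, t)
          dissolution_rate(prof[[d]]$kd_per_s, t, prof[[d]]$tlagd_h),
          outc$drug_id, outc$interval_min)
        outc$ra_pct <- mapply(function(d, t)
          absorption_fraction(prof[[d]]$ka_per_h, prof[[d]]$tlaga_h, t),
          outc$drug_id, outc$interval_min)
      }
      results <- as_interaction_results(outc)
      region <- optimal_region(results)
      pv_op <- predictive_value(results, th_rd, th_ra)
      note("optimal region: max %.1f %% (%d/%d)", region$max_predictive_value,
           region$n_consistent, region$n)
      note("predictive value at operating point (%g, %g): %.1f %%",
           th_rd, th_ra, pv_op)
      if (!region_contains(region, th_rd, th_ra))
        note("warning: operating point lies outside the optimal region")
      paths$region <- file.path(out_dir, "region.json")
      write_region_json(region, paths$region)
    }
  }

  paths$log <- file.path(out_dir, "run.log")
  writeLines(log_lines, paths$log)

  invisible(list(dissolution_fits = disso_fits, pk_fits = pk_fits,
                 profiles = prof, risk = risk, region = region,
                 predictive_value_at_operating_point = pv_op,
                 unclassifiable = unique(unclassifiable), paths = paths))
}
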