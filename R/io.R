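## CSV readers/writers. One dialect everywhere: comma-separated, header row,
## UTF-8, "." decimal. The simultaneous dosing interval is stored as integer 1;
## the alias "simultaneous" is accepted on input.

read_checked <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop(sprintf("malformed CSV '%s': %s",
                                                 path, conditionMessage(e))))
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop(sprintf("file '%s': missing columns %s", path, paste(miss, collapse = ", ")))
  x
}

check_numeric <- function(x, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(x[[cl]]))
    bad <- which(is.na(v) & !is.na(x[[cl]]))
    if (length(bad) > 0L)
      stop(sprintf("file '%s': non-numeric value in column '%s' (data line %d)",
                   path, cl, bad[1L]))
    x[[cl]] <- v
  }
  x
}

parse_interval <- function(x, path) {
  v <- tolower(trimws(as.character(x)))
  v[v == "simultaneous"] <- "1"
  out <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(out))
  if (length(bad) > 0L)
    stop(sprintf("file '%s': unparseable interval_min (data line %d)", path, bad[1L]))
  out
}

#' Read dissolution profiles from CSV
#'
#' @param path CSV with columns `drug_id, medium, time_min, dissolved_pct`;
#'   `medium` must be exactly `pH1.2` or `pH6.8`.
#' @return A named list of [dissolution_curve()] objects, one per
#'   (drug, medium) pair, named `"<drug_id>.<medium>"`.
#' @export
read_dissolution_csv <- function(path) {
  x <- read_checked(path, c("drug_id", "medium", "time_min", "dissolved_pct"))
  x <- check_numeric(x, c("time_min", "dissolved_pct"), path)
  if (!all(x$medium %in% c("pH1.2", "pH6.8")))
    stop(sprintf("file '%s': medium must be 'pH1.2' or 'pH6.8'", path))
  parts <- split(x, interaction(x$drug_id, x$medium, drop = TRUE))
  lapply(parts, function(p) {
    p <- p[order(p$time_min), ]
    dissolution_curve(p$drug_id[1L], p$time_min, p$dissolved_pct, p$medium[1L])
  })
}

#' Read plasma concentration profiles from CSV
#'
#' @param path CSV with columns `drug_id, time_h, conc` (an optional `dose`
#'   column is carried through as an attribute).
#' @return A named list of [plasma_curve()] objects, one per drug.
#' @export
read_pk_csv <- function(path) {
  x <- read_checked(path, c("drug_id", "time_h", "conc"))
  x <- check_numeric(x, c("time_h", "conc"), path)
  parts <- split(x, x$drug_id)
  lapply(parts, function(p) {
    p <- p[order(p$time_h), ]
    cv <- plasma_curve(p$drug_id[1L], p$time_h, p$conc)
    if ("dose" %in% names(p)) attr(cv, "dose") <- p$dose[1L]
    cv
  })
}

#' Read interaction-study outcomes from CSV
#'
#' @param path CSV with columns `drug_id, interval_min, observed`
#'   (`observed` in `{E, NE}`; `interval_min` accepts the alias
#'   `simultaneous` for 1). Optional `rd_pct`/`ra_pct` columns supply the
#'   rates directly; otherwise they are computed from profiles when the
#'   outcomes are used in [run_pipeline()].
#' @return A data frame.
#' @export
read_outcomes_csv <- function(path) {
  x <- read_checked(path, c("drug_id", "interval_min", "observed"))
  if (nrow(x) == 0L) return(x)
  x$interval_min <- parse_interval(x$interval_min, path)
  if (!all(x$observed %in% c("E", "NE")))
    stop(sprintf("file '%s': observed must be 'E' or 'NE'", path))
  if (all(c("rd_pct", "ra_pct") %in% names(x)))
    x <- check_numeric(x, c("rd_pct", "ra_pct"), path)
  x
}

#' Read drug rate-constant profiles from CSV
#'
#' @param path CSV with columns
#'   `drug_id, kd_per_s, tlagd_h, ka_per_h, tlaga_h, dissolution_complete`.
#' @return A data frame.
#' @export
read_profiles_csv <- function(path) {
  x <- read_checked(path, c("drug_id", "kd_per_s", "tlagd_h", "ka_per_h",
                            "tlaga_h", "dissolution_complete"))
  x <- check_numeric(x, c("kd_per_s", "tlagd_h", "ka_per_h", "tlaga_h"), path)
  x$dissolution_complete <- as.logical(x$dissolution_complete)
  x
}

#' Write a table of dissolution fits to CSV
#'
#' @param fits A list of `dissolution_fit` objects.
#' @param path Output CSV (`drug_id, medium, kd_per_s, tlagd_h, xe_pct, rss,
#'   complete, selected`).
#' @param selected Optional character vector of `"<drug_id>.<medium>"` keys
#'   marking the governing fits.
#' @return The written data frame, invisibly.
#' @export
write_dissolution_fits <- function(fits, path, selected = character(0)) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(drug_id = f$drug_id, medium = f$medium, kd_per_s = f$kd_per_s,
               tlagd_h = f$tlagd_h, xe_pct = f$xe_pct, rss = f$rss,
               complete = f$complete,
               selected = paste(f$drug_id, f$medium, sep = ".") %in% selected)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a table of pharmacokinetic fits to CSV
#'
#' @param fits A list of `pk_fit` objects.
#' @param path Output CSV (`drug_id, model_order, ka_per_h, tlaga_h`,
#'   disposition columns, `rss, aic`).
#' @return The written data frame, invisibly.
#' @export
write_pk_fits <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f) {
    d <- f$disposition
    data.frame(drug_id = f$drug_id, model_order = f$model_order,
               ka_per_h = f$ka, tlaga_h = f$tlaga_h,
               ke_per_h = if (f$model_order == 1L) d[["ke"]] else NA_real_,
               alpha_per_h = if (f$model_order == 2L) d[["alpha"]] else NA_real_,
               beta_per_h = if (f$model_order == 2L) d[["beta"]] else NA_real_,
               frac = if (f$model_order == 2L) d[["frac"]] else NA_real_,
               rss = f$rss, aic = f$aic)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a threshold region summary to JSON
#'
#' @param region A `threshold_region` from [optimal_region()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_region_json <- function(region, path) {
  stopifnot(inherits(region, "threshold_region"))
  out <- list(
    max_predictive_value = round(region$max_predictive_value, 1),
    n_results = region$n, n_consistent = region$n_consistent,
    rdth = list(low = region$rdth_low, low_open = region$rdth_low_open,
                high = region$rdth_high, high_closed = TRUE),
    rath = list(low = region$rath_low, low_open = region$rath_low_open,
                high = region$rath_high, high_closed = TRUE),
    rectangles = region$rectangles
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
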