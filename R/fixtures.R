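#' Bundled interaction-study fixtures
#'
#' Loads the six-drug reference set shipped with the package: published rate
#' constants (dissolution constant in each Pharmacopoeia fluid, dissolution
#' lag, absorption constant and lag) for the drugs whose interaction with
#' AST-120 was studied in humans (amlodipine; the aspirin /
#' dihydroxyaluminum-aminoacetate / magnesium-carbonate combination tablet,
#' `bufferin`; losartan; metoprolol extended-release; nifedipine; triazolam),
#' and the 14 interaction-study results joining each studied dosing interval's
#' Rd/Ra values to the observed equivalence label (E: exposure unchanged, NE:
#' AUC or Cmax significantly changed).
#'
#' @return A list of class `ast120_fixtures` with components
#'   `profiles` (6 rows: `drug_id`, `kd_ph12_per_s`, `kd_ph68_per_s`,
#'   `kd_per_s` — the larger, governing constant —, `tlagd_h`, `ka_per_h`,
#'   `tlaga_h`, `dissolution_complete`) and
#'   `results` (14 rows: `drug_id`, `interval_min`, `rd_pct`, `ra_pct`,
#'   `observed`; simultaneous administration encoded as interval 1).
#' @examples
#' fx <- load_fixtures()
#' nrow(fx$results)  # 14
#' @export
load_fixtures <- function() {
  profiles <- utils::read.csv(
    system.file("extdata", "interaction_profiles.csv", package = "ast120di"),
    stringsAsFactors = FALSE
  )
  profiles$kd_per_s <- pmax(profiles$kd_ph12_per_s, profiles$kd_ph68_per_s)
  results <- as_interaction_results(utils::read.csv(
    system.file("extdata", "interaction_outcomes.csv", package = "ast120di"),
    stringsAsFactors = FALSE
  ))
  structure(list(profiles = profiles, results = results),
            class = "ast120_fixtures")
}

#' @export
print.ast120_fixtures <- function(x, ...) {
  cat(sprintf("AST-120 interaction fixtures: %d drug profiles, %d study results (%d E / %d NE)\n",
              nrow(x$profiles), nrow(x$results),
              sum(x$results$observed == "E"), sum(x$results$observed == "NE")))
  invisible(x)
}

#' Drug profile from a fixture row
#'
#' @param fixtures The list from [load_fixtures()].
#' @param drug_id One of the fixture drug ids.
#' @return A [drug_profile()] using the governing (larger) kd.
#' @export
fixture_profile <- function(fixtures, drug_id) {
  row <- fixtures$profiles[fixtures$profiles$drug_id == drug_id, ]
  if (nrow(row) != 1L) stop("unknown fixture drug: ", drug_id)
  drug_profile(drug_id = row$drug_id, kd_per_s = row$kd_per_s,
               tlagd_h = row$tlagd_h, ka_per_h = row$ka_per_h,
               tlaga_h = row$tlaga_h,
               dissolution_complete = row$dissolution_complete)
}
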