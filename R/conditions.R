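#' Structured conditions
#'
#' Drugs whose dissolution never completes in either test medium cannot be
#' scored (no Rd exists), and curves that never reach 1 % dissolved have no
#' lag time. Both situations are signalled as classed errors so callers can
#' route them to an "unclassifiable" bucket instead of aborting a batch.
#'
#' @name ast120-conditions
#' @keywords internal
NULL

excluded_drug_error <- function(drug_id, reason) {
  structure(
    class = c("ast120_excluded_drug", "error", "condition"),
    list(
      message = sprintf("drug '%s' excluded from prediction: %s", drug_id, reason),
      call = sys.call(-1), drug_id = drug_id, reason = reason
    )
  )
}

no_dissolution_error <- function(drug_id) {
  structure(
    class = c("ast120_no_dissolution", "error", "condition"),
    list(
      message = sprintf("drug '%s': profile never reaches 1 %% dissolved; no lag time exists",
                        drug_id),
      call = sys.call(-1), drug_id = drug_id
    )
  )
}

fitting_error <- function(drug_id, what, diagnostics) {
  structure(
    class = c("ast120_fitting_error", "error", "condition"),
    list(
      message = sprintf("drug '%s': %s did not converge (%s)", drug_id, what, diagnostics),
      call = sys.call(-1), drug_id = drug_id, diagnostics = diagnostics
    )
  )
}

#' Test whether a condition is an excluded-drug signal
#'
#' @param cond A condition object (e.g. caught by [tryCatch()]).
#' @return `TRUE` for the exclusion signal raised when neither dissolution
#'   medium reaches completeness, `FALSE` otherwise.
#' @export
is_excluded_signal <- function(cond) inherits(cond, "ast120_excluded_drug")
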