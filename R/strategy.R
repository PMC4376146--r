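# Match strategies and classifier parameters.

#' Define a match strategy
#'
#' A match strategy is a boolean combination over the three linkage
#' identifiers that decides when another patient is a candidate relative of a
#' child: `single` (one identifier), `any_of` (at least one of the listed
#' identifiers equal) or `all_of` (every listed identifier non-missing and
#' equal on both records).
#'
#' @param name Short label used in reports.
#' @param combinator One of `"single"`, `"any_of"`, `"all_of"`.
#' @param identifiers Non-empty subset of `"insurance"`, `"phone"`,
#'   `"address"`; exactly one for `single`.
#' @return A `match_strategy` object.
#' @export
match_strategy <- function(name,
                           combinator = c("single", "any_of", "all_of"),
                           identifiers) {
  combinator <- match.arg(combinator)
  identifiers <- unique(identifiers)
  bad <- setdiff(identifiers, IDENTIFIERS)
  if (length(bad) > 0 || length(identifiers) == 0) {
    abort(
      paste0(
        "identifiers must be a non-empty subset of ",
        paste(IDENTIFIERS, collapse = ", ")
      ),
      class = "fairlink_config_error"
    )
  }
  if (combinator == "single" && length(identifiers) != 1) {
    abort("a single strategy lists exactly one identifier",
      class = "fairlink_config_error"
    )
  }
  identifiers <- IDENTIFIERS[IDENTIFIERS %in% identifiers]
  structure(
    list(name = name, combinator = combinator, identifiers = identifiers),
    class = "match_strategy"
  )
}

#' @export
print.match_strategy <- function(x, ...) {
  cat(sprintf(
    "<match_strategy> %s: %s{%s}\n", x$name, x$combinator,
    paste(x$identifiers, collapse = ", ")
  ))
  invisible(x)
}

#' The six identifier strategies evaluated in the pilot study design
#'
#' Each identifier alone, insurance-or-phone, any-of-three, and
#' insurance-and-phone.
#'
#' @return Named list of [match_strategy()] objects.
#' @export
study_strategies <- function() {
  s <- list(
    match_strategy("insurance", "single", "insurance"),
    match_strategy("phone", "single", "phone"),
    match_strategy("address", "single", "address"),
    match_strategy("insurance_or_phone", "any_of", c("insurance", "phone")),
    match_strategy(
      "insurance_phone_or_address", "any_of",
      c("insurance", "phone", "address")
    ),
    match_strategy("insurance_and_phone", "all_of", c("insurance", "phone"))
  )
  stats::setNames(s, vapply(s, `[[`, character(1), "name"))
}

#' Parameters of the mother-classification rule
#'
#' A candidate is classified as the child's mother when she is recorded
#' female and is `min_age_gap_years` to `max_age_gap_years` older than the
#' child (inclusive, completed years at `reference_date`). When several
#' candidates qualify, the tie-break cascade prefers stronger evidence —
#' by default candidates matching on both insurance and phone, then
#' insurance, then phone — and the oldest female among the survivors is
#' selected (avoiding sibling links); a residual birth-date tie is broken on
#' the smallest `patient_id` so runs are deterministic.
#'
#' @param reference_date `Date` at which ages are computed.
#' @param min_age_gap_years,max_age_gap_years Inclusive age-gap window in
#'   completed years (defaults 15 and 50).
#' @param tie_break_cascade Ordered list of identifier sets; each stage keeps
#'   only candidates whose matched identifiers contain the whole stage set,
#'   and a stage that would eliminate everyone is skipped.
#' @param final_rule Only `"oldest_female"` is defined.
#' @return A `classifier_params` object.
#' @export
classifier_params <- function(reference_date,
                              min_age_gap_years = 15L,
                              max_age_gap_years = 50L,
                              tie_break_cascade = list(
                                c("insurance", "phone"),
                                "insurance",
                                "phone"
                              ),
                              final_rule = "oldest_female") {
  min_age_gap_years <- as.integer(min_age_gap_years)
  max_age_gap_years <- as.integer(max_age_gap_years)
  if (!(min_age_gap_years > 0 && min_age_gap_years <= max_age_gap_years)) {
    abort("need 0 < min_age_gap_years <= max_age_gap_years",
      class = "fairlink_config_error"
    )
  }
  if (!identical(final_rule, "oldest_female")) {
    abort("final_rule must be 'oldest_female'",
      class = "fairlink_config_error"
    )
  }
  bad <- setdiff(unlist(tie_break_cascade), IDENTIFIERS)
  if (length(bad) > 0) {
    abort(paste0("unknown identifier in tie_break_cascade: ", bad[1]),
      class = "fairlink_config_error"
    )
  }
  structure(
    list(
      reference_date = as.Date(reference_date),
      min_age_gap_years = min_age_gap_years,
      max_age_gap_years = max_age_gap_years,
      tie_break_cascade = tie_break_cascade,
      final_rule = final_rule
    ),
    class = "classifier_params"
  )
}
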