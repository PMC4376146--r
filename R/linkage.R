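# The two-step automated linkage algorithm: candidate generation by exact
# identifier matching (step 1) and mother classification by the
# oldest-eligible-female rule with a tie-break cascade (step 2).

#' Select the index cohort of children
#'
#' Children are patients aged at most `max_age_years` in completed years at
#' `reference_date` (and at least 0 — patients born after the reference date
#' are excluded). Optionally restricts to a phone area code and draws a
#' uniform random sample without replacement; both the full cohort and the
#' sample are returned sorted by `patient_id`, so a fixed seed gives a fixed
#' cohort.
#'
#' @param patients Patient tibble.
#' @param max_age_years Inclusive upper age bound (default 17).
#' @param reference_date `Date` at which age is computed.
#' @param sample_size Optional sample size; must not exceed the eligible
#'   cohort size.
#' @param seed Optional integer seed for the sample draw (the caller's RNG
#'   state is left untouched).
#' @param area_code Optional string; keep only children whose normalized
#'   phone key starts with it (e.g. `"774"`).
#' @param rules [normalization_rules()] used for the area-code filter.
#' @return Character vector of child `patient_id`s, sorted.
#' @export
select_index_cohort <- function(patients, max_age_years = 17L,
                                reference_date,
                                sample_size = NULL, seed = NULL,
                                area_code = NULL,
                                rules = normalization_rules()) {
  if (max_age_years < 0) {
    abort("max_age_years must be >= 0", class = "fairlink_config_error")
  }
  age <- age_completed_years(patients$birth_date, reference_date)
  keep <- age >= 0 & age <= max_age_years
  if (!is.null(area_code)) {
    key <- normalize_phone(patients$phone_raw, rules)
    keep <- keep & !is.na(key) & startsWith(key, area_code)
  }
  cohort <- sort(patients$patient_id[keep])
  if (is.null(sample_size)) {
    return(cohort)
  }
  if (sample_size > length(cohort)) {
    abort(
      sprintf(
        "sample_size (%d) exceeds eligible cohort size (%d)",
        sample_size, length(cohort)
      ),
      class = "fairlink_config_error"
    )
  }
  sort(local_seed(seed, sample(cohort, sample_size)))
}

#' Build an inverted identifier index
#'
#' Maps each identifier key to the set of patients carrying it, so candidate
#' search is a hash lookup instead of an all-pairs scan. Missing keys are
#' indexed nowhere.
#'
#' @param normalized Output of [normalize_table()].
#' @return An `identifier_index` object.
#' @export
build_identifier_index <- function(normalized) {
  by_key <- lapply(c(
    insurance = "insurance_key", phone = "phone_key",
    address = "address_key"
  ), function(col) {
    keep <- !is.na(normalized[[col]])
    split(normalized$patient_id[keep], normalized[[col]][keep])
  })
  structure(list(keys = normalized, by_key = by_key),
    class = "identifier_index"
  )
}

#' Find candidate relatives for one child
#'
#' Step 1 of the linkage algorithm: patients sharing identifier keys with
#' the child, under a [match_strategy()]. For `single`/`any_of`, any listed
#' identifier equal on both records qualifies; for `all_of`, every listed
#' identifier must be non-missing and equal on both records. The child never
#' matches itself, and a missing key never matches anything.
#'
#' @param child_id The child's `patient_id` (must be in the index).
#' @param index From [build_identifier_index()].
#' @param strategy A [match_strategy()].
#' @return Tibble of candidates: `child_id`, `candidate_id`,
#'   `shared_identifiers` (all listed identifiers shared with the child, as
#'   a `+`-joined string in canonical order).
#' @export
find_candidates <- function(child_id, index, strategy) {
  keys <- index$keys
  row <- match(child_id, keys$patient_id)
  if (is.na(row)) {
    abort(paste0("unknown child_id: ", child_id),
      class = "fairlink_data_error"
    )
  }
  shared <- list()
  for (ident in strategy$identifiers) {
    key <- keys[[paste0(ident, "_key")]][row]
    ids <- if (is.na(key)) character(0) else index$by_key[[ident]][[key]]
    shared[[ident]] <- setdiff(ids, child_id)
  }
  cand <- if (strategy$combinator == "all_of") {
    Reduce(intersect, shared)
  } else {
    unique(unlist(shared, use.names = FALSE))
  }
  if (length(cand) == 0) {
    return(tibble(
      child_id = character(0), candidate_id = character(0),
      shared_identifiers = character(0)
    ))
  }
  label <- vapply(cand, function(id) {
    identifier_set_label(names(shared)[vapply(
      shared, function(s) id %in% s,
      logical(1)
    )])
  }, character(1))
  tibble(
    child_id = child_id, candidate_id = unname(cand),
    shared_identifiers = unname(label)
  )
}

#' Classify the mother among a child's candidates
#'
#' Step 2 of the linkage algorithm. Candidates are filtered to patients
#' recorded female whose age gap over the child (difference in completed
#' years at the reference date) lies in the configured window. If more than
#' one remains, the tie-break cascade is applied: each stage keeps the
#' candidates whose shared identifiers contain the stage's whole set,
#' skipping any stage that would leave none, and stopping at the first stage
#' that leaves at least one. The oldest survivor is selected; a residual
#' birth-date tie falls to the smallest `patient_id`. A child with no
#' surviving candidate gets a no-link record.
#'
#' @param child_id The child's `patient_id`.
#' @param candidates Tibble from [find_candidates()] for this child.
#' @param patients Patient tibble (for sex and birth date lookups).
#' @param params A [classifier_params()].
#' @return One-row link tibble: `child_id`, `mother_id` (`NA` when no link),
#'   `matched_identifiers`, `tie_break_path`, `n_candidates`.
#' @export
classify_mother <- function(child_id, candidates, patients, params) {
  no_link <- tibble(
    child_id = child_id, mother_id = NA_character_,
    matched_identifiers = NA_character_,
    tie_break_path = NA_character_,
    n_candidates = nrow(candidates)
  )
  if (nrow(candidates) == 0) {
    return(no_link)
  }
  if (!all(candidates$child_id == child_id)) {
    abort("candidates do not all reference the child",
      class = "fairlink_data_error"
    )
  }

  ref <- params$reference_date
  child_row <- match(child_id, patients$patient_id)
  child_age <- age_completed_years(patients$birth_date[child_row], ref)

  rows <- match(candidates$candidate_id, patients$patient_id)
  gap <- age_completed_years(patients$birth_date[rows], ref) - child_age
  eligible <- patients$sex[rows] == "female" &
    gap >= params$min_age_gap_years & gap <= params$max_age_gap_years

  surv <- candidates[eligible, , drop = FALSE]
  if (nrow(surv) == 0) {
    return(no_link)
  }

  path <- character(0)
  if (nrow(surv) > 1) {
    for (stage in params$tie_break_cascade) {
      keep <- vapply(surv$shared_identifiers, function(lbl) {
        all(stage %in% identifier_set_unlabel(lbl))
      }, logical(1))
      path <- c(path, identifier_set_label(stage))
      if (any(keep)) {
        surv <- surv[keep, , drop = FALSE]
        if (nrow(surv) >= 1) break
      }
    }
    if (nrow(surv) > 1) path <- c(path, "oldest_female")
  }

  birth <- patients$birth_date[match(surv$candidate_id, patients$patient_id)]
  oldest <- surv[birth == min(birth), , drop = FALSE]
  if (nrow(oldest) > 1) {
    path <- c(path, "patient_id")
    oldest <- oldest[order(oldest$candidate_id)[1], , drop = FALSE]
  }

  tibble(
    child_id = child_id,
    mother_id = oldest$candidate_id[1],
    matched_identifiers = oldest$shared_identifiers[1],
    tie_break_path = if (length(path) == 0) {
      NA_character_
    } else {
      paste(path, collapse = " > ")
    },
    n_candidates = nrow(candidates)
  )
}

#' Link an index cohort of children to their likely mothers
#'
#' Runs the full two-step pipeline — [normalize_table()],
#' [build_identifier_index()], [find_candidates()] and [classify_mother()]
#' per child — and returns one link record per child, in cohort order. The
#' output is a pure function of its inputs: identical data and configuration
#' give a byte-identical link table.
#'
#' @param patients Patient tibble.
#' @param cohort Character vector of child `patient_id`s (must all exist in
#'   `patients`).
#' @param strategy A [match_strategy()].
#' @param params A [classifier_params()].
#' @param rules A [normalization_rules()].
#' @return Link tibble, one row per cohort child (see [classify_mother()]).
#' @examples
#' pop <- simulate_population(simulation_config(n_children = 50, seed = 1))
#' params <- classifier_params(reference_date = as.Date("2014-06-30"))
#' links <- link_cohort(
#'   pop$patients, pop$reference$child_id,
#'   study_strategies()$insurance_or_phone, params
#' )
#' head(links)
#' @export
link_cohort <- function(patients, cohort, strategy, params,
                        rules = normalization_rules()) {
  unknown <- setdiff(cohort, patients$patient_id)
  if (length(unknown) > 0) {
    abort(
      paste0(
        "cohort child_id(s) not in patient table: ",
        paste(utils::head(unknown, 5), collapse = ", ")
      ),
      class = "fairlink_data_error"
    )
  }
  normalized <- normalize_table(patients, rules)
  index <- build_identifier_index(normalized)
  links <- purrr::map(cohort, function(id) {
    classify_mother(id, find_candidates(id, index, strategy),
      patients,
      params = params
    )
  })
  out <- dplyr::bind_rows(links)
  if (length(cohort) == 0) {
    out <- tibble(
      child_id = character(0), mother_id = character(0),
      matched_identifiers = character(0),
      tie_break_path = character(0), n_candidates = integer(0)
    )
  }
  validate_links(out)
  out
}
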