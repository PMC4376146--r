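# Independent O(n^2) brute-force implementation of the linkage algorithm:
# every patient is compared against every cohort child directly on the
# normalized keys (no inverted index), and the classification rule is
# re-transcribed with its own completed-years age computation. Used only as
# a test oracle.

oracle_age <- function(birth, ref) {
  # completed years = number of whole-year steps from birth to ref
  length(seq(as.Date(birth), as.Date(ref), by = "year")) - 1L
}

brute_force_link <- function(patients, cohort, strategy, params,
                             rules = normalization_rules()) {
  norm <- normalize_table(patients, rules)
  keys <- list(
    insurance = norm$insurance_key,
    phone = norm$phone_key,
    address = norm$address_key
  )
  ids <- norm$patient_id
  ages <- vapply(
    patients$birth_date, oracle_age,
    integer(1),
    ref = params$reference_date
  )
  sexes <- patients$sex
  births <- patients$birth_date

  out <- lapply(cohort, function(child) {
    ci <- which(ids == child)
    # all-pairs key equality against every other patient
    eq <- sapply(strategy$identifiers, function(ident) {
      kc <- keys[[ident]][ci]
      k <- keys[[ident]]
      !is.na(kc) & !is.na(k) & k == kc
    })
    eq <- matrix(eq,
      ncol = length(strategy$identifiers),
      dimnames = list(NULL, strategy$identifiers)
    )
    eq[ci, ] <- FALSE
    is_cand <- if (strategy$combinator == "all_of") {
      rowSums(eq) == length(strategy$identifiers)
    } else {
      rowSums(eq) >= 1
    }
    n_cand <- sum(is_cand)
    cand_id <- ids[is_cand]
    cand_shared <- lapply(which(is_cand), function(j) {
      strategy$identifiers[eq[j, ]]
    })

    gap <- ages[is_cand] - ages[ci]
    keep <- sexes[is_cand] == "female" &
      gap >= params$min_age_gap_years & gap <= params$max_age_gap_years
    cand_id <- cand_id[keep]
    cand_shared <- cand_shared[keep]

    if (length(cand_id) == 0) {
      return(tibble::tibble(
        child_id = child, mother_id = NA_character_,
        matched_identifiers = NA_character_, n_candidates = n_cand
      ))
    }
    if (length(cand_id) > 1) {
      for (stage in params$tie_break_cascade) {
        hit <- vapply(cand_shared, function(s) all(stage %in% s), logical(1))
        if (any(hit)) {
          cand_id <- cand_id[hit]
          cand_shared <- cand_shared[hit]
          break
        }
      }
    }
    # oldest female; residual birth-date tie -> smallest patient_id
    b <- births[match(cand_id, ids)]
    best <- order(b, cand_id)[1]
    tibble::tibble(
      child_id = child,
      mother_id = cand_id[best],
      matched_identifiers = paste(
        c("insurance", "phone", "address")[
          c("insurance", "phone", "address") %in% cand_shared[[best]]
        ],
        collapse = "+"
      ),
      n_candidates = n_cand
    )
  })
  dplyr::bind_rows(out)
}
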