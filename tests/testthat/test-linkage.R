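test_that("index cohort selection applies the inclusive age bound", {
  patients <- make_patients(
    list(id = "A17", birth = format(birth_for_age(17, 0)), sex = "male"),
    list(id = "A17b", birth = format(birth_for_age(17, 364)), sex = "male"),
    list(id = "A18", birth = format(birth_for_age(18, 0)), sex = "male"),
    list(id = "BABY", birth = format(REF_DATE - 10), sex = "female"),
    list(id = "UNBORN", birth = format(REF_DATE + 10), sex = "female")
  )
  cohort <- select_index_cohort(patients, 17, REF_DATE)
  # a child is 17 from the 17th birthday to the day before the 18th
  expect_setequal(cohort, c("A17", "A17b", "BABY"))
})

test_that("cohort sampling is seed-deterministic and validated", {
  patients <- do.call(make_patients, lapply(1:10, function(i) {
    list(id = sprintf("C%02d", i), birth = format(birth_for_age(i %% 5 + 1)))
  }))
  all10 <- select_index_cohort(patients, 17, REF_DATE, sample_size = 10, seed = 1)
  expect_equal(all10, sort(patients$patient_id))
  s1 <- select_index_cohort(patients, 17, REF_DATE, sample_size = 4, seed = 9)
  s2 <- select_index_cohort(patients, 17, REF_DATE, sample_size = 4, seed = 9)
  expect_identical(s1, s2)
  expect_error(
    select_index_cohort(patients, 17, REF_DATE, sample_size = 11),
    "11.*10",
    class = "fairlink_config_error"
  )
})

test_that("area-code restriction filters on the normalized phone prefix", {
  patients <- make_patients(
    list(id = "C1", birth = "2005-01-01", phone = "(774) 555-0001"),
    list(id = "C2", birth = "2005-01-01", phone = "(617) 555-0002"),
    list(id = "C3", birth = "2005-01-01")
  )
  expect_equal(
    select_index_cohort(patients, 17, REF_DATE, area_code = "774"),
    "C1"
  )
})

test_that("the identifier index maps keys to patient sets and skips missing", {
  patients <- make_patients(
    list(id = "P1", birth = "2000-01-01", phone = "(774) 555-0123"),
    list(id = "P2", birth = "1980-01-01", phone = "774-555-0123"),
    list(id = "P3", birth = "1980-01-01")
  )
  idx <- build_identifier_index(normalize_table(patients))
  expect_setequal(idx$by_key$phone[["7745550123"]], c("P1", "P2"))
  # a patient with every key missing is indexed nowhere
  expect_false("P3" %in% unlist(idx$by_key))
})

test_that("candidate generation respects the strategy combinator", {
  patients <- make_patients(
    list(
      id = "C1", birth = "2006-01-01", phone = "7745550123",
      insurance = "ABC1-01"
    ),
    list(id = "P2", birth = "1980-01-01", phone = "7745550123",
      insurance = "XYZ9-01")
  )
  idx <- build_identifier_index(normalize_table(patients))
  s <- study_strategies()

  any_ip <- find_candidates("C1", idx, s$insurance_or_phone)
  expect_equal(any_ip$candidate_id, "P2")
  expect_equal(any_ip$shared_identifiers, "phone")

  # the same pair fails the conjunctive strategy
  expect_equal(nrow(find_candidates("C1", idx, s$insurance_and_phone)), 0)

  # a missing identifier never matches
  patients2 <- make_patients(
    list(id = "C1", birth = "2006-01-01"),
    list(id = "P2", birth = "1980-01-01", insurance = "ABC1-01")
  )
  idx2 <- build_identifier_index(normalize_table(patients2))
  expect_equal(nrow(find_candidates("C1", idx2, s$insurance)), 0)
})

test_that("mother classification applies sex, age window, cascade and oldest rule", {
  params <- default_params()
  child <- make_patients(list(id = "C1", sex = "male", birth = "2006-03-15"))

  cand_tbl <- function(ids, shared) {
    tibble::tibble(
      child_id = "C1", candidate_id = ids,
      shared_identifiers = shared
    )
  }

  # no candidates -> no link
  none <- classify_mother(
    "C1", cand_tbl(character(0), character(0)),
    child, params
  )
  expect_true(is.na(none$mother_id))
  expect_true(is.na(none$matched_identifiers))
  expect_equal(none$n_candidates, 0)

  # one female candidate 22 years older -> linked
  pats <- dplyr::bind_rows(child, make_patients(
    list(id = "F22", sex = "female", birth = "1984-03-15")
  ))
  one <- classify_mother("C1", cand_tbl("F22", "phone"), pats, params)
  expect_equal(one$mother_id, "F22")
  expect_true(is.na(one$tie_break_path))

  # 14-year gap is below the inclusive window -> no link
  pats14 <- dplyr::bind_rows(child, make_patients(
    list(id = "F14", sex = "female", birth = "1992-03-15")
  ))
  expect_true(is.na(
    classify_mother("C1", cand_tbl("F14", "phone"), pats14, params)$mother_id
  ))

  # boundary gaps 15 and 50 are both eligible
  for (yr in c("1991-03-15", "1956-03-15")) {
    pb <- dplyr::bind_rows(child, make_patients(
      list(id = "FB", sex = "female", birth = yr)
    ))
    expect_equal(
      classify_mother("C1", cand_tbl("FB", "phone"), pb, params)$mother_id,
      "FB"
    )
  }

  # males are never classified as mothers
  patsm <- dplyr::bind_rows(child, make_patients(
    list(id = "M30", sex = "male", birth = "1980-01-01")
  ))
  expect_true(is.na(
    classify_mother("C1", cand_tbl("M30", "phone"), patsm, params)$mother_id
  ))

  # cascade: insurance+phone evidence beats an older insurance-only candidate
  pats2 <- dplyr::bind_rows(child, make_patients(
    list(id = "A", sex = "female", birth = "1985-01-01"),
    list(id = "B", sex = "female", birth = "1975-01-01")
  ))
  casc <- classify_mother(
    "C1", cand_tbl(c("A", "B"), c("insurance+phone", "insurance")),
    pats2, params
  )
  expect_equal(casc$mother_id, "A")
  expect_match(casc$tie_break_path, "insurance\\+phone")

  # phone-only tie falls to the oldest female
  old <- classify_mother(
    "C1", cand_tbl(c("A", "B"), c("phone", "phone")), pats2, params
  )
  expect_equal(old$mother_id, "B")
  expect_match(old$tie_break_path, "oldest_female")

  # identical birth dates: deterministic smallest-id tie break, logged
  pats3 <- dplyr::bind_rows(child, make_patients(
    list(id = "Z", sex = "female", birth = "1985-01-01"),
    list(id = "Y", sex = "female", birth = "1985-01-01")
  ))
  tie <- classify_mother(
    "C1", cand_tbl(c("Z", "Y"), c("phone", "phone")), pats3, params
  )
  expect_equal(tie$mother_id, "Y")
  expect_match(tie$tie_break_path, "patient_id")
})

test_that("link_cohort links a hand-built household to the mother", {
  phone <- "(774) 555-8800"
  patients <- make_patients(
    list(id = "KID", sex = "male", birth = "2008-05-01", phone = phone),
    list(id = "MOM", sex = "female", birth = "1982-02-01", phone = phone),
    list(id = "DAD", sex = "male", birth = "1979-01-01", phone = phone),
    list(id = "GRAN", sex = "female", birth = "1948-01-01", phone = phone),
    list(id = "OTHER", sex = "female", birth = "1985-01-01",
      phone = "(774) 555-0001"),
    list(id = "SIB", sex = "female", birth = "2004-03-01", phone = phone)
  )
  links <- link_cohort(
    patients, "KID", study_strategies()$phone, default_params()
  )
  # father is male, grandmother is 60 years older, sibling gap is 4:
  # only the mother survives the filter
  expect_equal(links$mother_id, "MOM")
  expect_equal(links$matched_identifiers, "phone")
  expect_equal(links$n_candidates, 4)
})

test_that("link_cohort handles empty cohorts and unknown children", {
  patients <- make_patients(list(id = "P1", birth = "2000-01-01"))
  empty <- link_cohort(
    patients, character(0), study_strategies()$phone, default_params()
  )
  expect_equal(nrow(empty), 0)
  expect_named(empty, c(
    "child_id", "mother_id", "matched_identifiers",
    "tie_break_path", "n_candidates"
  ))
  expect_error(
    link_cohort(patients, "GHOST", study_strategies()$phone, default_params()),
    "GHOST",
    class = "fairlink_data_error"
  )
})

test_that("linkage is deterministic: identical inputs give identical output files", {
  pop <- simulate_population(simulation_config(n_children = 60, seed = 11))
  params <- default_params()
  s <- study_strategies()$insurance_or_phone
  f1 <- tempfile()
  f2 <- tempfile()
  write_links(link_cohort(pop$patients, pop$reference$child_id, s, params), f1)
  write_links(link_cohort(pop$patients, pop$reference$child_id, s, params), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("indexed candidate search agrees with a brute-force all-pairs scan", {
  pop <- simulate_population(simulation_config(n_children = 12, seed = 3))
  patients <- utils::head(pop$patients, 20)
  norm <- normalize_table(patients)
  idx <- build_identifier_index(norm)
  s <- study_strategies()$insurance_phone_or_address
  for (child in patients$patient_id) {
    fast <- find_candidates(child, idx, s)
    slow <- brute_force_link(
      patients, child, s, default_params()
    )
    # candidate counts must agree with the all-pairs oracle
    expect_equal(nrow(fast), slow$n_candidates[1])
  }
})

test_that("candidate sets are monotone across the strategy lattice", {
  pop <- simulate_population(simulation_config(n_children = 40, seed = 5))
  idx <- build_identifier_index(normalize_table(pop$patients))
  s <- study_strategies()
  for (child in pop$reference$child_id[1:20]) {
    any2 <- find_candidates(child, idx, s$insurance_or_phone)$candidate_id
    any3 <- find_candidates(
      child, idx,
      s$insurance_phone_or_address
    )$candidate_id
    ins <- find_candidates(child, idx, s$insurance)$candidate_id
    ph <- find_candidates(child, idx, s$phone)$candidate_id
    both <- find_candidates(child, idx, s$insurance_and_phone)$candidate_id
    expect_true(all(ins %in% any2))
    expect_true(all(ph %in% any2))
    expect_true(all(any2 %in% any3))
    expect_true(all(both %in% ins))
    expect_true(all(both %in% ph))
  }
})

test_that("no self-links and no out-of-window or male mothers are ever emitted", {
  pop <- simulate_population(simulation_config(
    n_children = 150, seed = 21,
    p_stepmother = 0.2, p_unit_missing = 0.6, n_decoy_households = 3
  ))
  params <- default_params()
  for (s in study_strategies()[c("phone", "insurance_phone_or_address")]) {
    links <- link_cohort(pop$patients, pop$reference$child_id, s, params)
    got <- links[!is.na(links$mother_id), ]
    expect_false(any(got$mother_id == got$child_id))
    rows <- match(got$mother_id, pop$patients$patient_id)
    expect_true(all(pop$patients$sex[rows] == "female"))
    gap <- age_completed_years(pop$patients$birth_date[rows], REF_DATE) -
      age_completed_years(
        pop$patients$birth_date[
          match(got$child_id, pop$patients$patient_id)
        ],
        REF_DATE
      )
    expect_true(all(gap >= 15 & gap <= 50))
  }
})
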