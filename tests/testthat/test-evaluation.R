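ref4 <- tibble::tibble(
  child_id = c("C1", "C2", "C3", "C4"),
  mother_id = c("M1", "M2", NA, NA)
)
links4 <- tibble::tibble(
  child_id = c("C1", "C2", "C3", "C4"),
  mother_id = c("M1", NA, NA, "X9"),
  matched_identifiers = c("phone", NA, NA, "address"),
  tie_break_path = NA_character_,
  n_candidates = c(1L, 0L, 0L, 1L)
)

test_that("confusion counts enumerate the four per-child outcomes", {
  cc <- confusion(links4, ref4)
  expect_equal(as.list(cc[, c("tp", "fp", "tn", "fn")]),
    list(tp = 1L, fp = 1L, tn = 1L, fn = 1L),
    ignore_attr = TRUE
  )
  # per_child counts always partition the cohort
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, nrow(ref4))
})

test_that("an empty link table over a no-mother reference is all TN", {
  ref <- tibble::tibble(
    child_id = sprintf("C%02d", 1:10),
    mother_id = NA_character_
  )
  links <- tibble::tibble(
    child_id = ref$child_id, mother_id = NA_character_,
    matched_identifiers = NA_character_, tie_break_path = NA_character_,
    n_candidates = 0L
  )
  cc <- confusion(links, ref)
  expect_equal(unlist(cc), c(tp = 0L, fp = 0L, tn = 10L, fn = 0L))
})

test_that("a wrong-person link is FN in per_child mode and FN+FP in strict mode", {
  ref <- tibble::tibble(child_id = "C1", mother_id = "M1")
  links <- tibble::tibble(
    child_id = "C1", mother_id = "W1",
    matched_identifiers = "phone", tie_break_path = NA_character_,
    n_candidates = 1L
  )
  pc <- confusion(links, ref, mode = "per_child")
  expect_equal(unlist(pc), c(tp = 0L, fp = 0L, tn = 0L, fn = 1L))
  st <- confusion(links, ref, mode = "strict")
  expect_equal(unlist(st), c(tp = 0L, fp = 1L, tn = 0L, fn = 1L))
})

test_that("mismatched child sets are a fatal error", {
  expect_error(
    confusion(links4[1:3, ], ref4),
    "same set",
    class = "fairlink_data_error"
  )
})

test_that("test characteristics compute the four metrics with printed rounding", {
  tc <- test_characteristics(
    tibble::tibble(tp = 264, fn = 137, fp = 6, tn = 93)
  )
  est <- setNames(tc$percent, tc$metric)
  expect_equal(unname(est["sensitivity"]), 65.8)
  expect_equal(unname(est["ppv"]), 97.8)
  expect_equal(unname(est["npv"]), 40.4)
  sp <- test_characteristics(
    tibble::tibble(tp = 264, fn = 137, fp = 6, tn = 93),
    rounding = "whole_percent"
  )
  expect_equal(sp$percent[sp$metric == "specificity"], 94)
  expect_equal(tc$label[tc$metric == "ppv"], "264/270 (97.8)")
})

test_that("zero-denominator metrics are undefined, not zero", {
  tc <- test_characteristics(tibble::tibble(tp = 0, fn = 0, fp = 0, tn = 5))
  expect_true(is.na(tc$estimate[tc$metric == "sensitivity"]))
  expect_true(is.na(tc$estimate[tc$metric == "ppv"]))
  expect_equal(tc$estimate[tc$metric == "specificity"], 1)
  expect_equal(tc$estimate[tc$metric == "npv"], 1)
  expect_equal(tc$label[tc$metric == "sensitivity"], "NA")
})

test_that("balanced counts give 50 percent across the board", {
  tc <- test_characteristics(tibble::tibble(tp = 1, fn = 1, fp = 1, tn = 1))
  expect_equal(tc$percent, rep(50, 4))
})

test_that("percentage rounding is half away from zero", {
  expect_equal(round_half_away(93.94949, 0), 94)
  expect_equal(round_half_away(97.95, 1), 98.0)
  expect_equal(round_half_away(22.45, 1), 22.5)
  expect_equal(round_half_away(-0.5, 0), -1)
})

test_that("a single-strategy comparison yields one row and sane structure", {
  pop <- simulate_population(simulation_config(n_children = 60, seed = 2))
  cmp <- compare_strategies(
    pop$patients, pop$reference$child_id, pop$reference,
    strategies = study_strategies()["phone"],
    params = default_params()
  )
  expect_equal(nrow(cmp$results), 1)
  expect_equal(cmp$results$strategy, "phone")
  expect_equal(
    cmp$results$tp + cmp$results$fp + cmp$results$tn + cmp$results$fn,
    length(pop$reference$child_id)
  )
  expect_equal(nrow(tidy(cmp)), 1)
  g <- glance(cmp)
  expect_equal(g$n_children, 60)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("insurance matching is perfectly specific on clean family-plan data", {
  cfg <- simulation_config(
    n_children = 200, seed = 13,
    p_safety_net_insurance = 0, p_family_insurance_number = 1,
    p_phone_churn = 0, p_unit_missing = 0, p_stepmother = 0,
    n_decoy_households = 0, p_insurance_available = 1,
    p_address_available = 1
  )
  pop <- simulate_population(cfg)
  cmp <- compare_strategies(
    pop$patients, pop$reference$child_id, pop$reference,
    strategies = study_strategies()["insurance"],
    params = default_params()
  )
  expect_equal(cmp$results$specificity, 1)
  # family accounts shared by exactly mother and child: perfect sensitivity
  expect_equal(cmp$results$sensitivity, 1)
})

test_that("specificity orderings across the strategy lattice hold on simulations", {
  for (seed in c(31, 32, 33)) {
    pop <- simulate_population(simulation_config(
      n_children = 120, seed = seed,
      p_stepmother = 0.1, n_decoy_households = 2
    ))
    cmp <- compare_strategies(
      pop$patients, pop$reference$child_id, pop$reference,
      params = default_params()
    )
    r <- cmp$results
    spec <- setNames(r$specificity, r$strategy)
    expect_gte(
      spec[["insurance_and_phone"]],
      max(spec[["insurance"]], spec[["phone"]])
    )
    expect_lte(
      spec[["insurance_or_phone"]],
      min(spec[["insurance"]], spec[["phone"]])
    )
    expect_lte(
      spec[["insurance_phone_or_address"]],
      min(spec[["insurance"]], spec[["phone"]], spec[["address"]])
    )
    # ROC x-coordinate ordering follows directly
    roc <- setNames(cmp$roc$fpr, cmp$roc$strategy)
    expect_lte(roc[["insurance_and_phone"]], roc[["phone"]])
  }
})

test_that("stratified breakdowns appear when annotations are supplied", {
  pop <- simulate_population(simulation_config(n_children = 80, seed = 4))
  cmp <- compare_strategies(
    pop$patients, pop$reference$child_id, pop$reference,
    strategies = study_strategies()["insurance"],
    params = default_params(),
    annotations = pop$annotations
  )
  expect_false(is.null(cmp$strata))
  expect_true("safety_net" %in% cmp$strata$stratum)
  # safety-net families can never match on insurance
  sn <- cmp$strata[cmp$strata$stratum == "safety_net" & cmp$strata$level, ]
  expect_equal(sn$tp, 0)
})

test_that("characteristics_table renders the printed n (%) style", {
  pop <- simulate_population(simulation_config(n_children = 50, seed = 6))
  cmp <- compare_strategies(
    pop$patients, pop$reference$child_id, pop$reference,
    strategies = study_strategies()["phone"],
    params = default_params()
  )
  tab <- characteristics_table(cmp)
  expect_match(tab$ppv, "^\\d+/\\d+ \\(")
  expect_match(tab$sensitivity, "^\\d+ \\(")
})
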