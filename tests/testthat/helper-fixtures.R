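# Shared fixtures built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

REF_DATE <- as.Date("2014-06-30")

default_params <- function(...) {
  classifier_params(reference_date = REF_DATE, ...)
}

# Build a patient tibble from compact per-patient argument lists.
make_patients <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      patient_id = r$id,
      sex = r$sex %||% "female",
      birth_date = as.Date(r$birth),
      race = r$race %||% NA_character_,
      insurance_raw = r$insurance %||% NA_character_,
      phone_raw = r$phone %||% NA_character_,
      address_raw = r$address %||% NA_character_
    )
  }))
}

# A birth date giving exactly `age` completed years at REF_DATE.
birth_for_age <- function(age, extra_days = 100) {
  d <- as.POSIXlt(REF_DATE)
  d$year <- d$year - age
  as.Date(d) - extra_days
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  path
}
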