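# Patient-table, reference-standard and link-table I/O.
#
# All files are RFC 4180 CSV with a mandatory header row, UTF-8 encoded.
# Warehouse extracts differ in column naming and missing-value sentinels, so
# both are configurable.

#' Default mapping from source sex codes to the internal sex levels
#'
#' Codes are matched case-insensitively after trimming. Anything not in the
#' map becomes `"unknown"` — deliberately conservative, because only patients
#' recorded as female may ever be classified as mothers.
#'
#' @return Named character vector: source code -> one of
#'   `"female"`, `"male"`, `"other"`, `"unknown"`.
#' @export
default_sex_map <- function() {
  c(
    "F" = "female", "FEMALE" = "female", "2" = "female",
    "M" = "male", "MALE" = "male", "1" = "male",
    "O" = "other", "OTHER" = "other",
    "U" = "unknown", "UNK" = "unknown", "UNKNOWN" = "unknown"
  )
}

#' Read a patient table
#'
#' Reads one row per patient: an opaque unique `patient_id`, `sex`,
#' `birth_date`, optional `race`, and the three raw linkage identifiers
#' (`insurance_raw`, `phone_raw`, `address_raw`). Empty cells and sentinel
#' strings become `NA`. Rows whose birth date fails to parse, or lies after
#' `reference_date` when one is supplied, are rejected (reported via a
#' warning and attached as the `"rejects"` attribute) — rows are never
#' silently dropped.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Named character vector mapping the canonical column names
#'   (`patient_id`, `sex`, `birth_date`, `race`, `insurance_raw`,
#'   `phone_raw`, `address_raw`) to the source file's column names. Defaults
#'   to the identity mapping.
#' @param sentinels Strings (case-insensitive) treated as missing, in
#'   addition to empty cells.
#' @param date_format `strptime` format for birth dates (default ISO 8601).
#' @param sex_map See [default_sex_map()].
#' @param reference_date Optional `Date`; birth dates after it are rejected.
#' @return A tibble of validated patient records with attribute `"rejects"`
#'   (a tibble of rejected source rows and reasons).
#' @export
read_patients <- function(path,
                          col_map = NULL,
                          sentinels = c("", "NA", "NULL"),
                          date_format = "%Y-%m-%d",
                          sex_map = default_sex_map(),
                          reference_date = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )

  required <- c("patient_id", "sex", "birth_date")
  optional <- c("race", "insurance_raw", "phone_raw", "address_raw")
  map <- stats::setNames(c(required, optional), c(required, optional))
  if (!is.null(col_map)) map[names(col_map)] <- col_map

  missing_cols <- setdiff(map[required], names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "patient table is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "fairlink_config_error"
    )
  }

  get_col <- function(canon) {
    src <- map[[canon]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }

  out <- tibble(
    patient_id = trimws(get_col("patient_id")),
    sex = get_col("sex"),
    birth_date_raw = get_col("birth_date"),
    race = get_col("race"),
    insurance_raw = get_col("insurance_raw"),
    phone_raw = get_col("phone_raw"),
    address_raw = get_col("address_raw")
  )

  if (any(is_blank(out$patient_id, sentinels))) {
    abort("patient table contains empty patient_id values",
      class = "fairlink_data_error"
    )
  }
  dup <- unique(out$patient_id[duplicated(out$patient_id)])
  if (length(dup) > 0) {
    abort(
      paste0(
        "duplicate patient_id value(s): ",
        paste(utils::head(dup, 5), collapse = ", ")
      ),
      class = "fairlink_data_error"
    )
  }

  for (col in c("race", "insurance_raw", "phone_raw", "address_raw")) {
    out[[col]] <- ifelse(is_blank(out[[col]], sentinels), NA_character_,
      out[[col]]
    )
  }

  sex_in <- toupper(trimws(out$sex))
  mapped <- unname(sex_map[sex_in])
  already <- sex_in %in% toupper(c("female", "male", "other", "unknown"))
  mapped[is.na(mapped) & already] <- tolower(sex_in[is.na(mapped) & already])
  mapped[is.na(mapped)] <- "unknown"
  out$sex <- mapped

  out$birth_date <- as.Date(out$birth_date_raw, format = date_format)
  bad_date <- is.na(out$birth_date)
  future <- rep(FALSE, nrow(out))
  if (!is.null(reference_date)) {
    future <- !bad_date & out$birth_date > as.Date(reference_date)
  }
  reject <- bad_date | future
  rejects <- tibble(
    row = which(reject),
    patient_id = out$patient_id[reject],
    reason = ifelse(bad_date[reject], "unparseable birth_date",
      "birth_date after reference date"
    )
  )
  if (nrow(rejects) > 0) {
    warn(paste0(
      nrow(rejects), " row(s) rejected: ",
      paste(rejects$patient_id, " (", rejects$reason, ")",
        sep = "", collapse = "; "
      )
    ))
  }

  out <- out[!reject, c(
    "patient_id", "sex", "birth_date", "race",
    "insurance_raw", "phone_raw", "address_raw"
  )]
  attr(out, "rejects") <- rejects
  out
}

#' Read a reference standard (child -> true mother)
#'
#' Two-column CSV (`child_id`, `mother_id`); the literal `"none"`
#' (case-insensitive) or an empty cell means the child has no in-system
#' mother. When `patients` is supplied the mapping is cross-checked: every
#' non-missing mother must exist in the patient table, differ from the child,
#' and be recorded female.
#'
#' @param path Path to the CSV file.
#' @param patients Optional patient tibble from [read_patients()] for
#'   cross-checking.
#' @return A tibble with columns `child_id` and `mother_id` (`NA` = no
#'   in-system mother), one row per child.
#' @export
read_reference <- function(path, patients = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (!all(c("child_id", "mother_id") %in% names(raw))) {
    abort("reference standard must have columns child_id, mother_id",
      class = "fairlink_config_error"
    )
  }
  ref <- tibble(
    child_id = trimws(raw$child_id),
    mother_id = trimws(raw$mother_id)
  )
  ref$mother_id[is_blank(ref$mother_id) |
    tolower(ref$mother_id) == "none"] <- NA_character_

  dup <- unique(ref$child_id[duplicated(ref$child_id)])
  if (length(dup) > 0) {
    abort(
      paste0(
        "child_id listed more than once in reference standard: ",
        paste(utils::head(dup, 5), collapse = ", ")
      ),
      class = "fairlink_data_error"
    )
  }
  if (any(!is.na(ref$mother_id) & ref$mother_id == ref$child_id)) {
    abort("reference standard links a child to itself",
      class = "fairlink_data_error"
    )
  }

  if (!is.null(patients)) {
    mothers <- ref$mother_id[!is.na(ref$mother_id)]
    unknown <- setdiff(mothers, patients$patient_id)
    if (length(unknown) > 0) {
      abort(
        paste0(
          "reference mother(s) absent from patient table: ",
          paste(utils::head(unknown, 5), collapse = ", ")
        ),
        class = "fairlink_data_error"
      )
    }
    sex <- patients$sex[match(mothers, patients$patient_id)]
    if (any(sex != "female")) {
      abort(
        paste0(
          "reference mother(s) not recorded female: ",
          paste(utils::head(unique(mothers[sex != "female"]), 5),
            collapse = ", "
          )
        ),
        class = "fairlink_data_error"
      )
    }
  }
  ref
}

#' Write / read a link table
#'
#' `write_links()` writes the per-child output of [link_cohort()] as RFC 4180
#' CSV; `read_links()` reads it back. The pair round-trips losslessly:
#' `read_links(write_links(x, p))` is identical to `x`.
#'
#' @param links Link tibble from [link_cohort()].
#' @param path Output path.
#' @return `write_links()` returns `path` invisibly; `read_links()` returns
#'   the link tibble.
#' @export
write_links <- function(links, path) {
  validate_links(links)
  readr::write_csv(links, path, na = "")
  invisible(path)
}

#' @rdname write_links
#' @export
read_links <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      mother_id = readr::col_character(),
      matched_identifiers = readr::col_character(),
      tie_break_path = readr::col_character(),
      n_candidates = readr::col_integer()
    ),
    na = "", progress = FALSE
  )
  out <- strip_readr_attrs(out)
  validate_links(out)
  out
}

# Structural invariants of a link table: a link is emitted if and only if at
# least one identifier matched, and a tie-break trace implies more than one
# candidate was in play.
validate_links <- function(links) {
  needed <- c(
    "child_id", "mother_id", "matched_identifiers",
    "tie_break_path", "n_candidates"
  )
  if (!all(needed %in% names(links))) {
    abort(
      paste0(
        "link table must have columns: ",
        paste(needed, collapse = ", ")
      ),
      class = "fairlink_config_error"
    )
  }
  if (!identical(is.na(links$mother_id), is.na(links$matched_identifiers))) {
    abort("mother_id must be missing exactly when matched_identifiers is",
      class = "fairlink_data_error"
    )
  }
  if (any(links$n_candidates < 0)) {
    abort("n_candidates must be non-negative", class = "fairlink_data_error")
  }
  if (any(!is.na(links$tie_break_path) & links$n_candidates <= 1)) {
    abort("tie_break_path requires more than one candidate",
      class = "fairlink_data_error"
    )
  }
  invisible(links)
}
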