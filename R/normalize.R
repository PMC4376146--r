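# Identifier canonicalization.
#
# Matching in this package is exact string equality on canonical keys — no
# fuzzy or probabilistic comparison — so all forgiveness lives here: raw
# warehouse strings are cleaned into keys that are equal exactly when the
# identifiers should be treated as the same.

#' Construct a single insurance normalization rule
#'
#' Insurance numbers typically carry an account part and a member part, in
#' provider-specific layouts. Each rule pairs a regex `pattern` with a
#' `mode`:
#'
#' * `"strip_member_suffix"` — the family-plan case: the key is the account
#'   portion, i.e. the text before the final `delimiter`, or the string with
#'   a fixed-length `suffix_length` member code removed. Family members then
#'   share a key.
#' * `"individual_unique"` — safety-net style plans (e.g. Medicaid) that
#'   number individuals, not families: the whole string is the key, so
#'   relatives never share it by construction.
#' * `"keep_whole"` — the key is the whole string; the required catch-all.
#'
#' @param pattern Regular expression selecting the plans the rule covers.
#' @param mode One of `"strip_member_suffix"`, `"individual_unique"`,
#'   `"keep_whole"`.
#' @param delimiter For `strip_member_suffix`: the member-suffix delimiter
#'   (split at its final occurrence).
#' @param suffix_length For `strip_member_suffix`: alternatively, a fixed
#'   member-suffix length to drop.
#' @return An `insurance_rule` object.
#' @export
insurance_rule <- function(pattern,
                           mode = c(
                             "keep_whole", "strip_member_suffix",
                             "individual_unique"
                           ),
                           delimiter = NULL, suffix_length = NULL) {
  mode <- match.arg(mode)
  if (mode == "strip_member_suffix" &&
    is.null(delimiter) && is.null(suffix_length)) {
    abort("strip_member_suffix needs a delimiter or a suffix_length",
      class = "fairlink_config_error"
    )
  }
  structure(
    list(
      pattern = pattern, mode = mode, delimiter = delimiter,
      suffix_length = suffix_length
    ),
    class = "insurance_rule"
  )
}

#' Default insurance rules
#'
#' Safety-net plans (here, numbers starting `MCD`) keep their whole
#' individually assigned number; delimited numbers are split into account and
#' member at the final `-`; everything else is kept whole (the catch-all).
#'
#' @return List of [insurance_rule()] objects, first match wins.
#' @export
default_insurance_rules <- function() {
  list(
    insurance_rule("^MCD", "individual_unique"),
    insurance_rule("-", "strip_member_suffix", delimiter = "-"),
    insurance_rule(".*", "keep_whole")
  )
}

#' Default street-type abbreviation expansions
#' @return Named character vector, abbreviation -> canonical token.
#' @export
default_address_abbreviations <- function() {
  c(
    ST = "STREET", AVE = "AVENUE", RD = "ROAD", DR = "DRIVE",
    LN = "LANE", CT = "COURT", BLVD = "BOULEVARD", PL = "PLACE",
    HWY = "HIGHWAY", SQ = "SQUARE", TER = "TERRACE", PKWY = "PARKWAY"
  )
}

#' Bundle of normalization rules for the three identifiers
#'
#' @param insurance_rules Ordered list of [insurance_rule()]s; the first rule
#'   whose pattern matches fires. A `keep_whole` catch-all is appended if the
#'   last rule is not already a universal match.
#' @param phone_min_digits A phone key must have exactly this many digits
#'   after cleaning (default 10, US numbers).
#' @param address_abbreviations Named vector of token expansions applied
#'   after upper-casing and punctuation stripping.
#' @return A `normalization_rules` object.
#' @export
normalization_rules <- function(insurance_rules = default_insurance_rules(),
                                phone_min_digits = 10L,
                                address_abbreviations =
                                  default_address_abbreviations()) {
  if (length(insurance_rules) == 0 ||
    utils::tail(insurance_rules, 1)[[1]]$pattern != ".*") {
    insurance_rules <- c(
      insurance_rules,
      list(insurance_rule(".*", "keep_whole"))
    )
  }
  structure(
    list(
      insurance_rules = insurance_rules,
      phone_min_digits = as.integer(phone_min_digits),
      address_abbreviations = address_abbreviations
    ),
    class = "normalization_rules"
  )
}

apply_insurance_rule <- function(x, rule) {
  switch(rule$mode,
    keep_whole = x,
    individual_unique = x,
    strip_member_suffix = {
      out <- x
      if (!is.null(rule$delimiter)) {
        d <- rule$delimiter
        has <- grepl(d, out, fixed = TRUE)
        stripped <- sub(
          paste0("(.*)", gsub("([^[:alnum:]])", "\\\\\\1", d), ".*$"),
          "\\1", out[has]
        )
        # never produce an empty key: a bare delimiter keeps the whole string
        out[has] <- ifelse(nchar(stripped) > 0, stripped, out[has])
      } else {
        k <- rule$suffix_length
        long <- nchar(out) > k
        out[long] <- substr(out[long], 1, nchar(out[long]) - k)
      }
      out
    }
  )
}

#' Normalize raw insurance numbers into account keys
#'
#' Applies the first matching rule (see [insurance_rule()]); blank or missing
#' input yields a missing key.
#'
#' @param raw Character vector of raw insurance numbers (may contain `NA`).
#' @param rules A [normalization_rules()] object.
#' @return Character vector of keys, `NA` where the input was missing.
#' @export
normalize_insurance <- function(raw, rules = normalization_rules()) {
  x <- trimws(raw)
  out <- rep(NA_character_, length(x))
  live <- !is.na(x) & x != ""
  pending <- live
  for (rule in rules$insurance_rules) {
    hit <- pending & grepl(rule$pattern, x)
    if (any(hit)) {
      out[hit] <- apply_insurance_rule(x[hit], rule)
      pending <- pending & !hit
    }
  }
  out
}

#' Normalize raw phone numbers into 10-digit keys
#'
#' Strips every non-digit, drops a single leading country-code `1` from an
#' 11-digit string, and returns the key only when exactly
#' `phone_min_digits` digits remain — partial numbers never match anything.
#'
#' @inheritParams normalize_insurance
#' @return Character vector of digit-string keys, `NA` where missing or not
#'   canonicalizable.
#' @export
normalize_phone <- function(raw, rules = normalization_rules()) {
  x <- gsub("\\D", "", ifelse(is.na(raw), "", raw))
  eleven <- nchar(x) == 11 & substr(x, 1, 1) == "1"
  x[eleven] <- substr(x[eleven], 2, 11)
  ifelse(nchar(x) == rules$phone_min_digits, x, NA_character_)
}

#' Normalize raw addresses into comparable keys
#'
#' Upper-cases, replaces punctuation with spaces, collapses whitespace and
#' expands street-type abbreviations token-wise (`ST` -> `STREET`). Unit
#' designators (`APT 3`) are retained verbatim when present and never
#' imputed when absent: two records for the same multi-unit building compare
#' equal only when both lack (or both carry the same) unit token — which is
#' exactly how unit-less warehouse addresses generate false family matches.
#'
#' @inheritParams normalize_insurance
#' @return Character vector of canonical address keys, `NA` where missing.
#' @export
normalize_address <- function(raw, rules = normalization_rules()) {
  x <- toupper(ifelse(is.na(raw), "", raw))
  x <- gsub("[^A-Z0-9]+", " ", x)
  x <- trimws(gsub(" +", " ", x))
  abbr <- rules$address_abbreviations
  out <- vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    hit <- tok %in% names(abbr)
    tok[hit] <- abbr[tok[hit]]
    paste(tok, collapse = " ")
  }, character(1))
  ifelse(out == "", NA_character_, out)
}

#' Normalize every identifier of a patient table
#'
#' Applies the three normalizers to each record and reports per-identifier
#' raw availability (share of records with a non-missing raw value), the
#' quantity clinical linkage studies quote per identifier.
#'
#' @param patients Patient tibble from [read_patients()] or
#'   [simulate_population()].
#' @param rules A [normalization_rules()] object.
#' @param verbose If `TRUE`, message the availability percentages.
#' @return Tibble with columns `patient_id`, `insurance_key`, `phone_key`,
#'   `address_key`; attribute `"availability"` holds the availability table
#'   (see [identifier_availability()]).
#' @export
normalize_table <- function(patients, rules = normalization_rules(),
                            verbose = FALSE) {
  out <- tibble(
    patient_id = patients$patient_id,
    insurance_key = normalize_insurance(patients$insurance_raw, rules),
    phone_key = normalize_phone(patients$phone_raw, rules),
    address_key = normalize_address(patients$address_raw, rules)
  )
  n <- nrow(patients)
  avail <- tibble(
    identifier = IDENTIFIERS,
    n_available = c(
      sum(!is.na(patients$insurance_raw)),
      sum(!is.na(patients$phone_raw)),
      sum(!is.na(patients$address_raw))
    ),
    n = n
  )
  avail$pct <- ifelse(avail$n > 0,
    round_half_away(100 * avail$n_available / avail$n, 1), NA_real_
  )
  if (verbose) {
    inform(paste(
      sprintf(
        "%s available for %d/%d (%s%%)",
        avail$identifier, avail$n_available, avail$n, avail$pct
      ),
      collapse = "; "
    ))
  }
  attr(out, "availability") <- avail
  out
}

#' Per-identifier availability of a normalized table
#'
#' @param normalized Output of [normalize_table()].
#' @return Tibble with `identifier`, `n_available`, `n`, `pct`.
#' @export
identifier_availability <- function(normalized) {
  attr(normalized, "availability")
}
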