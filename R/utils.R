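# Shared low-level helpers.

#' Round half away from zero
#'
#' Base `round()` uses round-half-to-even; printed clinical tables round
#' halves away from zero (93.94 -> 94, 97.95 -> 98.0). Used for all percentage
#' renderings in this package.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5), 0)
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Age in completed years at a reference date
#'
#' Ages are integer completed years (floor), never fractional: a patient is
#' "17 years old" from their 17th birthday up to the day before their 18th.
#'
#' @param birth_date,reference_date `Date` vectors (recycled).
#' @return Integer vector of completed years (negative if born after
#'   `reference_date`).
#' @export
age_completed_years <- function(birth_date, reference_date) {
  b <- as.POSIXlt(as.Date(birth_date))
  r <- as.POSIXlt(as.Date(reference_date))
  a <- r$year - b$year
  before <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  as.integer(a - before)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Canonical ordering of the three linkage identifiers; used everywhere a set
# of identifiers is rendered as a string ("insurance+phone").
IDENTIFIERS <- c("insurance", "phone", "address")

identifier_set_label <- function(idents) {
  idents <- IDENTIFIERS[IDENTIFIERS %in% idents]
  if (length(idents) == 0) NA_character_ else paste(idents, collapse = "+")
}

identifier_set_unlabel <- function(label) {
  if (is.na(label)) character(0) else strsplit(label, "+", fixed = TRUE)[[1]]
}

# readr attaches spec/problems metadata; drop it so write-then-read
# round-trips compare identical.
strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

is_blank <- function(x, sentinels = c("", "NA", "NULL")) {
  is.na(x) | toupper(trimws(x)) %in% toupper(sentinels)
}
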