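#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages: ties go away from
#' zero (-65.5 -> -66, 2.25 -> 2.3), unlike base [round()] which rounds half
#' to even. A tiny guard absorbs floating-point noise just below a half.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(c(-65.64, 6.53, 0.4), 0)
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## ATC level-5 code: letter, 2 digits, 2 letters, 2 digits (e.g. N06AB04).
atc5_pattern <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

is_atc5 <- function(x) {
  stringr::str_detect(x, atc5_pattern)
}

## ICD-10 codes are compared dot-free and upper-case so "I50.1" matches the
## prefix "I50".
normalize_icd10 <- function(x) {
  toupper(stringr::str_remove_all(x, "\\."))
}

icd10_matches <- function(codes, prefixes) {
  codes <- normalize_icd10(codes)
  prefixes <- normalize_icd10(prefixes)
  vapply(codes, function(cd) any(startsWith(cd, prefixes)), logical(1),
         USE.NAMES = FALSE)
}

## Completed years between two dates (floor), robust to leap years.
age_at <- function(birth_date, at_date) {
  b <- as.POSIXlt(birth_date)
  a <- as.POSIXlt(at_date)
  age <- a$year - b$year
  before_birthday <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - before_birthday)
}

as_date_strict <- function(x) {
  suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
}

## Compare a value against a threshold under a named comparator.
cmp_apply <- function(value, comparator, threshold) {
  switch(comparator,
    gt = value > threshold,
    ge = value >= threshold,
    lt = value < threshold,
    le = value <= threshold,
    abort(paste0("unknown comparator: ", comparator))
  )
}

cmp_known <- c("gt", "ge", "lt", "le")

## Collapse / split the |-separated code sets used in alert tables.
collapse_codes <- function(x) paste(sort(unique(x)), collapse = "|")

split_codes <- function(x) {
  if (length(x) == 1 && (is.na(x) || x == "")) return(character(0))
  stringr::str_split_1(x, stringr::fixed("|"))
}

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
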