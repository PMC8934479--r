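#' Pharmacological group tags understood by the rule engine
#'
#' The fixed vocabulary of group tags a drug catalog may assign, excluding
#' therapeutic-duplication tags, which are declared per rule catalog and
#' always carry the `dup:` prefix. A tag outside this vocabulary (and not a
#' `dup:` tag) is a validation error, so typos in a hand-edited catalog fail
#' loudly instead of silently never matching.
#'
#' @return Character vector of valid tags.
#' @export
sa_tag_vocabulary <- function() {
  c("nsaid", "coxib", "ras_inhibitor", "ace_inhibitor", "diuretic",
    "antiplatelet", "oral_anticoagulant", "antidiabetic", "qt_prolonging",
    "anticholinergic", "bisphosphonate", "geriatric_inadvisable", "avoidable")
}

#' Load a drug catalog
#'
#' Reads a CSV mapping ATC level-5 drug codes to their component active
#' principles and pharmacological group tags. Columns: `drug_code`, `name`,
#' `component_principles` (`|`-separated, at least one; more than one for
#' combination products) and `group_tags` (`|`-separated, possibly empty).
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return A tibble of class `sa_drug_catalog` with list-columns
#'   `principles` and `tags`.
#' @export
load_drug_catalog <- function(path) {
  df <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  required <- c("drug_code", "name", "component_principles", "group_tags")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(paste0("drug catalog: missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (any(!is_atc5(df$drug_code)))
    abort(paste0("drug catalog: not an ATC level-5 code: ",
                 paste(df$drug_code[!is_atc5(df$drug_code)], collapse = ", ")))
  if (anyDuplicated(df$drug_code))
    abort("drug catalog: duplicated drug_code")

  df$principles <- lapply(df$component_principles, function(x) {
    if (is.na(x) || x == "") character(0) else stringr::str_split_1(x, stringr::fixed("|"))
  })
  if (any(lengths(df$principles) == 0))
    abort("drug catalog: component_principles must be non-empty")
  df$tags <- lapply(df$group_tags, function(x) {
    if (is.na(x) || x == "") character(0) else stringr::str_split_1(x, stringr::fixed("|"))
  })
  all_tags <- unique(unlist(df$tags))
  bad <- all_tags[!all_tags %in% sa_tag_vocabulary() &
                    !startsWith(all_tags, "dup:")]
  if (length(bad))
    abort(paste0("drug catalog: unknown group tag(s): ",
                 paste(bad, collapse = ", ")))
  out <- df[c("drug_code", "name", "principles", "tags")]
  class(out) <- c("sa_drug_catalog", class(out))
  out
}

#' The packaged illustrative drug catalog
#'
#' A small ATC level-5 catalog covering every drug referenced by the built-in
#' rule catalogs, with active-principle and group-tag assignments. The
#' membership lists are illustrative defaults for testing and simulation,
#' not a clinically authoritative formulary.
#'
#' @return An `sa_drug_catalog` tibble.
#' @export
builtin_drug_catalog <- function() {
  load_drug_catalog(system.file("extdata", "drug_catalog.csv",
                                package = "selfaudit", mustWork = TRUE))
}

## Fast code -> (principles, tags) lookup closure. Codes absent from the
## catalog are treated as single-principle untagged drugs (principle = code),
## so inert background prescriptions need no catalog entry.
catalog_lookup <- function(drug_catalog) {
  principles <- stats::setNames(drug_catalog$principles, drug_catalog$drug_code)
  tags <- stats::setNames(drug_catalog$tags, drug_catalog$drug_code)
  function(codes) {
    p <- principles[codes]
    t <- tags[codes]
    unknown <- is.na(names(p)) | !codes %in% names(principles)
    if (any(unknown)) {
      p[unknown] <- as.list(codes[unknown])
      t[unknown] <- list(character(0))
    }
    list(principles = unname(p), tags = unname(t))
  }
}
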