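rule_categories <- c("duplicate_therapy", "aemps_alert",
                     "contraindication_clinical", "treatment_duration",
                     "geriatric_inadvisable", "anticholinergic_combination",
                     "avoidable_medication", "polymedication")

rule_kinds <- c("dose_threshold", "age_restriction",
                "comorbidity_contraindication", "co_prescription",
                "clinical_variable", "list_membership",
                "composite_triple_whammy", "duration", "duplication_group",
                "polymedication")

#' Load a rule catalog from YAML
#'
#' A rule catalog is the year-versioned clinical content of the engine:
#' declarative rules, therapeutic-duplication groups with their
#' clinical-relevance flag, named ICD-10 concept sets, and the year's
#' polymedication threshold. Rules live in data rather than code because the
#' clinical content is revised every year.
#'
#' Validation is total: any malformed catalog is rejected with an error that
#' names the offending rule and field. Checked invariants include unique
#' rule ids, kind-specific parameter completeness, comparators drawn from
#' `gt/ge/lt/le`, concept references resolving to declared concept sets, tag
#' references drawn from [sa_tag_vocabulary()] or the catalog's `dup:` tags,
#' and the restriction that only high-relevance duplications, regulatory
#' safety alerts and polymedication may be linked to the safety indicator.
#'
#' @param path Path to a YAML catalog file, or an already-parsed list with
#'   the same structure.
#' @return An object of class `sa_catalog`.
#' @seealso [builtin_catalog()] for the packaged yearly catalogs.
#' @export
load_rule_catalog <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  for (field in c("year_label", "polymedication_threshold", "rules")) {
    if (is.null(raw[[field]]))
      abort(paste0("catalog: missing top-level field: ", field))
  }
  cat_obj <- structure(
    list(
      year_label = as.character(raw$year_label),
      polymedication_threshold = as.integer(raw$polymedication_threshold),
      polymedication_comparator = raw$polymedication_comparator %||% "ge",
      icd10_concept_sets = lapply(raw$icd10_concept_sets, as.character),
      duplication_groups = dplyr::bind_rows(lapply(
        raw$duplication_groups,
        function(g) tibble::tibble(group_id = g$group_id, tag = g$tag,
                                   clinically_relevant = isTRUE(g$clinically_relevant))
      )),
      rules = raw$rules
    ),
    class = "sa_catalog"
  )
  if (is.null(raw$duplication_groups)) {
    cat_obj$duplication_groups <- tibble::tibble(
      group_id = character(), tag = character(), clinically_relevant = logical())
  }
  validate_rule_catalog(cat_obj)
  cat_obj
}

#' Built-in yearly rule catalogs
#'
#' Returns the packaged catalog for one study year. The three catalogs share
#' most content; they differ where the clinical content changed between
#' years: the polymedication threshold drops from 10 concurrent drugs
#' (2016, 2017) to 8 (2018), the strontium ranelate alert applies in
#' 2016-2017 only, and the canagliflozin amputation-risk alert exists only
#' from 2018.
#'
#' @param year_label One of `"2016"`, `"2017"`, `"2018"`.
#' @return An `sa_catalog`.
#' @examples
#' builtin_catalog("2018")$polymedication_threshold
#' @export
builtin_catalog <- function(year_label) {
  year_label <- as.character(year_label)
  if (!year_label %in% c("2016", "2017", "2018"))
    abort(paste0("no built-in catalog for year_label: ", year_label))
  load_rule_catalog(system.file(
    "extdata", "catalogs", paste0("selfaudit-", year_label, ".yaml"),
    package = "selfaudit", mustWork = TRUE))
}

#' @export
print.sa_catalog <- function(x, ...) {
  cat("<sa_catalog> year ", x$year_label, ": ", length(x$rules), " rules, ",
      nrow(x$duplication_groups), " duplication groups, polymedication ",
      x$polymedication_comparator, " ", x$polymedication_threshold,
      " drugs\n", sep = "")
  invisible(x)
}

catalog_rule <- function(catalog, rule_id) {
  for (r in catalog$rules) if (identical(r$rule_id, rule_id)) return(r)
  abort(paste0("no such rule in catalog: ", rule_id))
}

catalog_tags <- function(catalog) {
  c(sa_tag_vocabulary(), catalog$duplication_groups$tag)
}

validate_rule_catalog <- function(catalog) {
  ids <- vapply(catalog$rules, function(r) r$rule_id %||% NA_character_,
                character(1))
  if (anyNA(ids)) abort("catalog: every rule needs a rule_id")
  if (anyDuplicated(ids))
    abort(paste0("catalog: duplicated rule_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyDuplicated(catalog$duplication_groups$group_id))
    abort("catalog: duplicated duplication group_id")
  if (is.na(catalog$polymedication_threshold))
    abort("catalog: polymedication_threshold must be an integer")

  known_tags <- catalog_tags(catalog)
  for (r in catalog$rules) validate_rule(r, catalog, known_tags, ids)
  invisible(catalog)
}

validate_rule <- function(r, catalog, known_tags, all_ids) {
  where <- function(field) paste0("catalog rule '", r$rule_id, "': ", field)
  need <- function(cond, msg) if (!cond) abort(where(msg))
  p <- r$parameters

  need(!is.null(r$category) && r$category %in% rule_categories,
       "category missing or not a known category")
  need(!is.null(r$relevance) && r$relevance %in% c("high", "low"),
       "relevance must be 'high' or 'low'")
  need(is.logical(r$indicator_linked %||% NA) && !is.na(r$indicator_linked),
       "indicator_linked must be true or false")
  if (isTRUE(r$indicator_linked)) {
    ok <- r$category %in% c("aemps_alert", "polymedication") ||
      (r$category == "duplicate_therapy" && r$relevance == "high")
    need(ok, "indicator_linked allowed only for aemps_alert, polymedication and high-relevance duplicate_therapy")
  }
  need(!is.null(r$kind) && r$kind %in% rule_kinds,
       "kind missing or not a known rule kind")
  need(is.list(p), "missing parameters block")

  check_age <- function(a, field = "age") {
    need(is.list(a) && !is.null(a$comparator) && !is.null(a$years),
         paste0("parameters.", field, " needs comparator and years"))
    need(a$comparator %in% cmp_known,
         paste0("parameters.", field, ".comparator must be one of gt/ge/lt/le"))
  }
  check_drug_set <- function(q, field) {
    need(!is.null(q$codes) || !is.null(q$tag),
         paste0("parameters.", field, " needs 'codes' or 'tag'"))
    if (!is.null(q$tag))
      need(q$tag %in% known_tags,
           paste0("parameters.", field, ".tag '", q$tag,
                  "' not in the catalog tag vocabulary"))
    if (!is.null(q$codes))
      need(all(is_atc5(unlist(q$codes))),
           paste0("parameters.", field, ".codes must be ATC level-5 codes"))
  }
  check_concepts <- function(cs, field = "concepts") {
    need(length(cs) >= 1, paste0("parameters.", field, " must be non-empty"))
    missing <- setdiff(unlist(cs), names(catalog$icd10_concept_sets))
    need(length(missing) == 0,
         paste0("parameters.", field, " references undeclared concept set(s): ",
                paste(missing, collapse = ", ")))
  }

  switch(r$kind,
    dose_threshold = {
      check_drug_set(p, "codes/tag")
      need(is.numeric(p$threshold_mg_per_day %||% NA) &&
             !is.na(p$threshold_mg_per_day),
           "parameters.threshold_mg_per_day missing or not numeric")
      if (!is.null(p$age)) check_age(p$age)
      if (!is.null(p$concept)) check_concepts(p$concept, "concept")
    },
    age_restriction = {
      check_drug_set(p, "codes/tag")
      check_age(p$age %||% NULL)
    },
    comorbidity_contraindication = {
      check_drug_set(p, "codes/tag")
      check_concepts(p$concepts)
    },
    co_prescription = {
      need(is.list(p$groups) && length(p$groups) >= 1,
           "parameters.groups must list at least one drug group")
      for (i in seq_along(p$groups))
        check_drug_set(p$groups[[i]], paste0("groups[", i, "]"))
      total <- sum(vapply(p$groups, function(g) as.integer(g$min_count %||% 1L),
                          integer(1)))
      need(total >= 2, "co_prescription must require at least two drugs in total")
    },
    clinical_variable = {
      check_drug_set(p, "codes/tag")
      need(!is.null(p$variable), "parameters.variable missing")
      need((p$comparator %||% "") %in% cmp_known,
           "parameters.comparator must be one of gt/ge/lt/le")
      need(is.numeric(p$threshold %||% NA) && !is.na(p$threshold),
           "parameters.threshold missing or not numeric")
    },
    list_membership = {
      check_drug_set(p, "codes/tag")
    },
    composite_triple_whammy = {
      need(is.list(p$groups) &&
             all(c("nsaid", "ras", "diuretic") %in% names(p$groups)),
           "parameters.groups needs nsaid, ras and diuretic tags")
      for (nm in c("nsaid", "ras", "diuretic"))
        need(p$groups[[nm]] %in% known_tags,
             paste0("parameters.groups.", nm, " not in the tag vocabulary"))
      check_age(p$age %||% NULL)
      need((p$treatment_tag %||% "") %in% known_tags,
           "parameters.treatment_tag not in the tag vocabulary")
    },
    duration = {
      need((p$variant %||% "") %in% c("per_drug", "concurrent"),
           "parameters.variant must be 'per_drug' or 'concurrent'")
      check_drug_set(p, "codes/tag")
      need(is.numeric(p$min_days %||% NA) && !is.na(p$min_days),
           "parameters.min_days missing or not numeric")
      if (identical(p$variant, "concurrent"))
        need(as.integer(p$min_count %||% 0L) >= 2,
             "concurrent duration needs min_count >= 2")
    },
    polymedication = {
      check_age(p$age %||% NULL)
      need((p$count_comparator %||% "") %in% cmp_known,
           "parameters.count_comparator must be one of gt/ge/lt/le")
      qr <- unlist(p$qualifying_rules)
      need(length(qr) >= 1, "parameters.qualifying_rules must be non-empty")
      missing <- setdiff(qr, all_ids)
      need(length(missing) == 0,
           paste0("parameters.qualifying_rules references unknown rule(s): ",
                  paste(missing, collapse = ", ")))
    },
    duplication_group = {
      abort(where("duplication_group rules are derived from duplication_groups, not declared"))
    }
  )
  invisible(r)
}
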