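#' Configuration of the incentive-based safety indicator
#'
#' Captures the evaluation calendar and the per-physician goal. The study
#' years evaluated the indicator in September and December of 2016 and in
#' June, September and December of 2017 and 2018, always against the April
#' baseline; those checkpoint dates are the defaults per year.
#'
#' @param year_label Catalog year (`"2016"`, `"2017"`, `"2018"`, or any
#'   label when `checkpoint_dates` is given explicitly).
#' @param checkpoint_dates Dates at which goal attainment is evaluated;
#'   strictly increasing, all after the April baseline.
#' @param goal_reduction Required decrease versus the physician's baseline
#'   count. With `goal_type = "absolute"` (default) this is a number of
#'   problems; with `"fraction"` it is a fraction of the baseline.
#' @param goal_type `"absolute"` or `"fraction"`.
#' @return An object of class `sa_indicator_config`.
#' @export
indicator_config <- function(year_label,
                             checkpoint_dates = NULL,
                             goal_reduction = 1,
                             goal_type = c("absolute", "fraction")) {
  goal_type <- match.arg(goal_type)
  year_label <- as.character(year_label)
  if (is.null(checkpoint_dates)) {
    months <- if (year_label == "2016") c("09", "12") else c("06", "09", "12")
    checkpoint_dates <- as.Date(paste0(year_label, "-", months, "-01"))
  }
  checkpoint_dates <- sort(as.Date(checkpoint_dates))
  if (anyDuplicated(checkpoint_dates))
    abort("checkpoint_dates must be strictly increasing")
  if (goal_reduction < 0) abort("goal_reduction must be non-negative")
  if (goal_type == "fraction" && goal_reduction > 1)
    abort("fractional goal_reduction must lie in [0, 1]")
  structure(
    list(year_label = year_label, checkpoint_dates = checkpoint_dates,
         goal_reduction = goal_reduction, goal_type = goal_type),
    class = "sa_indicator_config"
  )
}

#' Indicator-linked alert counts per physician
#'
#' Counts, for each physician, the alerts linked to the safety indicator:
#' high-relevance therapeutic duplications, regulatory safety alerts, and
#' qualifying polymedication. Physicians without any linked alert do not
#' appear (their count is implicitly zero).
#'
#' @param snapshot An `sa_snapshot`.
#' @return A tibble with columns `physician_id`, `n_linked`.
#' @export
indicator_counts <- function(snapshot) {
  stopifnot(inherits(snapshot, "sa_snapshot"))
  linked <- snapshot$alerts[snapshot$alerts$indicator_linked, ]
  dplyr::count(linked, .data$physician_id, name = "n_linked")
}

#' Evaluate the per-physician safety indicator
#'
#' For every physician with indicator-linked alerts in any supplied
#' snapshot, evaluates goal attainment at each checkpoint against the April
#' baseline: the goal is met when the checkpoint count is at most
#' `baseline - goal` (absolute form) or `baseline * (1 - goal)` (fractional
#' form). The last checkpoint also yields the final variation and percentage
#' versus baseline; a physician with a zero baseline and new problems at the
#' final point has no defined percentage (`NA`).
#'
#' @param baseline An `sa_snapshot` taken at the April baseline.
#' @param checkpoints List of `sa_snapshot`s, one per configured checkpoint
#'   date, in any order; matched to `config$checkpoint_dates` by date.
#' @param config An [indicator_config()].
#' @return An object of class `sa_indicator`: list with `results` (long
#'   tibble: `physician_id`, `checkpoint_date`, `count`, `goal_met`),
#'   `summary` (per physician: `baseline_count`, `final_count`,
#'   `final_variation`, `final_pct`, `goal_met_final`) and the `config`.
#' @export
evaluate_indicator <- function(baseline, checkpoints, config) {
  stopifnot(inherits(baseline, "sa_snapshot"),
            inherits(config, "sa_indicator_config"))
  if (inherits(checkpoints, "sa_snapshot")) checkpoints <- list(checkpoints)
  have <- as.Date(vapply(checkpoints, function(s) format(s$snapshot_date),
                         character(1)))
  missing <- setdiff(format(config$checkpoint_dates), format(have))
  if (length(missing))
    abort(paste0("no snapshot supplied for checkpoint date(s): ",
                 paste(missing, collapse = ", ")))
  checkpoints <- checkpoints[match(config$checkpoint_dates, have)]

  base_counts <- indicator_counts(baseline)
  cp_counts <- lapply(checkpoints, indicator_counts)
  physicians <- sort(unique(c(base_counts$physician_id,
                              unlist(lapply(cp_counts,
                                            function(x) x$physician_id)))))
  count_of <- function(tab, ids) {
    out <- tab$n_linked[match(ids, tab$physician_id)]
    dplyr::coalesce(out, 0L)
  }
  base_n <- count_of(base_counts, physicians)
  goal_of <- function(baseline_count) {
    if (config$goal_type == "absolute") {
      baseline_count - config$goal_reduction
    } else {
      baseline_count * (1 - config$goal_reduction)
    }
  }

  results <- purrr::list_rbind(purrr::map2(
    cp_counts, config$checkpoint_dates,
    function(tab, date) {
      n <- count_of(tab, physicians)
      tibble::tibble(
        physician_id = physicians,
        checkpoint_date = date,
        count = n,
        goal_met = n <= goal_of(base_n)
      )
    }))

  final_n <- count_of(cp_counts[[length(cp_counts)]], physicians)
  final_pct <- ifelse(
    base_n == 0,
    ifelse(final_n == 0, 0L, NA_integer_),
    as.integer(round_half_away(100 * (final_n - base_n) / pmax(base_n, 1L)))
  )
  summary <- tibble::tibble(
    physician_id = physicians,
    baseline_count = base_n,
    final_count = final_n,
    final_variation = final_n - base_n,
    final_pct = final_pct,
    goal_met_final = final_n <= goal_of(base_n)
  )

  structure(list(results = results, summary = summary, config = config),
            class = "sa_indicator")
}

#' @export
print.sa_indicator <- function(x, ...) {
  cat("<sa_indicator> year ", x$config$year_label, ": ",
      nrow(x$summary), " physicians, ",
      length(x$config$checkpoint_dates), " checkpoints, ",
      sum(x$summary$goal_met_final), " met the final goal\n", sep = "")
  invisible(x)
}

#' Aggregate indicator-linked resolutions
#'
#' Sums the resolved-case counts of the three indicator-linked problem
#' types — therapeutic duplications, regulatory safety alerts and
#' polymedication — and, when the baseline number of linked problems is
#' supplied, the joint resolution percentage.
#'
#' @param per_category_resolved Named numeric vector (or list) with exactly
#'   the names `duplicate_therapy`, `aemps_alert`, `polymedication`.
#' @param baseline_linked_total Optional baseline count of indicator-linked
#'   problems; when given, the percentage `100 * total / baseline` (rounded
#'   half away from zero) is reported.
#' @return A list with `total_resolved` and `pct` (`NA` when no baseline
#'   was supplied).
#' @examples
#' indicator_aggregate(c(duplicate_therapy = 5413, aemps_alert = 6815,
#'                       polymedication = 5130))$total_resolved # 17358
#' @export
indicator_aggregate <- function(per_category_resolved,
                                baseline_linked_total = NULL) {
  x <- unlist(per_category_resolved)
  expected <- c("duplicate_therapy", "aemps_alert", "polymedication")
  if (!setequal(names(x), expected) || length(x) != 3)
    abort(paste0("per_category_resolved must carry exactly the categories: ",
                 paste(expected, collapse = ", ")))
  total <- sum(x)
  pct <- if (is.null(baseline_linked_total)) NA_integer_ else
    pct_share(total, baseline_linked_total)
  list(total_resolved = as.integer(total), pct = pct)
}
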