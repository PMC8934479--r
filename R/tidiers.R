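#' Tidy a snapshot into its alert table
#'
#' @param x An `sa_snapshot`.
#' @param ... Unused.
#' @return The alert tibble, one row per detected problem.
#' @export
tidy.sa_snapshot <- function(x, ...) x$alerts

#' One-row summary of a snapshot
#'
#' @param x An `sa_snapshot`.
#' @param ... Unused.
#' @return A one-row tibble: date, catalog year, alert totals and the
#'   indicator-linked subtotal.
#' @export
glance.sa_snapshot <- function(x, ...) {
  tibble::tibble(
    snapshot_date = x$snapshot_date,
    year_label = x$year_label,
    n_alerts = nrow(x$alerts),
    n_indicator_linked = sum(x$alerts$indicator_linked),
    n_patients_with_alerts = dplyr::n_distinct(x$alerts$patient_id),
    n_categories = nrow(x$per_category_counts)
  )
}

#' Tidy a snapshot comparison into one row per baseline/new alert
#'
#' @param x An `sa_comparison`.
#' @param ... Unused.
#' @return A tibble of all classified alerts with a `status` column
#'   (`resolved` / `persisting` / `new`) and, for resolved alerts,
#'   `resolution_reason` and `unattributed`.
#' @export
tidy.sa_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$resolved, status = "resolved"),
    dplyr::mutate(x$persisting, status = "persisting",
                  resolution_reason = NA_character_, unattributed = NA),
    dplyr::mutate(x$new, status = "new",
                  resolution_reason = NA_character_, unattributed = NA)
  )
}

#' One-row summary of a snapshot comparison
#'
#' @param x An `sa_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with resolved/persisting/new counts and the
#'   overall variation and percentage.
#' @export
glance.sa_comparison <- function(x, ...) {
  baseline <- nrow(x$resolved) + nrow(x$persisting)
  final <- nrow(x$persisting) + nrow(x$new)
  v <- compute_variation(baseline, final)
  tibble::tibble(
    baseline_date = x$baseline_date, final_date = x$final_date,
    year_label = x$year_label,
    n_baseline = baseline, n_final = final,
    n_resolved = nrow(x$resolved), n_persisting = nrow(x$persisting),
    n_new = nrow(x$new),
    variation = v$variation, pct = v$pct
  )
}

#' Tidy an indicator evaluation into its per-checkpoint results
#'
#' @param x An `sa_indicator`.
#' @param ... Unused.
#' @return Long tibble: one row per physician and checkpoint.
#' @export
tidy.sa_indicator <- function(x, ...) x$results

#' Per-physician summary of an indicator evaluation
#'
#' @param x An `sa_indicator`.
#' @param ... Unused.
#' @return The per-physician summary tibble (baseline, final count,
#'   variation, percentage, final goal attainment).
#' @export
glance.sa_indicator <- function(x, ...) x$summary

#' Plot per-category alert counts of a snapshot
#'
#' @param object An `sa_snapshot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sa_snapshot <- function(object, ...) {
  ggplot2::ggplot(object$per_category_counts,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  .data$n_alerts),
                               y = .data$n_alerts)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Alerts",
      title = paste0("Detected problems at ", format(object$snapshot_date)),
      subtitle = paste0("Catalog year ", object$year_label)
    )
}

#' Plot baseline vs final counts per category for a comparison
#'
#' @param object An `sa_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sa_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_category_variation,
    cols = c("baseline", "final"),
    names_to = "snapshot", values_to = "count")
  long$snapshot <- factor(long$snapshot, levels = c("baseline", "final"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$count,
                                     fill = .data$snapshot)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Alerts", fill = NULL,
      title = paste0("Problem counts, ", format(object$baseline_date),
                     " vs ", format(object$final_date))
    )
}

#' Plot the distribution of per-physician indicator outcomes
#'
#' @param object An `sa_indicator`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sa_indicator <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$final_variation,
                               fill = .data$goal_met_final)) +
    ggplot2::geom_histogram(binwidth = 1, colour = "white") +
    ggplot2::labs(
      x = "Final variation vs April baseline (indicator-linked problems)",
      y = "Physicians", fill = "Goal met",
      title = paste0("Safety indicator, year ", object$config$year_label)
    )
}
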