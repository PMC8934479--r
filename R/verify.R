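#' Recompute the reported study arithmetic
#'
#' The deployment the engine models published per-category counts for its
#' April baselines and December finals (2016-2018), per-alert breakdowns,
#' indicator-linked resolution counts and prevalence figures. This function
#' takes those printed counts (packaged as CSV fixtures) as inputs, reruns
#' the package's own arithmetic — [compute_variation()],
#' [mrp_prevalence()], [pct_share()], [indicator_aggregate()] — and compares
#' every recomputed value to the printed one.
#'
#' Printed cells whose published value is internally inconsistent (table
#' vs accompanying text) are not part of the fixture. A missing fixture file
#' yields `skipped` rows rather than an error, so partial fixture sets can
#' be checked.
#'
#' @param fixture_dir Directory of fixture CSVs; defaults to the packaged
#'   set (`category_counts.csv`, `aemps_alert_counts.csv`,
#'   `prevalence.csv`, `triple_whammy_share.csv`, `indicator_resolved.csv`).
#' @return A tibble of class `sa_verification` with columns `check`,
#'   `computed`, `printed`, `status` (`pass` / `fail` / `skipped`).
#' @examples
#' v <- verify_reported_arithmetic()
#' all(v$status == "pass")
#' @export
verify_reported_arithmetic <- function(fixture_dir = NULL) {
  fixture_dir <- fixture_dir %||%
    system.file("extdata", "reported", package = "selfaudit", mustWork = TRUE)
  rows <- list()
  add <- function(check, computed, printed) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, computed = as.numeric(computed),
      printed = as.numeric(printed),
      status = ifelse(is.na(computed), "skipped",
                      ifelse(computed == printed, "pass", "fail")))
  }
  skip_all <- function(checks) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = checks, computed = NA_real_, printed = NA_real_,
      status = "skipped")
  }
  read_fixture <- function(name) {
    path <- file.path(fixture_dir, name)
    if (!file.exists(path)) return(NULL)
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!nrow(out)) NULL else out
  }

  ## Per-category April -> December variations and the column-sum identity
  cc <- read_fixture("category_counts.csv")
  if (is.null(cc)) {
    skip_all("category_counts")
  } else {
    v <- compute_variation(cc$baseline, cc$final)
    for (i in seq_len(nrow(cc))) {
      id <- paste0(cc$year[i], ":", cc$category[i])
      add(paste0(id, ":variation"), v$variation[i], cc$printed_variation[i])
      add(paste0(id, ":pct"), v$pct[i], cc$printed_pct[i])
    }
    for (yr in unique(cc$year)) {
      part <- cc[cc$year == yr & cc$category != "total", ]
      tot <- cc[cc$year == yr & cc$category == "total", ]
      if (nrow(tot) == 1) {
        add(paste0(yr, ":total_baseline_is_sum"), sum(part$baseline),
            tot$baseline)
        add(paste0(yr, ":total_final_is_sum"), sum(part$final), tot$final)
      }
    }
  }

  ## Per-alert breakdown of the regulatory safety alerts
  aa <- read_fixture("aemps_alert_counts.csv")
  if (is.null(aa)) {
    skip_all("aemps_alert_counts")
  } else {
    v <- compute_variation(aa$baseline, aa$final)
    for (i in seq_len(nrow(aa))) {
      id <- paste0(aa$year[i], ":", aa$alert[i])
      add(paste0(id, ":variation"), v$variation[i], aa$printed_variation[i])
      add(paste0(id, ":pct"), v$pct[i], aa$printed_pct[i])
    }
  }

  ## Problem prevalence among active prescriptions
  pv <- read_fixture("prevalence.csv")
  if (is.null(pv)) {
    skip_all("prevalence")
  } else {
    for (i in seq_len(nrow(pv))) {
      add(paste0(pv$year[i], ":prevalence"),
          mrp_prevalence(pv$mrp_count[i], pv$active_prescriptions[i]),
          pv$printed_pct[i])
    }
  }

  ## Triple-Whammy share of the alert total
  tw <- read_fixture("triple_whammy_share.csv")
  if (is.null(tw)) {
    skip_all("triple_whammy_share")
  } else {
    for (i in seq_len(nrow(tw))) {
      add(paste0(tw$year[i], ":triple_whammy_share"),
          pct_share(tw$triple_whammy[i], tw$total_alerts[i]),
          tw$printed_share[i])
    }
  }

  ## Indicator-linked resolutions: yearly sums, cross-year total and the
  ## share of all resolved problems that were indicator-linked
  ir <- read_fixture("indicator_resolved.csv")
  if (is.null(ir)) {
    skip_all("indicator_resolved")
  } else {
    yearly <- vapply(seq_len(nrow(ir)), function(i) {
      indicator_aggregate(c(duplicate_therapy = ir$duplicate_therapy[i],
                            aemps_alert = ir$aemps_alert[i],
                            polymedication = ir$polymedication[i]))$total_resolved
    }, integer(1))
    for (i in seq_len(nrow(ir))) {
      add(paste0(ir$year[i], ":indicator_resolved_total"), yearly[i],
          ir$printed_total[i])
    }
    add("all_years:indicator_resolved_total", sum(yearly), 33148)
    add("all_years:indicator_share_of_resolved", pct_share(sum(yearly), 41492),
        80)
  }

  out <- dplyr::bind_rows(rows)
  class(out) <- c("sa_verification", class(out))
  out
}

#' @export
print.sa_verification <- function(x, ...) {
  cat("<sa_verification> ", sum(x$status == "pass"), " pass, ",
      sum(x$status == "fail"), " fail, ",
      sum(x$status == "skipped"), " skipped (", nrow(x), " checks)\n",
      sep = "")
  if (any(x$status == "fail")) {
    bad <- x[x$status == "fail", ]
    for (i in seq_len(min(nrow(bad), 10)))
      cat("  FAIL ", bad$check[i], ": computed ", bad$computed[i],
          ", printed ", bad$printed[i], "\n", sep = "")
  }
  invisible(x)
}
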