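#' Side-by-side scenario comparison ("main dashboard")
#'
#' Builds the dashboard table used to compare design scenarios: total
#' annual cost, cost by function, headline utilization, and cost as a
#' percent of a designated baseline (the baseline row shows 100%). Rows
#' keep the input order.
#'
#' @param results List of `scenario_result` objects (see
#'   [evaluate_scenario()]).
#' @param baseline Name of the baseline scenario; must be among `results`.
#' @return A `comparison_table` tibble: one row per scenario with columns
#'   `scenario`, `total_cost_usd`, `storage_usd`, `transportation_usd`,
#'   `management_usd`, `km_per_year`, `vehicles_required`,
#'   `percent_of_baseline`.
#' @export
compare_scenarios <- function(results, baseline) {
  if (length(results) < 1L) rsc_abort("results", "must be non-empty")
  if (!all(vapply(results, inherits, logical(1), "scenario_result"))) {
    rsc_abort("results", "must be a list of scenario_result objects")
  }
  nms <- vapply(results, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    rsc_abort("results", "duplicate scenario names: %s",
              paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  if (!baseline %in% nms) {
    rsc_abort("baseline", "\"%s\" is not among the results (%s)", baseline,
              paste(nms, collapse = ", "))
  }
  totals <- vapply(results, cost_totals, numeric(1))
  base_total <- totals[[match(baseline, nms)]]
  if (base_total <= 0) {
    rsc_abort("baseline", "degenerate baseline: total cost is %g", base_total)
  }
  cat_total <- function(r, cat) {
    tc <- cost_totals(r, "category")
    out <- tc$annual_cost_usd[tc$category == cat]
    if (length(out) == 0) 0 else out
  }
  tbl <- tibble::tibble(
    scenario = nms,
    total_cost_usd = totals,
    storage_usd = vapply(results, cat_total, numeric(1), "storage"),
    transportation_usd = vapply(results, cat_total, numeric(1),
                                "transportation"),
    management_usd = vapply(results, cat_total, numeric(1), "management"),
    km_per_year = vapply(results, function(r)
      sum(r$utilization$km_per_year), numeric(1)),
    vehicles_required = vapply(results, function(r)
      sum(r$utilization$vehicles_required), numeric(1)),
    percent_of_baseline = 100 * totals / base_total
  )
  attr(tbl, "baseline") <- baseline
  class(tbl) <- c("comparison_table", class(tbl))
  tbl
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("Scenario comparison (baseline: %s)\n",
              attr(x, "baseline")))
  y <- as.data.frame(x)
  y$total_cost_usd <- format(round(y$total_cost_usd), big.mark = ",")
  y$percent_of_baseline <- sprintf("%.1f%%", y$percent_of_baseline)
  print(y[, c("scenario", "total_cost_usd", "percent_of_baseline")],
        row.names = FALSE)
  invisible(x)
}

#' Aggregate independently modelled submodels
#'
#' Supply chains that use different designs in different subregions are
#' modelled separately and then aggregated: cost lines are concatenated
#' (tagged with their submodel of origin) and utilization is kept per
#' submodel, never merged.
#'
#' @param results Non-empty list of `scenario_result` objects with unique
#'   names.
#' @param name Name for the aggregate result.
#' @return A `scenario_result` whose `costs` carry a `submodel` column.
#' @export
aggregate_submodels <- function(results, name = "aggregate") {
  if (length(results) < 1L) rsc_abort("results", "must be non-empty")
  nms <- vapply(results, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    rsc_abort("results", "duplicate scenario names: %s",
              paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  costs <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(r$costs, submodel = r$name)
  }))
  util <- dplyr::bind_rows(lapply(results, function(r) {
    dplyr::mutate(r$utilization, submodel = r$name)
  }))
  structure(
    list(name = name, costs = costs, utilization = util,
         link_stats = stats::setNames(lapply(results, `[[`, "link_stats"),
                                      nms),
         scenario = NULL, submodels = nms),
    class = "scenario_result"
  )
}

#' Bar chart of the comparison dashboard
#'
#' Renders total cost per scenario as a percent of the baseline, stacked by
#' cost function. Requires ggplot2.
#'
#' @param tbl A `comparison_table` from [compare_scenarios()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_comparison() requires the ggplot2 package")
  }
  base_total <- tbl$total_cost_usd[tbl$scenario == attr(tbl, "baseline")]
  long <- dplyr::bind_rows(lapply(
    c("storage_usd", "transportation_usd", "management_usd"),
    function(col) tibble::tibble(
      scenario = tbl$scenario,
      category = sub("_usd$", "", col),
      percent = 100 * tbl[[col]] / base_total
    )
  ))
  long$scenario <- factor(long$scenario, levels = tbl$scenario)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$percent,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of baseline total cost",
                  fill = "function") +
    ggplot2::theme_minimal()
}
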