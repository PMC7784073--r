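#' Absolute percent error against a reference value
#'
#' @param model Model estimate.
#' @param reference Reference value (> 0); items with a non-positive
#'   reference must be excluded (and reported), never silently dropped.
#' @return `100 * |model - reference| / reference`, in percent.
#' @export
absolute_percent_error <- function(model, reference) {
  assert_number(model, "model")
  assert_number(reference, "reference")
  if (reference <= 0) {
    rsc_abort("reference", "must be > 0 (APE undefined); exclude and report %s",
              "the item instead of dropping it silently")
  }
  100 * abs(model - reference) / reference
}

#' An external reference cost analysis
#'
#' Wraps an existing cost study reshaped to the model's line-item form so
#' model output can be validated against it.
#'
#' @param name Analysis identifier.
#' @param items Data frame / tibble with columns `tier`, `category`,
#'   `label`, `annual_cost_usd`; (tier, category, label) must be unique and
#'   costs non-negative.
#' @param scope_notes Free-text notes on what the analysis covers.
#' @return A `reference_analysis` object.
#' @export
reference_analysis <- function(name, items, scope_notes = "") {
  assert_string(name, "reference.name")
  items <- tibble::as_tibble(items)
  needed <- c("tier", "category", "label", "annual_cost_usd")
  missing <- setdiff(needed, names(items))
  if (length(missing) > 0) {
    rsc_abort("reference.items", "missing column(s): %s",
              paste(missing, collapse = ", "))
  }
  if (any(items$annual_cost_usd < 0)) {
    rsc_abort("reference.items", "annual_cost_usd must be >= 0")
  }
  key <- paste(items$tier, items$category, items$label, sep = "|")
  if (anyDuplicated(key)) {
    rsc_abort("reference.items", "(tier, category, label) must be unique; %s",
              paste0("duplicated: ",
                     paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  structure(list(name = name, items = items[needed],
                 scope_notes = scope_notes),
            class = "reference_analysis")
}

#' Read a reference analysis from CSV
#'
#' Expects columns `tier`, `category`, `label`, `annual_cost_usd` -- the
#' same tidy shape [export_result_csv()] writes, so any scenario can be
#' validated against its own export.
#'
#' @param path CSV file path.
#' @param name Analysis name; defaults to the file stem.
#' @param scope_notes Free-text scope notes.
#' @return A [reference_analysis()].
#' @export
read_reference_analysis <- function(path, name = NULL, scope_notes = "") {
  if (!file.exists(path)) rsc_abort("path", "file not found: %s", path)
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_analysis(name %||% sub("\\.[^.]*$", "", basename(path)),
                     items, scope_notes)
}

normalize_key <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ _]+", " ", x)
}

item_keys <- function(items, alias = NULL, side = c("model", "reference")) {
  side <- match.arg(side)
  key <- paste(normalize_key(items$tier), normalize_key(items$category),
               normalize_key(items$label), sep = "|")
  if (!is.null(alias) && side == "model") {
    from <- normalize_key(alias$model_key)
    to <- normalize_key(alias$reference_key)
    hit <- match(key, from)
    key[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  key
}

#' MAPE validation at three aggregation levels
#'
#' Compares model output against a reference analysis at (1) individual
#' line items, (2) tier-by-category totals, and (3) the system grand
#' total, reporting a mean absolute percent error at each level. Items are
#' matched on normalized `(tier, category, label)` keys; a user-supplied
#' alias map handles analyses that scope or group items differently.
#' Unmatched items on either side are reported, never averaged in.
#' Tier-by-category cells with a zero reference total are excluded with a
#' warning (APE undefined there).
#'
#' @param model A `scenario_result` or a cost-items tibble.
#' @param ref A [reference_analysis()] (or items tibble).
#' @param alias Optional data frame with columns `model_key`,
#'   `reference_key`: normalized `"tier|category|label"` keys mapping model
#'   lines onto the reference's naming.
#' @return A `validation_report`: list with `ape_by_line_item` (tibble),
#'   `mape_line_item`, `mape_tier_category`, `mape_total` (percent), and
#'   `unmatched` (tibble with a `side` column).
#' @export
mape_three_levels <- function(model, ref, alias = NULL) {
  m_items <- if (inherits(model, "scenario_result")) model$costs else
    tibble::as_tibble(model)
  r_items <- if (inherits(ref, "reference_analysis")) ref$items else
    tibble::as_tibble(ref)
  if (!is.null(alias)) {
    alias <- as.data.frame(alias)
    if (!all(c("model_key", "reference_key") %in% names(alias))) {
      rsc_abort("alias", "needs columns model_key and reference_key")
    }
  }
  m_items <- dplyr::summarise(
    dplyr::group_by(m_items, .data$tier, .data$category, .data$label),
    annual_cost_usd = sum(.data$annual_cost_usd), .groups = "drop")
  mk <- item_keys(m_items, alias, "model")
  rk <- item_keys(r_items, alias, "reference")

  matched <- intersect(mk, rk)
  if (length(matched) == 0) {
    rsc_abort("items", "no matchable line items.\n  model keys: %s\n  %s",
              paste(mk, collapse = "; "),
              paste0("reference keys: ", paste(rk, collapse = "; ")))
  }
  mi <- match(matched, mk)
  ri <- match(matched, rk)

  # level 1: individual line items (intersection)
  zero_ref <- r_items$annual_cost_usd[ri] <= 0
  if (any(zero_ref)) {
    warn(sprintf("%d matched line item(s) have a zero reference cost; %s",
                 sum(zero_ref), "excluded from level-1 MAPE"))
  }
  ape_items <- tibble::tibble(
    key = matched[!zero_ref],
    tier = r_items$tier[ri][!zero_ref],
    category = r_items$category[ri][!zero_ref],
    label = r_items$label[ri][!zero_ref],
    model_usd = m_items$annual_cost_usd[mi][!zero_ref],
    reference_usd = r_items$annual_cost_usd[ri][!zero_ref]
  )
  ape_items$ape <- 100 * abs(ape_items$model_usd - ape_items$reference_usd) /
    ape_items$reference_usd

  unmatched <- dplyr::bind_rows(
    dplyr::mutate(m_items[!mk %in% matched, ], side = "model"),
    dplyr::mutate(r_items[!rk %in% matched, ], side = "reference")
  )

  # level 2: tier x category totals over the full items of each side
  m_tc <- cost_totals(m_items, "tier_category")
  r_tc <- cost_totals(r_items, "tier_category")
  tck <- function(d) paste(normalize_key(d$tier), normalize_key(d$category),
                           sep = "|")
  tc_matched <- intersect(tck(m_tc), tck(r_tc))
  m2 <- m_tc$annual_cost_usd[match(tc_matched, tck(m_tc))]
  r2 <- r_tc$annual_cost_usd[match(tc_matched, tck(r_tc))]
  zero2 <- r2 <= 0
  if (any(zero2)) {
    warn(sprintf("%d tier x category cell(s) have zero reference total; %s",
                 sum(zero2), "excluded from level-2 MAPE"))
  }
  ape_tc <- 100 * abs(m2[!zero2] - r2[!zero2]) / r2[!zero2]

  report <- structure(
    list(
      reference = if (inherits(ref, "reference_analysis")) ref$name else
        "reference",
      ape_by_line_item = ape_items,
      mape_line_item = mean(ape_items$ape),
      mape_tier_category = if (length(ape_tc) > 0) mean(ape_tc) else NA_real_,
      mape_total = absolute_percent_error(sum(m_items$annual_cost_usd),
                                          sum(r_items$annual_cost_usd)),
      unmatched = unmatched
    ),
    class = "validation_report"
  )
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> vs %s\n", x$reference))
  cat(sprintf("  MAPE, line items:       %6.2f%%  (%d matched)\n",
              x$mape_line_item, nrow(x$ape_by_line_item)))
  cat(sprintf("  MAPE, tier x category:  %6.2f%%\n", x$mape_tier_category))
  cat(sprintf("  MAPE, system total:     %6.2f%%\n", x$mape_total))
  if (nrow(x$unmatched) > 0) {
    cat(sprintf("  %d unmatched line item(s) excluded (see $unmatched)\n",
                nrow(x$unmatched)))
  }
  invisible(x)
}

#' Comparability adjustments before validation
#'
#' Reference analyses differ in scope and conventions; these adjustments
#' reshape a model result to match, from a closed set:
#'
#' * `list(type = "utilized_assets_only")` -- scale fixed vehicle lines
#'   (depreciation, insurance) by each tier's vehicle utilization, costing
#'   only the actively used fraction of the fleet (storage is already
#'   charged at required peak volume, so no storage scaling is needed).
#' * `list(type = "reassign_cost_owner", from_tier =, to_tier =,
#'   category =)` -- move a category's lines to the tier holding the
#'   budget line; conserves the grand total exactly.
#' * `list(type = "exclude_category_at_tier", tier =, label =)` -- drop
#'   lines entirely (e.g. facility storage depreciation omitted by the
#'   reference).
#'
#' @param result A `scenario_result`.
#' @param adjustments List of adjustment specs (each a named list with a
#'   `type` field).
#' @return A new `scenario_result`; applied adjustments are logged in
#'   `attr(, "adjustment_log")`.
#' @export
apply_comparability_adjustments <- function(result, adjustments) {
  if (!inherits(result, "scenario_result")) {
    rsc_abort("result", "must be a scenario_result")
  }
  out <- result
  log <- character(0)
  for (adj in adjustments) {
    type <- adj$type %||% "(missing)"
    if (type == "utilized_assets_only") {
      fixed <- out$costs$label %in% c("vehicle depreciation",
                                      "vehicle insurance")
      util <- stats::setNames(out$utilization$vehicle_utilization,
                              out$utilization$tier)
      scale <- util[out$costs$tier[fixed]]
      scale[is.na(scale)] <- 1
      out$costs$annual_cost_usd[fixed] <-
        out$costs$annual_cost_usd[fixed] * scale
      log <- c(log, "utilized_assets_only: fixed vehicle lines scaled by vehicle utilization")
    } else if (type == "reassign_cost_owner") {
      assert_string(adj$from_tier, "adjustment.from_tier")
      assert_string(adj$to_tier, "adjustment.to_tier")
      assert_string(adj$category, "adjustment.category")
      sel <- out$costs$tier == adj$from_tier &
        out$costs$category == adj$category
      out$costs$tier[sel] <- adj$to_tier
      log <- c(log, sprintf("reassign_cost_owner: %d %s line(s) %s -> %s",
                            sum(sel), adj$category, adj$from_tier,
                            adj$to_tier))
    } else if (type == "exclude_category_at_tier") {
      assert_string(adj$tier, "adjustment.tier")
      assert_string(adj$label, "adjustment.label")
      sel <- out$costs$tier == adj$tier &
        normalize_key(out$costs$label) == normalize_key(adj$label)
      out$costs <- out$costs[!sel, ]
      log <- c(log, sprintf("exclude_category_at_tier: removed %d \"%s\" line(s) at %s",
                            sum(sel), adj$label, adj$tier))
    } else {
      rsc_abort("adjustment.type",
                "unknown adjustment \"%s\" (known: %s)", type,
                "utilized_assets_only, reassign_cost_owner, exclude_category_at_tier")
    }
  }
  attr(out, "adjustment_log") <- c(attr(result, "adjustment_log"), log)
  out
}
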