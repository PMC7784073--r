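ref_items <- function(...) {
  tibble::tibble(...)
}

test_that("absolute percent error is |model - ref| / ref", {
  expect_equal(absolute_percent_error(110, 100), 10)
  expect_equal(absolute_percent_error(100, 100), 0)
  expect_equal(absolute_percent_error(50, 100), 50)
  expect_error(absolute_percent_error(50, 0),
               class = "rapidsc_validation_error")
})

test_that("hand-computed fixture: aggregation shrinks the error", {
  # fuel 110 vs 100 (APE 10%), maintenance 95 vs 100 (APE 5%), same tier
  # and category: level 1 = mean(10, 5) = 7.5; level 2 = |205-200|/200 =
  # 2.5; level 3 likewise 2.5
  model <- ref_items(tier = "facility", category = "transportation",
                     label = c("fuel", "maintenance"),
                     annual_cost_usd = c(110, 95))
  ref <- reference_analysis("fixture", ref_items(
    tier = "facility", category = "transportation",
    label = c("fuel", "maintenance"), annual_cost_usd = c(100, 100)))
  rep <- mape_three_levels(model, ref)
  expect_equal(rep$mape_line_item, 7.5)
  expect_equal(rep$mape_tier_category, 2.5)
  expect_equal(rep$mape_total, 2.5)
  # the 10%/30% -> 20% mean example
  model2 <- ref_items(tier = "t", category = "storage",
                      label = c("a", "b"), annual_cost_usd = c(110, 130))
  ref2 <- ref_items(tier = "t", category = "storage",
                    label = c("a", "b"), annual_cost_usd = c(100, 100))
  expect_equal(mape_three_levels(model2, ref2)$mape_line_item, 20)
})

test_that("self-validation returns zero at all three levels", {
  r <- evaluate_scenario(four_tier())
  rep <- mape_three_levels(r, reference_analysis("self", r$costs))
  expect_equal(rep$mape_line_item, 0)
  expect_equal(rep$mape_tier_category, 0)
  expect_equal(rep$mape_total, 0)
  expect_identical(nrow(rep$unmatched), 0L)
})

test_that("MAPE is invariant to uniform scaling of both sides", {
  r <- evaluate_scenario(toy_two_tier())
  ref <- r$costs
  set.seed(7)
  ref$annual_cost_usd <- ref$annual_cost_usd * runif(nrow(ref), 0.8, 1.2)
  rep1 <- mape_three_levels(r$costs, reference_analysis("x", ref))
  scaled_model <- r$costs
  scaled_model$annual_cost_usd <- scaled_model$annual_cost_usd * 7
  ref7 <- ref
  ref7$annual_cost_usd <- ref7$annual_cost_usd * 7
  rep7 <- mape_three_levels(scaled_model, reference_analysis("x", ref7))
  expect_equal(rep7$mape_line_item, rep1$mape_line_item)
  expect_equal(rep7$mape_tier_category, rep1$mape_tier_category)
  expect_equal(rep7$mape_total, rep1$mape_total)
})

test_that("unmatched items are reported, never averaged in", {
  model <- ref_items(tier = "t", category = "storage",
                     label = c("dry storage", "only in model"),
                     annual_cost_usd = c(100, 999))
  ref <- reference_analysis("r", ref_items(
    tier = "t", category = "storage",
    label = c("dry storage", "only in reference"),
    annual_cost_usd = c(100, 50)))
  rep <- mape_three_levels(model, ref)
  expect_equal(rep$mape_line_item, 0)  # the one matched pair is exact
  expect_identical(nrow(rep$unmatched), 2L)
  expect_setequal(rep$unmatched$side, c("model", "reference"))
})

test_that("alias map aligns differently named line items", {
  model <- ref_items(tier = "t", category = "transportation",
                     label = "fuel", annual_cost_usd = 110)
  ref <- reference_analysis("r", ref_items(
    tier = "t", category = "transportation", label = "petrol and diesel",
    annual_cost_usd = 100))
  expect_error(mape_three_levels(model, ref),
               class = "rapidsc_validation_error")
  alias <- data.frame(model_key = "t|transportation|fuel",
                      reference_key = "t|transportation|petrol and diesel")
  rep <- mape_three_levels(model, ref, alias = alias)
  expect_equal(rep$mape_line_item, 10)
})

test_that("comparability adjustments reshape results as specified", {
  area <- (50 / 0.3826)^2
  s <- toy_two_tier(monthly_demand = 0.5, n_facilities = 1,
                    region_area = area)
  r <- evaluate_scenario(s)

  # utilized assets: fixed $3,500 at utilization 0.024 -> $84
  adj <- apply_comparability_adjustments(
    r, list(list(type = "utilized_assets_only")))
  fixed <- adj$costs$label %in% c("vehicle depreciation",
                                  "vehicle insurance")
  expect_equal(sum(adj$costs$annual_cost_usd[fixed]), 0.024 * 3500)

  # exclusion removes the lines and exactly their sum
  excl <- apply_comparability_adjustments(
    r, list(list(type = "exclude_category_at_tier", tier = "facility",
                 label = "dry storage")))
  dropped <- r$costs$annual_cost_usd[r$costs$tier == "facility" &
                                       r$costs$label == "dry storage"]
  expect_equal(cost_totals(excl), cost_totals(r) - sum(dropped))
  expect_false(any(excl$costs$tier == "facility" &
                     excl$costs$label == "dry storage"))

  # reassignment conserves the grand total exactly
  moved <- apply_comparability_adjustments(
    r, list(list(type = "reassign_cost_owner", from_tier = "hub",
                 to_tier = "facility", category = "transportation")))
  expect_identical(cost_totals(moved), cost_totals(r))
  expect_false(any(moved$costs$tier == "hub" &
                     moved$costs$category == "transportation"))

  expect_error(
    apply_comparability_adjustments(r, list(list(type = "nonsense"))),
    class = "rapidsc_validation_error")
})

test_that("reference CSV round-trips through export and read", {
  r <- evaluate_scenario(toy_two_tier())
  dir <- withr::local_tempdir()
  paths <- export_result_csv(r, dir)
  ref <- read_reference_analysis(paths[["costs"]])
  rep <- mape_three_levels(r, ref)
  expect_equal(rep$mape_line_item, 0)
  expect_equal(rep$mape_tier_category, 0)
  expect_equal(rep$mape_total, 0)
})
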