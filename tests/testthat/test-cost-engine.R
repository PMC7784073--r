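test_that("shipments per year is 12 over the interval", {
  expect_equal(shipments_per_year(1), 12)
  expect_equal(shipments_per_year(2), 6)
  expect_equal(shipments_per_year(3), 4)
  expect_error(shipments_per_year(0), class = "rapidsc_validation_error")
})

test_that("peak stock uses the max-stock convention", {
  p <- storage_policy(1, safety_stock_months = 2)
  expect_equal(peak_stock_m3(2, p), 6)
  expect_equal(peak_stock_m3(2, p, buffer_multiplier = 1.3), 7.8)
  expect_equal(peak_stock_m3(2, storage_policy(1)), 2)
})

test_that("trips per shipment ceilings at effective capacity", {
  v <- vehicle_spec("v", cargo_capacity_m3 = 4)
  expect_identical(trips_per_shipment(10, v), 3L)
  expect_identical(trips_per_shipment(4, v), 1L)
  expect_identical(trips_per_shipment(4.0001, v), 2L)
  expect_identical(trips_per_shipment(0, v), 0L)
  expect_identical(trips_per_shipment(4, v, max_load_factor = 0.5), 2L)
})

test_that("storage lines split peak stock into cold and dry at the rates", {
  # peak 6 m3/site, cold_fraction 0.5, cold $200, dry $20, 10 sites
  s <- toy_two_tier(monthly_demand = 2, interval = 1, safety = 2)
  lines <- storage_cost_tier(s, "facility")
  expect_equal(lines$annual_cost_usd[lines$label == "cold storage"], 6000)
  expect_equal(lines$annual_cost_usd[lines$label == "dry storage"], 600)

  # a pass-through tier has no storage lines
  passthrough <- supply_chain_scenario(
    "pt", region_geometry(400),
    tiers = list(
      tier_spec("hub", 0L, 1L, storage = storage_policy(3)),
      tier_spec("dock", 1L, 2L, holds_inventory = FALSE,
                storage = storage_policy(1),
                transport = transport_policy("van", "hub_and_spoke")),
      tier_spec("facility", 2L, 10L, storage = storage_policy(1, 1),
                transport = transport_policy("van", "hub_and_spoke"))),
    demand = demand_spec(monthly_demand_m3_per_facility = 0.1),
    rates = toy_rates())
  expect_identical(nrow(storage_cost_tier(passthrough, "dock")), 0L)
})

test_that("management cost is per-site staffing plus technology", {
  s <- toy_two_tier(n_facilities = 10)
  lines <- management_cost_tier(s, "facility")
  # (0.2 FTE x $6,000 + $300 tech) x 10 sites
  expect_equal(sum(lines$annual_cost_usd), 15000)
  one_site <- toy_two_tier(n_facilities = 1)
  expect_equal(sum(management_cost_tier(one_site, "facility")$annual_cost_usd),
               1500)
  expect_identical(nrow(management_cost_tier(s, "hub")), 0L)
})

test_that("transport link arithmetic matches the hand calculation", {
  # geometry chosen so the round trip is exactly 100 km: 12 shipments/yr,
  # 1 trip each, fuel 0.12 L/km @ $1/L, maintenance $0.05/km, speed 50
  area <- (50 / 0.3826)^2
  s <- toy_two_tier(monthly_demand = 0.5, n_facilities = 1,
                    region_area = area)
  link <- rapidsc:::transport_link(s, "facility")
  expect_equal(link$stats$route_km, 100)
  expect_equal(link$stats$km_per_year, 1200)
  items <- link$items
  cost_of <- function(lbl) items$annual_cost_usd[items$label == lbl]
  expect_equal(cost_of("fuel"), 144)
  expect_equal(cost_of("maintenance"), 60)
  # $30,000 vehicle over 10 years + $500 insurance, one vehicle
  expect_equal(cost_of("vehicle depreciation") +
                 cost_of("vehicle insurance"), 3500)
  # 12 trips x 2 h = 24 trip-hours over 1,000 available hours
  expect_equal(link$stats$trip_hours_per_year, 24)
  expect_equal(link$stats$vehicles_required, 1)
  expect_equal(link$stats$vehicle_utilization, 0.024)
  # per diem: 1 day per trip at $10
  expect_equal(cost_of("per diem"), 120)
})

test_that("transport lines are charged to the operating tier", {
  s <- toy_two_tier()
  items_sup <- transport_cost_link(s, "facility")
  expect_true(all(items_sup$tier == "hub"))
  s$tiers$facility$transport$operator <- "receiving_tier"
  items_rec <- transport_cost_link(s, "facility")
  expect_true(all(items_rec$tier == "facility"))
  expect_equal(sum(items_rec$annual_cost_usd),
               sum(items_sup$annual_cost_usd))
})

test_that("two-tier toy matches the independent spreadsheet-style total", {
  # every line recomputed by hand from the stated formulas:
  # facility storage: peak 1.5 -> (150 cold + 15 dry) x 10   = 1650
  # hub storage:      peak 20  -> 2000 cold + 200 dry        = 2200
  # transport: leg 7.652, 10 routes x 15.304 km x 12         = 1836.48 km
  #   fuel 220.3776, maint 91.824, per-diem 1200, fixed 3500
  # management: (1200 + 300) x 10                            = 15000
  s <- toy_two_tier()
  r <- evaluate_scenario(s)
  expect_equal(cost_totals(r),
               1650 + 2200 + 220.3776 + 91.824 + 1200 + 3500 + 15000,
               tolerance = 1e-12)
  bytier <- cost_totals(r, "tier")
  expect_equal(bytier$annual_cost_usd[bytier$tier == "hub"],
               2200 + 220.3776 + 91.824 + 1200 + 3500)
  expect_equal(bytier$annual_cost_usd[bytier$tier == "facility"],
               1650 + 15000)
})

test_that("totals are conserved under any regrouping", {
  r <- evaluate_scenario(four_tier())
  total <- cost_totals(r)
  expect_equal(sum(cost_totals(r, "tier")$annual_cost_usd), total,
               tolerance = 1e-12)
  expect_equal(sum(cost_totals(r, "category")$annual_cost_usd), total,
               tolerance = 1e-12)
  expect_equal(sum(cost_totals(r, "tier_category")$annual_cost_usd), total,
               tolerance = 1e-12)
})

test_that("zero demand zeroes variable lines but keeps fixed ones", {
  s <- toy_two_tier(monthly_demand = 1e-12)
  s$demand$monthly_demand_m3_per_facility <- 0  # degenerate limit
  r <- evaluate_scenario(s)
  items <- r$costs
  variable <- items$label %in% c("fuel", "maintenance", "per diem",
                                 "cold storage", "dry storage")
  expect_true(all(items$annual_cost_usd[variable] == 0))
  fixed <- items$label %in% c("vehicle depreciation", "vehicle insurance")
  expect_equal(sum(items$annual_cost_usd[fixed]), 3500)
  expect_equal(sum(items$annual_cost_usd[items$category == "management"]),
               15000)
})

test_that("utilized-asset mode costs fractional vehicles", {
  area <- (50 / 0.3826)^2
  s <- toy_two_tier(monthly_demand = 0.5, n_facilities = 1,
                    region_area = area)
  owned <- evaluate_scenario(s)
  used <- evaluate_scenario(s, utilized_assets = TRUE)
  fixed <- function(r) sum(r$costs$annual_cost_usd[
    r$costs$label %in% c("vehicle depreciation", "vehicle insurance")])
  # 24 trip-hours / 1,000 available = 0.024 vehicles
  expect_equal(fixed(used), 0.024 * 3500)
  expect_equal(fixed(owned), 3500)
  # variable lines unchanged
  expect_equal(
    owned$costs$annual_cost_usd[owned$costs$label == "fuel"],
    used$costs$annual_cost_usd[used$costs$label == "fuel"])
})

test_that("evaluation is deterministic", {
  s <- four_tier()
  expect_identical(evaluate_scenario(s)$costs, evaluate_scenario(s)$costs)
})
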