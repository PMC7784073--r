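test_that("constructors enforce field invariants with named errors", {
  expect_error(region_geometry(0), class = "rapidsc_validation_error")
  expect_error(region_geometry(100, circuity_factor = 0.9),
               class = "rapidsc_validation_error")
  expect_error(storage_policy(0), class = "rapidsc_validation_error")
  expect_error(storage_policy(1, cold_fraction = 1.2),
               class = "rapidsc_validation_error")
  expect_error(transport_policy("v", "multi_stop_loop"),
               class = "rapidsc_validation_error")
  expect_error(vehicle_spec("v", cargo_capacity_m3 = 0),
               class = "rapidsc_validation_error")
  err <- tryCatch(storage_policy(-1), error = identity)
  expect_match(conditionMessage(err), "replenishment_interval_months")
})

test_that("a minimal two-tier configuration builds with levels 0 and 1", {
  s <- toy_two_tier()
  expect_s3_class(s, "supply_chain_scenario")
  expect_identical(unname(vapply(s$tiers, `[[`, integer(1), "level")),
                   c(0L, 1L))
  expect_named(s$tiers, c("hub", "facility"))
})

test_that("scenario validation catches structural problems", {
  tiers_gap <- list(
    tier_spec("a", 0L, 1L, storage = storage_policy(1)),
    tier_spec("b", 2L, 5L, storage = storage_policy(1),
              transport = transport_policy("van", "hub_and_spoke")))
  expect_error(
    supply_chain_scenario("x", region_geometry(100), tiers_gap,
                          demand_spec(monthly_demand_m3_per_facility = 1),
                          toy_rates()),
    "contiguous", class = "rapidsc_validation_error")

  # dangling vehicle reference
  tiers_bad_vehicle <- list(
    tier_spec("a", 0L, 1L, storage = storage_policy(1)),
    tier_spec("b", 1L, 5L, storage = storage_policy(1),
              transport = transport_policy("lorry", "hub_and_spoke")))
  expect_error(
    supply_chain_scenario("x", region_geometry(100), tiers_bad_vehicle,
                          demand_spec(monthly_demand_m3_per_facility = 1),
                          toy_rates()),
    "unknown vehicle", class = "rapidsc_validation_error")

  # role missing from the salary table
  tiers_bad_role <- list(
    tier_spec("a", 0L, 1L, storage = storage_policy(1),
              management = management_policy(c(pilot = 1))),
    tier_spec("b", 1L, 5L, storage = storage_policy(1),
              transport = transport_policy("van", "hub_and_spoke")))
  expect_error(
    supply_chain_scenario("x", region_geometry(100), tiers_bad_role,
                          demand_spec(monthly_demand_m3_per_facility = 1),
                          toy_rates()),
    "pilot", class = "rapidsc_validation_error")

  # facility counts decreasing with level only warns
  tiers_decreasing <- list(
    tier_spec("a", 0L, 10L, storage = storage_policy(1)),
    tier_spec("b", 1L, 5L, storage = storage_policy(1),
              transport = transport_policy("van", "hub_and_spoke")))
  expect_warning(
    supply_chain_scenario("x", region_geometry(100), tiers_decreasing,
                          demand_spec(monthly_demand_m3_per_facility = 1),
                          toy_rates()),
    "non-decreasing")
})

test_that("level skip removes the tier, re-links and re-indexes", {
  s <- four_tier()
  expect_length(s$tiers, 4L)
  skipped <- apply_level_skip(s, "province")
  expect_length(skipped$tiers, 3L)
  expect_named(skipped$tiers, c("national", "municipality",
                                "health_facility"))
  expect_identical(unname(vapply(skipped$tiers, `[[`, integer(1),
                                 "level")), 0:2)
  # municipality keeps its inbound transport policy
  expect_identical(skipped$tiers$municipality$transport,
                   s$tiers$municipality$transport)
  # transforms are pure: the input scenario is untouched
  expect_length(s$tiers, 4L)
  expect_identical(s, four_tier())
})

test_that("skipping the top or bottom tier errors", {
  s <- four_tier()
  expect_error(apply_level_skip(s, "national"),
               class = "rapidsc_validation_error")
  expect_error(apply_level_skip(s, "health_facility"),
               class = "rapidsc_validation_error")
  expect_error(apply_level_skip(s, "nowhere"),
               class = "rapidsc_validation_error")
})

test_that("level skip then re-adding the tier restores an equivalent scenario", {
  s <- four_tier()
  skipped <- apply_level_skip(s, "province")
  prov <- s$tiers$province
  tiers <- c(list(skipped$tiers[[1]]), list(prov),
             skipped$tiers[2:3])
  for (i in seq_along(tiers)) tiers[[i]]$level <- i - 1L
  restored <- supply_chain_scenario(
    s$name, s$region, unname(tiers), s$demand, s$rates, s$geometry,
    s$throughput_buffer, s$workday_hours)
  expect_identical(restored$tiers, s$tiers)
  expect_equal(cost_totals(evaluate_scenario(restored)),
               cost_totals(evaluate_scenario(s)))
})

test_that("set_replenishment_interval changes only that tier's interval", {
  s <- four_tier()
  s2 <- set_replenishment_interval(s, "municipality", 2)
  expect_equal(
    s2$tiers$municipality$storage$replenishment_interval_months, 2)
  s2$tiers$municipality$storage$replenishment_interval_months <-
    s$tiers$municipality$storage$replenishment_interval_months
  expect_identical(s2, s)
  expect_identical(set_replenishment_interval(s, "municipality", 1), s)
  expect_error(set_replenishment_interval(s, "municipality", 0),
               class = "rapidsc_validation_error")
  expect_error(set_replenishment_interval(s, "national", 2),
               class = "rapidsc_validation_error")
})

test_that("throughput buffer validates and blends as stated", {
  s <- toy_two_tier()
  expect_error(set_throughput_buffer(s, 0.9, 2),
               class = "rapidsc_validation_error")
  expect_error(set_throughput_buffer(s, 1.3, 13),
               class = "rapidsc_validation_error")
  b <- set_throughput_buffer(s, 2, 6)
  bf <- rapidsc:::buffer_factors(b)
  expect_equal(bf$capacity, 2)
  expect_equal(bf$flow, 1.5)
  # multiplier 1 is identical to no buffer
  none <- evaluate_scenario(s)
  one <- evaluate_scenario(set_throughput_buffer(s, 1, 6))
  expect_equal(one$costs, none$costs)
  expect_equal(one$utilization, none$utilization)
})
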