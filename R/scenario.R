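#' Region geometry
#'
#' Describes the region a supply chain serves: its land area and a road
#' circuity factor that converts straight-line to road distance. Facilities
#' within a tier are assumed evenly distributed over this area, so every
#' facility sits the same average distance from its resupply point.
#'
#' @param land_area_km2 Region land area in square kilometres (> 0).
#' @param circuity_factor Unitless road-distance multiplier (>= 1). A value
#'   of 1.5 means road distances average 50% longer than straight lines.
#' @return A `region_geometry` object.
#' @export
#' @examples
#' region_geometry(1246700, circuity_factor = 1.5)
region_geometry <- function(land_area_km2, circuity_factor = 1) {
  assert_number(land_area_km2, "region.land_area_km2", min = 0, strict_min = TRUE)
  assert_number(circuity_factor, "region.circuity_factor", min = 1)
  structure(
    list(land_area_km2 = land_area_km2, circuity_factor = circuity_factor),
    class = "region_geometry"
  )
}

#' Storage policy for a tier
#'
#' Inventory is managed on a periodic-review max-stock convention: a site is
#' topped up every `replenishment_interval_months` and additionally holds
#' `safety_stock_months` of demand, so peak (post-delivery) stock equals
#' monthly demand times the sum of the two.
#'
#' @param replenishment_interval_months Months between resupply shipments
#'   (> 0).
#' @param safety_stock_months Safety stock expressed in months of demand
#'   (>= 0).
#' @param cold_fraction Share of stored volume requiring cold chain, in
#'   \[0, 1\].
#' @param available_capacity_m3 Optional storage capacity (m^3) of the
#'   typical site at this tier; when absent, storage utilization is
#'   undefined (reported as `NA`).
#' @return A `storage_policy` object.
#' @export
storage_policy <- function(replenishment_interval_months,
                           safety_stock_months = 0,
                           cold_fraction = 0,
                           available_capacity_m3 = NULL) {
  assert_number(replenishment_interval_months,
                "storage.replenishment_interval_months",
                min = 0, strict_min = TRUE)
  assert_number(safety_stock_months, "storage.safety_stock_months", min = 0)
  assert_number(cold_fraction, "storage.cold_fraction", min = 0, max = 1)
  assert_number(available_capacity_m3, "storage.available_capacity_m3",
                min = 0, allow_null = TRUE)
  structure(
    list(
      replenishment_interval_months = as.numeric(replenishment_interval_months),
      safety_stock_months = as.numeric(safety_stock_months),
      cold_fraction = cold_fraction,
      available_capacity_m3 = available_capacity_m3
    ),
    class = "storage_policy"
  )
}

#' Transport policy for resupplying a tier
#'
#' Describes how shipments reach a tier from the tier above: the vehicle
#' used, whether each facility gets a dedicated out-and-back trip
#' (`hub_and_spoke`) or several facilities share a multi-stop loop
#' ("milk run"), and which tier operates -- and is charged for -- the
#' transport (`supplying_tier` for delivery designs, `receiving_tier` for
#' facility-collection designs).
#'
#' @param vehicle Name of a vehicle defined in the scenario's [cost_rates()].
#' @param distribution_model `"hub_and_spoke"` or `"multi_stop_loop"`.
#' @param stops_per_loop Facilities served per loop (required for
#'   `multi_stop_loop`; `1` collapses to hub-and-spoke semantics).
#' @param max_load_factor Usable fraction of vehicle cargo capacity, in
#'   (0, 1\].
#' @param operator `"supplying_tier"` or `"receiving_tier"`; transport cost
#'   lines are assigned to the tier where the activity occurs.
#' @param service_time_hours_per_stop Loading/unloading time per stop, hours.
#' @return A `transport_policy` object.
#' @export
transport_policy <- function(vehicle,
                             distribution_model = c("hub_and_spoke",
                                                    "multi_stop_loop"),
                             stops_per_loop = NULL,
                             max_load_factor = 1,
                             operator = c("supplying_tier", "receiving_tier"),
                             service_time_hours_per_stop = 0) {
  assert_string(vehicle, "transport.vehicle")
  distribution_model <- assert_choice(distribution_model[[1]],
                                      "transport.distribution_model",
                                      c("hub_and_spoke", "multi_stop_loop"))
  if (distribution_model == "multi_stop_loop") {
    stops_per_loop <- assert_count(stops_per_loop, "transport.stops_per_loop",
                                   min = 1L)
    if (stops_per_loop == 1L) distribution_model <- "hub_and_spoke"
  } else {
    stops_per_loop <- 1L
  }
  assert_number(max_load_factor, "transport.max_load_factor",
                min = 0, max = 1, strict_min = TRUE)
  operator <- assert_choice(operator[[1]], "transport.operator",
                            c("supplying_tier", "receiving_tier"))
  assert_number(service_time_hours_per_stop,
                "transport.service_time_hours_per_stop", min = 0)
  structure(
    list(
      vehicle = vehicle,
      distribution_model = distribution_model,
      stops_per_loop = stops_per_loop,
      max_load_factor = max_load_factor,
      operator = operator,
      service_time_hours_per_stop = service_time_hours_per_stop
    ),
    class = "transport_policy"
  )
}

#' Management (staffing and technology) policy for a tier
#'
#' @param fte_by_role Named numeric vector or list: full-time-equivalent
#'   staff per typical site, by role. Roles must exist in the scenario's
#'   salary table.
#' @param technology_cost_per_site_year Annual technology cost per site
#'   (USD/yr), e.g. logistics information systems.
#' @return A `management_policy` object.
#' @export
management_policy <- function(fte_by_role = NULL,
                              technology_cost_per_site_year = 0) {
  fte <- unlist(fte_by_role) %||% stats::setNames(numeric(0), character(0))
  if (length(fte) > 0 && (is.null(names(fte)) || any(!nzchar(names(fte))))) {
    rsc_abort("management.fte_by_role", "must be named by role")
  }
  for (r in names(fte)) {
    assert_number(fte[[r]], paste0("management.fte_by_role.", r), min = 0)
  }
  assert_number(technology_cost_per_site_year,
                "management.technology_cost_per_site_year", min = 0)
  structure(
    list(fte_by_role = fte,
         technology_cost_per_site_year = technology_cost_per_site_year),
    class = "management_policy"
  )
}

#' Vehicle specification
#'
#' @param name Vehicle identifier.
#' @param cargo_capacity_m3 Usable cargo volume, m^3 (> 0).
#' @param fuel_l_per_km Fuel consumption, litres per km.
#' @param fuel_type Label only (no conversion performed).
#' @param purchase_price_usd Acquisition cost, annualized straight-line
#'   over `service_life_years`.
#' @param service_life_years Depreciation horizon, years (> 0).
#' @param insurance_usd_year Annual insurance cost.
#' @param maintenance_usd_per_km Maintenance cost per km travelled.
#' @param speed_kmh Average travel speed, km/h (> 0).
#' @param available_hours_year Annual hours one vehicle can operate (> 0).
#' @param per_diem_usd_per_trip_day Driver per-diem per trip day.
#' @return A `vehicle_spec` object.
#' @export
vehicle_spec <- function(name,
                         cargo_capacity_m3,
                         fuel_l_per_km = 0,
                         fuel_type = "diesel",
                         purchase_price_usd = 0,
                         service_life_years = 1,
                         insurance_usd_year = 0,
                         maintenance_usd_per_km = 0,
                         speed_kmh = 50,
                         available_hours_year = 1800,
                         per_diem_usd_per_trip_day = 0) {
  assert_string(name, "vehicle.name")
  pre <- function(f) paste0("vehicle.", name, ".", f)
  assert_number(cargo_capacity_m3, pre("cargo_capacity_m3"),
                min = 0, strict_min = TRUE)
  assert_number(fuel_l_per_km, pre("fuel_l_per_km"), min = 0)
  assert_string(fuel_type, pre("fuel_type"))
  assert_number(purchase_price_usd, pre("purchase_price_usd"), min = 0)
  assert_number(service_life_years, pre("service_life_years"),
                min = 0, strict_min = TRUE)
  assert_number(insurance_usd_year, pre("insurance_usd_year"), min = 0)
  assert_number(maintenance_usd_per_km, pre("maintenance_usd_per_km"), min = 0)
  assert_number(speed_kmh, pre("speed_kmh"), min = 0, strict_min = TRUE)
  assert_number(available_hours_year, pre("available_hours_year"),
                min = 0, strict_min = TRUE)
  assert_number(per_diem_usd_per_trip_day, pre("per_diem_usd_per_trip_day"),
                min = 0)
  structure(
    list(name = name, cargo_capacity_m3 = cargo_capacity_m3,
         fuel_l_per_km = fuel_l_per_km, fuel_type = fuel_type,
         purchase_price_usd = purchase_price_usd,
         service_life_years = service_life_years,
         insurance_usd_year = insurance_usd_year,
         maintenance_usd_per_km = maintenance_usd_per_km,
         speed_kmh = speed_kmh, available_hours_year = available_hours_year,
         per_diem_usd_per_trip_day = per_diem_usd_per_trip_day),
    class = "vehicle_spec"
  )
}

#' Unit cost rates
#'
#' The typical-cost database behind a scenario: storage rates (annualized
#' cost per usable cubic metre and year, with a separate, usually much
#' higher, rate for cold chain), fuel price, salary table, and the vehicle
#' fleet catalogue.
#'
#' @param fuel_price_usd_per_l Fuel price, USD per litre.
#' @param dry_storage_usd_per_m3_year Dry storage rate, USD per m^3-year.
#' @param cold_storage_usd_per_m3_year Cold-chain storage rate, USD per
#'   m^3-year (annualized equipment plus energy).
#' @param salary_usd_year_by_role Named vector/list: annual salary by role.
#' @param vehicles Named list of [vehicle_spec()] objects.
#' @return A `cost_rates` object.
#' @export
cost_rates <- function(fuel_price_usd_per_l = 0,
                       dry_storage_usd_per_m3_year = 0,
                       cold_storage_usd_per_m3_year = 0,
                       salary_usd_year_by_role = NULL,
                       vehicles = list()) {
  assert_number(fuel_price_usd_per_l, "rates.fuel_price_usd_per_l", min = 0)
  assert_number(dry_storage_usd_per_m3_year,
                "rates.dry_storage_usd_per_m3_year", min = 0)
  assert_number(cold_storage_usd_per_m3_year,
                "rates.cold_storage_usd_per_m3_year", min = 0)
  salaries <- unlist(salary_usd_year_by_role) %||%
    stats::setNames(numeric(0), character(0))
  for (r in names(salaries)) {
    assert_number(salaries[[r]], paste0("rates.salaries.", r), min = 0)
  }
  if (length(vehicles) > 0) {
    if (is.null(names(vehicles)) || any(!nzchar(names(vehicles)))) {
      rsc_abort("rates.vehicles", "must be a named list of vehicle_spec")
    }
    for (v in vehicles) {
      if (!inherits(v, "vehicle_spec")) {
        rsc_abort("rates.vehicles", "entries must be vehicle_spec objects")
      }
    }
  }
  structure(
    list(fuel_price_usd_per_l = fuel_price_usd_per_l,
         dry_storage_usd_per_m3_year = dry_storage_usd_per_m3_year,
         cold_storage_usd_per_m3_year = cold_storage_usd_per_m3_year,
         salary_usd_year_by_role = salaries,
         vehicles = vehicles),
    class = "cost_rates"
  )
}

#' Tier specification
#'
#' One level of the distribution hierarchy, described through its typical
#' facility: every service point at a tier shares the same demand, distance
#' and cost profile. Level 0 is the top (national) tier; levels increase
#' downstream and each tier is resupplied by the tier one level above.
#'
#' @param name Tier identifier (e.g. `"province"`).
#' @param level Non-negative integer; 0 = national, increasing downstream.
#' @param n_service_points Number of facilities/stores at this tier (>= 1).
#' @param holds_inventory Does this tier hold stock? Pass-through tiers
#'   (cross-docks) contribute no storage cost.
#' @param storage A [storage_policy()]; required when `holds_inventory`.
#' @param transport A [transport_policy()] describing how this tier is
#'   resupplied from the tier above; must be absent for level 0.
#' @param management A [management_policy()]; optional.
#' @return A `tier_spec` object.
#' @export
tier_spec <- function(name, level, n_service_points,
                      holds_inventory = TRUE,
                      storage = NULL, transport = NULL, management = NULL) {
  assert_string(name, "tier.name")
  pre <- function(f) paste0("tiers.", name, ".", f)
  level <- assert_count(level, pre("level"), min = 0L)
  n_service_points <- assert_count(n_service_points, pre("n_service_points"),
                                   min = 1L)
  assert_flag(holds_inventory, pre("holds_inventory"))
  if (holds_inventory && is.null(storage)) {
    rsc_abort(pre("storage"), "is required when holds_inventory is TRUE")
  }
  if (!is.null(storage) && !inherits(storage, "storage_policy")) {
    rsc_abort(pre("storage"), "must be a storage_policy")
  }
  if (!is.null(transport) && !inherits(transport, "transport_policy")) {
    rsc_abort(pre("transport"), "must be a transport_policy")
  }
  if (level == 0L && !is.null(transport)) {
    rsc_abort(pre("transport"),
              "level-0 tier has no inbound transport (it is the source)")
  }
  if (!is.null(management) && !inherits(management, "management_policy")) {
    rsc_abort(pre("management"), "must be a management_policy")
  }
  structure(
    list(name = name, level = level, n_service_points = n_service_points,
         holds_inventory = holds_inventory, storage = storage,
         transport = transport, management = management),
    class = "tier_spec"
  )
}

#' Assemble and validate a supply chain scenario
#'
#' A scenario is the full model input: an ordered list of tiers with their
#' policies, the region geometry, a demand specification, unit cost rates,
#' and an optional campaign throughput buffer. Construction validates all
#' cross-references (contiguous levels, a single top tier, vehicles and
#' roles resolvable, loop sizes feasible).
#'
#' @param name Scenario identifier.
#' @param region A [region_geometry()].
#' @param tiers List of [tier_spec()] objects (any order; sorted by level).
#' @param demand A [demand_spec()].
#' @param rates A [cost_rates()].
#' @param geometry A [geometry_model()]; defaults suit a square service
#'   area with a central hub.
#' @param throughput_buffer Optional buffer from [set_throughput_buffer()]:
#'   list with `multiplier` (>= 1) and `months_per_year` (0--12).
#' @param workday_hours Hours per working day used to convert trip hours to
#'   per-diem days (default 8).
#' @return A `supply_chain_scenario` object.
#' @export
supply_chain_scenario <- function(name, region, tiers, demand, rates,
                                  geometry = geometry_model(),
                                  throughput_buffer = NULL,
                                  workday_hours = 8) {
  assert_string(name, "name")
  if (!inherits(region, "region_geometry")) {
    rsc_abort("region", "must be a region_geometry")
  }
  if (!inherits(demand, "demand_spec")) {
    rsc_abort("demand", "must be a demand_spec")
  }
  if (!inherits(rates, "cost_rates")) {
    rsc_abort("rates", "must be a cost_rates")
  }
  if (!inherits(geometry, "geometry_model")) {
    rsc_abort("geometry", "must be a geometry_model")
  }
  assert_number(workday_hours, "workday_hours", min = 0, strict_min = TRUE)
  if (!is.list(tiers) || length(tiers) < 1L ||
      !all(vapply(tiers, inherits, logical(1), "tier_spec"))) {
    rsc_abort("tiers", "must be a non-empty list of tier_spec objects")
  }
  tiers <- tiers[order(vapply(tiers, `[[`, integer(1), "level"))]
  levels <- vapply(tiers, `[[`, integer(1), "level")
  names(tiers) <- vapply(tiers, `[[`, character(1), "name")
  if (anyDuplicated(names(tiers))) {
    rsc_abort("tiers", "tier names must be unique")
  }
  if (!identical(levels, seq_along(levels) - 1L)) {
    rsc_abort("tiers", "levels must be contiguous integers starting at 0 (got %s)",
              paste(levels, collapse = ", "))
  }
  n_pts <- vapply(tiers, `[[`, integer(1), "n_service_points")
  if (is.unsorted(n_pts)) {
    warn(sprintf(
      "scenario \"%s\": n_service_points is not non-decreasing with level (%s)",
      name, paste(n_pts, collapse = ", ")))
  }
  for (i in seq_along(tiers)) {
    t <- tiers[[i]]
    if (t$level > 0L) {
      if (is.null(t$transport)) {
        rsc_abort(paste0("tiers.", t$name, ".transport"),
                  "is required for every tier below level 0")
      }
      if (!t$transport$vehicle %in% names(rates$vehicles)) {
        rsc_abort(paste0("tiers.", t$name, ".transport.vehicle"),
                  "references unknown vehicle \"%s\" (available: %s)",
                  t$transport$vehicle,
                  paste(names(rates$vehicles), collapse = ", "))
      }
      if (t$transport$stops_per_loop > t$n_service_points) {
        rsc_abort(paste0("tiers.", t$name, ".transport.stops_per_loop"),
                  "(%d) exceeds the tier's n_service_points (%d)",
                  t$transport$stops_per_loop, t$n_service_points)
      }
    }
    if (!is.null(t$management)) {
      missing_roles <- setdiff(names(t$management$fte_by_role),
                               names(rates$salary_usd_year_by_role))
      if (length(missing_roles) > 0) {
        rsc_abort(paste0("tiers.", t$name, ".management.fte_by_role"),
                  "role(s) %s missing from rates.salaries",
                  paste(sprintf('"%s"', missing_roles), collapse = ", "))
      }
    }
  }
  buffer <- validate_buffer(throughput_buffer)
  structure(
    list(name = name, region = region, tiers = tiers, demand = demand,
         rates = rates, geometry = geometry, throughput_buffer = buffer,
         workday_hours = workday_hours),
    class = "supply_chain_scenario"
  )
}

validate_buffer <- function(buffer) {
  if (is.null(buffer)) return(NULL)
  assert_number(buffer$multiplier, "throughput_buffer.multiplier", min = 1)
  months <- assert_count(buffer$months_per_year,
                         "throughput_buffer.months_per_year",
                         min = 0L)
  if (months > 12L) {
    rsc_abort("throughput_buffer.months_per_year", "must be at most 12")
  }
  list(multiplier = buffer$multiplier, months_per_year = months)
}

# Demand multipliers implied by the throughput buffer: `capacity` applies to
# capacity-sizing quantities (peak stock, trips, fleet); `flow` is the
# blended annual multiplier for flow-proportional quantities (km, fuel,
# per-diem).
buffer_factors <- function(s) {
  b <- s$throughput_buffer
  if (is.null(b)) return(list(capacity = 1, flow = 1))
  list(
    capacity = b$multiplier,
    flow = 1 + (b$multiplier - 1) * b$months_per_year / 12
  )
}

tier_names <- function(s) names(s$tiers)

get_tier <- function(s, tier) {
  if (!tier %in% names(s$tiers)) {
    rsc_abort("tier", "unknown tier \"%s\" (tiers: %s)", tier,
              paste(names(s$tiers), collapse = ", "))
  }
  s$tiers[[tier]]
}

supplying_tier <- function(s, tier) {
  t <- get_tier(s, tier)
  if (t$level == 0L) return(NULL)
  s$tiers[[t$level]]  # list is level-ordered: index = level
}

bottom_tier <- function(s) s$tiers[[length(s$tiers)]]

#' @export
print.supply_chain_scenario <- function(x, ...) {
  cat(sprintf("<supply_chain_scenario> %s\n", x$name))
  cat(sprintf("  region: %s km2, circuity %.2f\n",
              format(x$region$land_area_km2, big.mark = ","),
              x$region$circuity_factor))
  for (t in x$tiers) {
    cat(sprintf("  [%d] %-14s n=%-6d %s%s\n", t$level, t$name,
                t$n_service_points,
                if (t$holds_inventory) "stocked" else "pass-through",
                if (!is.null(t$transport))
                  sprintf(", inbound %s by %s", t$transport$distribution_model,
                          t$transport$vehicle)
                else ""))
  }
  if (!is.null(x$throughput_buffer)) {
    cat(sprintf("  buffer: x%.2f for %d month(s)/yr\n",
                x$throughput_buffer$multiplier,
                x$throughput_buffer$months_per_year))
  }
  invisible(x)
}

# ---- scenario transforms ----------------------------------------------------
# All transforms are pure: they return a new scenario and never mutate the
# input.

#' Bypass a tier (level skipping)
#'
#' Produces the redesign in which a middle tier is removed and the tier
#' above it delivers directly to the tier below (e.g. a national warehouse
#' delivering straight to municipalities past the province level). Levels
#' are re-indexed to stay contiguous. The re-linked tier keeps its inbound
#' transport policy unless `transport_override` is supplied.
#'
#' @param s A [supply_chain_scenario()].
#' @param skipped_tier Name of the tier to bypass; must be neither the top
#'   (level 0) nor the bottom tier.
#' @param transport_override Optional [transport_policy()] for the
#'   re-linked tier below the skipped one.
#' @return A new `supply_chain_scenario`; the input is unmodified.
#' @export
apply_level_skip <- function(s, skipped_tier, transport_override = NULL) {
  t <- get_tier(s, skipped_tier)
  if (t$level == 0L) {
    rsc_abort("skipped_tier", "cannot skip the top (level-0) tier")
  }
  if (t$level == bottom_tier(s)$level) {
    rsc_abort("skipped_tier", "cannot skip the bottom tier")
  }
  tiers <- s$tiers[names(s$tiers) != skipped_tier]
  below <- which(vapply(tiers, `[[`, integer(1), "level") > t$level)[1]
  if (!is.null(transport_override)) {
    if (!inherits(transport_override, "transport_policy")) {
      rsc_abort("transport_override", "must be a transport_policy")
    }
    tiers[[below]]$transport <- transport_override
  }
  for (i in seq_along(tiers)) tiers[[i]]$level <- i - 1L
  supply_chain_scenario(
    name = s$name, region = s$region, tiers = unname(tiers),
    demand = s$demand, rates = s$rates, geometry = s$geometry,
    throughput_buffer = s$throughput_buffer, workday_hours = s$workday_hours
  )
}

#' Change a tier's replenishment interval
#'
#' Models redesigns such as moving a tier from monthly to two-monthly
#' resupply cycles. Only the named tier's interval changes; shipment
#' frequency on its inbound link becomes `12 / months` per year.
#'
#' @inheritParams apply_level_skip
#' @param tier Tier name (not the level-0 tier).
#' @param months New replenishment interval in months (> 0).
#' @return A new `supply_chain_scenario`.
#' @export
set_replenishment_interval <- function(s, tier, months) {
  t <- get_tier(s, tier)
  assert_number(months, "months", min = 0, strict_min = TRUE)
  if (t$level == 0L) {
    rsc_abort("tier", "level-0 interval is part of its own storage policy; %s",
              "pass that tier's name only for tiers below level 0")
  }
  s$tiers[[tier]]$storage$replenishment_interval_months <-
    as.numeric(months)
  s
}

#' Add a campaign throughput buffer
#'
#' Periodic campaigns (e.g. supplemental immunization activities) raise
#' throughput by a known factor during some months of the year. Capacity
#' must be sized for the spike, while annual flows only grow by the
#' time-weighted blend. Downstream of this transform, capacity-sizing
#' quantities (peak stock, trips per shipment, fleet size) use
#' `demand * multiplier`, and annual flow-proportional quantities (km,
#' fuel, per-diem) use `demand * (1 + (multiplier - 1) * months_per_year / 12)`.
#'
#' @inheritParams apply_level_skip
#' @param multiplier Throughput multiplier during campaign months (>= 1).
#' @param months_per_year Number of campaign months per year (0--12).
#' @return A new `supply_chain_scenario`.
#' @export
set_throughput_buffer <- function(s, multiplier, months_per_year) {
  s$throughput_buffer <- validate_buffer(
    list(multiplier = multiplier, months_per_year = months_per_year))
  s
}
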