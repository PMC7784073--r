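#' Shipments per year for a replenishment interval
#'
#' @param interval_months Replenishment interval, months (> 0).
#' @return `12 / interval_months`.
#' @export
shipments_per_year <- function(interval_months) {
  assert_number(interval_months, "interval_months", min = 0, strict_min = TRUE)
  12 / interval_months
}

#' Peak (post-delivery) stock at a site
#'
#' Max-stock convention: immediately after a delivery a site holds one
#' replenishment cycle of demand plus its safety stock, and capacity must
#' exist for that peak year-round.
#'
#' @param monthly_demand_m3 Monthly throughput of the site, m^3.
#' @param p A [storage_policy()].
#' @param buffer_multiplier Capacity-sizing demand multiplier (>= 1), from
#'   the scenario's throughput buffer.
#' @return Peak stock, m^3: `monthly_demand * buffer *
#'   (replenishment_interval + safety_stock_months)`.
#' @export
#' @examples
#' peak_stock_m3(2, storage_policy(1, safety_stock_months = 2))  # 6
peak_stock_m3 <- function(monthly_demand_m3, p, buffer_multiplier = 1) {
  assert_number(monthly_demand_m3, "monthly_demand_m3", min = 0)
  if (!inherits(p, "storage_policy")) rsc_abort("p", "must be a storage_policy")
  assert_number(buffer_multiplier, "buffer_multiplier", min = 1)
  monthly_demand_m3 * buffer_multiplier *
    (p$replenishment_interval_months + p$safety_stock_months)
}

#' Vehicle trips needed per shipment
#'
#' @param shipment_volume_m3 Volume of one shipment, m^3.
#' @param v A [vehicle_spec()] (or a number, taken as cargo capacity m^3).
#' @param max_load_factor Usable fraction of capacity, in (0, 1\].
#' @param buffer_multiplier Capacity-sizing demand multiplier (>= 1).
#' @return Integer trips: `ceiling(volume * buffer / (capacity * load))`;
#'   0 for zero volume.
#' @export
trips_per_shipment <- function(shipment_volume_m3, v, max_load_factor = 1,
                               buffer_multiplier = 1) {
  assert_number(shipment_volume_m3, "shipment_volume_m3", min = 0)
  capacity <- if (inherits(v, "vehicle_spec")) v$cargo_capacity_m3 else v
  assert_number(capacity, "cargo_capacity_m3", min = 0)
  assert_number(max_load_factor, "max_load_factor", min = 0, max = 1,
                strict_min = TRUE)
  assert_number(buffer_multiplier, "buffer_multiplier", min = 1)
  if (shipment_volume_m3 == 0) return(0L)
  effective <- capacity * max_load_factor
  if (effective <= 0) rsc_abort("cargo_capacity_m3", "effective capacity is 0")
  as.integer(ceiling(shipment_volume_m3 * buffer_multiplier / effective))
}

cost_item <- function(tier, category, label, annual_cost_usd) {
  tibble::tibble(tier = tier, category = category, label = label,
                 annual_cost_usd = annual_cost_usd)
}

empty_items <- function() {
  tibble::tibble(tier = character(), category = character(),
                 label = character(), annual_cost_usd = numeric())
}

#' Annual storage cost lines for a tier
#'
#' Storage is charged on the peak stock the tier must be able to hold
#' (required capacity), split into cold-chain and dry volume at the
#' tier's `cold_fraction` and priced at the respective per-m^3-year rates.
#' Costing required rather than owned capacity means a scenario's storage
#' cost already reflects the "true" cost of closing any capacity
#' shortage. Pass-through tiers contribute no storage lines.
#'
#' @param s A [supply_chain_scenario()].
#' @param tier Tier name.
#' @return A tibble of cost line items (tier, category, label,
#'   annual_cost_usd); empty for a non-stocking tier.
#' @export
storage_cost_tier <- function(s, tier) {
  t <- get_tier(s, tier)
  if (!t$holds_inventory) return(empty_items())
  bf <- buffer_factors(s)
  peak <- peak_stock_m3(monthly_demand_m3_per_facility(s, tier), t$storage,
                        bf$capacity)
  n <- t$n_service_points
  cold <- peak * t$storage$cold_fraction * n *
    s$rates$cold_storage_usd_per_m3_year
  dry <- peak * (1 - t$storage$cold_fraction) * n *
    s$rates$dry_storage_usd_per_m3_year
  dplyr::bind_rows(
    cost_item(tier, "storage", "cold storage", cold),
    cost_item(tier, "storage", "dry storage", dry)
  )
}

#' Annual management cost lines for a tier
#'
#' Staffing (FTE by role at the salary table's rates) plus technology cost,
#' per typical site, scaled by the tier's facility count. Management effort
#' is modelled as per-site constant, independent of shipment frequency.
#'
#' @inheritParams storage_cost_tier
#' @return A tibble of cost line items; empty when the tier has no
#'   management policy.
#' @export
management_cost_tier <- function(s, tier) {
  t <- get_tier(s, tier)
  m <- t$management
  if (is.null(m)) return(empty_items())
  salaries <- s$rates$salary_usd_year_by_role
  missing_roles <- setdiff(names(m$fte_by_role), names(salaries))
  if (length(missing_roles) > 0) {
    rsc_abort(paste0("tiers.", tier, ".management"),
              "role(s) %s missing from rates.salaries",
              paste(sprintf('"%s"', missing_roles), collapse = ", "))
  }
  staff <- if (length(m$fte_by_role) == 0) 0 else
    sum(m$fte_by_role * salaries[names(m$fte_by_role)])
  n <- t$n_service_points
  dplyr::bind_rows(
    cost_item(tier, "management", "salaries", staff * n),
    cost_item(tier, "management", "technology",
              m$technology_cost_per_site_year * n)
  )
}

# Full transport computation for the inbound link of `receiving_tier`.
# Returns cost lines plus the link statistics needed for utilization
# reporting. `utilized_assets` switches fleet costing to fractional
# vehicles (no ceiling), eliminating idle capacity.
transport_link <- function(s, receiving_tier, utilized_assets = FALSE) {
  r <- get_tier(s, receiving_tier)
  if (is.null(r$transport)) {
    rsc_abort(paste0("tiers.", receiving_tier, ".transport"),
              "tier has no inbound transport link")
  }
  sup <- supplying_tier(s, receiving_tier)
  tp <- r$transport
  v <- s$rates$vehicles[[tp$vehicle]]
  bf <- buffer_factors(s)
  geom <- round_trip_distance_km(
    tp$distribution_model, s$region$land_area_km2,
    sup$n_service_points, r$n_service_points,
    stops_per_loop = tp$stops_per_loop,
    g = s$geometry, circuity_factor = s$region$circuity_factor
  )

  interval <- r$storage$replenishment_interval_months
  freq <- shipments_per_year(interval)
  # volume moved per route per shipment cycle, before buffers
  d_fac <- monthly_demand_m3_per_facility(s, receiving_tier)
  route_volume <- d_fac * interval * geom$stops_per_route

  trips_flow <- trips_per_shipment(route_volume, v, tp$max_load_factor,
                                   bf$flow)
  trips_cap <- trips_per_shipment(route_volume, v, tp$max_load_factor,
                                  bf$capacity)

  hours_per_trip <- geom$route_km / v$speed_kmh +
    geom$stops_per_route * tp$service_time_hours_per_stop
  days_per_trip <- ceiling(hours_per_trip / s$workday_hours)

  trips_year_flow <- geom$routes_per_cycle * trips_flow * freq
  trips_year_cap <- geom$routes_per_cycle * trips_cap * freq
  km_year <- geom$route_km * trips_year_flow
  hours_year_flow <- trips_year_flow * hours_per_trip
  hours_year_cap <- trips_year_cap * hours_per_trip

  # fleet is held at each supplying hub: at least one vehicle per hub,
  # sized against the buffered (capacity) workload
  n_hubs <- sup$n_service_points
  hours_per_hub <- hours_year_cap / n_hubs
  if (utilized_assets) {
    vehicles_required <- hours_year_cap / v$available_hours_year
    vehicle_utilization <- if (vehicles_required > 0) 1 else 0
  } else {
    vehicles_required <- n_hubs *
      max(1, ceiling(hours_per_hub / v$available_hours_year))
    vehicle_utilization <- hours_year_cap /
      (vehicles_required * v$available_hours_year)
  }

  owner <- if (tp$operator == "supplying_tier") sup$name else r$name
  fixed_annualized <- v$purchase_price_usd / v$service_life_years
  items <- dplyr::bind_rows(
    cost_item(owner, "transportation", "fuel",
              km_year * v$fuel_l_per_km * s$rates$fuel_price_usd_per_l),
    cost_item(owner, "transportation", "maintenance",
              km_year * v$maintenance_usd_per_km),
    cost_item(owner, "transportation", "per diem",
              trips_year_flow * days_per_trip * v$per_diem_usd_per_trip_day),
    cost_item(owner, "transportation", "vehicle depreciation",
              vehicles_required * fixed_annualized),
    cost_item(owner, "transportation", "vehicle insurance",
              vehicles_required * v$insurance_usd_year)
  )
  list(
    items = items,
    stats = list(
      receiving_tier = r$name,
      operator_tier = owner,
      vehicle = v$name,
      route_km = geom$route_km,
      routes_per_cycle = geom$routes_per_cycle,
      trips_per_shipment = trips_flow,
      shipments_per_year = freq,
      km_per_year = km_year,
      trip_hours_per_year = hours_year_flow,
      vehicles_required = vehicles_required,
      vehicle_utilization = vehicle_utilization,
      m3_delivered_per_facility_year = d_fac * 12 * bf$flow
    )
  )
}

#' Annual transport cost lines for a tier's inbound link
#'
#' Distances come from the continuous-approximation geometry; annual
#' kilometres are route distance times trips per shipment times shipments
#' per year times routes per cycle. Variable lines are fuel, maintenance
#' and driver per-diem (one per-diem day per started block of
#' `workday_hours` trip hours); fixed lines are straight-line vehicle
#' depreciation and insurance for the fleet. The fleet is sized per
#' supplying hub against the buffered workload (at least one vehicle per
#' hub); flow-proportional lines use the blended annual demand. All lines
#' are assigned to the tier operating the transport (`operator`).
#'
#' @inheritParams storage_cost_tier
#' @param tier Receiving tier name (must have an inbound transport policy).
#' @return A tibble of cost line items. Link statistics are available via
#'   [evaluate_scenario()]'s utilization report.
#' @export
transport_cost_link <- function(s, tier) {
  transport_link(s, tier)$items
}

#' Evaluate a scenario
#'
#' Runs the full typical-facility cost model: storage, transport and
#' management lines for every tier and link, a utilization report, and
#' operational statistics. Deterministic: identical inputs give identical
#' output.
#'
#' @param s A [supply_chain_scenario()].
#' @param utilized_assets If `TRUE`, fleets are costed as fractional
#'   vehicles (annual trip-hours over available hours, no ceiling),
#'   eliminating idle capacity -- the convention of reference analyses
#'   that track only actively used assets. Default `FALSE` costs whole
#'   owned vehicles.
#' @return A `scenario_result`: list with `name`, `costs` (tibble: tier,
#'   category, label, annual_cost_usd), `utilization` (tibble per tier),
#'   and the evaluated `scenario`.
#' @export
evaluate_scenario <- function(s, utilized_assets = FALSE) {
  if (!inherits(s, "supply_chain_scenario")) {
    rsc_abort("s", "must be a supply_chain_scenario")
  }
  bf <- buffer_factors(s)
  links <- list()
  items <- list()
  for (t in s$tiers) {
    items <- c(items, list(storage_cost_tier(s, t$name),
                           management_cost_tier(s, t$name)))
    if (t$level > 0L) {
      link <- transport_link(s, t$name, utilized_assets = utilized_assets)
      items <- c(items, list(link$items))
      links[[t$name]] <- link$stats
    }
  }
  costs <- dplyr::bind_rows(items)
  # canonical ordering: tier level, then category, then label
  lvl <- stats::setNames(vapply(s$tiers, `[[`, integer(1), "level"),
                         names(s$tiers))
  costs <- costs[order(lvl[costs$tier],
                       match(costs$category,
                             c("storage", "transportation", "management")),
                       costs$label), ]

  util <- lapply(s$tiers, function(t) {
    peak <- if (t$holds_inventory) {
      peak_stock_m3(monthly_demand_m3_per_facility(s, t$name), t$storage,
                    bf$capacity)
    } else 0
    cap <- if (t$holds_inventory) t$storage$available_capacity_m3 else NULL
    # transport stats of the links this tier operates
    op <- Filter(function(l) l$operator_tier == t$name, links)
    inbound <- links[[t$name]]
    tibble::tibble(
      tier = t$name,
      level = t$level,
      n_service_points = t$n_service_points,
      peak_stock_m3_per_site = peak,
      cold_capacity_required_m3 = peak *
        (if (t$holds_inventory) t$storage$cold_fraction else 0) *
        t$n_service_points,
      storage_utilization = if (!is.null(cap) && cap > 0) peak / cap
                            else NA_real_,
      km_per_year = sum(vapply(op, `[[`, numeric(1), "km_per_year")),
      vehicles_required = sum(vapply(op, `[[`, numeric(1),
                                     "vehicles_required")),
      vehicle_utilization = if (length(op) > 0) {
        hrs <- vapply(op, function(l) l$vehicle_utilization *
                        l$vehicles_required, numeric(1))
        veh <- vapply(op, `[[`, numeric(1), "vehicles_required")
        if (sum(veh) > 0) sum(hrs) / sum(veh) else 0
      } else NA_real_,
      m3_delivered_per_facility_year = if (!is.null(inbound)) {
        inbound$m3_delivered_per_facility_year
      } else NA_real_
    )
  })
  util <- dplyr::bind_rows(util)

  structure(
    list(name = s$name, costs = costs, utilization = util,
         link_stats = links, scenario = s,
         utilized_assets = utilized_assets),
    class = "scenario_result"
  )
}

#' Cost totals at any grouping
#'
#' @param x A `scenario_result` or a cost-items tibble.
#' @param by One of `"overall"`, `"tier"`, `"category"`,
#'   `"tier_category"`.
#' @return For `"overall"` a single number; otherwise a tibble of totals.
#' @export
cost_totals <- function(x, by = c("overall", "tier", "category",
                                  "tier_category")) {
  by <- match.arg(by)
  items <- if (inherits(x, "scenario_result")) x$costs else x
  switch(by,
    overall = sum(items$annual_cost_usd),
    tier = dplyr::summarise(dplyr::group_by(items, .data$tier),
                            annual_cost_usd = sum(.data$annual_cost_usd),
                            .groups = "drop"),
    category = dplyr::summarise(dplyr::group_by(items, .data$category),
                                annual_cost_usd = sum(.data$annual_cost_usd),
                                .groups = "drop"),
    tier_category = dplyr::summarise(
      dplyr::group_by(items, .data$tier, .data$category),
      annual_cost_usd = sum(.data$annual_cost_usd), .groups = "drop")
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$name))
  cat(sprintf("  total annual operating cost: $%s\n",
              format(round(cost_totals(x)), big.mark = ",",
                     scientific = FALSE)))
  bycat <- cost_totals(x, "category")
  for (i in seq_len(nrow(bycat))) {
    cat(sprintf("    %-15s $%s\n", bycat$category[i],
                format(round(bycat$annual_cost_usd[i]), big.mark = ",",
                       scientific = FALSE)))
  }
  cat(sprintf("  %d cost lines over %d tiers\n", nrow(x$costs),
              nrow(x$utilization)))
  invisible(x)
}

#' Export a result as tidy CSV files
#'
#' Writes `<name>_costs.csv` (tier, category, label, annual_cost_usd) and
#' `<name>_utilization.csv` into `dir`. The costs file round-trips into
#' [read_reference_analysis()] for self-validation.
#'
#' @param result A `scenario_result`.
#' @param dir Output directory (created if needed).
#' @param name Basename stem; defaults to the scenario name.
#' @return Invisibly, the two file paths.
#' @export
export_result_csv <- function(result, dir, name = result$name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  safe <- gsub("[^A-Za-z0-9_.-]", "_", name)
  costs_path <- file.path(dir, paste0(safe, "_costs.csv"))
  util_path <- file.path(dir, paste0(safe, "_utilization.csv"))
  utils::write.csv(result$costs, costs_path, row.names = FALSE)
  utils::write.csv(result$utilization, util_path, row.names = FALSE)
  invisible(c(costs = costs_path, utilization = util_path))
}
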