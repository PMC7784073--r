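# Synthetic facility-level networks and a brute-force costing oracle.
# The typical-facility model replaces per-facility demand and distance
# with tier averages; these generators build explicit networks so the
# error introduced by that approximation can be measured directly.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic facility-level network
#'
#' Places `n_facilities` in a square region with a central hub and draws
#' per-facility monthly demand from a log-normal distribution
#' parameterized by mean and coefficient of variation (`demand_cv = 0`
#' degenerates to equal demands). `clustering` pulls facilities toward the
#' hub: 0 is uniform placement, 1 puts all mass at the hub. Deterministic
#' for a given seed; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_facilities Number of facilities (>= 1).
#' @param region_area_km2 Region area; the region is the square of side
#'   `sqrt(region_area_km2)`.
#' @param demand_mean_m3 Mean monthly demand per facility, m^3.
#' @param demand_cv Coefficient of variation of demand (>= 0).
#' @param clustering Spatial concentration toward the hub, in \[0, 1\].
#' @return A `synthetic_network`: list with `seed`, `side_km`, `hub`
#'   (tibble: id, x_km, y_km) and `facilities` (tibble: id, x_km, y_km,
#'   monthly_demand_m3).
#' @export
generate_network <- function(seed, n_facilities, region_area_km2,
                             demand_mean_m3, demand_cv = 0, clustering = 0) {
  seed <- assert_count(seed, "seed")
  n_facilities <- assert_count(n_facilities, "n_facilities", min = 1L)
  assert_number(region_area_km2, "region_area_km2", min = 0,
                strict_min = TRUE)
  assert_number(demand_mean_m3, "demand_mean_m3", min = 0, strict_min = TRUE)
  assert_number(demand_cv, "demand_cv", min = 0)
  assert_number(clustering, "clustering", min = 0, max = 1)
  side <- sqrt(region_area_km2)
  centre <- side / 2
  with_seed(seed, {
    x <- runif(n_facilities, 0, side)
    y <- runif(n_facilities, 0, side)
    x <- centre + (x - centre) * (1 - clustering)
    y <- centre + (y - centre) * (1 - clustering)
    demand <- if (demand_cv == 0) {
      rep(demand_mean_m3, n_facilities)
    } else {
      sigma2 <- log(1 + demand_cv^2)
      exp(rnorm(n_facilities, log(demand_mean_m3) - sigma2 / 2,
                sqrt(sigma2)))
    }
    structure(
      list(
        seed = seed,
        side_km = side,
        hub = tibble::tibble(id = "hub", x_km = centre, y_km = centre),
        facilities = tibble::tibble(
          id = sprintf("f%04d", seq_len(n_facilities)),
          x_km = x, y_km = y, monthly_demand_m3 = demand)
      ),
      class = "synthetic_network"
    )
  })
}

#' Write a synthetic network to CSV
#'
#' @param net A [generate_network()] result.
#' @param path Output CSV path (columns id, x_km, y_km, monthly_demand_m3;
#'   the hub row has zero demand).
#' @return Invisibly, `path`.
#' @export
export_network_csv <- function(net, path) {
  rows <- dplyr::bind_rows(
    dplyr::mutate(net$hub, monthly_demand_m3 = 0),
    net$facilities
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Two-tier scenario matching a synthetic network
#'
#' Builds the typical-facility counterpart of an explicit network: a hub
#' tier (one store) supplying a facility tier, with demand given as the
#' per-facility monthly volume. Used to compare [evaluate_scenario()]
#' against [brute_force_cost()] on the same policies and rates.
#'
#' @param n_facilities Facilities at the bottom tier.
#' @param region_area_km2 Region area, km^2.
#' @param monthly_demand_m3 Monthly demand of the typical facility, m^3.
#' @param circuity_factor Road circuity multiplier.
#' @param interval_months Facility replenishment interval, months.
#' @param safety_stock_months Facility safety stock, months of demand.
#' @param hub_interval_months,hub_safety_stock_months Hub storage policy.
#' @param cold_fraction Cold-chain share of stored volume (both tiers).
#' @param distribution_model `"hub_and_spoke"` or `"multi_stop_loop"`.
#' @param stops_per_loop Facilities per loop (multi-stop only).
#' @param service_time_hours_per_stop Hours per delivery stop.
#' @param rates A [cost_rates()]; `oracle_rates()` gives a plausible
#'   default set.
#' @param name Scenario name.
#' @return A [supply_chain_scenario()].
#' @export
oracle_scenario <- function(n_facilities, region_area_km2, monthly_demand_m3,
                            circuity_factor = 1,
                            interval_months = 1, safety_stock_months = 1,
                            hub_interval_months = 3,
                            hub_safety_stock_months = 1,
                            cold_fraction = 0,
                            distribution_model = "hub_and_spoke",
                            stops_per_loop = 1,
                            service_time_hours_per_stop = 0.5,
                            rates = oracle_rates(),
                            name = "oracle") {
  supply_chain_scenario(
    name = name,
    region = region_geometry(region_area_km2,
                             circuity_factor = circuity_factor),
    tiers = list(
      tier_spec("hub", 0L, 1L, holds_inventory = TRUE,
                storage = storage_policy(hub_interval_months,
                                         hub_safety_stock_months,
                                         cold_fraction = cold_fraction),
                management = management_policy(
                  c(storekeeper = 2), technology_cost_per_site_year = 500)),
      tier_spec("facility", 1L, n_facilities, holds_inventory = TRUE,
                storage = storage_policy(interval_months,
                                         safety_stock_months,
                                         cold_fraction = cold_fraction),
                transport = transport_policy(
                  vehicle = "van",
                  distribution_model = distribution_model,
                  stops_per_loop = stops_per_loop,
                  max_load_factor = 0.9,
                  operator = "supplying_tier",
                  service_time_hours_per_stop = service_time_hours_per_stop),
                management = management_policy(
                  c(storekeeper = 0.1), technology_cost_per_site_year = 50))
    ),
    demand = demand_spec(
      monthly_demand_m3_per_facility = monthly_demand_m3),
    rates = rates
  )
}

#' Default rate card for oracle experiments
#'
#' A plausible mid-sized van plus storage and salary rates; every value is
#' an illustrative proxy, not country data.
#'
#' @return A [cost_rates()].
#' @export
oracle_rates <- function() {
  cost_rates(
    fuel_price_usd_per_l = 1.2,
    dry_storage_usd_per_m3_year = 25,
    cold_storage_usd_per_m3_year = 150,
    salary_usd_year_by_role = c(storekeeper = 4000, driver = 3000),
    vehicles = list(van = vehicle_spec(
      "van", cargo_capacity_m3 = 5, fuel_l_per_km = 0.15,
      purchase_price_usd = 30000, service_life_years = 10,
      insurance_usd_year = 500, maintenance_usd_per_km = 0.08,
      speed_kmh = 60, available_hours_year = 1800,
      per_diem_usd_per_trip_day = 10))
  )
}

euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Nearest-neighbour ordering of facilities starting from the hub.
nn_order <- function(xs, ys, x0, y0) {
  n <- length(xs)
  left <- seq_len(n)
  out <- integer(n)
  cx <- x0; cy <- y0
  for (i in seq_len(n)) {
    d <- euclid(xs[left], ys[left], cx, cy)
    j <- left[which.min(d)]
    out[i] <- j
    cx <- xs[j]; cy <- ys[j]
    left <- setdiff(left, j)
  }
  out
}

# Closed-tour length hub -> stops (in given order) -> hub.
tour_length <- function(xs, ys, x0, y0) {
  px <- c(x0, xs, x0)
  py <- c(y0, ys, y0)
  sum(euclid(px[-length(px)], py[-length(py)], px[-1], py[-1]))
}

# 2-opt improvement on a closed tour (first point fixed as depot).
two_opt <- function(px, py, max_pass = 10) {
  n <- length(px)
  if (n < 4) return(list(x = px, y = py))
  improved <- TRUE
  pass <- 0
  dist2 <- function(i, j) euclid(px[i], py[i], px[j], py[j])
  while (improved && pass < max_pass) {
    improved <- FALSE
    pass <- pass + 1
    for (i in 1:(n - 2)) {
      jj <- (i + 2):n
      jn <- ifelse(jj == n, 1, jj + 1)
      gain <- dist2(i, i + 1) + euclid(px[jj], py[jj], px[jn], py[jn]) -
        euclid(px[i], py[i], px[jj], py[jj]) -
        euclid(px[i + 1], py[i + 1], px[jn], py[jn])
      k <- which(gain > 1e-12)
      if (length(k) > 0) {
        j <- jj[k[which.max(gain[k])]]
        seg <- (i + 1):j
        px[seg] <- rev(px[seg])
        py[seg] <- rev(py[seg])
        improved <- TRUE
      }
    }
  }
  list(x = px, y = py)
}

#' Heuristic closed-tour length through a point set
#'
#' Nearest-neighbour construction from the depot followed by 2-opt
#' improvement. Used as the independent oracle for the `k_tour`
#' continuous-approximation constant.
#'
#' @param xs,ys Facility coordinates.
#' @param x0,y0 Depot coordinates.
#' @param improve Apply 2-opt improvement (default `TRUE`).
#' @return Tour length (same units as the coordinates).
#' @export
heuristic_tour_length <- function(xs, ys, x0, y0, improve = TRUE) {
  ord <- nn_order(xs, ys, x0, y0)
  px <- c(x0, xs[ord])
  py <- c(y0, ys[ord])
  if (improve) {
    opt <- two_opt(px, py)
    px <- opt$x; py <- opt$y
  }
  tour_length(px[-1], py[-1], px[1], py[1])
}

#' Brute-force facility-level cost of a synthetic network
#'
#' Applies the same cost formulas as [evaluate_scenario()] but at facility
#' resolution: each facility contributes its own demand and its exact
#' Euclidean-times-circuity distance (out-and-back under hub-and-spoke, or
#' nearest-neighbour loops of `stops_per_loop` facilities under
#' multi-stop), with no typical-facility averaging.
#'
#' @param net A [generate_network()] network.
#' @param s A two-tier [supply_chain_scenario()] (e.g. from
#'   [oracle_scenario()]) whose bottom tier has `nrow(net$facilities)`
#'   service points. Its demand spec is ignored in favour of the network's
#'   facility demands.
#' @param distance_override_km Optional: replace every hub-to-facility
#'   distance with this road distance (hub-and-spoke only). With
#'   homogeneous demands this collapses the brute-force computation onto
#'   the typical-facility arithmetic exactly.
#' @return A list: `costs` (line-item tibble, same shape as a
#'   `scenario_result`'s), `total_usd`, `km_per_year`, `vehicles_required`.
#' @export
brute_force_cost <- function(net, s, distance_override_km = NULL) {
  if (!inherits(net, "synthetic_network")) {
    rsc_abort("net", "must be a synthetic_network")
  }
  if (length(s$tiers) != 2L) {
    rsc_abort("s", "oracle scenario must have exactly 2 tiers")
  }
  fac_tier <- bottom_tier(s)
  hub_tier <- s$tiers[[1]]
  n <- nrow(net$facilities)
  if (fac_tier$n_service_points != n) {
    rsc_abort("s", "bottom tier has %d service points but network has %d",
              fac_tier$n_service_points, n)
  }
  tp <- fac_tier$transport
  v <- s$rates$vehicles[[tp$vehicle]]
  bf <- buffer_factors(s)
  circ <- s$region$circuity_factor
  demand <- net$facilities$monthly_demand_m3
  interval <- fac_tier$storage$replenishment_interval_months
  freq <- shipments_per_year(interval)

  if (tp$distribution_model == "hub_and_spoke") {
    d <- if (!is.null(distance_override_km)) {
      rep(distance_override_km, n)
    } else {
      euclid(net$facilities$x_km, net$facilities$y_km,
             net$hub$x_km, net$hub$y_km) * circ
    }
    route_km <- 2 * d
    route_vol <- demand * interval
    stops <- rep(1L, n)
  } else {
    if (!is.null(distance_override_km)) {
      rsc_abort("distance_override_km",
                "only supported for hub_and_spoke networks")
    }
    ord <- nn_order(net$facilities$x_km, net$facilities$y_km,
                    net$hub$x_km, net$hub$y_km)
    groups <- split(ord, ceiling(seq_along(ord) / tp$stops_per_loop))
    route_km <- vapply(groups, function(g) {
      heuristic_tour_length(net$facilities$x_km[g], net$facilities$y_km[g],
                            net$hub$x_km, net$hub$y_km) * circ
    }, numeric(1))
    route_vol <- vapply(groups, function(g)
      sum(demand[g]) * interval, numeric(1))
    stops <- lengths(groups)
  }

  effective <- v$cargo_capacity_m3 * tp$max_load_factor
  trips_flow <- ifelse(route_vol == 0, 0,
                       ceiling(route_vol * bf$flow / effective))
  trips_cap <- ifelse(route_vol == 0, 0,
                      ceiling(route_vol * bf$capacity / effective))
  hours_per_trip <- route_km / v$speed_kmh +
    stops * tp$service_time_hours_per_stop
  days_per_trip <- ceiling(hours_per_trip / s$workday_hours)

  km_year <- sum(route_km * trips_flow * freq)
  hours_cap <- sum(hours_per_trip * trips_cap * freq)
  vehicles_required <- max(1, ceiling(hours_cap / v$available_hours_year))
  owner <- if (tp$operator == "supplying_tier") hub_tier$name else
    fac_tier$name

  transport <- dplyr::bind_rows(
    cost_item(owner, "transportation", "fuel",
              km_year * v$fuel_l_per_km * s$rates$fuel_price_usd_per_l),
    cost_item(owner, "transportation", "maintenance",
              km_year * v$maintenance_usd_per_km),
    cost_item(owner, "transportation", "per diem",
              sum(trips_flow * freq * days_per_trip) *
                v$per_diem_usd_per_trip_day),
    cost_item(owner, "transportation", "vehicle depreciation",
              vehicles_required * v$purchase_price_usd /
                v$service_life_years),
    cost_item(owner, "transportation", "vehicle insurance",
              vehicles_required * v$insurance_usd_year)
  )

  storage_lines <- function(tier, peak_total) {
    cf <- tier$storage$cold_fraction
    dplyr::bind_rows(
      cost_item(tier$name, "storage", "cold storage",
                peak_total * cf * s$rates$cold_storage_usd_per_m3_year),
      cost_item(tier$name, "storage", "dry storage",
                peak_total * (1 - cf) * s$rates$dry_storage_usd_per_m3_year)
    )
  }
  fac_peaks <- demand * bf$capacity *
    (interval + fac_tier$storage$safety_stock_months)
  hub_peak <- sum(demand) * bf$capacity *
    (hub_tier$storage$replenishment_interval_months +
       hub_tier$storage$safety_stock_months)
  storage <- dplyr::bind_rows(
    if (hub_tier$holds_inventory) storage_lines(hub_tier, hub_peak),
    if (fac_tier$holds_inventory) storage_lines(fac_tier, sum(fac_peaks))
  )
  management <- dplyr::bind_rows(
    management_cost_tier(s, hub_tier$name),
    management_cost_tier(s, fac_tier$name)
  )
  costs <- dplyr::bind_rows(storage, transport, management)
  list(costs = costs, total_usd = sum(costs$annual_cost_usd),
       km_per_year = km_year, vehicles_required = vehicles_required)
}

#' Typical-facility vs brute-force gap on one synthetic network
#'
#' Generates a network, evaluates the matching typical-facility scenario
#' (using the realized mean facility demand as the typical demand), costs
#' the explicit network brute-force, and returns the relative gap between
#' the two totals.
#'
#' @inheritParams generate_network
#' @param ... Passed to [oracle_scenario()] (policies and rates).
#' @return A one-row tibble: seed, n_facilities, demand_cv, clustering,
#'   typical_total_usd, brute_force_total_usd, rel_gap.
#' @export
typical_vs_brute_gap <- function(seed, n_facilities, region_area_km2,
                                 demand_mean_m3, demand_cv = 0,
                                 clustering = 0, ...) {
  net <- generate_network(seed, n_facilities, region_area_km2,
                          demand_mean_m3, demand_cv, clustering)
  s <- oracle_scenario(n_facilities, region_area_km2,
                       monthly_demand_m3 = mean(net$facilities$monthly_demand_m3),
                       ...)
  typical <- cost_totals(evaluate_scenario(s))
  brute <- brute_force_cost(net, s)$total_usd
  tibble::tibble(
    seed = seed, n_facilities = n_facilities, demand_cv = demand_cv,
    clustering = clustering, typical_total_usd = typical,
    brute_force_total_usd = brute,
    rel_gap = abs(typical - brute) / brute
  )
}

#' Approximation-error sweep over network size and heterogeneity
#'
#' For every grid cell (`n_facilities` x `demand_cv` x `clustering`)
#' averages the absolute relative gap between the typical-facility model
#' and the brute-force oracle over `n_seeds` replicate networks. On
#' homogeneous uniform networks the gap shrinks as facility counts grow
#' (outliers average out), which is why small networks warrant explicit
#' facility-level modelling.
#'
#' @param n_values Vector of facility counts.
#' @param demand_cv_values,clustering_values Heterogeneity grids.
#' @param n_seeds Replicate networks per cell (>= 1).
#' @param base_seed Seeds used are `base_seed + 1:n_seeds`.
#' @param region_area_km2,demand_mean_m3 Network parameters.
#' @param ... Passed to [oracle_scenario()].
#' @return A tibble: n_facilities, demand_cv, clustering, n_seeds,
#'   mean_abs_rel_gap.
#' @export
approximation_error_sweep <- function(n_values,
                                      demand_cv_values = 0,
                                      clustering_values = 0,
                                      n_seeds = 20,
                                      base_seed = 100,
                                      region_area_km2 = 10000,
                                      demand_mean_m3 = 0.4, ...) {
  if (length(n_values) < 1L) rsc_abort("n_values", "must be non-empty")
  n_seeds <- assert_count(n_seeds, "n_seeds", min = 1L)
  grid <- expand.grid(n_facilities = n_values, demand_cv = demand_cv_values,
                      clustering = clustering_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gaps <- vapply(seq_len(n_seeds), function(k) {
      typical_vs_brute_gap(base_seed + k, grid$n_facilities[i],
                           region_area_km2, demand_mean_m3,
                           grid$demand_cv[i], grid$clustering[i],
                           ...)$rel_gap
    }, numeric(1))
    tibble::tibble(
      n_facilities = grid$n_facilities[i],
      demand_cv = grid$demand_cv[i],
      clustering = grid$clustering[i],
      n_seeds = n_seeds,
      mean_abs_rel_gap = mean(gaps)
    )
  })
  dplyr::bind_rows(rows)
}
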