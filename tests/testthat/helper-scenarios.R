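# Shared fixtures, all built in code.

# Homogeneous two-tier toy: 1 hub supplying 10 facilities, chosen so every
# quantity is hand-computable (1 trip per shipment, 1 per-diem day).
toy_rates <- function(fuel_price = 1, dry = 20, cold = 200,
                      storekeeper = 6000) {
  cost_rates(
    fuel_price_usd_per_l = fuel_price,
    dry_storage_usd_per_m3_year = dry,
    cold_storage_usd_per_m3_year = cold,
    salary_usd_year_by_role = c(storekeeper = storekeeper),
    vehicles = list(van = vehicle_spec(
      "van", cargo_capacity_m3 = 4, fuel_l_per_km = 0.12,
      purchase_price_usd = 30000, service_life_years = 10,
      insurance_usd_year = 500, maintenance_usd_per_km = 0.05,
      speed_kmh = 50, available_hours_year = 1000,
      per_diem_usd_per_trip_day = 10))
  )
}

toy_two_tier <- function(monthly_demand = 0.5, n_facilities = 10,
                         region_area = 400, circuity = 1,
                         interval = 1, safety = 2,
                         rates = toy_rates(), name = "toy") {
  supply_chain_scenario(
    name = name,
    region = region_geometry(region_area, circuity_factor = circuity),
    tiers = list(
      tier_spec("hub", 0L, 1L,
                storage = storage_policy(3, 1, cold_fraction = 0.5)),
      tier_spec("facility", 1L, n_facilities,
                storage = storage_policy(interval, safety,
                                         cold_fraction = 0.5),
                transport = transport_policy(
                  "van", "hub_and_spoke", max_load_factor = 1,
                  operator = "supplying_tier",
                  service_time_hours_per_stop = 0),
                management = management_policy(
                  c(storekeeper = 0.2),
                  technology_cost_per_site_year = 300))
    ),
    demand = demand_spec(monthly_demand_m3_per_facility = monthly_demand),
    rates = rates
  )
}

# Four-tier scenario mirroring a national immunization network, small
# enough to evaluate instantly.
four_tier <- function(name = "baseline") {
  load_scenario(template = "immunization_4tier",
                overrides = list(name = name))
}

# Randomized but always-valid scenario for property tests.
random_scenario <- function(seed) {
  set.seed(seed)
  n_tiers <- sample(2:4, 1)
  n_pts <- sort(sample(1:40, n_tiers)) * c(1, sample(1:5, n_tiers - 1,
                                                     replace = TRUE))
  n_pts <- cummax(n_pts)
  veh <- vehicle_spec("v", cargo_capacity_m3 = runif(1, 2, 30),
                      fuel_l_per_km = runif(1, 0.05, 0.4),
                      purchase_price_usd = runif(1, 1e4, 1e5),
                      service_life_years = sample(5:12, 1),
                      insurance_usd_year = runif(1, 0, 3000),
                      maintenance_usd_per_km = runif(1, 0, 0.3),
                      speed_kmh = runif(1, 30, 80),
                      available_hours_year = runif(1, 800, 2500),
                      per_diem_usd_per_trip_day = runif(1, 0, 40))
  rates <- cost_rates(
    fuel_price_usd_per_l = runif(1, 0.5, 2),
    dry_storage_usd_per_m3_year = runif(1, 5, 60),
    cold_storage_usd_per_m3_year = runif(1, 80, 400),
    salary_usd_year_by_role = c(clerk = runif(1, 2000, 20000)),
    vehicles = list(v = veh))
  tiers <- lapply(seq_len(n_tiers), function(i) {
    n <- n_pts[i]
    multi <- i > 1 && runif(1) < 0.4 && n >= 3
    tier_spec(
      paste0("t", i - 1), i - 1L, n,
      holds_inventory = i == 1 || runif(1) < 0.8,
      storage = storage_policy(sample(c(1, 2, 3), 1),
                               runif(1, 0, 3), runif(1)),
      transport = if (i > 1) transport_policy(
        "v",
        distribution_model = if (multi) "multi_stop_loop" else
          "hub_and_spoke",
        stops_per_loop = if (multi) sample(2:min(6, n), 1) else NULL,
        max_load_factor = runif(1, 0.5, 1),
        operator = sample(c("supplying_tier", "receiving_tier"), 1),
        service_time_hours_per_stop = runif(1, 0, 2)),
      management = management_policy(c(clerk = runif(1, 0, 2)),
                                     technology_cost_per_site_year =
                                       runif(1, 0, 1000)))
  })
  buffer <- if (runif(1) < 0.3) {
    list(multiplier = runif(1, 1, 1.5), months_per_year = sample(0:12, 1))
  }
  suppressWarnings(supply_chain_scenario(
    name = paste0("rand", seed),
    region = region_geometry(runif(1, 1e3, 1e6),
                             circuity_factor = runif(1, 1, 2)),
    tiers = tiers,
    demand = demand_spec(
      monthly_demand_m3_per_facility = runif(1, 0.05, 2)),
    rates = rates,
    throughput_buffer = buffer
  ))
}
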