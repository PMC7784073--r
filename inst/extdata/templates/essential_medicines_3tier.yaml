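schema_version: 1
name: essential_medicines_3tier
notes: >
  Generic 3-tier essential-medicines network (central medical store,
  district store, health facility) with facility collection at the last
  mile. Demand uses the direct volume override (medicines are bulkier and
  mostly ambient). Illustrative proxy values only.
region:
  land_area_km2: 600000
  circuity_factor: 1.4
workday_hours: 8
demand:
  monthly_demand_m3_per_facility: 0.35
  wastage_rate: 0.05
rates:
  fuel_price_usd_per_l: 1.1
  dry_storage_usd_per_m3_year: 25
  cold_storage_usd_per_m3_year: 220
  salaries:
    logistician: 12000
    storekeeper: 5000
    driver: 4200
  vehicles:
    truck_10t:
      cargo_capacity_m3: 35
      fuel_l_per_km: 0.35
      fuel_type: diesel
      purchase_price_usd: 85000
      service_life_years: 10
      insurance_usd_year: 1800
      maintenance_usd_per_km: 0.12
      speed_kmh: 60
      available_hours_year: 2000
      per_diem_usd_per_trip_day: 22
    pickup:
      cargo_capacity_m3: 4
      fuel_l_per_km: 0.13
      fuel_type: diesel
      purchase_price_usd: 28000
      service_life_years: 8
      insurance_usd_year: 700
      maintenance_usd_per_km: 0.07
      speed_kmh: 55
      available_hours_year: 1800
      per_diem_usd_per_trip_day: 12
tiers:
  - name: central
    level: 0
    n_service_points: 1
    holds_inventory: true
    storage:
      replenishment_interval_months: 4
      safety_stock_months: 2
      cold_fraction: 0.05
      available_capacity_m3: 3000
    management:
      fte:
        logistician: 2
        storekeeper: 6
        driver: 3
      technology_cost_per_site_year: 15000
  - name: district
    level: 1
    n_service_points: 60
    holds_inventory: true
    storage:
      replenishment_interval_months: 2
      safety_stock_months: 1
      cold_fraction: 0.05
      available_capacity_m3: 60
    transport:
      vehicle: truck_10t
      distribution_model: hub_and_spoke
      max_load_factor: 0.8
      operator: supplying_tier
      service_time_hours_per_stop: 1.0
    management:
      fte:
        storekeeper: 1
        driver: 0.5
      technology_cost_per_site_year: 800
  - name: health_facility
    level: 2
    n_service_points: 450
    holds_inventory: true
    storage:
      replenishment_interval_months: 1
      safety_stock_months: 1
      cold_fraction: 0.05
      available_capacity_m3: 6
    transport:
      vehicle: pickup
      distribution_model: hub_and_spoke
      max_load_factor: 0.9
      operator: receiving_tier
      service_time_hours_per_stop: 0.5
    management:
      fte:
        storekeeper: 0.1
      technology_cost_per_site_year: 60
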