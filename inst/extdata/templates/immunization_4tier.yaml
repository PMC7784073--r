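schema_version: 1
name: immunization_4tier
notes: >
  Generic 4-tier national immunization supply chain (national, province,
  municipality, health facility) with monthly resupply at the lower tiers
  and 1,321 health facilities. Every value is an illustrative proxy
  assembled from public demographic and logistics planning figures
  (2019-era), not measured country data. Override any field with better
  local data.
region:
  land_area_km2: 1246700
  circuity_factor: 1.5
workday_hours: 8
demand:
  population: 31000000
  target_fraction: 0.04
  doses_per_course: 20
  coverage: 0.85
  wastage_rate: 0.25
  unit_volume_cm3: 18
  packaging_factor: 1.2
  price_per_dose: 1.5
rates:
  fuel_price_usd_per_l: 1.0
  dry_storage_usd_per_m3_year: 30
  cold_storage_usd_per_m3_year: 250
  salaries:
    logistician: 15000
    storekeeper: 6000
    driver: 5000
  vehicles:
    truck_10t:
      cargo_capacity_m3: 35
      fuel_l_per_km: 0.35
      fuel_type: diesel
      purchase_price_usd: 90000
      service_life_years: 10
      insurance_usd_year: 2000
      maintenance_usd_per_km: 0.12
      speed_kmh: 60
      available_hours_year: 2000
      per_diem_usd_per_trip_day: 25
    truck_4t:
      cargo_capacity_m3: 15
      fuel_l_per_km: 0.25
      fuel_type: diesel
      purchase_price_usd: 45000
      service_life_years: 8
      insurance_usd_year: 1000
      maintenance_usd_per_km: 0.10
      speed_kmh: 55
      available_hours_year: 2000
      per_diem_usd_per_trip_day: 20
    van:
      cargo_capacity_m3: 6
      fuel_l_per_km: 0.15
      fuel_type: petrol
      purchase_price_usd: 30000
      service_life_years: 8
      insurance_usd_year: 800
      maintenance_usd_per_km: 0.08
      speed_kmh: 50
      available_hours_year: 1800
      per_diem_usd_per_trip_day: 15
tiers:
  - name: national
    level: 0
    n_service_points: 1
    holds_inventory: true
    storage:
      replenishment_interval_months: 6
      safety_stock_months: 3
      cold_fraction: 0.6
      available_capacity_m3: 400
    management:
      fte:
        logistician: 3
        storekeeper: 4
        driver: 2
      technology_cost_per_site_year: 20000
  - name: province
    level: 1
    n_service_points: 18
    holds_inventory: true
    storage:
      replenishment_interval_months: 3
      safety_stock_months: 2
      cold_fraction: 0.5
      available_capacity_m3: 40
    transport:
      vehicle: truck_10t
      distribution_model: hub_and_spoke
      max_load_factor: 0.8
      operator: supplying_tier
      service_time_hours_per_stop: 1.0
    management:
      fte:
        logistician: 1
        storekeeper: 1
        driver: 1
      technology_cost_per_site_year: 2000
  - name: municipality
    level: 2
    n_service_points: 164
    holds_inventory: true
    storage:
      replenishment_interval_months: 1
      safety_stock_months: 1
      cold_fraction: 0.5
      available_capacity_m3: 5
    transport:
      vehicle: truck_4t
      distribution_model: hub_and_spoke
      max_load_factor: 0.8
      operator: supplying_tier
      service_time_hours_per_stop: 0.75
    management:
      fte:
        storekeeper: 0.5
        driver: 0.5
      technology_cost_per_site_year: 500
  - name: health_facility
    level: 3
    n_service_points: 1321
    holds_inventory: true
    storage:
      replenishment_interval_months: 1
      safety_stock_months: 0.5
      cold_fraction: 0.8
      available_capacity_m3: 0.5
    transport:
      vehicle: van
      distribution_model: multi_stop_loop
      stops_per_loop: 8
      max_load_factor: 0.9
      operator: supplying_tier
      service_time_hours_per_stop: 0.5
    management:
      fte:
        storekeeper: 0.05
      technology_cost_per_site_year: 50
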