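#' Demand specification
#'
#' Demand can be given two ways: derived from demographics (population,
#' target fraction such as the birth cohort share, doses per course,
#' coverage and wastage, plus a unit volume), or as a direct override of
#' the monthly volume handled by the typical bottom-tier facility. Demand
#' is stationary: every order period sees the same quantity.
#'
#' @param population Catchment population (> 0). Derivation field.
#' @param target_fraction Share of population targeted, in (0, 1\] (e.g.
#'   0.04 for a birth cohort).
#' @param doses_per_course Doses per fully immunized/treated person (>= 1).
#' @param coverage Expected programme coverage, in (0, 1\].
#' @param wastage_rate Fraction of supplied stock wasted, in \[0, 1). Doses
#'   supplied are inflated by `1 / (1 - wastage_rate)`.
#' @param unit_volume_cm3 Packed volume per dose, cm^3 (> 0).
#' @param packaging_factor Multiplier (>= 1) for secondary/tertiary
#'   packaging overhead.
#' @param price_per_dose Commodity price, USD per dose (for commodity value
#'   estimates; not an operating cost).
#' @param monthly_demand_m3_per_facility Direct override: m^3 handled per
#'   month by the typical bottom-tier facility, bypassing the derivation.
#' @return A `demand_spec` object.
#' @export
#' @examples
#' # derivation route
#' demand_spec(population = 100000, target_fraction = 0.04,
#'             doses_per_course = 3, coverage = 0.9, wastage_rate = 0.25,
#'             unit_volume_cm3 = 10)
#' # direct override route
#' demand_spec(monthly_demand_m3_per_facility = 0.2)
demand_spec <- function(population = NULL, target_fraction = NULL,
                        doses_per_course = NULL, coverage = NULL,
                        wastage_rate = 0, unit_volume_cm3 = NULL,
                        packaging_factor = 1, price_per_dose = 0,
                        monthly_demand_m3_per_facility = NULL) {
  has_override <- !is.null(monthly_demand_m3_per_facility)
  derivation_fields <- list(population = population,
                            target_fraction = target_fraction,
                            doses_per_course = doses_per_course,
                            coverage = coverage,
                            unit_volume_cm3 = unit_volume_cm3)
  has_derivation <- all(!vapply(derivation_fields, is.null, logical(1)))
  if (!has_override && !has_derivation) {
    missing <- names(derivation_fields)[vapply(derivation_fields, is.null,
                                               logical(1))]
    rsc_abort("demand",
              "needs either monthly_demand_m3_per_facility or the %s %s",
              "derivation fields; missing:", paste(missing, collapse = ", "))
  }
  if (has_derivation) {
    assert_count(population, "demand.population", min = 1L)
    assert_number(target_fraction, "demand.target_fraction",
                  min = 0, max = 1, strict_min = TRUE)
    assert_count(doses_per_course, "demand.doses_per_course", min = 1L)
    assert_number(coverage, "demand.coverage", min = 0, max = 1,
                  strict_min = TRUE)
    assert_number(unit_volume_cm3, "demand.unit_volume_cm3",
                  min = 0, strict_min = TRUE)
  }
  assert_number(wastage_rate, "demand.wastage_rate", min = 0, max = 1,
                strict_max = TRUE)
  assert_number(packaging_factor, "demand.packaging_factor", min = 1)
  assert_number(price_per_dose, "demand.price_per_dose", min = 0)
  assert_number(monthly_demand_m3_per_facility,
                "demand.monthly_demand_m3_per_facility",
                min = 0, strict_min = TRUE, allow_null = TRUE)
  structure(
    list(population = population, target_fraction = target_fraction,
         doses_per_course = doses_per_course, coverage = coverage,
         wastage_rate = wastage_rate, unit_volume_cm3 = unit_volume_cm3,
         packaging_factor = packaging_factor, price_per_dose = price_per_dose,
         monthly_demand_m3_per_facility = monthly_demand_m3_per_facility,
         has_derivation = has_derivation, has_override = has_override),
    class = "demand_spec"
  )
}

#' Annual doses supplied, from demographics
#'
#' `doses = population * target_fraction * doses_per_course * coverage /
#' (1 - wastage_rate)`: wastage is treated as a fraction of supplied stock,
#' the usual convention in immunization forecasting, so supplied doses are
#' grossed up relative to administered doses.
#'
#' @param d A [demand_spec()] built through the derivation route.
#' @return Annual doses supplied (positive real).
#' @export
#' @examples
#' d <- demand_spec(population = 100000, target_fraction = 0.04,
#'                  doses_per_course = 3, coverage = 0.9,
#'                  wastage_rate = 0.25, unit_volume_cm3 = 10)
#' estimate_annual_doses(d)  # 14400
estimate_annual_doses <- function(d) {
  if (!inherits(d, "demand_spec")) rsc_abort("d", "must be a demand_spec")
  if (!d$has_derivation) {
    rsc_abort("demand", "derivation fields absent (override-only spec)")
  }
  d$population * d$target_fraction * d$doses_per_course * d$coverage /
    (1 - d$wastage_rate)
}

#' Convert doses to cubic metres
#'
#' @param doses Number of doses (>= 0).
#' @param unit_volume_cm3 Packed cm^3 per dose (>= 0).
#' @param packaging_factor Packaging overhead multiplier (>= 1).
#' @return Volume in m^3: `doses * unit_volume_cm3 * packaging_factor / 1e6`.
#' @export
doses_to_volume_m3 <- function(doses, unit_volume_cm3, packaging_factor = 1) {
  assert_number(doses, "doses", min = 0)
  assert_number(unit_volume_cm3, "unit_volume_cm3", min = 0)
  assert_number(packaging_factor, "packaging_factor", min = 1)
  doses * unit_volume_cm3 * packaging_factor / 1e6
}

#' Warehouse dimensions
#'
#' @param floor_area_m2 Floor area, m^2 (> 0).
#' @param stacking_height_m Usable stacking height, m (> 0).
#' @param utilization_fraction Fraction of gross volume usable for storage
#'   once aisles, handling space and stacking limits are accounted for, in
#'   (0, 1\]. The 0.3 default is a common commercial heuristic.
#' @return A `warehouse_dims` object.
#' @export
warehouse_dims <- function(floor_area_m2, stacking_height_m,
                           utilization_fraction = 0.3) {
  assert_number(floor_area_m2, "warehouse.floor_area_m2",
                min = 0, strict_min = TRUE)
  assert_number(stacking_height_m, "warehouse.stacking_height_m",
                min = 0, strict_min = TRUE)
  assert_number(utilization_fraction, "warehouse.utilization_fraction",
                min = 0, max = 1, strict_min = TRUE)
  structure(
    list(floor_area_m2 = floor_area_m2, stacking_height_m = stacking_height_m,
         utilization_fraction = utilization_fraction),
    class = "warehouse_dims"
  )
}

#' Usable warehouse capacity from overall dimensions
#'
#' @param w A [warehouse_dims()].
#' @return Usable capacity in m^3:
#'   `floor_area * stacking_height * utilization_fraction`.
#' @export
#' @examples
#' warehouse_capacity_m3(warehouse_dims(100, 2.5))  # 75
warehouse_capacity_m3 <- function(w) {
  if (!inherits(w, "warehouse_dims")) rsc_abort("w", "must be warehouse_dims")
  w$floor_area_m2 * w$stacking_height_m * w$utilization_fraction
}

#' Annual system volume
#'
#' Total m^3 entering the system per year (before any throughput buffer).
#' Via the derivation route this is annual doses converted to volume; via
#' the override route it is the per-facility monthly volume times the
#' number of bottom-tier facilities times 12.
#'
#' @param s A [supply_chain_scenario()].
#' @return Annual volume, m^3/year.
#' @export
annual_system_volume_m3 <- function(s) {
  d <- s$demand
  if (d$has_override) {
    return(d$monthly_demand_m3_per_facility *
             bottom_tier(s)$n_service_points * 12)
  }
  doses_to_volume_m3(estimate_annual_doses(d), d$unit_volume_cm3,
                     d$packaging_factor)
}

#' Annual commodity value
#'
#' Value of supplied commodities (doses supplied, i.e. inflated by wastage,
#' times price per dose). Informational; not part of operating cost.
#'
#' @param s A [supply_chain_scenario()].
#' @return USD per year, or `NA` when demand uses the volume override.
#' @export
annual_commodity_value_usd <- function(s) {
  d <- s$demand
  if (!d$has_derivation) return(NA_real_)
  estimate_annual_doses(d) * d$price_per_dose
}

#' Monthly throughput of the typical facility at a tier
#'
#' All facilities at a tier share the same demand per order period;
#' intermediate tiers are pass-through (no tier-level consumption above
#' the bottom tier), so a tier's throughput is the system volume divided
#' by its facility count.
#'
#' @param s A [supply_chain_scenario()].
#' @param tier Tier name.
#' @return m^3 per month handled by one typical facility at `tier`.
#' @export
monthly_demand_m3_per_facility <- function(s, tier) {
  t <- get_tier(s, tier)
  annual_system_volume_m3(s) / 12 / t$n_service_points
}
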