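# Configuration schema (version 1), shared by YAML and JSON documents:
#
#   schema_version: 1
#   name: <scenario id>
#   notes: <free text, optional>
#   region:   {land_area_km2, circuity_factor}
#   geometry: {k_nearest, k_tour}              # optional
#   workday_hours: 8                           # optional
#   demand:   derivation fields or monthly_demand_m3_per_facility
#   rates:    {fuel_price_usd_per_l, dry_storage_usd_per_m3_year,
#              cold_storage_usd_per_m3_year, salaries: {role: usd},
#              vehicles: {name: {cargo_capacity_m3, ...}}}
#   tiers:    list of {name, level, n_service_points, holds_inventory,
#              storage: {...}, transport: {...}, management:
#              {fte: {role: fte}, technology_cost_per_site_year}}
#   throughput_buffer: {multiplier, months_per_year}   # optional
#
# Identifiers are ASCII; monetary values are USD/year unless a `currency`
# note overrides the label (no conversion is performed).

SCHEMA_VERSION <- 1L

CONFIG_TOP_FIELDS <- c("schema_version", "name", "notes", "currency",
                       "region", "geometry", "workday_hours", "demand",
                       "rates", "tiers", "throughput_buffer")

#' Build a validated scenario from a configuration list
#'
#' Accepts the plain nested list a YAML/JSON scenario document parses to
#' and constructs a fully validated [supply_chain_scenario()]. Unknown
#' top-level fields, dangling vehicle or role references, and any
#' constraint violation raise a structured error naming the field.
#'
#' @param config Nested list following the version-1 scenario schema (see
#'   the package vignette or a packaged template for the layout).
#' @param provenance Optional provenance tibble (`field`, `source`);
#'   [load_scenario()] supplies it when merging template/file/override
#'   layers. Defaults to marking every field `"user"`.
#' @return A `supply_chain_scenario` with a `provenance` attribute (a
#'   tibble of leaf fields and their source; `"user"` for all fields when
#'   called directly).
#' @export
build_scenario <- function(config, provenance = NULL) {
  if (!is.list(config)) rsc_abort("config", "must be a list")
  unknown <- setdiff(names(config), CONFIG_TOP_FIELDS)
  if (length(unknown) > 0) {
    rsc_abort("config", "unknown field(s): %s (schema version %d)",
              paste(unknown, collapse = ", "), SCHEMA_VERSION)
  }
  sv <- config$schema_version %||% SCHEMA_VERSION
  if (sv > SCHEMA_VERSION) {
    rsc_abort("schema_version",
              "document uses schema version %s; this reader supports <= %d",
              sv, SCHEMA_VERSION)
  }
  region <- do.call(region_geometry, req(config, "region"))
  geometry <- do.call(geometry_model, config$geometry %||% list())
  demand <- do.call(demand_spec, req(config, "demand"))
  rates_cfg <- req(config, "rates")
  vehicles <- lapply(names(rates_cfg$vehicles %||% list()), function(nm) {
    do.call(vehicle_spec, c(list(name = nm), rates_cfg$vehicles[[nm]]))
  })
  names(vehicles) <- names(rates_cfg$vehicles %||% list())
  rates <- cost_rates(
    fuel_price_usd_per_l = rates_cfg$fuel_price_usd_per_l %||% 0,
    dry_storage_usd_per_m3_year = rates_cfg$dry_storage_usd_per_m3_year %||% 0,
    cold_storage_usd_per_m3_year =
      rates_cfg$cold_storage_usd_per_m3_year %||% 0,
    salary_usd_year_by_role = rates_cfg$salaries,
    vehicles = vehicles
  )
  tiers_cfg <- req(config, "tiers")
  tiers <- lapply(tiers_cfg, function(tc) {
    storage <- if (!is.null(tc$storage)) {
      do.call(storage_policy, tc$storage)
    }
    transport <- if (!is.null(tc$transport)) {
      do.call(transport_policy, tc$transport)
    }
    management <- if (!is.null(tc$management)) {
      management_policy(
        fte_by_role = tc$management$fte,
        technology_cost_per_site_year =
          tc$management$technology_cost_per_site_year %||% 0)
    }
    tier_spec(
      name = tc$name, level = tc$level,
      n_service_points = tc$n_service_points,
      holds_inventory = tc$holds_inventory %||% TRUE,
      storage = storage, transport = transport, management = management)
  })
  s <- supply_chain_scenario(
    name = req(config, "name"),
    region = region, tiers = tiers, demand = demand, rates = rates,
    geometry = geometry,
    throughput_buffer = config$throughput_buffer,
    workday_hours = config$workday_hours %||% 8
  )
  attr(s, "provenance") <- provenance %||% tibble::tibble(
    field = names(flatten_config(config)),
    source = "user"
  )
  s
}

req <- function(config, field) {
  if (is.null(config[[field]])) rsc_abort(field, "is required")
  config[[field]]
}

# Flatten a nested config into dotted leaf paths (tiers indexed by name
# when available).
flatten_config <- function(x, prefix = "") {
  if (!is.list(x)) {
    return(stats::setNames(list(x), prefix))
  }
  nms <- names(x)
  if (is.null(nms)) {
    nms <- vapply(seq_along(x), function(i) {
      nm <- if (is.list(x[[i]])) x[[i]]$name else NULL
      nm %||% as.character(i)
    }, character(1))
  }
  out <- list()
  for (i in seq_along(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
    out <- c(out, flatten_config(x[[i]], key))
  }
  out
}

# Recursive merge: values in `over` win; named lists merge field-wise,
# everything else (including unnamed lists such as `tiers`) is replaced
# wholesale.
merge_configs <- function(base, over) {
  if (!is.list(base) || !is.list(over) ||
      is.null(names(base)) || is.null(names(over))) {
    return(over)
  }
  for (nm in names(over)) {
    base[[nm]] <- if (nm %in% names(base)) {
      merge_configs(base[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  base
}

read_config_file <- function(path) {
  if (!file.exists(path)) rsc_abort("path", "file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
             error = function(e) rsc_abort("path", "JSON parse error in %s: %s",
                                           path, conditionMessage(e)))
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) rsc_abort("path", "YAML parse error in %s: %s",
                                           path, conditionMessage(e)))
  }
}

template_dir <- function() {
  system.file("extdata", "templates", package = "rapidsc", mustWork = TRUE)
}

#' List packaged scenario templates
#'
#' Templates are complete proxy parameter sets: loading one alone yields a
#' scenario that validates and evaluates with no further input. All values
#' are illustrative proxies, not country data.
#'
#' @return A tibble: `template`, `notes`.
#' @export
list_templates <- function() {
  files <- list.files(template_dir(), pattern = "\\.yaml$", full.names = TRUE)
  tibble::tibble(
    template = sub("\\.yaml$", "", basename(files)),
    notes = vapply(files, function(f) {
      yaml::read_yaml(f)$notes %||% ""
    }, character(1))
  )
}

#' Load a scenario from template, file and overrides
#'
#' Parameter precedence is `overrides` > `path` (YAML or JSON document) >
#' `template`. The source of every leaf parameter is recorded in the
#' returned scenario's `provenance` attribute, so a user can audit which
#' values came from the packaged proxy template and which they supplied.
#'
#' @param path Optional scenario document (`.yaml`/`.yml` or `.json`).
#' @param template Optional packaged template name (see
#'   [list_templates()]).
#' @param overrides Optional nested list of final overrides.
#' @return A validated [supply_chain_scenario()] with `provenance`.
#' @export
#' @examples
#' s <- load_scenario(template = "immunization_4tier")
#' attr(s, "provenance")
load_scenario <- function(path = NULL, template = NULL, overrides = list()) {
  if (is.null(path) && is.null(template)) {
    rsc_abort("path", "supply a scenario file, a template name, or both")
  }
  tpl_cfg <- NULL
  if (!is.null(template)) {
    f <- file.path(template_dir(), paste0(template, ".yaml"))
    if (!file.exists(f)) {
      rsc_abort("template", "unknown template \"%s\" (available: %s)",
                template, paste(list_templates()$template, collapse = ", "))
    }
    tpl_cfg <- yaml::read_yaml(f)
  }
  file_cfg <- if (!is.null(path)) read_config_file(path) else NULL
  config <- tpl_cfg %||% list()
  if (!is.null(file_cfg)) config <- merge_configs(config, file_cfg)
  if (length(overrides) > 0) config <- merge_configs(config, overrides)

  leaf_source <- function(cfg, label) {
    if (is.null(cfg)) character(0) else
      stats::setNames(rep(label, length(flatten_config(cfg))),
                      names(flatten_config(cfg)))
  }
  src <- leaf_source(tpl_cfg, "template")
  for (layer in list(leaf_source(file_cfg, "file"),
                     leaf_source(overrides, "override"))) {
    src[names(layer)] <- layer
  }
  final_fields <- names(flatten_config(config))
  provenance <- tibble::tibble(
    field = final_fields,
    source = unname(src[final_fields])
  )
  build_scenario(config, provenance = provenance)
}

# Convert a scenario back to a plain schema-v1 config list.
scenario_to_config <- function(s) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  tiers <- lapply(unname(s$tiers), function(t) {
    drop_null(list(
      name = t$name, level = t$level,
      n_service_points = t$n_service_points,
      holds_inventory = t$holds_inventory,
      storage = if (!is.null(t$storage)) drop_null(unclass(t$storage)),
      transport = if (!is.null(t$transport)) drop_null(unclass(t$transport)),
      management = if (!is.null(t$management)) drop_null(list(
        fte = as.list(t$management$fte_by_role),
        technology_cost_per_site_year =
          t$management$technology_cost_per_site_year))
    ))
  })
  vehicles <- lapply(s$rates$vehicles, function(v) {
    unclass(v)[setdiff(names(unclass(v)), "name")]
  })
  demand <- drop_null(unclass(s$demand))
  demand$has_derivation <- NULL
  demand$has_override <- NULL
  drop_null(list(
    schema_version = SCHEMA_VERSION,
    name = s$name,
    region = unclass(s$region),
    geometry = unclass(s$geometry),
    workday_hours = s$workday_hours,
    demand = demand,
    rates = list(
      fuel_price_usd_per_l = s$rates$fuel_price_usd_per_l,
      dry_storage_usd_per_m3_year = s$rates$dry_storage_usd_per_m3_year,
      cold_storage_usd_per_m3_year = s$rates$cold_storage_usd_per_m3_year,
      salaries = as.list(s$rates$salary_usd_year_by_role),
      vehicles = vehicles
    ),
    tiers = tiers,
    throughput_buffer = s$throughput_buffer
  ))
}

#' Proxy product volume and value table
#'
#' A small, user-replaceable table of typical packed volumes (cm^3 per
#' dose/unit) and prices for common immunization and health commodities,
#' standing in for historical product unit-volume data when deriving
#' demand volumes.
#'
#' @return A tibble: `product`, `cm3_per_dose`, `usd_per_dose`,
#'   `cold_chain`.
#' @export
proxy_products <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "products.csv", package = "rapidsc",
                mustWork = TRUE),
    stringsAsFactors = FALSE))
}

#' Write a scenario document
#'
#' Serializes a scenario to a schema-v1 YAML document that [load_scenario()]
#' reads back to an equivalent scenario (round-trip: re-loading and
#' evaluating gives identical results).
#'
#' @param s A [supply_chain_scenario()].
#' @param path Output `.yaml` path.
#' @return Invisibly, `path`.
#' @export
write_scenario <- function(s, path) {
  if (!inherits(s, "supply_chain_scenario")) {
    rsc_abort("s", "must be a supply_chain_scenario")
  }
  yaml::write_yaml(scenario_to_config(s), path)
  invisible(path)
}
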