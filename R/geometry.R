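#' Continuous-approximation distance model
#'
#' Distances are never measured from coordinates; instead facilities are
#' assumed evenly distributed over each service area, and two classical
#' continuous-approximation constants convert area into expected road
#' distance:
#'
#' * `k_nearest`: mean distance from a central hub to a uniformly
#'   distributed point in its (square) service area is
#'   `k_nearest * sqrt(area)`. The default 0.3826 is the exact constant for
#'   the centre of a square, `(sqrt(2) + asinh(1)) / 6`.
#' * `k_tour`: the length of an efficient closed tour through `n` uniform
#'   points in an area `A` is approximately `k_tour * sqrt(n * A)`; 0.75 is
#'   the classical tour-length constant for random Euclidean instances.
#'
#' Both are multiplied by the region's circuity factor to convert
#' straight-line to road distance, and both are user-overridable.
#'
#' @param k_nearest Hub-to-facility shape constant (> 0), default 0.3826.
#' @param k_tour Tour-length constant (> 0), default 0.75.
#' @return A `geometry_model` object.
#' @export
geometry_model <- function(k_nearest = 0.3826, k_tour = 0.75) {
  assert_number(k_nearest, "geometry.k_nearest", min = 0, strict_min = TRUE)
  assert_number(k_tour, "geometry.k_tour", min = 0, strict_min = TRUE)
  structure(list(k_nearest = k_nearest, k_tour = k_tour),
            class = "geometry_model")
}

#' Service area per hub
#'
#' The region is partitioned into equal service areas, one per service
#' point: evenly distributed facilities make each hub responsible for
#' `region_area / n` square kilometres.
#'
#' @param region_area_km2 Region area, km^2 (> 0).
#' @param n_service_points Number of service points partitioning it (>= 1).
#' @return km^2 per service point.
#' @export
service_area_km2 <- function(region_area_km2, n_service_points) {
  assert_number(region_area_km2, "region_area_km2", min = 0, strict_min = TRUE)
  n_service_points <- assert_count(n_service_points, "n_service_points",
                                   min = 1L)
  region_area_km2 / n_service_points
}

#' Mean one-way leg distance from hub to typical facility
#'
#' @param service_area_km2 Service area of the hub, km^2 (>= 0).
#' @param g A [geometry_model()].
#' @param circuity_factor Road circuity multiplier (>= 1).
#' @return Expected one-way road distance, km:
#'   `k_nearest * sqrt(service_area) * circuity`.
#' @export
#' @examples
#' mean_leg_distance_km(400)  # 7.652
mean_leg_distance_km <- function(service_area_km2, g = geometry_model(),
                                 circuity_factor = 1) {
  assert_number(service_area_km2, "service_area_km2", min = 0)
  assert_number(circuity_factor, "circuity_factor", min = 1)
  g$k_nearest * sqrt(service_area_km2) * circuity_factor
}

#' Length of a multi-stop delivery loop
#'
#' Closed-tour continuous approximation: a loop visiting `stops` facilities
#' that jointly occupy `service_area_per_loop_km2` has expected length
#' `k_tour * sqrt(stops * service_area_per_loop) * circuity`.
#'
#' @param stops Facilities per loop (>= 2; use hub-and-spoke for 1).
#' @param service_area_per_loop_km2 Area covered by one loop, km^2.
#' @param g A [geometry_model()].
#' @param circuity_factor Road circuity multiplier (>= 1).
#' @return Expected loop length, km.
#' @export
#' @examples
#' loop_route_length_km(8, 400)  # 42.43
loop_route_length_km <- function(stops, service_area_per_loop_km2,
                                 g = geometry_model(), circuity_factor = 1) {
  stops <- assert_count(stops, "stops", min = 0L)
  if (stops < 2L) {
    rsc_abort("stops", "must be >= 2 for a loop (use hub_and_spoke for 1)")
  }
  assert_number(service_area_per_loop_km2, "service_area_per_loop_km2",
                min = 0)
  assert_number(circuity_factor, "circuity_factor", min = 1)
  g$k_tour * sqrt(stops * service_area_per_loop_km2) * circuity_factor
}

#' Route distance convention for a resupply link
#'
#' Under `hub_and_spoke` every facility is served by a dedicated
#' out-and-back trip: the round trip is twice the mean leg. Under
#' `multi_stop_loop` the facilities per hub are partitioned into loops of
#' `stops_per_loop` (the last, possibly partial, loop conservatively
#' travels the full approximation length), and the route distance is the
#' closed-loop length.
#'
#' @param distribution_model `"hub_and_spoke"` or `"multi_stop_loop"`.
#' @param region_area_km2 Region area, km^2.
#' @param n_supplying Hubs at the supplying tier.
#' @param n_receiving Facilities at the receiving tier.
#' @param stops_per_loop Facilities per loop (multi-stop only).
#' @param g A [geometry_model()].
#' @param circuity_factor Road circuity multiplier.
#' @return A list: `route_km` (distance travelled per route),
#'   `routes_per_cycle` (routes needed to serve all facilities once),
#'   `stops_per_route`.
#' @export
round_trip_distance_km <- function(distribution_model,
                                   region_area_km2, n_supplying, n_receiving,
                                   stops_per_loop = 1L,
                                   g = geometry_model(),
                                   circuity_factor = 1) {
  assert_choice(distribution_model, "distribution_model",
                c("hub_and_spoke", "multi_stop_loop"))
  n_supplying <- assert_count(n_supplying, "n_supplying", min = 1L)
  n_receiving <- assert_count(n_receiving, "n_receiving", min = 1L)
  if (distribution_model == "hub_and_spoke" || stops_per_loop <= 1L) {
    hub_area <- service_area_km2(region_area_km2, n_supplying)
    list(
      route_km = 2 * mean_leg_distance_km(hub_area, g, circuity_factor),
      routes_per_cycle = n_receiving,
      stops_per_route = 1L
    )
  } else {
    per_hub <- n_receiving / n_supplying
    loops_per_hub <- ceiling(per_hub / stops_per_loop)
    loop_area <- stops_per_loop * service_area_km2(region_area_km2,
                                                   n_receiving)
    list(
      route_km = loop_route_length_km(stops_per_loop, loop_area, g,
                                      circuity_factor),
      routes_per_cycle = as.integer(n_supplying * loops_per_hub),
      stops_per_route = as.integer(stops_per_loop)
    )
  }
}
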