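test_that("network generation is reproducible and leaves the RNG alone", {
  n1 <- generate_network(11, 50, 400, 0.4, demand_cv = 0.5)
  n2 <- generate_network(11, 50, 400, 0.4, demand_cv = 0.5)
  expect_identical(n1, n2)
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_network(3, 10, 100, 0.2)); after <- runif(1)
  expect_identical(before, after)
})

test_that("demand heterogeneity and clustering knobs behave at the limits", {
  flat <- generate_network(5, 40, 400, 0.4, demand_cv = 0)
  expect_true(all(flat$facilities$monthly_demand_m3 == 0.4))
  spread <- generate_network(5, 2000, 400, 0.4, demand_cv = 0.8)
  expect_gt(sd(spread$facilities$monthly_demand_m3), 0)
  # log-normal mean is preserved (law of large numbers at n = 2000)
  expect_equal(mean(spread$facilities$monthly_demand_m3), 0.4,
               tolerance = 0.05)
  clustered <- generate_network(5, 40, 400, 0.4, clustering = 1)
  expect_true(all(clustered$facilities$x_km == clustered$hub$x_km))
  expect_true(all(clustered$facilities$y_km == clustered$hub$y_km))
  # all coordinates stay inside the region
  u <- generate_network(5, 500, 400, 0.4)
  expect_true(all(u$facilities$x_km >= 0 & u$facilities$x_km <= 20))
  expect_true(all(u$facilities$y_km >= 0 & u$facilities$y_km <= 20))
})

test_that("a 20-facility district network builds and evaluates", {
  net <- generate_network(9, 20, 900, 0.3)
  s <- oracle_scenario(20, 900, 0.3)
  bf <- brute_force_cost(net, s)
  expect_gt(bf$total_usd, 0)
  expect_identical(sum(bf$costs$annual_cost_usd), bf$total_usd)
  r <- evaluate_scenario(s)
  expect_gt(cost_totals(r), 0)
})

test_that("pinned distances collapse brute force onto the typical model", {
  n <- 25
  area <- 400
  net <- generate_network(21, n, area, 0.4, demand_cv = 0)
  s <- oracle_scenario(n, area, 0.4)
  pinned <- mean_leg_distance_km(area, s$geometry,
                                 s$region$circuity_factor)
  bf <- brute_force_cost(net, s, distance_override_km = pinned)
  typical <- cost_totals(evaluate_scenario(s))
  expect_equal(bf$total_usd, typical, tolerance = 1e-12)
})

test_that("a single high-demand outlier widens the approximation gap", {
  # paired seeds: same placement, one facility's demand inflated 50x
  gaps <- vapply(1:8, function(seed) {
    base <- typical_vs_brute_gap(seed, 20, 900, 0.3)$rel_gap
    net <- generate_network(seed, 20, 900, 0.3)
    net$facilities$monthly_demand_m3[1] <-
      net$facilities$monthly_demand_m3[1] * 50
    s <- oracle_scenario(20, 900,
                         mean(net$facilities$monthly_demand_m3))
    out <- abs(cost_totals(evaluate_scenario(s)) -
                 brute_force_cost(net, s)$total_usd) /
      brute_force_cost(net, s)$total_usd
    out - base
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("multi-stop brute force uses nearest-neighbour loops", {
  net <- generate_network(13, 24, 400, 0.2)
  s <- oracle_scenario(24, 400, 0.2,
                       distribution_model = "multi_stop_loop",
                       stops_per_loop = 6)
  bf <- brute_force_cost(net, s)
  expect_gt(bf$km_per_year, 0)
  # a loop serving 6 stops drives less than 6 dedicated round trips
  hs <- brute_force_cost(net, oracle_scenario(24, 400, 0.2))
  expect_lt(bf$km_per_year, hs$km_per_year)
  expect_error(brute_force_cost(net, s, distance_override_km = 5),
               class = "rapidsc_validation_error")
})

test_that("approximation error sweep reports one row per cell", {
  sweep <- approximation_error_sweep(c(20, 50), n_seeds = 2,
                                     region_area_km2 = 900,
                                     demand_mean_m3 = 0.3)
  expect_identical(nrow(sweep), 2L)
  expect_true(all(sweep$mean_abs_rel_gap >= 0))
  expect_error(approximation_error_sweep(integer(0)),
               class = "rapidsc_validation_error")
})

test_that("networks export to CSV for inspection", {
  net <- generate_network(2, 5, 100, 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  export_network_csv(net, path)
  rows <- read.csv(path)
  expect_identical(nrow(rows), 6L)  # hub + 5 facilities
  expect_identical(names(rows), c("id", "x_km", "y_km",
                                  "monthly_demand_m3"))
})
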