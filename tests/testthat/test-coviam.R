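# The Egypt SDG model instance.

test_that("the packaged 2015 baseline is returned verbatim", {
  bl <- egypt_baseline()
  expect_identical(bl$below_poverty_pct, 27.8)
  expect_identical(bl$ghg_mt, 264.9)
  expect_identical(bl$takafol_covered, 2173274)
  expect_identical(bl$karama_covered, 1239732)
  expect_identical(bl$access_water_pct, 98)
  expect_identical(bl$access_electricity_pct, 100)
  expect_identical(bl$access_sanitation_pct, 93)
  expect_identical(bl$gov_spend_essential_pct, 5.59)
  expect_identical(bl$undernourishment_pct, 4.6)
  expect_identical(bl$food_price_anomaly_pct, 10.99)
  expect_identical(bl$food_insecurity_pct, 27.76)
  expect_identical(bl$child_malnutrition_pct, 9.48)
  expect_identical(bl$inflation_pct, 10.37)
  expect_identical(bl$gdp_pc_growth_pct, 5.43)
  expect_identical(bl$tourism_share_pct, 8.7)
  expect_identical(bl$unemployment_pct, 13.05)
  expect_identical(bl$informal_employment_pct, 30.94)
  expect_identical(bl$disaster_deaths, 40)
  expect_identical(bl$drr_adaptation_level, 0.2)
  expect_identical(bl$public_awareness_level, 0.3)
  expect_true(is.na(bl$production_per_labor))
  # alternative 2015 prints retained as metadata, not initial conditions
  alt <- attr(bl, "alternates")
  expect_identical(unname(alt[["below_poverty_pct"]]), 27.5)
  expect_identical(unname(alt[["ghg_mt"]]), 240)
  expect_identical(unname(alt[["gdp_growth_pct"]]), 4.37)
})

test_that("the built model validates with zero violations", {
  spec <- build_coviam(egypt_baseline(), coviam_parameters())
  expect_identical(nrow(validate_model(spec)), 0L)
})

test_that("parameters outside their declared bounds are rejected by name", {
  expect_error(coviam_parameters(pov_tau = -1), "pov_tau")
  expect_error(set_parameter_values(coviam_parameters(), list(ghg_vis_2049 = 1e5)),
               "ghg_vis_2049")
  expect_error(set_parameter_values(coviam_parameters(), list(not_a_param = 1)),
               "not_a_param")
})

test_that("the extracted graph carries the full narrated loop inventory", {
  spec <- build_coviam(egypt_baseline(), coviam_parameters())
  graph <- extract_causal_graph(spec)
  aud <- audit_expected_loops(graph, coviam_expected_loops(),
                              ignore = coviam_ignore_nodes())
  expect_true(attr(aud, "passed"))
  expect_identical(nrow(aud), 18L)
})

test_that("population is stationary when demographic rates are zeroed and shocks off", {
  p <- coviam_parameters(avg_birth_rate = 0, avg_death_rate = 0,
                         dd_pov_sens = 0, dd_sp_sens = 0, sld_base = 0,
                         sld_acc_sens = 0, sld_gs_sens = 0)
  bl <- egypt_baseline()
  # zero the base disaster-death count (the baseline feeds dd_ref)
  bl$disaster_deaths <- 0
  tr <- run_coviam("baseline", params = p, baseline = bl)
  expect_identical(unique(tr$series$population), p$values[["population_2015"]])
})

test_that("indicator extraction round-trips and starts at the baseline", {
  tr <- run_coviam("covid19_vision2030")
  ind <- extract_indicator(tr, "below_poverty_pct")
  expect_identical(ind$values, tr$series$below_poverty_pct)
  expect_identical(ind$years, tr$times)
  expect_length(ind$values, 36L)
  expect_identical(ind$values[[1L]], 27.8)
  expect_error(extract_indicator(tr, "nope"), "available")
  # every primary baseline variable is resolvable in the trajectory
  carried_as_metadata <- c("production_per_labor", "gdp_pc_growth_pct")
  for (nm in setdiff(names(egypt_baseline()), carried_as_metadata))
    expect_true(nm %in% names(tr$series), info = nm)
})

test_that("couplings move in the narrated directions (one factor at a time)", {
  p <- coviam_parameters()
  base <- run_coviam("baseline", params = p)

  # more disaster deaths -> lower population year on year
  spec <- build_coviam(egypt_baseline(), p)
  hi_dd <- simulate_model(spec, overrides = list(disaster_deaths = 5e5))
  expect_true(all(hi_dd$series$population[-1L] < base$series$population[-1L]))

  # higher inflation path -> higher food-price anomaly and faster poverty growth
  hi_infl <- run_coviam("baseline", params = set_parameter_values(p, list(infl_cur_2050 = 30)))
  expect_gt(trajectory_value(hi_infl, "food_price_anomaly_pct", 2030),
            trajectory_value(base, "food_price_anomaly_pct", 2030))
  expect_gt(trajectory_value(hi_infl, "below_poverty_pct", 2030),
            trajectory_value(base, "below_poverty_pct", 2030))

  # higher GDP growth -> more government spending and better access
  hi_gdp <- run_coviam("baseline", params = set_parameter_values(p, list(econ_cur_2018 = 9)))
  expect_gt(trajectory_value(hi_gdp, "gov_spend_essential_pct", 2019),
            trajectory_value(base, "gov_spend_essential_pct", 2019))
  expect_gt(trajectory_value(hi_gdp, "access_basic_pct", 2019),
            trajectory_value(base, "access_basic_pct", 2019))
})

test_that("percentage indicators stay within [0, 100] across scenarios and draws", {
  pct_vars <- c("below_poverty_pct", "food_insecurity_pct", "unemployment_pct",
                "gov_spend_essential_pct", "access_water_pct",
                "access_electricity_pct", "access_sanitation_pct",
                "access_basic_pct", "sp_covered_pct", "food_price_anomaly_pct",
                "undernourishment_pct", "child_malnutrition_pct",
                "tourism_share_pct", "informal_employment_pct")
  check <- function(tr) {
    for (v in pct_vars) {
      expect_true(all(tr$series[[v]] >= 0 & tr$series[[v]] <= 100), info = v)
    }
  }
  for (scn in c("baseline", "covid19", "covid19_vision2030"))
    check(suppressWarnings(run_coviam(scn)))
  # perturbed sensitivity draws within bounds
  set.seed(11)
  for (i in 1:5) {
    p <- coviam_parameters(
      pov_infl_sens = stats::runif(1, 0, 0.3),
      pov_fpa_sens = stats::runif(1, 0, 0.3),
      fi_fpa_sens = stats::runif(1, 0, 0.3),
      gdp_pp_sens = stats::runif(1, 0, 20),
      econ_unemp_sens = stats::runif(1, 0, 5))
    check(suppressWarnings(run_coviam("covid19_vision2030", params = p)))
  }
})

test_that("the model is a pure function of baseline, parameters and scenario", {
  p <- coviam_parameters()
  bl <- egypt_baseline()
  spec_before <- build_coviam(bl, p)
  a <- run_coviam("covid19_vision2030", params = p, baseline = bl)
  b <- run_coviam("covid19_vision2030", params = p, baseline = bl)
  expect_identical(a, b)
  expect_identical(build_coviam(bl, p), spec_before)
})
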