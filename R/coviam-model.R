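# The Egypt SDG model instance.
#
# Stocks: population, below-poverty percentage, food-insecurity percentage,
# economic strength (in GDP-growth-rate units), inflation, the GHG emission
# trend, the climate-action score and cumulative GHG.  Each driven indicator
# follows goal-seeking first-order dynamics toward a current-path or
# Vision-2030 goal lookup, plus the signed couplings narrated in the feedback
# loops (deaths -> population -> GDP -> spending -> access -> service-lack
# deaths; inflation -> purchasing power -> GDP and poverty; food-price
# anomaly -> poverty; unemployment -> economic strength).  COVID-19 enters as
# exogenous shock inputs (zero by default, overlaid by scenarios).
#
# Coupling terms are products of sensitivity coefficients and deviations from
# the 2015 operating point (or from an expected reference path, for the
# population level); they vanish at the base year by construction.

#' Build the Egypt SDG stock-flow model
#'
#' @param baseline An [egypt_baseline()].
#' @param params A [coviam_parameters()] (values already bounds-checked).
#' @param horizon Simulation horizon; default 2015-2050 at dt = 1 year.
#' @return A validated [sd_model()] whose extracted causal graph contains the
#'   18 narrated feedback loops (see [coviam_expected_loops()]).
#' @export
build_coviam <- function(baseline = egypt_baseline(),
                         params = coviam_parameters(),
                         horizon = list(start = 2015, end = 2050, dt = 1)) {
  stopifnot(inherits(baseline, "egypt_baseline"),
            inherits(params, "coviam_parameters"))
  v <- params$values
  # re-assert bounds (params may have been built by hand)
  set_parameter_values(params, v)

  acc_ref <- (baseline$access_water_pct + baseline$access_electricity_pct +
                baseline$access_sanitation_pct) / 3
  sp_persons <- baseline$takafol_covered + baseline$karama_covered
  sp_ref <- 100 * sp_persons / v[["population_2015"]]
  clim_0 <- (baseline$drr_adaptation_level + baseline$public_awareness_level) / 2

  consts <- list(
    pov_ref = baseline$below_poverty_pct,
    fi_ref = baseline$food_insecurity_pct,
    infl_ref = baseline$inflation_pct,
    fpa_ref = baseline$food_price_anomaly_pct,
    unemp_ref = baseline$unemployment_pct,
    gs_ref = baseline$gov_spend_essential_pct,
    acc_water_ref = baseline$access_water_pct,
    acc_elec_ref = baseline$access_electricity_pct,
    acc_sanit_ref = baseline$access_sanitation_pct,
    acc_ref = acc_ref,
    dd_ref = baseline$disaster_deaths,
    tour_ref = baseline$tourism_share_pct,
    inf_emp_ref = baseline$informal_employment_pct,
    un_ref = baseline$undernourishment_pct,
    chm_ref = baseline$child_malnutrition_pct,
    gdp_ref = v[["gdp_2015_total"]],
    sp_ref = sp_ref,
    awareness_0 = baseline$public_awareness_level,
    drr_0 = baseline$drr_adaptation_level,
    clim_0 = clim_0,
    takafol_persons = baseline$takafol_covered,
    karama_persons = baseline$karama_covered
  )
  parameters <- c(as.list(v), consts)

  # expected population reference path (piecewise-linear approximation of
  # exponential growth at the net demographic rate); the absolute population
  # level cancels out of all fraction-valued indicators
  net0 <- v[["avg_birth_rate"]] - v[["avg_death_rate"]]
  yrs <- seq(horizon$start, horizon$end, by = 5)
  lookups <- list(
    sd_lookup("pop_expected", yrs, v[["population_2015"]] * (1 + net0)^(yrs - horizon$start)),
    sd_lookup("pov_goal_current", c(2015, 2016, 2017, 2019, 2050),
              c(baseline$below_poverty_pct, v[["pov_cur_2016"]], v[["pov_cur_2017"]],
                v[["pov_cur_2019"]], v[["pov_cur_2050"]])),
    sd_lookup("pov_goal_vision", c(2022, 2029, 2049),
              c(v[["pov_vis_2022"]], v[["pov_vis_2029"]], v[["pov_vis_2049"]])),
    sd_lookup("fi_goal_current", c(2015, 2019, 2050),
              c(baseline$food_insecurity_pct, v[["fi_cur_2019"]], v[["fi_cur_2050"]])),
    sd_lookup("fi_goal_vision", c(2022, 2029, 2049),
              c(v[["fi_vis_2022"]], v[["fi_vis_2029"]], v[["fi_vis_2049"]])),
    sd_lookup("econ_goal_current", c(2015, 2018, 2050),
              c(v[["gdp_2015_total"]], v[["econ_cur_2018"]], v[["econ_cur_2050"]])),
    sd_lookup("econ_goal_vision", c(2022, 2029, 2049),
              c(v[["econ_vis_2022"]], v[["econ_vis_2029"]], v[["econ_vis_2049"]])),
    sd_lookup("ghg_goal_current", c(2015, 2019, 2020, 2021, 2050),
              c(baseline$ghg_mt, v[["ghg_cur_2019"]], v[["ghg_cur_2020"]],
                v[["ghg_cur_2021"]], v[["ghg_cur_2050"]])),
    sd_lookup("ghg_goal_vision", c(2022, 2029, 2049),
              c(v[["ghg_vis_2022"]], v[["ghg_vis_2029"]], v[["ghg_vis_2049"]])),
    sd_lookup("infl_goal_current", c(2015, 2050),
              c(baseline$inflation_pct, v[["infl_cur_2050"]])),
    sd_lookup("infl_goal_vision", c(2022, 2049),
              c(v[["infl_vis_2022"]], v[["infl_vis_2049"]])),
    sd_lookup("clim_goal_current", c(2015, 2050), c(clim_0, v[["clim_cur_2050"]])),
    sd_lookup("clim_goal_vision", c(2022, 2049), c(0.3, v[["clim_vis_2049"]])),
    sd_lookup("unemp_path", c(2015, 2019, 2030, 2050),
              c(baseline$unemployment_pct, v[["unemp_2019"]], v[["unemp_2030"]],
                v[["unemp_2050"]]))
  )

  stocks <- list(
    sd_stock("population", v[["population_2015"]], "person", non_negative = TRUE),
    sd_stock("below_poverty_pct", baseline$below_poverty_pct, "%", non_negative = TRUE),
    sd_stock("food_insecurity_pct", baseline$food_insecurity_pct, "%", non_negative = TRUE),
    sd_stock("econ_strength", v[["gdp_2015_total"]], "%"),
    sd_stock("inflation_pct", baseline$inflation_pct, "%", non_negative = TRUE),
    sd_stock("ghg_trend", baseline$ghg_mt, "Mt CO2-eq/yr", non_negative = TRUE),
    sd_stock("climate_action_score", clim_0, "dimensionless", non_negative = TRUE),
    sd_stock("ghg_cumulative", 0, "Mt CO2-eq", non_negative = TRUE)
  )

  aux <- list(
    # exogenous scenario inputs (zero in the baseline run, overlaid by scenarios)
    sd_aux("vision_active", "0", units = "dimensionless"),
    sd_aux("covid_gdp_gap", "0", units = "dimensionless"),
    sd_aux("covid_excess_mort", "0", units = "1/yr"),
    sd_aux("ghg_lockdown", "0", units = "dimensionless"),
    sd_aux("covid_food_stress", "0", units = "%/yr"),

    sd_aux("pop_dev", "population / lookup(pop_expected, t) - 1",
           signs = c(population = 1), units = "dimensionless"),
    sd_aux("purchasing_power", "1 - pp_infl_sens * (inflation_pct - infl_ref) / 100",
           signs = c(inflation_pct = -1), units = "index"),
    sd_aux("gdp_growth_pct",
           paste("covid_gdp_gap * gdp_covid_level + (1 - covid_gdp_gap) *",
                 "(econ_strength + gdp_pop_sens * pop_dev +",
                 "gdp_pp_sens * (purchasing_power - 1))"),
           signs = c(covid_gdp_gap = -1, econ_strength = 1, pop_dev = 1,
                     purchasing_power = 1),
           units = "%"),
    sd_aux("min_income_idx", "1 + mini_gdp_sens * (gdp_growth_pct - gdp_ref)",
           signs = c(gdp_growth_pct = 1), units = "index"),
    sd_aux("gov_spend_essential_pct",
           "max(0, min(100, gs_ref + gs_gdp_sens * (gdp_growth_pct - gdp_ref)))",
           signs = c(gdp_growth_pct = 1), units = "%"),
    sd_aux("access_water_pct",
           paste("max(0, min(100, acc_water_ref + acc_gdp_sens * (gdp_growth_pct - gdp_ref)",
                 "+ acc_gs_sens * (gov_spend_essential_pct - gs_ref)))"),
           signs = c(gdp_growth_pct = 1, gov_spend_essential_pct = 1), units = "%"),
    sd_aux("access_electricity_pct",
           paste("max(0, min(100, acc_elec_ref + acc_gdp_sens * (gdp_growth_pct - gdp_ref)",
                 "+ acc_gs_sens * (gov_spend_essential_pct - gs_ref)))"),
           signs = c(gdp_growth_pct = 1, gov_spend_essential_pct = 1), units = "%"),
    sd_aux("access_sanitation_pct",
           paste("max(0, min(100, acc_sanit_ref + acc_gdp_sens * (gdp_growth_pct - gdp_ref)",
                 "+ acc_gs_sens * (gov_spend_essential_pct - gs_ref)))"),
           signs = c(gdp_growth_pct = 1, gov_spend_essential_pct = 1), units = "%"),
    sd_aux("access_basic_pct",
           "(access_water_pct + access_electricity_pct + access_sanitation_pct) / 3",
           signs = c(access_water_pct = 1, access_electricity_pct = 1,
                     access_sanitation_pct = 1), units = "%"),
    sd_aux("sp_covered_pct",
           paste("max(0, min(100, 100 * (takafol_persons + karama_persons) / population *",
                 "(1 - sp_gdp_sens * (gdp_growth_pct - gdp_ref) / gdp_ref)))"),
           signs = c(population = -1, gdp_growth_pct = -1), units = "%"),
    sd_aux("takafol_covered", "takafol_persons", units = "person"),
    sd_aux("karama_covered", "karama_persons", units = "person"),
    sd_aux("disaster_deaths",
           paste("max(0, dd_ref + dd_pov_sens * (below_poverty_pct - pov_ref)",
                 "- dd_sp_sens * (sp_covered_pct - sp_ref))"),
           signs = c(below_poverty_pct = 1, sp_covered_pct = -1), units = "person/yr"),
    sd_aux("service_lack_deaths",
           paste("max(0, sld_base - sld_acc_sens * (access_basic_pct - acc_ref)",
                 "- sld_gs_sens * (gov_spend_essential_pct - gs_ref))"),
           signs = c(access_basic_pct = -1, gov_spend_essential_pct = -1),
           units = "person/yr"),
    sd_aux("avg_mortality_rate",
           paste("avg_death_rate + amr_dd_sens * disaster_deaths / population",
                 "+ amr_sld_sens * service_lack_deaths / population + covid_excess_mort"),
           signs = c(disaster_deaths = 1, service_lack_deaths = 1,
                     population = -1, covid_excess_mort = 1),
           units = "1/yr"),
    sd_aux("unemployment_pct",
           "max(0, min(100, lookup(unemp_path, t) + unemp_pop_sens * 100 * pop_dev))",
           signs = c(pop_dev = 1), units = "%"),
    sd_aux("food_price_anomaly_pct",
           "max(0, min(100, fpa_ref + fpa_infl_sens * (inflation_pct - infl_ref)))",
           signs = c(inflation_pct = 1), units = "%"),
    sd_aux("undernourishment_pct",
           "max(0, min(100, un_ref + un_fi_sens * (food_insecurity_pct - fi_ref)))",
           signs = c(food_insecurity_pct = 1), units = "%"),
    sd_aux("child_malnutrition_pct",
           "max(0, min(100, chm_ref + chm_fi_sens * (food_insecurity_pct - fi_ref)))",
           signs = c(food_insecurity_pct = 1), units = "%"),
    sd_aux("tourism_share_pct",
           "max(0, min(100, tour_ref + tour_gdp_sens * (gdp_growth_pct - gdp_ref)))",
           signs = c(gdp_growth_pct = 1), units = "%"),
    sd_aux("informal_employment_pct",
           "max(0, min(100, inf_emp_ref + inf_unemp_sens * (unemployment_pct - unemp_ref)))",
           signs = c(unemployment_pct = 1), units = "%"),
    sd_aux("public_awareness_level",
           "min(1, awareness_0 + awareness_ramp * (t - 2015))", units = "dimensionless"),
    sd_aux("drr_adaptation_level",
           "max(0, min(1, climate_action_score - (clim_0 - drr_0)))",
           signs = c(climate_action_score = 1), units = "dimensionless"),
    sd_aux("ghg_mt", "ghg_trend * (1 - ghg_lockdown)",
           signs = c(ghg_trend = 1, ghg_lockdown = -1), units = "Mt CO2-eq/yr"),
    # effective goals: switch to Vision-2030 levels when the policy scenario
    # is active; the GDP goal is additionally suppressed toward the
    # contracted level inside the COVID window
    sd_aux("pov_goal_eff",
           "if_then_else(vision_active >= 0.5, lookup(pov_goal_vision, t), lookup(pov_goal_current, t))",
           signs = c(vision_active = -1), units = "%"),
    sd_aux("fi_goal_eff",
           "if_then_else(vision_active >= 0.5, lookup(fi_goal_vision, t), lookup(fi_goal_current, t))",
           signs = c(vision_active = -1), units = "%"),
    sd_aux("econ_goal_eff",
           paste("covid_gdp_gap * gdp_covid_level + (1 - covid_gdp_gap) *",
                 "if_then_else(vision_active >= 0.5, lookup(econ_goal_vision, t),",
                 "lookup(econ_goal_current, t))"),
           signs = c(covid_gdp_gap = -1, vision_active = 1), units = "%"),
    sd_aux("ghg_goal_eff",
           "if_then_else(vision_active >= 0.5, lookup(ghg_goal_vision, t), lookup(ghg_goal_current, t))",
           signs = c(vision_active = -1), units = "Mt CO2-eq/yr"),
    sd_aux("infl_goal_eff",
           "if_then_else(vision_active >= 0.5, lookup(infl_goal_vision, t), lookup(infl_goal_current, t))",
           signs = c(vision_active = -1), units = "%"),
    sd_aux("clim_goal_eff",
           "if_then_else(vision_active >= 0.5, lookup(clim_goal_vision, t), lookup(clim_goal_current, t))",
           signs = c(vision_active = 1), units = "dimensionless")
  )

  flows <- list(
    sd_flow("pop_births", "avg_birth_rate * population",
            source = "CLOUD", sink = "population",
            signs = c(population = 1), units = "person/yr"),
    sd_flow("pop_deaths", "avg_mortality_rate * population",
            source = "population", sink = "CLOUD",
            signs = c(avg_mortality_rate = 1, population = 1), units = "person/yr"),
    sd_flow("pop_disaster_deaths", "disaster_deaths",
            source = "population", sink = "CLOUD",
            signs = c(disaster_deaths = 1), units = "person/yr"),
    sd_flow("pop_service_deaths", "service_lack_deaths",
            source = "population", sink = "CLOUD",
            signs = c(service_lack_deaths = 1), units = "person/yr"),
    sd_flow("pov_change",
            paste("(pov_goal_eff - below_poverty_pct) / pov_tau",
                  "+ pov_infl_sens * (inflation_pct - infl_ref)",
                  "+ pov_fpa_sens * (food_price_anomaly_pct - fpa_ref)",
                  "- pov_mini_sens * (min_income_idx - 1)",
                  "+ pov_pop_sens * pop_dev"),
            source = "CLOUD", sink = "below_poverty_pct",
            signs = c(pov_goal_eff = 1, below_poverty_pct = -1, inflation_pct = 1,
                      food_price_anomaly_pct = 1, min_income_idx = -1, pop_dev = 1),
            units = "%/yr"),
    sd_flow("fi_change",
            paste("(fi_goal_eff - food_insecurity_pct) / fi_tau",
                  "+ fi_fpa_sens * (food_price_anomaly_pct - fpa_ref)",
                  "+ covid_food_stress"),
            source = "CLOUD", sink = "food_insecurity_pct",
            signs = c(fi_goal_eff = 1, food_insecurity_pct = -1,
                      food_price_anomaly_pct = 1, covid_food_stress = 1),
            units = "%/yr"),
    sd_flow("econ_change",
            paste("(econ_goal_eff - econ_strength) / econ_tau",
                  "- econ_unemp_sens * (unemployment_pct - unemp_ref) / unemp_ref"),
            source = "CLOUD", sink = "econ_strength",
            signs = c(econ_goal_eff = 1, econ_strength = -1, unemployment_pct = -1),
            units = "%/yr"),
    sd_flow("infl_change",
            paste("(infl_goal_eff - inflation_pct) / infl_tau",
                  "- infl_gdp_sens * (gdp_growth_pct - gdp_ref)"),
            source = "CLOUD", sink = "inflation_pct",
            signs = c(infl_goal_eff = 1, inflation_pct = -1, gdp_growth_pct = -1),
            units = "%/yr"),
    sd_flow("ghg_change",
            paste("(ghg_goal_eff - ghg_trend) / ghg_tau",
                  "- ghg_clim_sens * (climate_action_score - clim_0)"),
            source = "CLOUD", sink = "ghg_trend",
            signs = c(ghg_goal_eff = 1, ghg_trend = -1, climate_action_score = -1),
            units = "Mt/yr^2"),
    sd_flow("clim_change",
            paste("(clim_goal_eff - climate_action_score) / clim_tau",
                  "+ clim_aw_sens * (public_awareness_level - awareness_0)"),
            source = "CLOUD", sink = "climate_action_score",
            signs = c(clim_goal_eff = 1, climate_action_score = -1,
                      public_awareness_level = 1),
            units = "1/yr"),
    sd_flow("ghg_emissions", "ghg_mt", source = "CLOUD", sink = "ghg_cumulative",
            signs = c(ghg_mt = 1), units = "Mt/yr")
  )

  sd_model("coviam_egypt", horizon = horizon, stocks = stocks, flows = flows,
           auxiliaries = aux, lookups = lookups, parameters = parameters)
}

#' The narrated feedback-loop inventory
#'
#' The 18 loops narrated in the dynamic hypothesis (seven balancing, eleven
#' reinforcing), expressed over the model's variable names; used with
#' [audit_expected_loops()] and [coviam_ignore_nodes()].
#'
#' @return List of entries `list(name=, nodes=, polarity=)`.
#' @export
coviam_expected_loops <- function() {
  DD <- "disaster_deaths"; AMR <- "avg_mortality_rate"; POP <- "population"
  PBP <- "below_poverty_pct"; GDP <- "gdp_growth_pct"; SP <- "sp_covered_pct"
  UN <- "unemployment_pct"; EC <- "econ_strength"; ACC <- "access_basic_pct"
  GS <- "gov_spend_essential_pct"; DLB <- "service_lack_deaths"
  INF <- "inflation_pct"; MINI <- "min_income_idx"; FPA <- "food_price_anomaly_pct"
  L <- function(name, nodes, polarity) list(name = name, nodes = nodes, polarity = polarity)
  list(
    L("B1", c(DD, AMR, POP, PBP), "balancing"),
    L("B2", c(DD, POP, PBP), "balancing"),
    L("B3", c(DD, POP, GDP, SP), "balancing"),
    L("B4", c(DD, AMR, POP, GDP, SP), "balancing"),
    L("B5", c(DLB, POP, UN, EC, GDP, ACC), "balancing"),
    L("B6", c(DLB, POP, UN, EC, GDP, GS), "balancing"),
    L("B7", c(DLB, AMR, POP, UN, EC, GDP, ACC), "balancing"),
    L("R1", c(DLB, POP, GDP, ACC), "reinforcing"),
    L("R2", c(DLB, POP, GDP, GS, ACC), "reinforcing"),
    L("R3", c(DLB, AMR, POP, GDP, GS, ACC), "reinforcing"),
    L("R4", c(DD, POP, GDP, INF, PBP), "reinforcing"),
    L("R5", c(DD, AMR, POP, GDP, INF, PBP), "reinforcing"),
    L("R6", c(DLB, AMR, POP, GDP, ACC), "reinforcing"),
    L("R7", c(DD, POP, GDP, MINI, PBP), "reinforcing"),
    L("R8", c(DD, AMR, POP, GDP, MINI, PBP), "reinforcing"),
    L("R9", c(DD, AMR, POP, UN, EC, GDP, SP), "reinforcing"),
    L("R10", c(DD, POP, GDP, INF, FPA, PBP), "reinforcing"),
    L("R11", c(DD, POP, UN, EC, GDP, SP), "reinforcing")
  )
}

#' Pass-through nodes collapsed out of cycles during the loop audit
#'
#' The stock-flow translation interposes flow variables (and the three
#' access-service components and the population-deviation helper) between the
#' causal-loop nodes; these are ignorable for node-set matching.
#'
#' @return Character vector of node names.
#' @export
coviam_ignore_nodes <- function() {
  c("pop_births", "pop_deaths", "pop_disaster_deaths", "pop_service_deaths",
    "pov_change", "fi_change", "econ_change", "infl_change", "ghg_change",
    "clim_change", "ghg_emissions",
    "pop_dev", "access_water_pct", "access_electricity_pct",
    "access_sanitation_pct")
}

#' Extract one indicator series from a trajectory
#'
#' @param traj An `sd_trajectory`.
#' @param name Indicator (variable) name present in the trajectory.
#' @return An `indicator_series`: list with `indicator`, `years`, `values`.
#' @export
extract_indicator <- function(traj, name) {
  stopifnot(inherits(traj, "sd_trajectory"))
  if (!name %in% names(traj$series))
    stop(sprintf("unknown indicator '%s'; available: %s", name,
                 paste(names(traj$series), collapse = ", ")), call. = FALSE)
  structure(list(indicator = name, years = traj$times,
                 values = traj$series[[name]]),
            class = "indicator_series")
}

#' @export
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series> %s over %s-%s\n", x$indicator,
              min(x$years), max(x$years)))
  print(utils::head(data.frame(year = x$years, value = x$values), 5L))
  invisible(x)
}
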