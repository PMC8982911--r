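# Free constants of the Egypt SDG model.
#
# The published material gives loop signs, initial values and output
# trajectories but no rate equations, so every driven indicator follows a
# goal-seeking first-order structure dx/dt = (goal_x(t) - x)/tau_x plus signed
# coupling terms, with goal_x(t) switching between the current-path and the
# Vision-2030 goal lookups per scenario.  The constants below parameterise the
# goal knots, adjustment times, COVID-19 shock magnitudes and coupling
# sensitivities.  Shipped defaults are the calibrated optimum of
# [coviam_problem()]: goal-knot and shock parameters are fitted to the printed
# trajectory anchors; demographic rates and sensitivities are held at
# documented, field-plausible values (see the methods vignette for
# identifiability notes).

coviam_parameter_table <- function() {
  p <- function(name, value, lower, upper, units, description)
    list(name = name, value = value, lower = lower, upper = upper,
         units = units, description = description)
  entries <- list(
    # demography and scale
    p("population_2015", 9.3e7, 5e7, 1.5e8, "person",
      "2015 population level; cancels out of all fraction-valued indicators"),
    p("avg_birth_rate", 0.0227, 0, 0.06, "1/yr", "average crude birth rate"),
    p("avg_death_rate", 0.0058, 0, 0.03, "1/yr", "average crude death rate"),
    p("gdp_2015_total", 4.37, 0, 30, "%", "total GDP growth rate in 2015"),
    # goal-adjustment times
    p("pov_tau", 1, 0.5, 5, "yr", "poverty goal adjustment time"),
    p("fi_tau", 1, 0.5, 5, "yr", "food-insecurity goal adjustment time"),
    p("econ_tau", 1, 0.5, 5, "yr", "economic-strength goal adjustment time"),
    p("ghg_tau", 1, 0.5, 5, "yr", "GHG trend goal adjustment time"),
    p("infl_tau", 2, 0.5, 10, "yr", "inflation goal adjustment time"),
    p("clim_tau", 8, 1, 30, "yr", "climate-action score adjustment time"),
    # current-path goal knots
    p("pov_cur_2016", 27.8, 0, 100, "%", "poverty goal knot 2016 (pre-reform hold)"),
    p("pov_cur_2017", 32.539, 0, 100, "%", "poverty goal knot 2017 (reform-period peak)"),
    p("pov_cur_2019", 29.7421, 0, 100, "%", "poverty goal knot 2019"),
    p("pov_cur_2050", 28.5, 0, 100, "%", "poverty current-path goal knot 2050"),
    p("fi_cur_2019", 29, 0, 100, "%", "food-insecurity current-path knot 2019"),
    p("fi_cur_2050", 29, 0, 100, "%", "food-insecurity current-path knot 2050"),
    p("econ_cur_2018", 5.50005, 0, 30, "%", "GDP-growth current-path knot 2018"),
    p("econ_cur_2050", 6.0, 0, 30, "%", "GDP-growth current-path knot 2050"),
    p("ghg_cur_2019", 245, 0, 600, "Mt CO2-eq/yr", "GHG current-path knot 2019"),
    p("ghg_cur_2020", 239.385, 0, 600, "Mt CO2-eq/yr", "GHG current-path knot 2020"),
    p("ghg_cur_2021", 236, 0, 600, "Mt CO2-eq/yr", "GHG current-path knot 2021"),
    p("ghg_cur_2050", 250, 0, 600, "Mt CO2-eq/yr", "GHG current-path knot 2050"),
    p("infl_cur_2050", 9, 0, 40, "%", "inflation current-path knot 2050"),
    p("clim_cur_2050", 0.35, 0, 1, "dimensionless", "climate-score current-path knot 2050"),
    p("unemp_2019", 11, 0, 100, "%", "unemployment path knot 2019"),
    p("unemp_2030", 8, 0, 100, "%", "unemployment path knot 2030"),
    p("unemp_2050", 7, 0, 100, "%", "unemployment path knot 2050"),
    # Vision-2030 goal knots (active from 2022 under the policy scenario)
    p("pov_vis_2022", 28.6, 0, 100, "%", "poverty Vision goal knot 2022"),
    p("pov_vis_2029", 25.4878, 0, 100, "%", "poverty Vision goal knot 2029"),
    p("pov_vis_2049", 16.8052, 0, 100, "%", "poverty Vision goal knot 2049"),
    p("fi_vis_2022", 26, 0, 100, "%", "food-insecurity Vision knot 2022"),
    p("fi_vis_2029", 3.10571, 0, 100, "%", "food-insecurity Vision knot 2029"),
    p("fi_vis_2049", 0, 0, 100, "%", "food-insecurity Vision knot 2049 (full sufficiency)"),
    p("econ_vis_2022", 4.6, 0, 30, "%", "GDP-growth Vision knot 2022 (post-shock restart)"),
    p("econ_vis_2029", 11.7441, 0, 30, "%", "GDP-growth Vision knot 2029"),
    p("econ_vis_2049", 13.3220, 0, 30, "%", "GDP-growth Vision knot 2049"),
    p("ghg_vis_2022", 235, 0, 600, "Mt CO2-eq/yr", "GHG Vision knot 2022"),
    p("ghg_vis_2029", 194.745, 0, 600, "Mt CO2-eq/yr", "GHG Vision knot 2029 (Paris-aligned)"),
    p("ghg_vis_2049", 109.644, 0, 600, "Mt CO2-eq/yr", "GHG Vision knot 2049"),
    p("infl_vis_2022", 9.5, 0, 40, "%", "inflation Vision knot 2022"),
    p("infl_vis_2049", 5, 0, 40, "%", "inflation Vision knot 2049"),
    p("clim_vis_2049", 0.8, 0, 1, "dimensionless", "climate-score Vision knot 2049"),
    # COVID-19 shock magnitudes, window [2020, 2022) (GHG lockdown [2020, 2021))
    p("gdp_covid_level", 3.80498, 0, 10, "%", "contracted GDP growth level during the shock"),
    p("gdp_covid_weight", 1, 0, 1, "dimensionless", "suppression weight toward the contracted level"),
    p("covid_excess_mort_rate", 8e-4, 0, 0.01, "1/yr", "pandemic excess mortality addition"),
    p("ghg_lockdown_cut", 0.216544, 0, 0.6, "dimensionless", "lockdown fractional cut of GHG emissions in 2020"),
    p("fi_covid_stress", 0.5, 0, 5, "%/yr", "pandemic food-system stress on food insecurity"),
    # coupling sensitivities (signed couplings of the narrated feedback loops)
    p("gdp_pop_sens", 3, 0, 10, "pct-pt per unit", "GDP response to relative population deviation"),
    p("gdp_pp_sens", 5, 0, 20, "pct-pt per unit", "GDP response to purchasing-power deviation"),
    p("pp_infl_sens", 0.5, 0, 2, "1/pct-pt", "purchasing-power loss per inflation point (x100)"),
    p("infl_gdp_sens", 0.1, 0, 0.5, "1/yr", "inflation relief per GDP-growth point"),
    p("pov_infl_sens", 0.05, 0, 0.3, "1/yr", "poverty push per inflation point"),
    p("pov_fpa_sens", 0.03, 0, 0.3, "1/yr", "poverty push per food-price-anomaly point"),
    p("pov_mini_sens", 5, 0, 20, "pct-pt/yr per unit", "poverty relief per minimum-income index gain"),
    p("pov_pop_sens", 2, 0, 10, "pct-pt/yr per unit", "poverty response to relative population deviation"),
    p("fi_fpa_sens", 0.05, 0, 0.3, "1/yr", "food-insecurity push per food-price-anomaly point"),
    p("fpa_infl_sens", 0.8, 0, 3, "pct-pt per pct-pt", "food-price-anomaly response to inflation"),
    p("mini_gdp_sens", 0.004, 0, 0.05, "1/pct-pt", "minimum-income index gain per GDP-growth point"),
    p("dd_pov_sens", 2, 0, 50, "person/yr per pct-pt", "disaster deaths per poverty point above base"),
    p("dd_sp_sens", 3, 0, 50, "person/yr per pct-pt", "disaster deaths avoided per protection-coverage point"),
    p("sld_base", 2000, 0, 1e5, "person/yr", "base deaths from lack of basic services"),
    p("sld_acc_sens", 150, 0, 5000, "person/yr per pct-pt", "service-lack deaths avoided per access point"),
    p("sld_gs_sens", 100, 0, 5000, "person/yr per pct-pt", "service-lack deaths avoided per spending point"),
    p("amr_dd_sens", 0.5, 0, 5, "dimensionless", "mortality-rate weight of disaster deaths"),
    p("amr_sld_sens", 0.5, 0, 5, "dimensionless", "mortality-rate weight of service-lack deaths"),
    p("econ_unemp_sens", 0.5, 0, 5, "pct-pt/yr per unit", "economic-strength drag per relative unemployment excess"),
    p("acc_gdp_sens", 0.05, 0, 1, "pct-pt per pct-pt", "access gain per GDP-growth point"),
    p("acc_gs_sens", 0.1, 0, 2, "pct-pt per pct-pt", "access gain per spending point"),
    p("gs_gdp_sens", 0.3, 0, 3, "pct-pt per pct-pt", "essential-services spending gain per GDP-growth point"),
    p("sp_gdp_sens", 0.15, 0, 3, "dimensionless", "counter-cyclical protection-coverage response to GDP"),
    p("unemp_pop_sens", 0.3, 0, 10, "pct-pt per %", "unemployment response to relative population deviation"),
    p("tour_gdp_sens", 0.2, 0, 2, "pct-pt per pct-pt", "tourism-share response to GDP growth"),
    p("inf_unemp_sens", 0.5, 0, 3, "pct-pt per pct-pt", "informal-employment response to unemployment"),
    p("un_fi_sens", 0.15, 0, 1, "pct-pt per pct-pt", "undernourishment response to food insecurity"),
    p("chm_fi_sens", 0.2, 0, 1, "pct-pt per pct-pt", "child-malnutrition response to food insecurity"),
    p("ghg_clim_sens", 20, 0, 200, "Mt/yr per unit", "emission reduction per climate-score gain"),
    p("awareness_ramp", 0.01, 0, 0.05, "1/yr", "public-awareness improvement per year"),
    p("clim_aw_sens", 0.1, 0, 1, "1/yr per unit", "climate-score gain per awareness gain")
  )
  entries
}

#' Construct the model parameter set
#'
#' @param ... Named value overrides, e.g. `coviam_parameters(pov_tau = 2)`.
#'   Values outside a parameter's declared bounds raise an error naming it.
#' @return An object of class `coviam_parameters`: list with named numeric
#'   `values` plus aligned `lower`, `upper`, `units`, `description`.
#' @export
coviam_parameters <- function(...) {
  tab <- coviam_parameter_table()
  nms <- vapply(tab, `[[`, character(1), "name")
  par <- list(
    values = stats::setNames(vapply(tab, `[[`, numeric(1), "value"), nms),
    lower = stats::setNames(vapply(tab, `[[`, numeric(1), "lower"), nms),
    upper = stats::setNames(vapply(tab, `[[`, numeric(1), "upper"), nms),
    units = stats::setNames(vapply(tab, `[[`, character(1), "units"), nms),
    description = stats::setNames(vapply(tab, `[[`, character(1), "description"), nms)
  )
  class(par) <- "coviam_parameters"
  set_parameter_values(par, list(...))
}

#' Update parameter values (with bounds checking)
#'
#' @param params A [coviam_parameters()] object.
#' @param values Named list/vector of new values.
#' @return The updated object.
#' @export
set_parameter_values <- function(params, values) {
  stopifnot(inherits(params, "coviam_parameters"))
  values <- unlist(values)
  if (length(values) == 0L) return(params)
  unknown <- setdiff(names(values), names(params$values))
  if (length(unknown))
    stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (nm in names(values)) {
    v <- as.numeric(values[[nm]])
    if (!is.finite(v) || v < params$lower[[nm]] || v > params$upper[[nm]])
      stop(sprintf("parameter '%s' = %g outside bounds [%g, %g]",
                   nm, v, params$lower[[nm]], params$upper[[nm]]), call. = FALSE)
    params$values[[nm]] <- v
  }
  params
}

#' @export
print.coviam_parameters <- function(x, ...) {
  cat(sprintf("<coviam_parameters> %d constants\n", length(x$values)))
  utils::str(as.list(x$values), give.attr = FALSE, list.len = 10L)
  invisible(x)
}

#' Names of the calibration free parameters
#'
#' The shipped calibration problem frees the goal-knot levels and shock
#' magnitudes that are in (near) one-to-one correspondence with the printed
#' trajectory anchors; adjustment times and coupling sensitivities stay at
#' their documented defaults.
#'
#' @return Character vector of parameter names.
#' @export
coviam_free_parameters <- function() {
  c("pov_cur_2017", "pov_cur_2019", "pov_vis_2029", "pov_vis_2049",
    "fi_vis_2029",
    "econ_cur_2018", "gdp_covid_level", "econ_vis_2029", "econ_vis_2049",
    "ghg_cur_2020", "ghg_lockdown_cut", "ghg_vis_2029", "ghg_vis_2049")
}
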