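# Time-dependent interventions as pure overlays.
#
# A scenario is a named set of parameter overrides and input overlays (time
# functions applied to the model's exogenous shock inputs).  Applying a
# scenario never modifies the model specification, and applying it twice
# equals applying it once.

#' Time-function constructors
#'
#' `make_step(t0, t1, level)` evaluates to `level` on the half-open window
#' `[t0, t1)` and 0 elsewhere; `make_pulse` is a one-`width` step;
#' `make_ramp` rises linearly from 0 at `t0` with the given slope;
#' `make_constant` is constant; `make_lookup_fn` interpolates a lookup table.
#'
#' @param t0,t1 Window start (inclusive) and end (exclusive), `t0 < t1`.
#' @param level Value inside the window.
#' @return A function of time of class `sd_timefun`, with `kind` and `args`
#'   attributes for serialization.
#' @export
make_step <- function(t0, t1, level) {
  if (!(t0 < t1)) stop("step window requires t0 < t1", call. = FALSE)
  timefun("step", list(t0 = t0, t1 = t1, level = level),
          function(t) ifelse(t >= t0 & t < t1, level, 0))
}

#' @rdname make_step
#' @param width Pulse width in years.
#' @export
make_pulse <- function(t0, width, level) {
  if (!(width > 0)) stop("pulse width must be positive", call. = FALSE)
  timefun("pulse", list(t0 = t0, width = width, level = level),
          function(t) ifelse(t >= t0 & t < t0 + width, level, 0))
}

#' @rdname make_step
#' @param slope Slope per year after `t0`.
#' @export
make_ramp <- function(t0, slope) {
  timefun("ramp", list(t0 = t0, slope = slope),
          function(t) pmax(0, t - t0) * slope)
}

#' @rdname make_step
#' @export
make_constant <- function(level) {
  timefun("constant", list(level = level), function(t) rep(level, length(t)))
}

#' @rdname make_step
#' @param knots Data frame or list with `x` and `y` knot vectors.
#' @export
make_lookup_fn <- function(knots) {
  tbl <- sd_lookup("tf", knots$x, knots$y)
  timefun("lookup", list(x = tbl$x, y = tbl$y), function(t) apply_lookup(tbl, t))
}

timefun <- function(kind, args, fn) {
  structure(fn, kind = kind, args = args, class = c("sd_timefun", "function"))
}

#' @export
print.sd_timefun <- function(x, ...) {
  a <- attr(x, "args")
  cat(sprintf("<sd_timefun> %s(%s)\n", attr(x, "kind"),
              paste(names(a), unlist(a), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Construct a scenario
#'
#' @param name Scenario name.
#' @param parameters Named numeric parameter overrides.
#' @param overlays Named list of `sd_timefun` input overlays.
#' @param description Free-text description.
#' @return An object of class `sd_scenario`.
#' @export
scenario <- function(name, parameters = list(), overlays = list(),
                     description = "") {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, parameters = parameters, overlays = overlays,
                 description = description),
            class = "sd_scenario")
}

#' @export
print.sd_scenario <- function(x, ...) {
  cat(sprintf("<sd_scenario> %s: %d parameter override(s), %d overlay(s)\n",
              x$name, length(x$parameters), length(x$overlays)))
  invisible(x)
}

#' Simulation overrides implementing a scenario
#'
#' Pure: the returned list is a fresh object; calling twice gives the same
#' overrides (idempotent application).
#'
#' @param sc An [scenario()].
#' @return Named list suitable for `simulate_model(..., overrides = )`.
#' @export
scenario_overrides <- function(sc) {
  stopifnot(inherits(sc, "sd_scenario"))
  c(as.list(sc$parameters), sc$overlays)
}

#' Compose two scenarios
#'
#' Overrides/overlays are unioned; the same variable named by both scenarios
#' is an error (never silently last-wins).  The shipped headline scenario is
#' `compose_scenarios(covid19_scenario(p), vision2030_scenario(p))`: the COVID
#' window [2020, 2022) precedes the policy goal switch at 2022.
#'
#' @param a,b Scenarios.
#' @param name Name of the composite (default `"a+b"`).
#' @return A composed [scenario()].
#' @export
compose_scenarios <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  stopifnot(inherits(a, "sd_scenario"), inherits(b, "sd_scenario"))
  clash <- c(intersect(names(a$parameters), names(b$parameters)),
             intersect(names(a$overlays), names(b$overlays)))
  if (length(clash))
    stop(sprintf("scenarios '%s' and '%s' both override: %s", a$name, b$name,
                 paste(unique(clash), collapse = ", ")), call. = FALSE)
  scenario(name, c(a$parameters, b$parameters), c(a$overlays, b$overlays),
           description = paste(a$description, b$description, sep = " / "))
}

#' The Egyptian current-path scenario (no shock, no policy switch)
#'
#' @return An empty [scenario()] named `"baseline"`.
#' @export
baseline_scenario <- function() {
  scenario("baseline", description = "Egyptian current path, no pandemic shock")
}

#' The COVID-19 shock scenario
#'
#' Overlays active on the window \[2020, 2022): suppression of GDP growth
#' toward the contracted level, excess mortality, lockdown suppression of GHG
#' emissions in 2020 (the 2021 rebound is the suppression simply ending, so
#' economy-coupled emissions resume), and food-system stress.  With all shock
#' magnitudes set to 0 the scenario reproduces the baseline exactly.
#'
#' @param params A [coviam_parameters()]; shock magnitudes are read from it.
#' @return An [scenario()].
#' @export
covid19_scenario <- function(params = coviam_parameters()) {
  stopifnot(inherits(params, "coviam_parameters"))
  v <- params$values
  scenario(
    "covid19",
    overlays = list(
      covid_gdp_gap = make_step(2020, 2022, v[["gdp_covid_weight"]]),
      covid_excess_mort = make_step(2020, 2022, v[["covid_excess_mort_rate"]]),
      ghg_lockdown = make_step(2020, 2021, v[["ghg_lockdown_cut"]]),
      covid_food_stress = make_step(2020, 2022, v[["fi_covid_stress"]])
    ),
    description = "pandemic shock window 2020-2021"
  )
}

#' The Vision-2030 policy scenario
#'
#' From 2022 onward the effective goal levels switch to the Vision-2030
#' targets: poverty declining, food insecurity heading to full sufficiency,
#' GDP growth recovering, GHG on a Paris-aligned decline.
#'
#' @param params A [coviam_parameters()] (goal levels are part of the model
#'   build; the scenario only flips the switch).
#' @return An [scenario()].
#' @export
vision2030_scenario <- function(params = coviam_parameters()) {
  scenario("vision2030",
           overlays = list(vision_active = make_step(2022, 2051, 1)),
           description = "Vision-2030 policy goals from 2022")
}

#' The headline composite scenario: COVID-19 shock then Vision-2030 recovery
#'
#' @inheritParams covid19_scenario
#' @return An [scenario()] named `"covid19_vision2030"`.
#' @export
covid19_vision2030_scenario <- function(params = coviam_parameters()) {
  compose_scenarios(covid19_scenario(params), vision2030_scenario(params),
                    name = "covid19_vision2030")
}

#' Build and run the Egypt model under a named or explicit scenario
#'
#' @param scenario_name One of `"baseline"`, `"covid19"`, `"vision2030"`,
#'   `"covid19_vision2030"`, or an [scenario()] object.
#' @param params A [coviam_parameters()].
#' @param baseline An [egypt_baseline()].
#' @param config Optional simulation config (see [simulate_model()]).
#' @return An `sd_trajectory`.
#' @export
run_coviam <- function(scenario_name = "covid19_vision2030",
                       params = coviam_parameters(),
                       baseline = egypt_baseline(),
                       config = list()) {
  sc <- if (inherits(scenario_name, "sd_scenario")) scenario_name
  else switch(scenario_name,
              baseline = baseline_scenario(),
              covid19 = covid19_scenario(params),
              vision2030 = vision2030_scenario(params),
              covid19_vision2030 = covid19_vision2030_scenario(params),
              stop(sprintf("unknown scenario '%s'", scenario_name), call. = FALSE))
  spec <- build_coviam(baseline, params)
  config$scenario <- sc$name
  simulate_model(spec, overrides = scenario_overrides(sc), config = config)
}

#' Write / read scenario files
#'
#' Scenario files use the same structured-text dialect as the model files,
#' under a top-level `scenario:` key; overlays serialize by their time-function
#' kind and arguments.
#'
#' @param sc An [scenario()].
#' @param path File path.
#' @return `path` (write) or an [scenario()] (read).
#' @export
write_scenario_yaml <- function(sc, path) {
  stopifnot(inherits(sc, "sd_scenario"))
  doc <- list(scenario = list(
    name = sc$name, description = sc$description,
    parameters = sc$parameters,
    overlays = lapply(sc$overlays, function(tf)
      c(list(kind = attr(tf, "kind")), attr(tf, "args")))
  ))
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  doc <- yaml::read_yaml(path)$scenario
  overlays <- lapply(doc$overlays, function(o) {
    switch(o$kind,
           step = make_step(o$t0, o$t1, o$level),
           pulse = make_pulse(o$t0, o$width, o$level),
           ramp = make_ramp(o$t0, o$slope),
           constant = make_constant(o$level),
           lookup = make_lookup_fn(list(x = unlist(o$x), y = unlist(o$y))),
           stop(sprintf("unknown time-function kind '%s'", o$kind), call. = FALSE))
  })
  scenario(doc$name,
           parameters = if (is.null(doc$parameters)) list() else doc$parameters,
           overlays = overlays,
           description = if (is.null(doc$description)) "" else doc$description)
}
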