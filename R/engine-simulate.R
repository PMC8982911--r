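# Fixed-step simulation over calendar time.
#
# Integration is explicit Euler: S(t+dt) = S(t) + dt * (sum of inflows - sum
# of outflows), with flows and auxiliaries evaluated in topological order at
# the current time.  The default step is one year, matching annually reported
# indicators; "value in year Y" means the trajectory sample at t = Y.

#' Simulate a stock-flow model
#'
#' Runs explicit Euler integration of `spec` over its horizon (or the horizon
#' in `config`).  Identical inputs produce bitwise-identical trajectories.
#'
#' @param spec A valid [sd_model()]; [validate_model()] must report no
#'   violations, otherwise the run is refused.
#' @param overrides Named list keyed by declared variable names.  A numeric
#'   value overrides a parameter (or a stock's initial value, or pins an
#'   auxiliary/flow to a constant); a function of time (for instance a
#'   [make_step()] overlay) replaces the variable's value at every step.
#' @param config Optional list overriding `start`, `end`, `dt` and carrying a
#'   `scenario` label recorded in the trajectory metadata.
#' @return An `sd_trajectory`: list with `times` (strictly increasing years),
#'   `series` (named list, one numeric vector per stock/flow/auxiliary) and
#'   `metadata` (scenario, dt, seed, floor warnings).
#' @export
simulate_model <- function(spec, overrides = list(), config = list()) {
  stopifnot(inherits(spec, "sd_model"))
  v <- validate_model(spec)
  if (nrow(v) > 0L)
    stop(sprintf("refusing to simulate an invalid model (%d violation%s): %s",
                 nrow(v), if (nrow(v) > 1L) "s" else "",
                 paste(utils::head(v$message, 3L), collapse = "; ")),
         call. = FALSE)

  declared <- model_variable_names(spec)
  bad <- setdiff(names(overrides), declared)
  if (length(bad))
    stop(sprintf("overrides reference undeclared name(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)

  start <- if (!is.null(config$start)) config$start else spec$horizon$start
  end <- if (!is.null(config$end)) config$end else spec$horizon$end
  dt <- if (!is.null(config$dt)) config$dt else spec$horizon$dt
  n_steps <- (end - start) / dt
  if (abs(n_steps - round(n_steps)) > 1e-9 || n_steps <= 0)
    stop("config horizon must span a positive whole number of steps", call. = FALSE)
  n_steps <- as.integer(round(n_steps))
  times <- start + dt * (0:n_steps)

  eqs <- c(spec$flows, spec$auxiliaries)
  asts <- lapply(eqs, function(eq) sd_parse_expr(eq$expression))
  deps <- lapply(asts, expr_deps)
  ord <- topo_order(names(eqs), deps)

  is_fun <- vapply(overrides, is.function, logical(1))
  fun_ov <- overrides[is_fun]
  const_ov <- overrides[!is_fun]

  env <- new.env(parent = sd_ops_env(spec$lookups))
  for (p in names(spec$parameters)) assign(p, spec$parameters[[p]]$value, envir = env)
  for (p in intersect(names(const_ov), names(spec$parameters)))
    assign(p, as.numeric(const_ov[[p]]), envir = env)

  state <- vapply(spec$stocks, `[[`, numeric(1), "initial_value")
  for (s in intersect(names(const_ov), names(spec$stocks)))
    state[[s]] <- as.numeric(const_ov[[s]])

  var_names <- c(names(spec$stocks), names(eqs))
  series <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(var_names),
                   dimnames = list(NULL, var_names))
  non_neg <- vapply(spec$stocks, `[[`, logical(1), "non_negative")
  flow_src <- vapply(spec$flows, `[[`, character(1), "source")
  flow_snk <- vapply(spec$flows, `[[`, character(1), "sink")
  floored <- list()

  for (i in seq_len(n_steps + 1L)) {
    t_now <- times[[i]]
    assign("t", t_now, envir = env)
    for (s in names(state)) assign(s, state[[s]], envir = env)
    for (p in intersect(names(fun_ov), names(spec$parameters)))
      assign(p, as.numeric(fun_ov[[p]](t_now)), envir = env)

    rates <- numeric(length(eqs)); names(rates) <- names(eqs)
    for (nm in ord) {
      val <- if (nm %in% names(fun_ov)) as.numeric(fun_ov[[nm]](t_now))
      else if (nm %in% names(const_ov)) as.numeric(const_ov[[nm]])
      else eval(asts[[nm]], envir = env)
      if (!is.finite(val))
        stop(sprintf("non-finite value for '%s' at t = %s (step %d)", nm, t_now, i),
             call. = FALSE)
      rates[[nm]] <- val
      assign(nm, val, envir = env)
    }
    series[i, names(state)] <- state
    series[i, names(rates)] <- rates

    if (i <= n_steps) {
      for (s in names(state)) {
        net <- sum(rates[names(spec$flows)[flow_snk == s]]) -
          sum(rates[names(spec$flows)[flow_src == s]])
        new_val <- state[[s]] + dt * net
        if (non_neg[[s]] && new_val < 0) {
          floored[[length(floored) + 1L]] <- list(stock = s, year = t_now + dt)
          new_val <- 0
        }
        if (!is.finite(new_val))
          stop(sprintf("non-finite value for stock '%s' at t = %s", s, t_now + dt),
               call. = FALSE)
        state[[s]] <- new_val
      }
    }
  }

  floor_df <- if (length(floored)) {
    data.frame(stock = vapply(floored, `[[`, character(1), "stock"),
               year = vapply(floored, `[[`, numeric(1), "year"))
  } else data.frame(stock = character(0), year = numeric(0))
  if (nrow(floor_df) > 0L)
    warning(sprintf("non-negative stock(s) floored at 0: %s",
                    paste(unique(floor_df$stock), collapse = ", ")), call. = FALSE)

  structure(
    list(times = times,
         series = stats::setNames(lapply(var_names, function(v) unname(series[, v])),
                                  var_names),
         metadata = list(model = spec$name,
                         scenario = if (!is.null(config$scenario)) config$scenario else "baseline",
                         dt = dt,
                         seed = if (!is.null(config$seed)) config$seed else NA_integer_,
                         floored = floor_df)),
    class = "sd_trajectory"
  )
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("<sd_trajectory> %s / %s: %d variables over %s-%s (dt = %s)\n",
              x$metadata$model, x$metadata$scenario, length(x$series),
              min(x$times), max(x$times), x$metadata$dt))
  invisible(x)
}

#' @export
as.data.frame.sd_trajectory <- function(x, ...) {
  cbind(data.frame(year = x$times), as.data.frame(x$series, optional = TRUE))
}

#' Value of one trajectory variable in a given year
#'
#' @param traj An `sd_trajectory`.
#' @param name Variable name.
#' @param year Calendar year(s); must lie on the simulated grid.
#' @return Numeric value(s).
#' @export
trajectory_value <- function(traj, name, year) {
  stopifnot(inherits(traj, "sd_trajectory"))
  if (!name %in% names(traj$series))
    stop(sprintf("variable '%s' not present in trajectory", name), call. = FALSE)
  idx <- match(year, traj$times)
  if (anyNA(idx))
    stop(sprintf("year(s) %s not on the simulated grid",
                 paste(year[is.na(idx)], collapse = ", ")), call. = FALSE)
  traj$series[[name]][idx]
}
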