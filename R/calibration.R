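# Trajectory-anchor calibration.
#
# An anchor is a printed (indicator, year, value) point the calibrated model
# must pass through.  The objective is the weighted sum of squared residuals
# of one deterministic simulation against the anchor set; fitting is
# derivative-free bounded local search (Nelder-Mead simplex on a logistic
# transform of the box constraints) from a seeded multi-start.

#' Construct an anchor set
#'
#' @param indicator Character vector of indicator names.
#' @param year Calendar years (within the simulation horizon).
#' @param value Target values.
#' @param weight Non-negative weights (default 1).
#' @param tolerance Positive per-anchor absolute tolerances used for the
#'   convergence flag.
#' @param provenance Free-text provenance tags.
#' @return Data frame of class `anchor_set`.
#' @export
anchor_set <- function(indicator, year, value, weight = 1, tolerance = Inf,
                       provenance = "") {
  out <- data.frame(indicator = as.character(indicator), year = as.numeric(year),
                    value = as.numeric(value), weight = as.numeric(weight),
                    tolerance = as.numeric(tolerance),
                    provenance = as.character(provenance),
                    stringsAsFactors = FALSE)
  if (any(out$weight < 0)) stop("anchor weights must be >= 0", call. = FALSE)
  if (any(!(out$tolerance > 0))) stop("anchor tolerances must be > 0", call. = FALSE)
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' The packaged results anchors
#'
#' The printed 2015-2050 trajectory values for the four headline indicators,
#' with absolute tolerances derived from the source's own precision language:
#' exactly printed values carry a relative 1% tolerance, values qualified as
#' "around"/"approximately"/"roughly" carry 5%.
#'
#' @return An [anchor_set()] (14 entries).
#' @export
paper_anchor_set <- function() {
  path <- system.file("extdata", "anchors_results.csv", package = "coviam",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  anchor_set(tab$indicator, tab$year, tab$value, tab$weight, tab$tolerance,
             tab$provenance)
}

#' Calibration objective
#'
#' @param values Named numeric vector of free-parameter values.
#' @param anchors An [anchor_set()].
#' @param builder Function mapping a named value vector to an
#'   `sd_trajectory` (see [make_coviam_builder()]).
#' @return Non-negative weighted sum of squared residuals; a failed
#'   simulation yields a large finite penalty with attribute `failed = TRUE`.
#' @export
calibration_objective <- function(values, anchors, builder) {
  traj <- tryCatch(suppressWarnings(builder(values)), error = function(e) e)
  if (inherits(traj, "error"))
    return(structure(1e12, failed = TRUE, message = conditionMessage(traj)))
  sim <- vapply(seq_len(nrow(anchors)), function(i)
    trajectory_value(traj, anchors$indicator[[i]], anchors$year[[i]]), numeric(1))
  sum(anchors$weight * (sim - anchors$value)^2)
}

#' Simulated values and residuals at the anchors
#'
#' @inheritParams calibration_objective
#' @return The anchor set with `simulated`, `residual` and `within_tol`
#'   columns appended.
#' @export
anchor_residuals <- function(values, anchors, builder) {
  traj <- suppressWarnings(builder(values))
  out <- as.data.frame(anchors)
  out$simulated <- vapply(seq_len(nrow(out)), function(i)
    trajectory_value(traj, out$indicator[[i]], out$year[[i]]), numeric(1))
  out$residual <- out$simulated - out$value
  out$within_tol <- abs(out$residual) <= out$tolerance
  out
}

#' Define a calibration problem
#'
#' @param builder Trajectory builder, a function of a named value vector.
#' @param free Names of the free parameters.
#' @param lower,upper Named finite bounds for the free parameters.
#' @param start Named default/start values (within bounds).
#' @param anchors An [anchor_set()].
#' @param seed Integer seed for the multi-start.
#' @param restarts Number of search starts (the first is `start`).
#' @param maxit Simplex iterations per start.
#' @return List of class `calibration_problem`.
#' @export
calibration_problem <- function(builder, free, lower, upper, start, anchors,
                                seed = 1L, restarts = 8L, maxit = 300L) {
  stopifnot(is.function(builder), inherits(anchors, "anchor_set"))
  free <- as.character(free)
  lower <- lower[free]; upper <- upper[free]; start <- start[free]
  if (length(free)) {
    stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper),
              all(start >= lower & start <= upper))
  }
  structure(list(builder = builder, free = free, lower = lower, upper = upper,
                 start = start, anchors = anchors, seed = as.integer(seed),
                 restarts = as.integer(restarts), maxit = as.integer(maxit)),
            class = "calibration_problem")
}

#' Calibrate free parameters to an anchor set
#'
#' Derivative-free bounded local search: Nelder-Mead on a logistic transform
#' of the box, restarted from `restarts` seeded points (the provided start
#' first, the rest drawn uniformly in the box).  Deterministic for a fixed
#' seed.
#'
#' @param problem A [calibration_problem()].
#' @return List of class `calibration_result`: fitted `par`, `objective`,
#'   per-anchor `residuals`, `converged` (all residuals within their
#'   tolerances), `iterations`, `evaluations`, `seed`.
#' @export
calibrate <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  free <- problem$free
  if (length(free) == 0L) {
    par <- numeric(0)
    obj <- calibration_objective(par, problem$anchors, problem$builder)
    res <- anchor_residuals(par, problem$anchors, problem$builder)
    return(structure(list(par = par, objective = as.numeric(obj),
                          residuals = res, converged = all(res$within_tol),
                          iterations = 0L, evaluations = 1L,
                          seed = problem$seed),
                     class = "calibration_result"))
  }
  lo <- problem$lower; hi <- problem$upper
  to_z <- function(x) stats::qlogis(pmin(pmax((x - lo) / (hi - lo), 1e-6), 1 - 1e-6))
  from_z <- function(z) lo + (hi - lo) * stats::plogis(z)
  evals <- 0L
  fn <- function(z) {
    evals <<- evals + 1L
    x <- stats::setNames(from_z(z), free)
    as.numeric(calibration_objective(x, problem$anchors, problem$builder))
  }

  set.seed(problem$seed)
  starts <- list(problem$start)
  if (problem$restarts > 1L) {
    for (i in seq_len(problem$restarts - 1L)) {
      starts[[i + 1L]] <- stats::setNames(
        lo + (hi - lo) * stats::runif(length(free)), free)
    }
  }
  best <- NULL; total_iter <- 0L
  for (st in starts) {
    fit <- stats::optim(to_z(st), fn, method = "Nelder-Mead",
                        control = list(maxit = problem$maxit, reltol = 1e-12))
    total_iter <- total_iter + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the winner
  fit <- stats::optim(best$par, fn, method = "Nelder-Mead",
                      control = list(maxit = problem$maxit, reltol = 1e-12))
  total_iter <- total_iter + fit$counts[["function"]]
  if (fit$value < best$value) best <- fit

  par <- stats::setNames(from_z(best$par), free)
  res <- anchor_residuals(par, problem$anchors, problem$builder)
  structure(list(par = par, objective = best$value, residuals = res,
                 converged = all(res$within_tol),
                 iterations = total_iter, evaluations = evals,
                 seed = problem$seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> objective = %.6g, converged = %s (%d evaluations)\n",
              x$objective, x$converged, x$evaluations))
  print(x$residuals[, c("indicator", "year", "value", "simulated", "residual",
                        "within_tol")])
  invisible(x)
}

#' Generate synthetic anchors from a model run
#'
#' Simulated indicator values plus independent Gaussian noise of the stated
#' spread; seeded and reproducible.  Used for parameter-recovery testing.
#'
#' @inheritParams calibration_objective
#' @param indicator Indicator names (recycled against `years`).
#' @param years Anchor years (within the horizon).
#' @param noise_sd Non-negative noise standard deviation.
#' @param seed Integer seed.
#' @return An [anchor_set()] with provenance `"synthetic"`.
#' @export
synth_anchors <- function(builder, values, indicator, years, noise_sd = 0,
                          seed = 1L) {
  stopifnot(noise_sd >= 0)
  grid <- data.frame(indicator = indicator, year = years,
                     stringsAsFactors = FALSE)
  traj <- suppressWarnings(builder(values))
  sim <- vapply(seq_len(nrow(grid)), function(i)
    trajectory_value(traj, grid$indicator[[i]], grid$year[[i]]), numeric(1))
  set.seed(seed)
  noisy <- sim + stats::rnorm(length(sim), sd = noise_sd)
  anchor_set(grid$indicator, grid$year, noisy, weight = 1,
             tolerance = pmax(noise_sd, 1e-6) * 3 + 1e-6,
             provenance = "synthetic")
}

#' Builder for the Egypt model calibration
#'
#' Returns a closure mapping named free-parameter values (merged into
#' `params`) to one deterministic trajectory of `scenario_name`.
#'
#' @param params Base [coviam_parameters()].
#' @param baseline An [egypt_baseline()].
#' @param scenario_name Scenario to simulate (default the headline
#'   `"covid19_vision2030"`).
#' @return Function `(values) -> sd_trajectory`.
#' @export
make_coviam_builder <- function(params = coviam_parameters(),
                                baseline = egypt_baseline(),
                                scenario_name = "covid19_vision2030") {
  force(params); force(baseline); force(scenario_name)
  function(values = numeric(0)) {
    p <- set_parameter_values(params, values)
    run_coviam(scenario_name, params = p, baseline = baseline)
  }
}

#' The shipped Egypt calibration problem
#'
#' Frees the goal-knot/shock parameters of [coviam_free_parameters()] with
#' their declared bounds, anchored to [paper_anchor_set()], under the
#' headline COVID + Vision-2030 scenario.
#'
#' @inheritParams make_coviam_builder
#' @param seed Integer seed.
#' @param restarts,maxit Search budget (see [calibration_problem()]).
#' @return A [calibration_problem()].
#' @export
coviam_problem <- function(params = coviam_parameters(),
                           baseline = egypt_baseline(),
                           seed = 1L, restarts = 4L, maxit = 300L) {
  free <- coviam_free_parameters()
  calibration_problem(
    builder = make_coviam_builder(params, baseline),
    free = free,
    lower = params$lower[free], upper = params$upper[free],
    start = params$values[free],
    anchors = paper_anchor_set(),
    seed = seed, restarts = restarts, maxit = maxit
  )
}
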