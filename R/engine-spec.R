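# Declarative stock-flow model representation.
#
# A model is a closed set of named variables: stocks (state, changed only by
# flows), flows (rates filling/draining stocks, may be negative), auxiliaries
# (memoryless algebraic variables), lookup tables (piecewise-linear table
# functions) and scalar parameters.  Feedback must pass through a stock: the
# auxiliary/flow dependency graph within one time step has to be acyclic.

#' Define a stock (accumulating state variable)
#'
#' @param name Variable name (unique across the model).
#' @param initial_value Finite starting value at the first simulated year.
#' @param units Free-text units label.
#' @param non_negative If `TRUE` the simulator floors the stock at 0 (with a
#'   logged warning) instead of letting it go negative.
#' @return An object of class `sd_stock`.
#' @export
sd_stock <- function(name, initial_value, units = "", non_negative = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, initial_value = as.numeric(initial_value),
         units = units, non_negative = isTRUE(non_negative)),
    class = "sd_stock"
  )
}

#' Define a flow between two stocks (or across the model boundary)
#'
#' Either endpoint may be the pseudo-stock `"CLOUD"`, marking a source or
#' drain outside the model boundary.  A flow's rate may evaluate negative.
#'
#' @param name Variable name.
#' @param expression Rate expression in the engine grammar (see
#'   [eval_expression()]).
#' @param source Stock drained by the flow, or `"CLOUD"`.
#' @param sink Stock filled by the flow, or `"CLOUD"`.
#' @param signs Named numeric vector of +1/-1 influence-sign annotations, one
#'   per variable referenced by `expression`; used by [extract_causal_graph()].
#' @param units Free-text units label.
#' @return An object of class `sd_flow`.
#' @export
sd_flow <- function(name, expression, source = "CLOUD", sink = "CLOUD",
                    signs = NULL, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, expression = expression, source = source, sink = sink,
         signs = normalize_signs(signs), units = units),
    class = "sd_flow"
  )
}

#' Define an auxiliary (converter) variable
#'
#' @inheritParams sd_flow
#' @return An object of class `sd_aux`.
#' @export
sd_aux <- function(name, expression, signs = NULL, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, expression = expression, signs = normalize_signs(signs),
         units = units),
    class = "sd_aux"
  )
}

#' Define a piecewise-linear lookup table
#'
#' @param name Table name, referenced as `lookup(name, x)` in expressions.
#' @param x Strictly increasing knot abscissae.
#' @param y Knot ordinates (same length as `x`).
#' @return An object of class `sd_lookup`.
#' @export
sd_lookup <- function(name, x, y) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            length(x) == length(y), length(x) >= 1L)
  structure(list(name = name, x = as.numeric(x), y = as.numeric(y)),
            class = "sd_lookup")
}

normalize_signs <- function(signs) {
  if (is.null(signs) || length(signs) == 0L) return(NULL)
  s <- vapply(signs, as.numeric, numeric(1))
  if (is.null(names(signs)) || any(!nzchar(names(signs))))
    stop("sign annotations must be named by the referenced variable")
  names(s) <- names(signs)
  s
}

#' Assemble a stock-flow model specification
#'
#' @param name Model name.
#' @param horizon List with elements `start`, `end` (calendar years) and `dt`
#'   (step, in years); `(end - start)/dt` must be a whole number of steps.
#' @param stocks List of [sd_stock()] objects.
#' @param flows List of [sd_flow()] objects.
#' @param auxiliaries List of [sd_aux()] objects.
#' @param lookups List of [sd_lookup()] objects.
#' @param parameters Named list; each element either a bare numeric or a list
#'   `list(value=, units=)`.
#' @return An object of class `sd_model`.  Use [validate_model()] to check the
#'   specification invariants.
#' @export
sd_model <- function(name, horizon = list(start = 2015, end = 2050, dt = 1),
                     stocks = list(), flows = list(), auxiliaries = list(),
                     lookups = list(), parameters = list()) {
  named_by <- function(xs) {
    if (length(xs) == 0L) return(stats::setNames(list(), character(0)))
    stats::setNames(xs, vapply(xs, `[[`, character(1), "name"))
  }
  params <- lapply(parameters, function(p) {
    if (is.list(p)) list(value = as.numeric(p$value),
                         units = if (is.null(p$units)) "" else p$units)
    else list(value = as.numeric(p), units = "")
  })
  structure(
    list(name = name,
         horizon = list(start = as.numeric(horizon$start),
                        end = as.numeric(horizon$end),
                        dt = as.numeric(horizon$dt)),
         stocks = named_by(stocks), flows = named_by(flows),
         auxiliaries = named_by(auxiliaries), lookups = named_by(lookups),
         parameters = params),
    class = "sd_model"
  )
}

#' @export
print.sd_model <- function(x, ...) {
  cat(sprintf(
    "<sd_model> %s: %d stocks, %d flows, %d auxiliaries, %d lookups, %d parameters\n",
    x$name, length(x$stocks), length(x$flows), length(x$auxiliaries),
    length(x$lookups), length(x$parameters)))
  cat(sprintf("  horizon: %s to %s, dt = %s years\n",
              x$horizon$start, x$horizon$end, x$horizon$dt))
  invisible(x)
}

model_variable_names <- function(spec) {
  c(names(spec$stocks), names(spec$flows), names(spec$auxiliaries),
    names(spec$parameters))
}

#' Names of the flows filling and draining a stock
#'
#' @param spec An [sd_model()].
#' @param stock Stock name.
#' @return List with character vectors `inflows` and `outflows`.
#' @export
stock_flows <- function(spec, stock) {
  fl <- spec$flows
  list(
    inflows = names(fl)[vapply(fl, function(f) identical(f$sink, stock), logical(1))],
    outflows = names(fl)[vapply(fl, function(f) identical(f$source, stock), logical(1))]
  )
}

#' Validate a model specification
#'
#' Checks every `sd_model` invariant: unique names, declared references,
#' acyclicity of the within-step auxiliary/flow dependency graph, a well-formed
#' horizon, finite initial values, legal flow endpoints and strictly increasing
#' lookup knots.  Violations are returned as data, not thrown.
#'
#' @param spec An [sd_model()].
#' @return A data frame of class `sd_validation` with columns `rule`,
#'   `variable` and `message`; zero rows iff the specification is valid.
#' @export
validate_model <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  rules <- character(0); vars <- character(0); msgs <- character(0)
  add <- function(rule, variable, message) {
    rules <<- c(rules, rule); vars <<- c(vars, variable); msgs <<- c(msgs, message)
  }

  all_names <- model_variable_names(spec)
  lk_names <- names(spec$lookups)
  dup <- unique(c(all_names[duplicated(all_names)],
                  intersect(all_names, lk_names),
                  lk_names[duplicated(lk_names)]))
  for (d in dup) add("duplicate-name", d, sprintf("name '%s' declared more than once", d))

  h <- spec$horizon
  if (!(is.finite(h$start) && is.finite(h$end) && h$start < h$end))
    add("bad-horizon", "horizon", "start_year must be strictly before end_year")
  if (!(is.finite(h$dt) && h$dt > 0))
    add("bad-horizon", "horizon", "dt must be positive")
  else if (is.finite(h$start) && is.finite(h$end)) {
    steps <- (h$end - h$start) / h$dt
    if (abs(steps - round(steps)) > 1e-9)
      add("bad-horizon", "horizon",
          "(end_year - start_year)/dt must be a whole number of steps")
  }

  for (s in spec$stocks) {
    if (!is.finite(s$initial_value))
      add("bad-initial", s$name, sprintf("stock '%s' has non-finite initial value", s$name))
    else if (s$non_negative && s$initial_value < 0)
      add("bad-initial", s$name,
          sprintf("non-negative stock '%s' has negative initial value", s$name))
  }

  for (lk in spec$lookups) {
    if (length(lk$x) < 1L)
      add("bad-lookup", lk$name, sprintf("lookup '%s' has no knots", lk$name))
    else if (length(lk$x) > 1L && any(diff(lk$x) <= 0))
      add("bad-lookup", lk$name,
          sprintf("lookup '%s' knot x values must be strictly increasing", lk$name))
    if (any(!is.finite(lk$y)))
      add("bad-lookup", lk$name, sprintf("lookup '%s' has non-finite knot values", lk$name))
  }

  eqs <- c(spec$flows, spec$auxiliaries)
  deps <- vector("list", length(eqs)); names(deps) <- names(eqs)
  for (eq in eqs) {
    d <- tryCatch(expr_deps(sd_parse_expr(eq$expression)), error = function(e) e)
    if (inherits(d, "error")) {
      add("syntax", eq$name,
          sprintf("expression for '%s' does not parse in the engine grammar: %s",
                  eq$name, conditionMessage(d)))
      deps[[eq$name]] <- list(vars = character(0), lookups = character(0))
      next
    }
    deps[[eq$name]] <- d
    for (v in setdiff(d$vars, c(all_names, "t")))
      add("undeclared-reference", v,
          sprintf("expression for '%s' references undeclared name '%s'", eq$name, v))
    for (v in setdiff(d$lookups, lk_names))
      add("undeclared-reference", v,
          sprintf("expression for '%s' references unknown lookup table '%s'", eq$name, v))
  }

  for (f in spec$flows) {
    for (endp in c(f$source, f$sink))
      if (!identical(endp, "CLOUD") && !endp %in% names(spec$stocks))
        add("bad-endpoint", f$name,
            sprintf("flow '%s' endpoint '%s' is neither a stock nor CLOUD", f$name, endp))
  }

  # algebraic (within-step) cycles among flows/auxiliaries
  cyc <- find_algebraic_cycles(names(eqs), deps)
  for (members in cyc)
    add("algebraic-cycle", paste(sort(members), collapse = ", "),
        sprintf("circular within-step dependency among {%s}; feedback must pass through a stock",
                paste(sort(members), collapse = ", ")))

  structure(data.frame(rule = rules, variable = vars, message = msgs,
                       stringsAsFactors = FALSE),
            class = c("sd_validation", "data.frame"))
}

# Kahn's algorithm over the flow/aux dependency graph; returns list of cycles
# (as character vectors of member names), empty list if acyclic.
find_algebraic_cycles <- function(eq_names, deps) {
  if (length(eq_names) == 0L) return(list())
  indeg <- stats::setNames(integer(length(eq_names)), eq_names)
  out_edges <- stats::setNames(vector("list", length(eq_names)), eq_names)
  for (nm in eq_names) {
    d <- intersect(deps[[nm]]$vars, eq_names)
    indeg[[nm]] <- length(d)
    for (v in d) out_edges[[v]] <- c(out_edges[[v]], nm)
  }
  queue <- names(indeg)[indeg == 0L]
  done <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; done <- c(done, v)
    for (w in out_edges[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  rest <- setdiff(eq_names, done)
  if (length(rest) == 0L) return(list())
  # split the remainder into strongly connected components (small graphs:
  # simple repeated reachability is adequate)
  reach <- function(start, nodes) {
    seen <- start; frontier <- start
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(out_edges[frontier]), nodes), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    seen
  }
  comps <- list()
  nodes <- rest
  while (length(nodes)) {
    v <- nodes[[1L]]
    fwd <- reach(v, nodes)
    bwd <- nodes[vapply(nodes, function(u) v %in% reach(u, nodes), logical(1))]
    comp <- intersect(fwd, bwd)
    if (length(comp) == 0L) comp <- v
    comps[[length(comps) + 1L]] <- comp
    nodes <- setdiff(nodes, comp)
  }
  comps[vapply(comps, length, integer(1)) > 1L |
          vapply(comps, function(cc) cc[[1L]] %in% unlist(out_edges[cc]), logical(1))]
}

# topological evaluation order of flows + auxiliaries (assumes acyclic)
topo_order <- function(eq_names, deps) {
  order <- character(0)
  placed <- stats::setNames(logical(length(eq_names)), eq_names)
  remaining <- eq_names
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      d <- intersect(deps[[nm]]$vars, eq_names)
      all(placed[d])
    }, logical(1))]
    if (length(ready) == 0L) stop("internal error: dependency cycle in topo_order")
    order <- c(order, ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  order
}
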