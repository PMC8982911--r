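# Closed expression grammar.
#
# Expressions are parsed with the R parser and the resulting syntax tree is
# validated against a fixed whitelist: the four arithmetic operators,
# parentheses, comparisons (inside if_then_else conditions), min, max, abs,
# if_then_else(cond, a, b), lookup(table, x), numeric literals, declared
# variable names and the time symbol `t`.  Evaluation happens in a sealed
# environment that contains only those operators, so nothing outside the
# grammar is reachable; division is checked for zero.

SD_ALLOWED_CALLS <- c("+", "-", "*", "/", "(", "min", "max", "abs",
                      "if_then_else", "lookup",
                      ">", ">=", "<", "<=", "==")

#' Parse an expression of the engine grammar
#'
#' @param text Expression text, e.g. `"max(0, goal - current)/at"`.
#' @return A validated abstract syntax tree (the first argument of `lookup()`
#'   is rewritten to a string constant).
#' @keywords internal
sd_parse_expr <- function(text) {
  ast <- tryCatch(str2lang(text), error = function(e)
    stop(sprintf("cannot parse expression '%s': %s", text, conditionMessage(e)),
         call. = FALSE))
  validate_ast(ast, text)
}

validate_ast <- function(node, text) {
  if (is.numeric(node) || is.character(node)) return(node)
  if (is.symbol(node)) return(node)
  if (is.call(node)) {
    head <- node[[1L]]
    if (!is.symbol(head) || !(as.character(head) %in% SD_ALLOWED_CALLS))
      stop(sprintf("'%s' is not part of the expression grammar (in '%s')",
                   deparse(head), text), call. = FALSE)
    fn <- as.character(head)
    if (fn == "lookup") {
      if (length(node) != 3L)
        stop(sprintf("lookup() takes exactly two arguments (in '%s')", text),
             call. = FALSE)
      tbl <- node[[2L]]
      if (is.symbol(tbl)) node[[2L]] <- as.character(tbl)
      else if (!is.character(tbl))
        stop(sprintf("first argument of lookup() must be a table name (in '%s')", text),
             call. = FALSE)
      node[[3L]] <- validate_ast(node[[3L]], text)
      return(node)
    }
    for (i in seq_along(node)[-1L]) node[[i]] <- validate_ast(node[[i]], text)
    return(node)
  }
  stop(sprintf("unsupported token '%s' in expression '%s'", deparse(node), text),
       call. = FALSE)
}

# names an AST references: model variables (vars) and lookup tables (lookups)
expr_deps <- function(ast) {
  vars <- character(0); lks <- character(0)
  walk <- function(node) {
    if (is.symbol(node)) {
      vars <<- c(vars, as.character(node))
    } else if (is.call(node)) {
      if (identical(as.character(node[[1L]]), "lookup")) {
        lks <<- c(lks, node[[2L]])
        walk(node[[3L]])
      } else {
        for (i in seq_along(node)[-1L]) walk(node[[i]])
      }
    }
  }
  walk(ast)
  list(vars = setdiff(unique(vars), "t"), lookups = unique(lks))
}

# Sealed operator environment.  `lookups` is a named list of sd_lookup tables.
sd_ops_env <- function(lookups = list()) {
  ops <- new.env(parent = emptyenv())
  ops$`+` <- function(e1, e2) if (missing(e2)) e1 else base::`+`(e1, e2)
  ops$`-` <- function(e1, e2) if (missing(e2)) -e1 else base::`-`(e1, e2)
  ops$`*` <- base::`*`
  ops$`/` <- function(e1, e2) {
    if (any(e2 == 0)) stop("division by zero", call. = FALSE)
    base::`/`(e1, e2)
  }
  ops$`(` <- function(x) x
  ops$min <- base::min
  ops$max <- base::max
  ops$abs <- base::abs
  ops$`>` <- base::`>`
  ops$`>=` <- base::`>=`
  ops$`<` <- base::`<`
  ops$`<=` <- base::`<=`
  ops$`==` <- base::`==`
  ops$if_then_else <- function(cond, a, b) {
    if (is.logical(cond)) { if (isTRUE(cond)) a else b }
    else if (cond != 0) a else b
  }
  ops$lookup <- function(nm, x) {
    tbl <- lookups[[nm]]
    if (is.null(tbl)) stop(sprintf("unknown lookup table '%s'", nm), call. = FALSE)
    apply_lookup(tbl, x)
  }
  ops
}

#' Evaluate an expression of the engine grammar
#'
#' Deterministically evaluates `expr` against a variable binding; the binding
#' is never modified.  The time symbol `t` is bound to `t`.
#'
#' @param expr Expression text.
#' @param env Named list (or named numeric vector) binding every variable name
#'   referenced by `expr`.
#' @param t Calendar time bound to the symbol `t`.
#' @param lookups Named list of [sd_lookup()] tables available to `lookup()`.
#' @return A single numeric value.
#' @examples
#' eval_expression("max(0, goal - current)/at", list(goal = 5, current = 3, at = 2))
#' @export
eval_expression <- function(expr, env = list(), t = 0, lookups = list()) {
  ast <- sd_parse_expr(expr)
  d <- expr_deps(ast)
  vals <- as.list(env)
  unbound <- setdiff(d$vars, names(vals))
  if (length(unbound))
    stop(sprintf("unbound name(s) in expression '%s': %s",
                 expr, paste(unbound, collapse = ", ")), call. = FALSE)
  missing_lk <- setdiff(d$lookups, names(lookups))
  if (length(missing_lk))
    stop(sprintf("unknown lookup table(s) in expression '%s': %s",
                 expr, paste(missing_lk, collapse = ", ")), call. = FALSE)
  vals$t <- t
  e <- list2env(vals, parent = sd_ops_env(lookups))
  out <- tryCatch(eval(ast, envir = e), error = function(err)
    stop(sprintf("error evaluating '%s': %s", expr, conditionMessage(err)),
         call. = FALSE))
  as.numeric(out)
}

#' Interpolate a lookup table
#'
#' Piecewise-linear interpolation between knots, clamped to the endpoint
#' values outside the knot range.
#'
#' @param table An [sd_lookup()].
#' @param x Query abscissa (vectorised).
#' @return Interpolated value(s).
#' @export
apply_lookup <- function(table, x) {
  stopifnot(inherits(table, "sd_lookup"))
  if (length(table$x) == 0L) stop("empty lookup table", call. = FALSE)
  if (length(table$x) == 1L) return(rep(table$y, length(x)))
  stats::approx(table$x, table$y, xout = x, method = "linear", rule = 2)$y
}
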