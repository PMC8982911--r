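# Structured-text (YAML) model specification files.
#
# Schema: top-level keys `name`, `horizon` (start/end/dt), `stocks`, `flows`,
# `auxiliaries`, `lookups`, `parameters`.  Files round-trip load -> save ->
# load identically.

#' Write a model specification to a YAML file
#'
#' @param spec An [sd_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "sd_model"))
  strip <- function(x) { x <- unclass(x); x[["name"]] <- NULL; x }
  doc <- list(
    name = spec$name,
    horizon = spec$horizon,
    parameters = spec$parameters,
    stocks = lapply(unname(spec$stocks), unclass),
    flows = lapply(unname(spec$flows), function(f) {
      f <- unclass(f)
      f$signs <- if (is.null(f$signs)) NULL else as.list(f$signs)
      f
    }),
    auxiliaries = lapply(unname(spec$auxiliaries), function(a) {
      a <- unclass(a)
      a$signs <- if (is.null(a$signs)) NULL else as.list(a$signs)
      a
    }),
    lookups = lapply(unname(spec$lookups), unclass)
  )
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a model specification from a YAML file
#'
#' @param path File written by [write_model_yaml()] (or hand-authored to the
#'   same schema).
#' @return An [sd_model()].
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  as_signs <- function(s) if (is.null(s) || length(s) == 0L) NULL else unlist(s)
  sd_model(
    name = doc$name,
    horizon = doc$horizon,
    parameters = if (is.null(doc$parameters)) list() else doc$parameters,
    stocks = lapply(doc$stocks, function(s)
      sd_stock(s$name, s$initial_value, units = if (is.null(s$units)) "" else s$units,
               non_negative = isTRUE(s$non_negative))),
    flows = lapply(doc$flows, function(f)
      sd_flow(f$name, f$expression, source = f$source, sink = f$sink,
              signs = as_signs(f$signs), units = if (is.null(f$units)) "" else f$units)),
    auxiliaries = lapply(doc$auxiliaries, function(a)
      sd_aux(a$name, a$expression, signs = as_signs(a$signs),
             units = if (is.null(a$units)) "" else a$units)),
    lookups = lapply(doc$lookups, function(lk) sd_lookup(lk$name, lk$x, lk$y))
  )
}
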