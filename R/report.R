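# Run-comparison reporting: trajectory I/O, comparison tables and a textual
# results document, one section per studied SDG.

SDG_SECTIONS <- list(
  list(id = "SDG 1", title = "No poverty",
       indicators = c("below_poverty_pct", "sp_covered_pct",
                      "gov_spend_essential_pct", "access_basic_pct")),
  list(id = "SDG 2", title = "Zero hunger",
       indicators = c("food_insecurity_pct", "undernourishment_pct",
                      "food_price_anomaly_pct", "child_malnutrition_pct")),
  list(id = "SDG 8", title = "Decent work and economic growth",
       indicators = c("gdp_growth_pct", "inflation_pct", "unemployment_pct",
                      "tourism_share_pct", "informal_employment_pct")),
  list(id = "SDG 13", title = "Climate action",
       indicators = c("ghg_mt", "ghg_cumulative", "climate_action_score",
                      "disaster_deaths", "drr_adaptation_level",
                      "public_awareness_level"))
)

#' Write a trajectory to CSV or JSON
#'
#' CSV: header `year` plus one column per variable, RFC-4180 quoting, full
#' double precision (round trips are lossless well below 1e-12).  JSON: a
#' `metadata` block (model, scenario, dt, seed) plus `times` and `series`.
#'
#' @param traj An `sd_trajectory`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(traj, path, format = c("csv", "json")) {
  stopifnot(inherits(traj, "sd_trajectory"))
  format <- match.arg(format)
  if (format == "csv") {
    quote_field <- function(x) {
      needs <- grepl('[",\n]', x)
      x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
      x
    }
    header <- paste(quote_field(c("year", names(traj$series))), collapse = ",")
    num <- function(v) sprintf("%.17g", v)
    rows <- vapply(seq_along(traj$times), function(i)
      paste(c(num(traj$times[[i]]),
              vapply(traj$series, function(s) num(s[[i]]), character(1))),
            collapse = ","), character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(header, rows), con)
  } else {
    doc <- list(metadata = traj$metadata[c("model", "scenario", "dt", "seed")],
                times = traj$times, series = traj$series)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a trajectory written by [write_timeseries()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return An `sd_trajectory` (CSV files carry no metadata block; scenario
#'   and model default to `NA`).
#' @export
read_timeseries <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    tab <- utils::read.csv(path, check.names = FALSE)
    stopifnot(names(tab)[[1L]] == "year")
    times <- as.numeric(tab[["year"]])
    series <- lapply(tab[-1L], as.numeric)
    meta <- list(model = NA_character_, scenario = NA_character_,
                 dt = if (length(times) > 1L) times[[2L]] - times[[1L]] else NA_real_,
                 seed = NA_integer_,
                 floored = data.frame(stock = character(0), year = numeric(0)))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    times <- as.numeric(doc$times)
    series <- lapply(doc$series, as.numeric)
    meta <- list(model = doc$metadata$model, scenario = doc$metadata$scenario,
                 dt = as.numeric(doc$metadata$dt),
                 seed = if (is.null(doc$metadata$seed)) NA_integer_ else doc$metadata$seed,
                 floored = data.frame(stock = character(0), year = numeric(0)))
  }
  structure(list(times = times, series = series, metadata = meta),
            class = "sd_trajectory")
}

#' Compare scenario runs at selected years
#'
#' Builds a per-indicator table of values for each run and signed differences
#' against the first (reference) run.
#'
#' @param runs List of at least two `sd_trajectory` objects on a shared time
#'   grid with shared variable sets.
#' @param years Years to tabulate.
#' @param indicators Indicator names to tabulate.
#' @return A `comparison_report`: list with `scenarios`, `years`,
#'   `indicators`, `values` (long data frame, one column per run) and
#'   `differences` (same shape, run minus reference).
#' @export
compare_runs <- function(runs, years, indicators) {
  stopifnot(length(runs) >= 2L)
  labels <- vapply(seq_along(runs), function(i) {
    sc <- runs[[i]]$metadata$scenario
    if (is.null(sc) || is.na(sc)) sprintf("run%d", i) else sc
  }, character(1))
  labels <- make.unique(labels, sep = "_")
  ref <- runs[[1L]]
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (!identical(r$times, ref$times))
      stop(sprintf("run '%s' is not on the reference time grid", labels[[i]]),
           call. = FALSE)
    if (!setequal(names(r$series), names(ref$series)))
      stop(sprintf("run '%s' does not share the reference variable set", labels[[i]]),
           call. = FALSE)
    missing <- setdiff(indicators, names(r$series))
    if (length(missing))
      stop(sprintf("run '%s' lacks indicator(s): %s", labels[[i]],
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  grid <- expand.grid(year = years, indicator = indicators,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("indicator", "year")]
  vals <- as.data.frame(lapply(runs, function(r)
    vapply(seq_len(nrow(grid)), function(k)
      trajectory_value(r, grid$indicator[[k]], grid$year[[k]]), numeric(1))))
  names(vals) <- labels
  diffs <- vals - vals[[1L]]
  structure(list(scenarios = labels, years = years, indicators = indicators,
                 values = cbind(grid, vals), differences = cbind(grid, diffs)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs reference '%s'\n",
              paste(x$scenarios[-1L], collapse = ", "), x$scenarios[[1L]]))
  print(x$values)
  invisible(x)
}

#' Render a comparison report as a text document
#'
#' One section per studied SDG (1, 2, 8, 13) holding the indicator table and
#' a deterministic narrative of the direction of change; byte-identical
#' output for identical reports.
#'
#' @param report A [compare_runs()] result.
#' @param template `"text"` or `"markdown"`.
#' @return Character scalar (the document).
#' @export
render_report <- function(report, template = "text") {
  stopifnot(inherits(report, "comparison_report"))
  if (!template %in% c("text", "markdown"))
    stop(sprintf("unknown template '%s'", template), call. = FALSE)
  md <- template == "markdown"
  hdr <- function(x) if (md) sprintf("## %s", x) else
    paste0(x, "\n", strrep("=", nchar(x)))
  lines <- c(if (md) "# Scenario comparison" else
    paste0("SCENARIO COMPARISON\n", strrep("-", 19)),
    sprintf("Reference run: %s; compared: %s.",
            report$scenarios[[1L]], paste(report$scenarios[-1L], collapse = ", ")),
    "")
  fmt_table <- function(df) {
    txt <- cbind(df[, c("indicator", "year")],
                 as.data.frame(lapply(df[report$scenarios], function(v)
                   sprintf("%.4f", v))))
    widths <- pmax(nchar(names(txt)),
                   vapply(txt, function(cc) max(nchar(as.character(cc)), 0L), integer(1)))
    pad <- function(v, w) formatC(as.character(v), width = w)
    c(paste(mapply(pad, names(txt), widths), collapse = "  "),
      vapply(seq_len(nrow(txt)), function(i)
        paste(mapply(function(cc, w) pad(cc[[i]], w), txt, widths), collapse = "  "),
        character(1)))
  }
  for (sec in SDG_SECTIONS) {
    lines <- c(lines, hdr(sprintf("%s: %s", sec$id, sec$title)), "")
    inds <- intersect(report$indicators, sec$indicators)
    if (length(inds) == 0L) {
      lines <- c(lines, "(no indicators requested for this goal)", "")
      next
    }
    sub <- report$values[report$values$indicator %in% inds, , drop = FALSE]
    lines <- c(lines, fmt_table(sub), "")
    for (ind in inds) {
      vi <- report$values[report$values$indicator == ind, , drop = FALSE]
      y0 <- min(vi$year); y1 <- max(vi$year)
      for (scn in report$scenarios) {
        v0 <- vi[vi$year == y0, scn][[1L]]; v1 <- vi[vi$year == y1, scn][[1L]]
        dir <- if (v1 < v0) "falls" else if (v1 > v0) "rises" else "is unchanged"
        lines <- c(lines, sprintf("%s under '%s' %s from %.4f (%s) to %.4f (%s).",
                                  ind, scn, dir, v0, y0, v1, y1))
      }
    }
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}
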