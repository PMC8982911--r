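# Egypt 2015 baseline.
#
# The base-year values (19 indicator variables across SDG 1/2/8/13) ship as a
# plain-text fixture with per-entry provenance labels.  Two provenance sets
# are retained: the primary variable table used to initialise stocks, and the
# alternative 2015 prints that appear in the results narrative (poverty 27.5
# vs 27.8, GHG 240 vs 264.9, total GDP growth 4.37); the alternates are kept
# as metadata and, where applicable, calibration anchors — never as initial
# conditions.

#' Egypt 2015 baseline values
#'
#' Returns the packaged base-year (2015) values verbatim.  Percentages are on
#' the 0-100 scale, social-protection coverage is in persons, GHG emissions in
#' Mt CO2-equivalents per year, and the two preparedness levels are
#' dimensionless in \[0, 1\].  `production_per_labor` has no published base
#' value and no narrated coupling; it is carried as an inert `NA` field.
#' The per-capita GDP growth rate (`gdp_pc_growth_pct`, 5.43) is carried as
#' metadata only; the simulated indicator is total GDP growth (4.37 in 2015,
#' available in `attr(x, "alternates")`).
#'
#' @return A named list of class `egypt_baseline`, with attribute
#'   `"alternates"` holding the alternative 2015 prints.
#' @export
egypt_baseline <- function() {
  path <- system.file("extdata", "egypt_baseline_2015.csv", package = "coviam",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  main <- tab[tab$provenance == "table1", ]
  alt <- tab[tab$provenance != "table1", ]
  bl <- stats::setNames(as.list(suppressWarnings(as.numeric(main$value))), main$field)
  pct <- grepl("_pct$", names(bl))
  stopifnot(all(unlist(bl[pct]) >= 0 & unlist(bl[pct]) <= 100, na.rm = TRUE),
            bl$takafol_covered >= 0, bl$karama_covered >= 0,
            bl$disaster_deaths >= 0,
            bl$drr_adaptation_level >= 0, bl$drr_adaptation_level <= 1,
            bl$public_awareness_level >= 0, bl$public_awareness_level <= 1)
  structure(bl,
            alternates = stats::setNames(as.numeric(alt$value), alt$field),
            class = "egypt_baseline")
}

#' @export
print.egypt_baseline <- function(x, ...) {
  cat("<egypt_baseline> 2015 base-year values:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
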