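#' Market growth trend for annual produced ENM amounts
#'
#' Annual production growth is modelled as a sampled percent-per-year rate
#' with a breakpoint: a lower median growth for application years before
#' the breakpoint and a higher one after, each with a relative spread on
#' both sides realized as a triangular distribution
#' (`median * (1 - spread)`, `median`, `median * (1 + spread)`).
#' Defaults: 1%/a before 2000, 5%/a after, spread 0.5.
#'
#' @param breakpoint_year Calendar year separating the two regimes.
#' @param median_rate_pre,median_rate_post Median growth rates in %/a.
#' @param relative_spread Relative half-width of the rate distribution,
#'   in `[0, 1)`.
#' @return An object of class `growth_trend`.
#' @export
growth_trend <- function(breakpoint_year = 2000, median_rate_pre = 1,
                         median_rate_post = 5, relative_spread = 0.5) {
  if (relative_spread < 0 || relative_spread >= 1)
    stop("relative_spread must lie in [0, 1)")
  if (median_rate_pre <= -100 || median_rate_post <= -100)
    stop("growth rates must exceed -100 %/a")
  structure(list(breakpoint_year = breakpoint_year,
                 median_rate_pre = median_rate_pre,
                 median_rate_post = median_rate_post,
                 relative_spread = relative_spread),
            class = "growth_trend")
}

#' Distribution of the annual growth rate for one step year
#'
#' The rate applied to the production step ending in calendar year `year`
#' (i.e. growth from `year - 1` to `year`) follows the post-breakpoint
#' distribution when `year > breakpoint_year`, otherwise the
#' pre-breakpoint one.
#'
#' @param trend A [growth_trend()].
#' @param year Step-ending calendar year.
#' @return A `dist_spec` for the rate in %/a.
#' @export
growth_rate_dist <- function(trend, year) {
  med <- if (year > trend$breakpoint_year) trend$median_rate_post
         else trend$median_rate_pre
  if (trend$relative_spread == 0) return(dist_point(med))
  dist_spread(med, trend$relative_spread)
}

#' One ENM use category
#'
#' An application profile ties a substance to one product category: the
#' (uncertain) share of the substance's regional mass entering that use,
#' the product lifespan `m` over which each annual cohort releases, and
#' transfer coefficients (TCs) per life-cycle phase:
#' \describe{
#'   \item{tc_production}{fraction of the cohort released during
#'     production/manufacturing, per receiving compartment, emitted in the
#'     cohort year}
#'   \item{tc_use}{total fraction released over the whole product use
#'     life, per receiving compartment, emitted uniformly over `m` years}
#'   \item{tc_eol}{split of the remaining (never-released) mass over
#'     technical sinks at end of life; must sum to 1}
#' }
#'
#' @param id Application identifier.
#' @param substance Substance (ENM) name.
#' @param start_year First calendar year with non-zero input.
#' @param lifespan_m Product lifespan in years, integer >= 1.
#' @param share `dist_spec` for the mass share (fraction in `[0, 1]`).
#' @param tc_production,tc_use,tc_eol Named lists of `dist_spec`s keyed by
#'   receiving compartment / technical sink.
#' @return An object of class `application_profile`.
#' @export
application_profile <- function(id, substance, start_year, lifespan_m,
                                share, tc_production = list(),
                                tc_use = list(), tc_eol) {
  structure(list(id = id, substance = substance,
                 start_year = as.integer(start_year),
                 lifespan_m = as.integer(lifespan_m), share = share,
                 tc_production = tc_production, tc_use = tc_use,
                 tc_eol = tc_eol),
            class = "application_profile")
}

NATURAL_COMPARTMENTS <- c("surface_water", "sea_water", "sediment_fresh",
                          "sediment_marine", "soil_agricultural",
                          "soil_sludge_treated", "soil_natural_urban", "air")
TECHNICAL_SINKS <- c("waste_water", "landfill", "recycling",
                     "waste_incineration", "elimination")

#' Regional compartment geometry
#'
#' Volumes, areas, depths and densities used to turn annual compartment
#' mass flows into concentrations for one target region. All values are
#' plain positive scalars; fractions lie in `[0, 1]`.
#'
#' @param freshwater_throughput Annual freshwater discharge, m3/a.
#' @param stp_effluent_volume Annual treated wastewater volume, m3/a.
#' @param sea_volume Coastal sea mixing volume, m3.
#' @param sediment_fresh_area,sediment_marine_area Sediment areas, m2.
#' @param sediment_depth Active sediment depth, m.
#' @param sediment_density Sediment bulk density, kg/m3.
#' @param soil_area_agricultural,soil_area_sludge_treated,soil_area_natural_urban
#'   Soil areas by class, m2.
#' @param soil_mixing_depth Soil mixing depth, m.
#' @param soil_bulk_density Soil bulk density, kg/m3.
#' @param air_mixing_volume Atmospheric mixing volume, m3.
#' @param air_exchange_rate Air exchange rate, 1/a.
#' @param sewer_connection_fraction Population fraction connected to
#'   sewage treatment.
#' @return An object of class `compartment_geometry`.
#' @export
compartment_geometry <- function(freshwater_throughput, stp_effluent_volume,
                                 sea_volume, sediment_fresh_area,
                                 sediment_marine_area, sediment_depth,
                                 sediment_density, soil_area_agricultural,
                                 soil_area_sludge_treated,
                                 soil_area_natural_urban, soil_mixing_depth,
                                 soil_bulk_density, air_mixing_volume,
                                 air_exchange_rate,
                                 sewer_connection_fraction) {
  g <- list(freshwater_throughput = freshwater_throughput,
            stp_effluent_volume = stp_effluent_volume,
            sea_volume = sea_volume,
            sediment_fresh_area = sediment_fresh_area,
            sediment_marine_area = sediment_marine_area,
            sediment_depth = sediment_depth,
            sediment_density = sediment_density,
            soil_area_agricultural = soil_area_agricultural,
            soil_area_sludge_treated = soil_area_sludge_treated,
            soil_area_natural_urban = soil_area_natural_urban,
            soil_mixing_depth = soil_mixing_depth,
            soil_bulk_density = soil_bulk_density,
            air_mixing_volume = air_mixing_volume,
            air_exchange_rate = air_exchange_rate,
            sewer_connection_fraction = sewer_connection_fraction)
  structure(g, class = "compartment_geometry")
}

#' Synthetic Germany-scale compartment geometry
#'
#' Order-of-magnitude placeholders for a large industrialized country.
#' These are synthetic defaults intended for testing and demonstration;
#' a real assessment must supply measured regional geometry through the
#' parameter book.
#'
#' @return A [compartment_geometry()].
#' @export
synthetic_geometry <- function() {
  compartment_geometry(
    freshwater_throughput = 1.8e11,   # m3/a, large river-basin scale
    stp_effluent_volume = 1.0e10,     # m3/a treated wastewater
    sea_volume = 5.0e11,              # m3 coastal mixing volume
    sediment_fresh_area = 8.0e9,      # m2
    sediment_marine_area = 2.4e10,    # m2
    sediment_depth = 0.03,            # m active layer
    sediment_density = 1300,          # kg/m3
    soil_area_agricultural = 1.7e11,  # m2
    soil_area_sludge_treated = 1.3e10,
    soil_area_natural_urban = 1.5e11,
    soil_mixing_depth = 0.2,          # m
    soil_bulk_density = 1350,         # kg/m3
    air_mixing_volume = 3.6e14,       # m3 (area x boundary layer)
    air_exchange_rate = 365,          # 1/a (about daily renewal)
    sewer_connection_fraction = 0.96)
}

#' Fate and treatment parameters
#'
#' Parameters of the technical treatment nodes and of the water-column
#' fate simplifications, each a `dist_spec` (use [dist_point()] for fixed
#' values):
#' \describe{
#'   \item{stp_removal}{fraction of STP influent transferred to sludge}
#'   \item{sludge_to_soil}{fraction of sludge applied to sludge-treated
#'     soil (remainder incinerated)}
#'   \item{incineration_elimination}{fraction of incinerated mass
#'     transformed/eliminated (remainder is residue routed to landfill)}
#'   \item{sea_export_fraction}{fraction of the freshwater-borne load
#'     exported to coastal seawater}
#'   \item{settling_fresh,settling_marine}{fraction of the waterborne
#'     load settling to the respective sediment}
#' }
#'
#' @param stp_removal,sludge_to_soil,incineration_elimination,sea_export_fraction,settling_fresh,settling_marine
#'   `dist_spec`s with support within `[0, 1]`.
#' @return An object of class `fate_params`.
#' @export
fate_params <- function(stp_removal = dist_triangular(0.85, 0.95, 0.99),
                        sludge_to_soil = dist_point(0.3),
                        incineration_elimination = dist_point(0.9),
                        sea_export_fraction = dist_point(0.1),
                        settling_fresh = dist_triangular(0.3, 0.6, 0.9),
                        settling_marine = dist_triangular(0.3, 0.6, 0.9)) {
  structure(list(stp_removal = stp_removal, sludge_to_soil = sludge_to_soil,
                 incineration_elimination = incineration_elimination,
                 sea_export_fraction = sea_export_fraction,
                 settling_fresh = settling_fresh,
                 settling_marine = settling_marine),
            class = "fate_params")
}

#' Assemble a parameter book
#'
#' The parameter book is the single input object of the pipeline: the
#' substances, their production estimates and growth trend, the
#' application profiles with shares and transfer coefficients, the
#' regional scaling, compartment geometry, fate parameters and simulation
#' settings.
#'
#' @param substances Character vector of substance names.
#' @param applications List of [application_profile()]s.
#' @param production_estimates data.frame with columns `substance`,
#'   `source_tag`, `low`, `high`, `year` (t/a; `low == high` for point
#'   estimates; `year` is the estimate's reference year).
#' @param geometry A [compartment_geometry()].
#' @param trend A [growth_trend()].
#' @param regional List with `domestic_demand` and `world_gdp` in the same
#'   currency and year; their ratio scales global to regional mass.
#' @param fate A [fate_params()].
#' @param sim List with `year_start`, `year_end`, `reference_year` (year
#'   production estimates refer to), `n_iterations`, `seed`, and
#'   `production_sampling` (`"linear"` or `"log"`, how ranged estimates
#'   are sampled).
#' @param validate Run [validate_parameter_book()]?
#' @return An object of class `parameter_book`.
#' @export
parameter_book <- function(substances, applications, production_estimates,
                           geometry, trend = growth_trend(),
                           regional = list(domestic_demand = 1,
                                           world_gdp = 1),
                           fate = fate_params(),
                           sim = list(year_start = 1950, year_end = 2050,
                                      reference_year = 2015,
                                      n_iterations = 1000, seed = 1,
                                      production_sampling = "linear"),
                           validate = TRUE) {
  if (is.null(sim$production_sampling)) sim$production_sampling <- "linear"
  if (is.null(sim$reference_year)) sim$reference_year <- 2015
  book <- structure(list(substances = substances,
                         applications = applications,
                         production_estimates = production_estimates,
                         geometry = geometry, trend = trend,
                         regional = regional, fate = fate, sim = sim),
                    class = "parameter_book")
  if (validate) validate_parameter_book(book)
  book
}

check_dist_role <- function(spec, path, lo, hi, errs) {
  if (!is_dist_spec(spec))
    return(c(errs, sprintf("%s: not a distribution spec", path)))
  if (spec$support_low < lo - 1e-12 || spec$support_high > hi + 1e-12)
    errs <- c(errs, sprintf("%s: support [%g, %g] outside [%g, %g]", path,
                            spec$support_low, spec$support_high, lo, hi))
  errs
}

#' Validate a parameter book
#'
#' Checks all structural invariants (horizon ordering, lifespans,
#' substance declarations, fraction supports, transfer-coefficient sums,
#' positive geometry) and stops with a message listing every violated
#' field path.
#'
#' @param book A [parameter_book()].
#' @return `book`, invisibly, if valid.
#' @export
validate_parameter_book <- function(book) {
  errs <- character()
  s <- book$sim
  if (s$year_start > s$year_end)
    errs <- c(errs, "sim.year_start: exceeds sim.year_end")
  if (is.null(s$n_iterations) || s$n_iterations < 1)
    errs <- c(errs, "sim.n_iterations: must be >= 1")
  if (!s$production_sampling %in% c("linear", "log"))
    errs <- c(errs, "sim.production_sampling: must be 'linear' or 'log'")
  tr <- book$trend
  if (tr$relative_spread < 0 || tr$relative_spread >= 1)
    errs <- c(errs, "trend.relative_spread: must lie in [0, 1)")
  if (book$regional$world_gdp <= 0)
    errs <- c(errs, "regional.world_gdp: must be > 0")
  if (book$regional$domestic_demand < 0)
    errs <- c(errs, "regional.domestic_demand: must be >= 0")

  pe <- book$production_estimates
  need <- c("substance", "source_tag", "low", "high", "year")
  if (!all(need %in% names(pe))) {
    errs <- c(errs, "production_estimates: missing columns")
  } else {
    if (any(pe$low > pe$high))
      errs <- c(errs, "production_estimates.low: exceeds high in some rows")
    if (any(pe$low < 0))
      errs <- c(errs, "production_estimates.low: negative values")
    miss <- setdiff(unique(pe$substance), book$substances)
    if (length(miss))
      errs <- c(errs, sprintf(
        "production_estimates.substance: undeclared substance(s) %s",
        paste(miss, collapse = ", ")))
  }

  for (app in book$applications) {
    p <- sprintf("applications.%s", app$id)
    if (!app$substance %in% book$substances)
      errs <- c(errs, sprintf("%s.substance: '%s' not declared", p,
                              app$substance))
    if (app$lifespan_m < 1)
      errs <- c(errs, sprintf("%s.lifespan_m: must be >= 1", p))
    if (app$start_year < s$year_start || app$start_year > s$year_end)
      errs <- c(errs, sprintf("%s.start_year: outside simulation horizon", p))
    errs <- check_dist_role(app$share, paste0(p, ".share"), 0, 1, errs)
    for (ph in c("tc_production", "tc_use", "tc_eol")) {
      tcs <- app[[ph]]
      for (cm in names(tcs))
        errs <- check_dist_role(tcs[[cm]], sprintf("%s.%s.%s", p, ph, cm),
                                0, 1, errs)
    }
    bad_use <- setdiff(names(app$tc_use),
                       c(NATURAL_COMPARTMENTS, "waste_water", "elimination"))
    if (length(bad_use))
      errs <- c(errs, sprintf("%s.tc_use: unknown compartment(s) %s", p,
                              paste(bad_use, collapse = ", ")))
    bad_eol <- setdiff(names(app$tc_eol), TECHNICAL_SINKS)
    if (length(bad_eol))
      errs <- c(errs, sprintf("%s.tc_eol: unknown sink(s) %s", p,
                              paste(bad_eol, collapse = ", ")))
    sum_use <- sum(vapply(app$tc_use, dist_central, 0))
    sum_prod <- sum(vapply(app$tc_production, dist_central, 0))
    sum_eol <- sum(vapply(app$tc_eol, dist_central, 0))
    if (sum_use > 1 + 1e-9)
      errs <- c(errs, sprintf("%s.tc_use: central values sum to %.4f > 1",
                              p, sum_use))
    if (sum_prod > 1 + 1e-9)
      errs <- c(errs, sprintf(
        "%s.tc_production: central values sum to %.4f > 1", p, sum_prod))
    if (abs(sum_eol - 1) > 1e-6)
      errs <- c(errs, sprintf(
        "%s.tc_eol: central values sum to %.4f, must equal 1", p, sum_eol))
  }
  for (sub in book$substances) {
    has <- any(vapply(book$applications,
                      function(a) a$substance == sub, TRUE))
    if (!has)
      errs <- c(errs, sprintf("substances.%s: no application declared", sub))
  }

  g <- book$geometry
  fracs <- "sewer_connection_fraction"
  for (f in names(g)) {
    if (f %in% fracs) {
      if (g[[f]] < 0 || g[[f]] > 1)
        errs <- c(errs, sprintf("geometry.%s: must lie in [0, 1]", f))
    } else if (!is.numeric(g[[f]]) || g[[f]] <= 0) {
      errs <- c(errs, sprintf("geometry.%s: must be > 0", f))
    }
  }
  for (f in names(book$fate))
    errs <- check_dist_role(book$fate[[f]], paste0("fate.", f), 0, 1, errs)

  if (length(errs))
    stop("invalid parameter book:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(book)
}
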