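#' Configuration for synthetic parameter books and endpoint tables
#'
#' Controls the seeded generators that emulate the structure of a real
#' parameter inventory: ranged production estimates, application shares
#' with expected sums near 1, product lifespans of one to about ten
#' years, transfer-coefficient distributions on `[0, 1]` per life-cycle
#' phase, and endpoint sets spanning several orders of magnitude.
#'
#' @param seed Master seed.
#' @param n_substances,n_applications Counts (applications per
#'   substance).
#' @param lifespan_range Integer range of product lifespans in years.
#' @param production_log10_range log10 range (t/a) of production
#'   estimate magnitudes.
#' @param n_species,endpoints_per_species Endpoint table shape.
#' @param orders_of_magnitude Guaranteed log10 span of each substance's
#'   endpoint concentrations (>= 3).
#' @param n_iterations Default Monte Carlo iterations written into the
#'   book.
#' @return Object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, n_substances = 2, n_applications = 3,
                           lifespan_range = c(1, 10),
                           production_log10_range = c(2, 5),
                           n_species = 8, endpoints_per_species = 3,
                           orders_of_magnitude = 4, n_iterations = 100) {
  stopifnot(n_substances >= 1, n_applications >= 1,
            lifespan_range[1] >= 1, n_species >= 2,
            endpoints_per_species >= 1, orders_of_magnitude >= 3,
            n_iterations >= 1)
  structure(list(seed = seed, n_substances = n_substances,
                 n_applications = n_applications,
                 lifespan_range = lifespan_range,
                 production_log10_range = production_log10_range,
                 n_species = n_species,
                 endpoints_per_species = endpoints_per_species,
                 orders_of_magnitude = orders_of_magnitude,
                 n_iterations = n_iterations),
            class = "fixture_config")
}

#' Generate a complete synthetic parameter book
#'
#' Emulates a transcribed parameter inventory: per substance, two to
#' three ranged production estimates (survey and literature style, with
#' their own reference years), applications with Dirichlet-derived share
#' distributions whose draws sum to at most 1 (expected sum near 1),
#' lifespans within the configured range, plausible transfer-coefficient
#' triangulars per phase (EOL coefficients summing to exactly 1), the
#' synthetic regional geometry, and the default growth trend. Fully
#' reproducible under the configuration seed.
#'
#' @param cfg A [fixture_config()].
#' @return A validated [parameter_book()].
#' @export
generate_parameter_book <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "synth/book"))
  subs <- sprintf("ENM%02d", seq_len(cfg$n_substances))

  est_rows <- list()
  for (sub in subs) {
    n_src <- sample(2:3, 1)
    for (k in seq_len(n_src)) {
      lo10 <- stats::runif(1, cfg$production_log10_range[1],
                           cfg$production_log10_range[2] - 0.5)
      hi10 <- lo10 + stats::runif(1, 0.2, 1.5)
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        substance = sub,
        source_tag = if (k == 1) "survey" else sprintf("literature_%d", k),
        low = round(10^lo10, 3), high = round(10^hi10, 3),
        year = sample(2008:2015, 1), stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, est_rows)

  apps <- list()
  for (sub in subs) {
    # Dirichlet weights scaled slightly below 1: expected share sums near
    # (but never above) 1; the remainder is unallocated production
    w <- stats::rgamma(cfg$n_applications, shape = 1.5)
    w <- w / sum(w) * stats::runif(1, 0.9, 1)
    for (j in seq_len(cfg$n_applications)) {
      use_comps <- sample(c("waste_water", "surface_water", "air",
                            "soil_agricultural"),
                          sample(1:3, 1))
      tc_use <- list()
      budget <- stats::runif(1, 0.05, 0.6)  # total use-life release
      uw <- stats::rgamma(length(use_comps), 1)
      uw <- uw / sum(uw) * budget
      for (k in seq_along(use_comps))
        tc_use[[use_comps[k]]] <- dist_spread(uw[k], clip_unit = TRUE)
      tc_prod <- list()
      if (stats::runif(1) < 0.5)
        tc_prod$waste_water <- dist_spread(stats::runif(1, 0.001, 0.05),
                                           clip_unit = TRUE)
      ew <- stats::rgamma(3, 1.5)
      ew <- ew / sum(ew)
      sinks <- c("landfill", "recycling", "waste_incineration")
      tc_eol <- list()
      for (k in 1:3)
        tc_eol[[sinks[k]]] <- dist_spread(ew[k], spread = 0.3,
                                          clip_unit = TRUE)
      apps[[length(apps) + 1L]] <- application_profile(
        id = sprintf("%s_app%d", sub, j), substance = sub,
        start_year = sample(1960:2005, 1),
        lifespan_m = sample(cfg$lifespan_range[1]:cfg$lifespan_range[2], 1),
        share = dist_spread(w[j], clip_unit = TRUE),
        tc_production = tc_prod, tc_use = tc_use, tc_eol = tc_eol)
    }
  }

  parameter_book(
    substances = subs, applications = apps,
    production_estimates = estimates,
    geometry = synthetic_geometry(),
    trend = growth_trend(),
    regional = list(domestic_demand = 3.4e12, world_gdp = 8.5e13),
    fate = fate_params(),
    sim = list(year_start = 1950, year_end = 2050, reference_year = 2015,
               n_iterations = cfg$n_iterations, seed = cfg$seed,
               production_sampling = "linear"))
}

#' Deterministic toy parameter book with closed-form answers
#'
#' One substance, one application, all-point distributions: flat regional
#' production of 100 t/a from 2000, share 1, lifespan 3 years, a total
#' use-life release of 0.3 to surface water, and full EOL assignment to
#' landfill, over a 10-year horizon (2000-2009) with zero growth.
#'
#' Hand-checkable consequences (per iteration, exactly):
#' \itemize{
#'   \item use-destined cohort mass 30 t/a, EOL-destined 70 t/a;
#'   \item use release ramps 10, 20, then 30 t/a from 2002 onwards;
#'   \item EOL release to landfill is 0 until 2002 and 70 t/a from 2003;
#'   \item use stock ramps 20, 30, then stays 30 t; EOL stock ramps 70,
#'     140, then stays 210 t;
#'   \item both stock series equal cumulative input minus cumulative
#'     release in every year.
#' }
#'
#' @return A validated [parameter_book()].
#' @export
toy_fixture <- function() {
  app <- application_profile(
    id = "toy_app", substance = "toyENM", start_year = 2000,
    lifespan_m = 3, share = dist_point(1),
    tc_use = list(surface_water = dist_point(0.3)),
    tc_eol = list(landfill = dist_point(1)))
  parameter_book(
    substances = "toyENM", applications = list(app),
    production_estimates = data.frame(
      substance = "toyENM", source_tag = "fixed", low = 100, high = 100,
      year = 2000, stringsAsFactors = FALSE),
    geometry = synthetic_geometry(),
    trend = growth_trend(median_rate_pre = 0, median_rate_post = 0,
                         relative_spread = 0),
    regional = list(domestic_demand = 1, world_gdp = 1),
    fate = fate_params(stp_removal = dist_point(0.9),
                       sludge_to_soil = dist_point(0.5),
                       incineration_elimination = dist_point(0.9),
                       sea_export_fraction = dist_point(0.1),
                       settling_fresh = dist_point(0.5),
                       settling_marine = dist_point(0.5)),
    sim = list(year_start = 2000, year_end = 2009, reference_year = 2000,
               n_iterations = 1, seed = 7, production_sampling = "linear"))
}

#' Generate a synthetic ecotoxicological endpoint table
#'
#' Log-uniform concentrations spanning at least the configured number of
#' orders of magnitude (the global extremes are anchored so the span is
#' guaranteed), mixed endpoint kinds, one table per substance, fully
#' seeded.
#'
#' @param cfg A [fixture_config()].
#' @return data.frame with columns `substance`, `species`,
#'   `endpoint_kind`, `concentration` (ug/L), `unit`, `source_tag`.
#' @export
generate_endpoints <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "synth/endpoints"))
  rows <- list()
  for (si in seq_len(cfg$n_substances)) {
    sub <- sprintf("ENM%02d", si)
    lo10 <- stats::runif(1, -1, 1)
    hi10 <- lo10 + cfg$orders_of_magnitude
    n_ep <- cfg$n_species * cfg$endpoints_per_species
    conc <- 10^stats::runif(n_ep, lo10, hi10)
    conc[1] <- 10^lo10  # anchor the extremes: span is guaranteed
    conc[n_ep] <- 10^hi10
    k <- 0
    for (sp in seq_len(cfg$n_species)) for (e in
                                            seq_len(cfg$endpoints_per_species)) {
      k <- k + 1
      rows[[length(rows) + 1L]] <- data.frame(
        substance = sub, species = sprintf("species_%02d", sp),
        endpoint_kind = sample(ENDPOINT_KINDS, 1),
        concentration = conc[k], unit = "ug/L",
        source_tag = "synthetic", stringsAsFactors = FALSE)
    }
  }
  validate_endpoints(do.call(rbind, rows))
}
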