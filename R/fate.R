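#' Partition a mass flow over receiving compartments
#'
#' Multiplies a mass stream by sampled transfer coefficients. For the
#' production and use phases the coefficients may sum below 1 and the
#' residual stays in the product; at end of life the coefficients must
#' exhaust the stream.
#'
#' @param mass Mass flow (scalar, vector or matrix), t/a.
#' @param tcs Named list of sampled transfer-coefficient vectors (or
#'   scalars), one per receiving compartment.
#' @param phase `"use"`, `"production"` or `"eol"`; for `"eol"` the
#'   coefficients must sum to 1 (within 1e-6) in every draw.
#' @return List with `flux` (named list of mass flows) and `retained`
#'   (the residual stream, zero for `"eol"`).
#' @export
partition_phase <- function(mass, tcs, phase = c("use", "production",
                                                 "eol")) {
  phase <- match.arg(phase)
  tot <- if (length(tcs)) Reduce(`+`, tcs) else 0
  if (phase == "eol") {
    if (any(abs(tot - 1) > 1e-6))
      stop("EOL transfer coefficients must sum to 1 in every draw")
  } else if (any(tot > 1 + 1e-9)) {
    stop(phase, " transfer coefficients must sum to <= 1 in every draw")
  }
  flux <- lapply(tcs, function(tc) mass * tc)
  list(flux = flux, retained = mass * (1 - tot))
}

#' Sewage-treatment-plant transfer node
#'
#' Splits a wastewater-borne mass stream: the sewer-connected part enters
#' the plant, where `removal` is transferred to sludge and the rest leaves
#' with the effluent to surface water; the unconnected part bypasses
#' treatment and reaches surface water directly.
#'
#' @param influent Wastewater-borne mass, t/a.
#' @param removal Fraction of treated mass transferred to sludge, in
#'   `[0, 1]`.
#' @param connection Sewer connection fraction, in `[0, 1]`.
#' @return List with `effluent`, `sludge`, `bypass` mass flows (t/a).
#' @export
stp_transfer <- function(influent, removal, connection) {
  if (any(removal < 0 | removal > 1) || any(connection < 0 | connection > 1))
    stop("removal and connection must lie in [0, 1]")
  connected <- influent * connection
  list(effluent = connected * (1 - removal),
       sludge = connected * removal,
       bypass = influent * (1 - connection))
}

zero_like <- function(template) {
  z <- template * 0
  z
}

add_flux <- function(acc, cm, val) {
  acc[[cm]] <- if (is.null(acc[[cm]])) val else acc[[cm]] + val
  acc
}

# Route raw per-compartment release fluxes through the technical
# treatment nodes (STP, incineration, sludge disposition) and the
# water-column simplifications (riverine sea export, settling).
# `raw` is a named list of equally shaped flux matrices; names may be
# natural compartments or technical sinks. `fd` holds per-iteration fate
# parameter draws; `connection` is the sewer connection fraction.
route_fluxes <- function(raw, fd, connection) {
  if (!length(raw)) stop("no fluxes to route")
  tmpl <- zero_like(raw[[1]])
  nat <- list(); tech <- list()
  for (cm in names(raw)) {
    if (cm %in% NATURAL_COMPARTMENTS) nat <- add_flux(nat, cm, raw[[cm]])
    else if (cm %in% c("landfill", "recycling", "elimination"))
      tech <- add_flux(tech, cm, raw[[cm]])
  }
  ww <- if (!is.null(raw$waste_water)) raw$waste_water else tmpl
  stp <- stp_transfer(ww, fd$stp_removal, connection)
  nat <- add_flux(nat, "surface_water", stp$effluent + stp$bypass)
  nat <- add_flux(nat, "soil_sludge_treated", stp$sludge * fd$sludge_to_soil)
  sludge_incin <- stp$sludge * (1 - fd$sludge_to_soil)

  incin_in <- (if (!is.null(raw$waste_incineration)) raw$waste_incineration
               else tmpl) + sludge_incin
  tech <- add_flux(tech, "waste_incineration", incin_in)
  tech <- add_flux(tech, "elimination",
                   incin_in * fd$incineration_elimination)
  tech <- add_flux(tech, "landfill",
                   incin_in * (1 - fd$incineration_elimination))

  fresh <- if (!is.null(nat$surface_water)) nat$surface_water else tmpl
  nat <- add_flux(nat, "sea_water", fresh * fd$sea_export)
  sea <- nat$sea_water
  nat <- add_flux(nat, "sediment_fresh", fresh * fd$settling_fresh)
  nat <- add_flux(nat, "sediment_marine", sea * fd$settling_marine)
  list(natural = nat, technical = tech)
}

sample_fate_params <- function(fate, n, seed) {
  draw <- function(name) {
    set.seed(substream_seed(seed, paste0("fate/", name)))
    sample_dist(fate[[name]], n)
  }
  list(stp_removal = draw("stp_removal"),
       sludge_to_soil = draw("sludge_to_soil"),
       incineration_elimination = draw("incineration_elimination"),
       sea_export = draw("sea_export_fraction"),
       settling_fresh = draw("settling_fresh"),
       settling_marine = draw("settling_marine"))
}

#' Aggregate a simulation into compartment mass fluxes
#'
#' Sums all applications of each substance into annual mass fluxes per
#' receiving compartment, routing wastewater through the STP node, sludge
#' to soil or incineration, incineration residues to landfill, and the
#' freshwater load to sea and sediments. Fluxes are kept separately for
#' the use-origin load (production + use-phase release) and the EOL-origin
#' load, so exposure can be attributed.
#'
#' Sediment, seawater and freshwater loads deliberately describe the same
#' waterborne mass from different vantage points (whole-mass convention);
#' mass-balance accounting therefore applies to the release streams, not
#' to the routed exposure fluxes.
#'
#' @param sim An [simulate_release()] result.
#' @param seed Seed for the fate-parameter draws (default: the
#'   simulation's book seed).
#' @return Object of class `compartment_flux`: `years`, `n`,
#'   `fate_draws`, and per substance a list with `use`, `eol` and `total`
#'   flux sets, each holding `natural` and `technical` named lists of
#'   `n x years` matrices (t/a).
#' @export
compartment_flux <- function(sim, seed = NULL) {
  if (is.null(seed)) seed <- sim$book$sim$seed
  fd <- sample_fate_params(sim$book$fate, sim$n, seed)
  connection <- sim$book$geometry$sewer_connection_fraction
  tmpl <- matrix(0, sim$n, length(sim$years),
                 dimnames = list(NULL, sim$years))
  out <- list(years = sim$years, n = sim$n, fate_draws = fd,
              substances = list())
  for (sub in sim$book$substances) {
    raw <- list(use = list(), eol = list())
    for (app in sim$applications) {
      if (app$substance != sub) next
      for (stream in c("production", "use"))
        for (cm in names(app$flux[[stream]]))
          raw$use <- add_flux(raw$use, cm, app$flux[[stream]][[cm]])
      for (cm in names(app$flux$eol))
        raw$eol <- add_flux(raw$eol, cm, app$flux$eol[[cm]])
    }
    routed <- lapply(raw, function(r) {
      if (!length(r)) r <- list(surface_water = tmpl)
      route_fluxes(r, fd, connection)
    })
    tot <- list(natural = list(), technical = list())
    for (set in c("natural", "technical"))
      for (cm in union(names(routed$use[[set]]), names(routed$eol[[set]]))) {
        u <- routed$use[[set]][[cm]]; e <- routed$eol[[set]][[cm]]
        if (is.null(u)) u <- tmpl
        if (is.null(e)) e <- tmpl
        tot[[set]][[cm]] <- u + e
      }
    out$substances[[sub]] <- list(use = routed$use, eol = routed$eol,
                                  total = tot)
  }
  class(out) <- "compartment_flux"
  out
}

#' Water, soil, sediment and air concentration conversions
#'
#' Plain dilution conversions from annual compartment mass fluxes to
#' concentrations; no mechanistic fate. For soils and sediments two
#' scenarios are supported: `degradation_1yr` (only the current year's
#' influx is present; the material is degraded/eliminated within a year)
#' and `persistent` (no degradation; the cumulative influx since the
#' start of the series is present).
#'
#' @param mass Annual mass flux, t/a (vector or `iterations x years`
#'   matrix).
#' @param volume Dilution volume, m3/a (water) .
#' @param unit Output unit.
#' @return Concentration, same shape as `mass`.
#' @name pec
NULL

conc_factor <- function(unit) {
  switch(unit,
         "ng/L" = 1e12,   # t / (m3 -> L), g -> ng
         "ug/L" = 1e9,
         "ng/kg" = 1e15,
         "ug/kg" = 1e12,
         "ng/m3" = 1e15,
         stop("unknown unit: ", unit))
}

#' @rdname pec
#' @export
pec_water <- function(mass, volume, unit = "ng/L") {
  if (volume <= 0) stop("dilution volume must be > 0")
  mass * conc_factor(unit) / volume
}

apply_scenario <- function(mass, scenario) {
  switch(scenario,
         degradation_1yr = mass,
         persistent = accumulative_release(mass),
         stop("unknown scenario: ", scenario))
}

#' @rdname pec
#' @param area Compartment area, m2.
#' @param depth Mixing/active depth, m.
#' @param bulk_density Bulk density, kg/m3.
#' @param scenario `"degradation_1yr"` or `"persistent"`.
#' @export
pec_soil <- function(mass, area, depth, bulk_density,
                     scenario = c("degradation_1yr", "persistent"),
                     unit = "ng/kg") {
  scenario <- match.arg(scenario)
  if (area <= 0 || depth <= 0 || bulk_density <= 0)
    stop("soil geometry must be strictly positive")
  apply_scenario(mass, scenario) * conc_factor(unit) /
    (area * depth * bulk_density)
}

#' @rdname pec
#' @param settling_fraction Fraction of the waterborne load settling to
#'   the sediment, in `[0, 1]`.
#' @export
pec_sediment <- function(mass, settling_fraction, area, depth, bulk_density,
                         scenario = c("degradation_1yr", "persistent"),
                         unit = "ng/kg") {
  if (any(settling_fraction < 0 | settling_fraction > 1))
    stop("settling_fraction must lie in [0, 1]")
  pec_soil(mass * settling_fraction, area, depth, bulk_density,
           match.arg(scenario), unit)
}

#' @rdname pec
#' @param emission Annual emission to air, t/a.
#' @param mixing_volume Atmospheric mixing volume, m3.
#' @param exchange_rate Air exchange rate, 1/a.
#' @export
pec_air <- function(emission, mixing_volume, exchange_rate,
                    unit = "ng/m3") {
  if (mixing_volume <= 0 || exchange_rate <= 0)
    stop("mixing volume and exchange rate must be > 0")
  emission * conc_factor(unit) / (mixing_volume * exchange_rate)
}

PEC_UNITS <- c(surface_water = "ng/L", sea_water = "ng/L",
               sediment_fresh = "ng/kg", sediment_marine = "ng/kg",
               soil_agricultural = "ng/kg", soil_sludge_treated = "ng/kg",
               soil_natural_urban = "ng/kg", air = "ng/m3")

#' Predicted environmental concentrations for all compartments
#'
#' Converts routed compartment fluxes to concentration sample matrices.
#' Waters and air carry a short residence time and are evaluated from the
#' annual flux in both scenarios; soils and sediments are evaluated under
#' the one-year-degradation and the full-persistence (accumulative)
#' scenario. Sediments are already settling-scaled during routing, so the
#' geometric conversion is applied directly.
#'
#' @param flux A [compartment_flux()] result.
#' @param geometry A [compartment_geometry()] (default: the one used for
#'   routing is not stored, so pass the book's).
#' @return Object of class `pec_set`: per substance, per load
#'   (`total`, `eol_only`), per compartment, per scenario an
#'   `iterations x years` concentration matrix with a `unit` attribute.
#' @export
compute_pec <- function(flux, geometry) {
  g <- geometry
  conv <- function(cm, mass, scenario) {
    switch(cm,
      surface_water = pec_water(mass, g$freshwater_throughput),
      sea_water = pec_water(mass, g$sea_volume),
      sediment_fresh = pec_soil(mass, g$sediment_fresh_area,
                                g$sediment_depth, g$sediment_density,
                                scenario),
      sediment_marine = pec_soil(mass, g$sediment_marine_area,
                                 g$sediment_depth, g$sediment_density,
                                 scenario),
      soil_agricultural = pec_soil(mass, g$soil_area_agricultural,
                                   g$soil_mixing_depth,
                                   g$soil_bulk_density, scenario),
      soil_sludge_treated = pec_soil(mass, g$soil_area_sludge_treated,
                                     g$soil_mixing_depth,
                                     g$soil_bulk_density, scenario),
      soil_natural_urban = pec_soil(mass, g$soil_area_natural_urban,
                                    g$soil_mixing_depth,
                                    g$soil_bulk_density, scenario),
      air = pec_air(mass, g$air_mixing_volume, g$air_exchange_rate),
      NULL)
  }
  accumulating <- c("sediment_fresh", "sediment_marine",
                    "soil_agricultural", "soil_sludge_treated",
                    "soil_natural_urban")
  out <- list(years = flux$years, n = flux$n, substances = list())
  for (sub in names(flux$substances)) {
    per_load <- list()
    for (load in c("total", "eol_only")) {
      src <- if (load == "total") flux$substances[[sub]]$total
             else flux$substances[[sub]]$eol
      comps <- list()
      for (cm in names(src$natural)) {
        if (!cm %in% names(PEC_UNITS)) next
        scen <- list()
        for (scenario in c("degradation_1yr", "persistent")) {
          eff_scen <- if (cm %in% accumulating) scenario
                      else "degradation_1yr"
          p <- conv(cm, src$natural[[cm]], eff_scen)
          attr(p, "unit") <- PEC_UNITS[[cm]]
          scen[[scenario]] <- p
        }
        comps[[cm]] <- scen
      }
      per_load[[load]] <- comps
    }
    out$substances[[sub]] <- per_load
  }
  class(out) <- "pec_set"
  out
}

#' Fraction of an application's input mass reaching nature
#'
#' Routes one application's release fluxes through the treatment nodes
#' and divides the mass arriving in primary natural compartments (surface
#' water, soils, air — sediment and sea re-expressions of the waterborne
#' load are excluded to avoid double counting) by the application's total
#' cohort input, per iteration.
#'
#' @param sim An [simulate_release()] result.
#' @param id Application id.
#' @param seed Seed for fate-parameter draws (default: book seed).
#' @return List with `samples` (per-iteration fractions) and `summary`
#'   (a [summarize_samples()] result).
#' @export
application_nature_fraction <- function(sim, id, seed = NULL) {
  app <- sim$applications[[id]]
  if (is.null(app)) stop("unknown application id: ", id)
  if (is.null(seed)) seed <- sim$book$sim$seed
  fd <- sample_fate_params(sim$book$fate, sim$n, seed)
  raw <- list()
  for (stream in c("production", "use", "eol"))
    for (cm in names(app$flux[[stream]]))
      raw <- add_flux(raw, cm, app$flux[[stream]][[cm]])
  routed <- route_fluxes(raw, fd,
                         sim$book$geometry$sewer_connection_fraction)
  primary <- setdiff(names(routed$natural),
                     c("sea_water", "sediment_fresh", "sediment_marine"))
  nature <- 0
  for (cm in primary) nature <- nature + rowSums(routed$natural[[cm]])
  input <- rowSums(app$input)
  frac <- ifelse(input > 0, nature / input, 0)
  list(samples = frac, summary = summarize_samples(frac, unit = "fraction"))
}
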