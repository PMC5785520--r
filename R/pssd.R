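ENDPOINT_KINDS <- c("acute_effect", "chronic_effect", "acute_noec",
                    "chronic_noec")

#' Read and validate an ecotoxicological endpoint table
#'
#' Expects a CSV with columns `species`, `endpoint_kind` (one of
#' `acute_effect`, `chronic_effect`, `acute_noec`, `chronic_noec`),
#' `concentration` (> 0), `unit`, `source_tag`, and optionally
#' `substance`.
#'
#' @param path CSV file path.
#' @return A validated data.frame.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_endpoints(df)
}

#' @rdname read_endpoints
#' @param df Endpoint data.frame.
#' @export
validate_endpoints <- function(df) {
  need <- c("species", "endpoint_kind", "concentration")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("endpoint table: missing column(s) ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$endpoint_kind), ENDPOINT_KINDS)
  if (length(bad))
    stop("endpoint table: unknown endpoint_kind(s) ",
         paste(bad, collapse = ", "))
  if (any(df$concentration <= 0))
    stop("endpoint table: concentrations must be > 0")
  df
}

#' Transform an endpoint into chronic no-effect concentration draws
#'
#' Every endpoint carries a 50% uncertainty/variability interval, applied
#' multiplicatively as a triangular factor around 1. Acute endpoints are
#' additionally divided by an acute-to-chronic assessment factor, and
#' observed-effect endpoints by an effect-to-no-effect factor; each factor
#' has central value 10 with the same 50% interval (triangular 5, 10, 15).
#' A chronic NOEC therefore passes through unchanged on the median path.
#'
#' @param concentration Reported endpoint concentration (> 0).
#' @param endpoint_kind One of `acute_effect`, `chronic_effect`,
#'   `acute_noec`, `chronic_noec`.
#' @param n Number of draws.
#' @param assessment_factor Central assessment factor (default 10).
#' @param spread Relative half-width of the uncertainty interval
#'   (default 0.5).
#' @return Numeric vector of `n` no-effect concentration draws.
#' @export
transform_endpoint <- function(concentration, endpoint_kind, n,
                               assessment_factor = 10, spread = 0.5) {
  if (!endpoint_kind %in% ENDPOINT_KINDS)
    stop("unknown endpoint_kind: ", endpoint_kind)
  if (concentration <= 0) stop("concentration must be > 0")
  u <- sample_dist(dist_spread(1, spread), n)
  x <- concentration * u
  if (startsWith(endpoint_kind, "acute"))
    x <- x / sample_dist(dist_spread(assessment_factor, spread), n)
  if (endsWith(endpoint_kind, "effect"))
    x <- x / sample_dist(dist_spread(assessment_factor, spread), n)
  x
}

#' Single-species sensitivity distribution
#'
#' Builds the sensitivity sample for one species: each draw picks one of
#' the species' endpoints uniformly at random and transforms it with
#' [transform_endpoint()].
#'
#' @param endpoints data.frame of this species' endpoints (columns
#'   `endpoint_kind`, `concentration`).
#' @param n Number of draws.
#' @inheritParams transform_endpoint
#' @return Numeric vector of `n` positive concentration draws.
#' @export
build_species_distribution <- function(endpoints, n,
                                       assessment_factor = 10,
                                       spread = 0.5) {
  if (nrow(endpoints) == 0) stop("species has no endpoints")
  pick <- sample.int(nrow(endpoints), n, replace = TRUE)
  out <- numeric(n)
  for (i in seq_len(nrow(endpoints))) {
    idx <- which(pick == i)
    if (!length(idx)) next
    out[idx] <- transform_endpoint(endpoints$concentration[i],
                                   endpoints$endpoint_kind[i],
                                   length(idx), assessment_factor, spread)
  }
  out
}

#' Build an ensemble of probabilistic species sensitivity curves
#'
#' Each curve takes one draw per species from the single-species
#' distributions, sorts them ascending, and assigns cumulative affected
#' fractions `k/S`. Ties are broken by a deterministic relative jitter of
#' 1 part in 1e9 so every curve is strictly increasing.
#'
#' @param species_samples Named list (one entry per species, >= 2
#'   species) of positive sample vectors from
#'   [build_species_distribution()].
#' @param n_curves Number of curves in the ensemble (default 1000).
#' @return Object of class `pssd_curves`: `curves`
#'   (`n_curves x n_species` matrix, rows sorted ascending), `fractions`
#'   (`k/S`), `species`.
#' @export
build_pssd_curves <- function(species_samples, n_curves = 1000) {
  S <- length(species_samples)
  if (S < 2) stop("need at least 2 species to build a PSSD")
  draws <- vapply(species_samples, function(v)
    v[sample.int(length(v), n_curves, replace = TRUE)],
    numeric(n_curves))
  curves <- t(apply(draws, 1, sort))
  # deterministic tie-jitter keeps every curve strictly increasing
  for (k in 2:S) {
    tied <- curves[, k] <= curves[, k - 1]
    if (any(tied))
      curves[tied, k] <- curves[tied, k - 1] * (1 + 1e-9)
  }
  structure(list(curves = curves, fractions = seq_len(S) / S,
                 species = names(species_samples)),
            class = "pssd_curves")
}

#' Probabilistic risk from PEC / PSSD overlap
#'
#' Combines two probabilities: `p_critical_pec`, the fraction of PEC
#' samples exceeding the lowest concentration of any curve in the
#' ensemble (critical PECs), and `p_critical_pssd`, the fraction of
#' curves whose most sensitive species draw lies below the highest PEC
#' sample (critical PSSDs). The default combination is their product, in
#' percent; `"paired"` instead pairs each PEC sample with a random curve
#' and reports the joint exceedance frequency.
#'
#' @param pec_samples Positive PEC sample vector.
#' @param curves A [build_pssd_curves()] ensemble.
#' @param combination `"product"` (default) or `"paired"`.
#' @return List with `risk_percent`, `p_critical_pec`,
#'   `p_critical_pssd`.
#' @export
risk_percent <- function(pec_samples, curves,
                         combination = c("product", "paired")) {
  combination <- match.arg(combination)
  if (!length(pec_samples)) stop("empty PEC sample vector")
  if (!inherits(curves, "pssd_curves")) stop("curves must be pssd_curves")
  curve_min <- curves$curves[, 1]
  p_a <- mean(pec_samples > min(curve_min))
  p_b <- mean(curve_min < max(pec_samples))
  risk <- if (combination == "product") {
    100 * p_a * p_b
  } else {
    j <- sample.int(length(curve_min), length(pec_samples), replace = TRUE)
    100 * mean(pec_samples > curve_min[j])
  }
  list(risk_percent = risk, p_critical_pec = p_a, p_critical_pssd = p_b)
}

#' Risk table for the aquatic compartments
#'
#' Screens fresh and marine water PECs (total and EOL-only load) against
#' a PSSD ensemble for the requested years. Terrestrial and sediment
#' compartments are refused: no PSSD can be built for them from aquatic
#' endpoint data.
#'
#' @param pec A [compute_pec()] result.
#' @param curves_by_substance Named list of [build_pssd_curves()]
#'   ensembles, keyed by substance (a single ensemble is recycled for
#'   all).
#' @param years Calendar years to evaluate.
#' @param compartments Water compartments to screen.
#' @param combination Passed to [risk_percent()].
#' @return data.frame with columns `substance`, `year`, `water_body`,
#'   `load`, `risk_percent`, `p_critical_pec`, `p_critical_pssd`.
#' @export
risk_table <- function(pec, curves_by_substance,
                       years = c(2017, 2030, 2050),
                       compartments = c("surface_water", "sea_water"),
                       combination = "product") {
  bad <- grep("soil|sediment", compartments, value = TRUE)
  if (length(bad))
    stop("risk is only computed for water compartments; no PSSD can be ",
         "built for: ", paste(bad, collapse = ", "))
  body_name <- c(surface_water = "freshwater", sea_water = "seawater")
  rows <- list()
  for (sub in names(pec$substances)) {
    curves <- if (inherits(curves_by_substance, "pssd_curves"))
      curves_by_substance else curves_by_substance[[sub]]
    if (is.null(curves)) stop("no PSSD curves for substance ", sub)
    for (cm in compartments) for (load in c("total", "eol_only")) {
      mat <- pec$substances[[sub]][[load]][[cm]]$degradation_1yr
      if (is.null(mat)) next
      for (yr in years) {
        col <- as.character(yr)
        if (!col %in% colnames(mat)) next
        rr <- risk_percent(mat[, col], curves, combination)
        rows[[length(rows) + 1L]] <- data.frame(
          substance = sub, year = yr, water_body = body_name[[cm]],
          load = load, risk_percent = rr$risk_percent,
          p_critical_pec = rr$p_critical_pec,
          p_critical_pssd = rr$p_critical_pssd,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
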