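#' Sample per-year growth rates
#'
#' Draws one growth rate (%/a) per step-ending calendar year and per Monte
#' Carlo iteration. Rates are independent across years and iterations;
#' within an iteration, all of a substance's applications share this one
#' macro path.
#'
#' @param trend A [growth_trend()].
#' @param years Step-ending calendar years (rate of `years[k]` governs the
#'   step from `years[k] - 1` to `years[k]`).
#' @param n Number of iterations.
#' @return `n x length(years)` matrix of rates in %/a, with `years` as
#'   column names.
#' @export
sample_growth_rates <- function(trend, years, n) {
  m <- matrix(0, n, length(years), dimnames = list(NULL, years))
  for (k in seq_along(years))
    m[, k] <- sample_dist(growth_rate_dist(trend, years[k]), n)
  m
}

#' Median-path growth rates
#'
#' The deterministic rate path with every year's rate at its median; used
#' for scaling single estimates between reference years.
#'
#' @inheritParams sample_growth_rates
#' @return Named numeric vector of rates in %/a.
#' @export
median_growth_path <- function(trend, years) {
  r <- vapply(years, function(y) dist_central(growth_rate_dist(trend, y)), 0)
  names(r) <- years
  r
}

#' Compound a mass along a growth-rate path
#'
#' Applies compound annual growth from `year_from` to `year_to`:
#' multiplication by `prod(1 + rate/100)` over the step years crossed when
#' moving forward, division when moving backward, identity when the years
#' coincide. `rates` may be a vector (one path) or an `n x years` matrix
#' (per-iteration paths); `mass` is recycled across iterations or may be a
#' vector of length `n`.
#'
#' @param mass Mass in t/a (scalar or length-`n` vector).
#' @param year_from,year_to Calendar years.
#' @param rates Rate path from [sample_growth_rates()] or
#'   [median_growth_path()] with named year columns/entries.
#' @return Scaled mass, same shape as `mass` (or length `n` for matrix
#'   `rates`).
#' @export
apply_growth <- function(mass, year_from, year_to, rates) {
  if (year_from == year_to) return(mass)
  lo <- min(year_from, year_to); hi <- max(year_from, year_to)
  step_years <- as.character(seq(lo + 1L, hi))
  if (is.matrix(rates)) {
    missing <- setdiff(step_years, colnames(rates))
    if (length(missing))
      stop("rate path does not cover years ",
           paste(missing, collapse = ", "))
    fac <- apply(1 + rates[, step_years, drop = FALSE] / 100, 1, prod)
  } else {
    missing <- setdiff(step_years, names(rates))
    if (length(missing))
      stop("rate path does not cover years ",
           paste(missing, collapse = ", "))
    fac <- prod(1 + rates[step_years] / 100)
  }
  if (year_to > year_from) mass * fac else mass / fac
}

#' Sample the global annual production volume of a substance
#'
#' Each Monte Carlo draw picks one estimate source uniformly at random
#' (equal weighting of survey and literature sources), samples its
#' `[low, high]` range (uniform on the linear scale by default, or uniform
#' in log10 for order-of-magnitude ranges), and rescales the value from
#' the estimate's own year to `reference_year` along the supplied
#' growth-rate path.
#'
#' @param estimates data.frame with columns `source_tag`, `low`, `high`,
#'   `year` (t/a).
#' @param reference_year Year the returned volumes refer to.
#' @param n Number of draws.
#' @param rates Growth-rate path covering all years between estimate years
#'   and `reference_year` (vector, or `n x years` matrix for
#'   per-iteration paths).
#' @param scale `"linear"` or `"log"` range sampling.
#' @return List with `mass` (length-`n` vector, t/a at `reference_year`)
#'   and `source` (integer row index of the estimate used per draw).
#' @export
sample_global_production <- function(estimates, reference_year, n, rates,
                                     scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (is.null(estimates) || nrow(estimates) == 0)
    stop("no production estimates supplied")
  src <- sample.int(nrow(estimates), n, replace = TRUE)
  lo <- estimates$low[src]; hi <- estimates$high[src]
  raw <- if (scale == "log") {
    lo2 <- pmax(lo, 1e-12)
    10^stats::runif(n, log10(lo2), log10(pmax(hi, lo2)))
  } else {
    stats::runif(n, lo, hi)
  }
  raw[lo == hi] <- lo[lo == hi]  # point estimates
  mass <- raw
  for (yr in unique(estimates$year)) {
    idx <- which(estimates$year[src] == yr)
    if (!length(idx) || yr == reference_year) next
    r <- if (is.matrix(rates)) rates[idx, , drop = FALSE] else rates
    mass[idx] <- apply_growth(raw[idx], yr, reference_year, r)
  }
  list(mass = mass, source = src)
}

#' Regional share of a global production volume
#'
#' Scales global production to the target region by the ratio of the
#' region's annual domestic demand to the worldwide gross domestic
#' product (both in the same currency and year; the ratio is
#' dimensionless).
#'
#' @param global_mass Global production, t/a.
#' @param domestic_demand,world_gdp Monetary aggregates, same units.
#' @return Regional mass, t/a.
#' @export
regional_share <- function(global_mass, domestic_demand, world_gdp) {
  if (world_gdp <= 0) stop("world_gdp must be > 0")
  if (domestic_demand < 0 || any(global_mass < 0))
    stop("masses and demand must be non-negative")
  global_mass * domestic_demand / world_gdp
}

#' Renormalize application-share draws that jointly exceed 1
#'
#' Shares are independent per-category fractions of a substance's
#' production; a joint Monte Carlo draw can therefore sum above 1. Such
#' draws are rescaled proportionally to sum to exactly 1; draws summing
#' below 1 are left untouched (the remainder is unallocated mass that
#' never enters the system).
#'
#' @param shares `n x k` matrix of share draws (columns = applications).
#' @return Matrix of the same shape with row sums <= 1.
#' @export
renormalize_shares <- function(shares) {
  rs <- rowSums(shares)
  over <- rs > 1
  if (any(over)) shares[over, ] <- shares[over, , drop = FALSE] / rs[over]
  shares
}

#' Annual cohort input masses for every application
#'
#' The driver of the release model: for each Monte Carlo iteration and
#' calendar year, the regional mass of each substance entering each
#' application ("cohort"). Per iteration, one production volume is drawn
#' at the reference year, scaled regionally, propagated along that
#' iteration's growth path to every horizon year, and split over the
#' substance's applications by sampled shares (renormalized when a joint
#' draw exceeds 1). Years before an application's `start_year` get exactly
#' zero.
#'
#' All draws run under substream seeds derived from `seed` and the
#' substance/application names, so books can grow without perturbing
#' other substances' samples.
#'
#' @param book A [parameter_book()].
#' @param n Number of iterations (default `book$sim$n_iterations`).
#' @param seed Master seed (default `book$sim$seed`).
#' @return Object of class `cohort_inputs`: list with `years`, and per
#'   substance `production` (`n x years` regional mass matrix), `rates`
#'   (growth paths) and per application `cohorts[[app_id]]`
#'   (`n x years` cohort matrix, t/a).
#' @export
cohort_inputs <- function(book, n = NULL, seed = NULL) {
  if (is.null(n)) n <- book$sim$n_iterations
  if (is.null(seed)) seed <- book$sim$seed
  years <- seq(book$sim$year_start, book$sim$year_end)
  ref <- book$sim$reference_year
  rate_years <- seq(min(book$sim$year_start,
                        min(book$production_estimates$year), ref) + 1L,
                    max(book$sim$year_end, ref))
  out <- list(years = years, n = n, substances = list())
  for (sub in book$substances) {
    apps <- Filter(function(a) a$substance == sub, book$applications)
    if (!length(apps)) stop("no applications for substance ", sub)
    est <- book$production_estimates[
      book$production_estimates$substance == sub, , drop = FALSE]

    set.seed(substream_seed(seed, paste0(sub, "/rates")))
    rates <- sample_growth_rates(book$trend, rate_years, n)
    set.seed(substream_seed(seed, paste0(sub, "/production")))
    glob <- sample_global_production(est, ref, n, rates,
                                     scale = book$sim$production_sampling)
    reg_ref <- regional_share(glob$mass, book$regional$domestic_demand,
                              book$regional$world_gdp)

    # propagate the reference-year mass to every horizon year along the
    # iteration's own growth path
    prod_mat <- matrix(0, n, length(years),
                       dimnames = list(NULL, years))
    for (k in seq_along(years))
      prod_mat[, k] <- apply_growth(reg_ref, ref, years[k], rates)

    shares <- matrix(0, n, length(apps))
    for (j in seq_along(apps)) {
      set.seed(substream_seed(seed, paste0(sub, "/", apps[[j]]$id,
                                           "/share")))
      shares[, j] <- sample_dist(apps[[j]]$share, n)
    }
    shares <- renormalize_shares(shares)

    cohorts <- list()
    for (j in seq_along(apps)) {
      a <- apps[[j]]
      cm <- prod_mat * shares[, j]
      cm[, years < a$start_year] <- 0
      cohorts[[a$id]] <- cm
    }
    out$substances[[sub]] <- list(production = prod_mat, rates = rates,
                                  shares = shares, cohorts = cohorts)
  }
  class(out) <- "cohort_inputs"
  out
}
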