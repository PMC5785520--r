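#' Summarize Monte Carlo samples in the reporting convention
#'
#' Reports sample extremes (`min`, `max`), a most-probable inter-percentile
#' range (default 5th-95th, excluding simultaneous-extreme parameter
#' scenarios), the arithmetic mean, and the mode: the midpoint of the
#' highest-count bin of a histogram whose bin count follows the
#' Freedman-Diaconis rule. Because Monte Carlo outputs typically span
#' orders of magnitude, the histogram is built on a log axis whenever all
#' samples are positive (set `log_axis = FALSE` for a linear axis).
#'
#' @param x Numeric sample vector (>= 1 value).
#' @param unit Unit string carried along for reporting.
#' @param probs Lower and upper probabilities of the most-probable range.
#' @param log_axis Build the mode histogram on a log10 axis when
#'   possible?
#' @return Object of class `summary_stat`: list with `min`, `mode`,
#'   `range_low`, `range_high`, `max`, `mean`, `unit`.
#' @export
summarize_samples <- function(x, unit = NA_character_,
                              probs = c(0.05, 0.95), log_axis = TRUE) {
  if (!length(x)) stop("cannot summarize an empty sample vector")
  if (anyNA(x)) stop("samples contain NA")
  qs <- unname(stats::quantile(x, probs))
  structure(list(min = min(x), mode = sample_mode(x, log_axis),
                 range_low = qs[1], range_high = qs[2], max = max(x),
                 mean = mean(x), unit = unit),
            class = "summary_stat")
}

sample_mode <- function(x, log_axis = TRUE) {
  ux <- unique(x)
  if (length(ux) == 1) return(ux)
  use_log <- log_axis && all(x > 0)
  v <- if (use_log) log10(x) else x
  iqr <- stats::IQR(v)
  width <- 2 * iqr / length(v)^(1 / 3)           # Freedman-Diaconis
  span <- diff(range(v))
  nbins <- if (width > 0) max(1L, ceiling(span / width)) else 30L
  nbins <- min(nbins, 10000L)
  h <- graphics::hist(v, breaks = seq(min(v), max(v),
                                      length.out = nbins + 1L),
                      plot = FALSE)
  mid <- h$mids[which.max(h$counts)]
  if (use_log) 10^mid else mid
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(sprintf(
    "min %.4g | mode %.4g | range [%.4g, %.4g] | max %.4g | mean %.4g %s\n",
    x$min, x$mode, x$range_low, x$range_high, x$max, x$mean,
    ifelse(is.na(x$unit), "", x$unit)))
  invisible(x)
}

summary_row <- function(s) {
  data.frame(min = s$min, mode = s$mode, range_low = s$range_low,
             range_high = s$range_high, max = s$max, mean = s$mean,
             unit = s$unit, stringsAsFactors = FALSE)
}

write_report_csv <- function(df, path) {
  for (cl in names(df))
    if (is.numeric(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, eol = "\n")
}

#' Export pipeline results as tidy report tables
#'
#' Runs the fate and concentration stages on a completed simulation and
#' writes deterministic CSVs to `out_dir`:
#' \describe{
#'   \item{release_summary.csv}{annual release to nature vs. technical
#'     sinks per substance, origin stream and year}
#'   \item{pec_summary.csv}{PEC summary per substance, compartment, load,
#'     scenario and year}
#'   \item{risk_summary.csv}{aquatic risk percentages (only when an
#'     endpoint table is supplied)}
#'   \item{density_<year>.csv}{log10 freshwater PEC density curves}
#' }
#' Re-running with the same seed reproduces every file byte for byte.
#'
#' @param sim An [simulate_release()] result.
#' @param out_dir Output directory (created if missing).
#' @param years Reporting years.
#' @param endpoints Optional endpoint data.frame (see
#'   [read_endpoints()]); may carry a `substance` column.
#' @param n_curves PSSD ensemble size.
#' @param seed Seed for fate and PSSD draws (default: book seed).
#' @return Invisibly, a list with the computed `flux`, `pec` and `risk`
#'   objects.
#' @export
report <- function(sim, out_dir, years = c(2017, 2030, 2050),
                   endpoints = NULL, n_curves = 1000, seed = NULL) {
  if (is.null(seed)) seed <- sim$book$sim$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  years <- years[years >= min(sim$years) & years <= max(sim$years)]
  flux <- compartment_flux(sim, seed)
  pec <- compute_pec(flux, sim$book$geometry)

  primary_nat <- function(set) setdiff(names(set),
    c("sea_water", "sediment_fresh", "sediment_marine"))
  terminal_tech <- c("landfill", "recycling", "elimination")
  rel_rows <- list()
  for (sub in names(flux$substances)) for (orig in c("use", "eol")) {
    fx <- flux$substances[[sub]][[orig]]
    for (yr in years) {
      col <- as.character(yr)
      nat <- 0
      for (cm in primary_nat(fx$natural)) nat <- nat + fx$natural[[cm]][, col]
      tech <- 0
      for (cm in intersect(terminal_tech, names(fx$technical)))
        tech <- tech + fx$technical[[cm]][, col]
      for (dest in c("nature", "technosphere")) {
        s <- summarize_samples(if (dest == "nature") nat else tech,
                               unit = "t/a")
        rel_rows[[length(rel_rows) + 1L]] <- cbind(
          data.frame(substance = sub, origin = orig, destination = dest,
                     year = yr, stringsAsFactors = FALSE), summary_row(s))
      }
    }
  }
  write_report_csv(do.call(rbind, rel_rows),
                   file.path(out_dir, "release_summary.csv"))

  pec_rows <- list()
  for (sub in names(pec$substances)) for (load in c("total", "eol_only")) {
    comps <- pec$substances[[sub]][[load]]
    for (cm in sort(names(comps))) for (scen in names(comps[[cm]])) {
      mat <- comps[[cm]][[scen]]
      for (yr in years) {
        col <- as.character(yr)
        s <- summarize_samples(mat[, col], unit = attr(mat, "unit"))
        pec_rows[[length(pec_rows) + 1L]] <- cbind(
          data.frame(substance = sub, compartment = cm, load = load,
                     scenario = scen, year = yr, stringsAsFactors = FALSE),
          summary_row(s))
      }
    }
  }
  write_report_csv(do.call(rbind, pec_rows),
                   file.path(out_dir, "pec_summary.csv"))

  for (yr in years) {
    dens_rows <- list()
    for (sub in names(pec$substances)) {
      mat <- pec$substances[[sub]]$total$surface_water$degradation_1yr
      if (is.null(mat)) next
      x <- mat[, as.character(yr)]
      x <- x[x > 0]
      if (length(x) < 2) next
      d <- stats::density(log10(x), n = 128)
      dens_rows[[length(dens_rows) + 1L]] <- data.frame(
        substance = sub, log10_conc = d$x, density = d$y,
        unit = "ng/L", stringsAsFactors = FALSE)
    }
    if (length(dens_rows))
      write_report_csv(do.call(rbind, dens_rows),
                       file.path(out_dir, sprintf("density_%d.csv", yr)))
  }

  risk <- NULL
  if (!is.null(endpoints)) {
    endpoints <- validate_endpoints(endpoints)
    curves <- list()
    for (sub in names(pec$substances)) {
      ep <- if ("substance" %in% names(endpoints))
        endpoints[endpoints$substance == sub, , drop = FALSE] else endpoints
      if (nrow(ep) == 0) next
      set.seed(substream_seed(seed, paste0("pssd/", sub)))
      species_samples <- list()
      for (sp in unique(ep$species)) {
        rows <- ep[ep$species == sp, , drop = FALSE]
        species_samples[[sp]] <- build_species_distribution(rows, n_curves)
      }
      curves[[sub]] <- build_pssd_curves(species_samples, n_curves)
    }
    if (length(curves)) {
      risk <- risk_table(pec, curves, years = years)
      write_report_csv(risk, file.path(out_dir, "risk_summary.csv"))
    }
  }
  invisible(list(flux = flux, pec = pec, risk = risk))
}
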