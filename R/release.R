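#' Cohort-based annual release and stock series
#'
#' The mathematical core of the pipeline: each calendar-year cohort
#' `I(j)` of mass entering an application is released uniformly over the
#' product lifespan `m` (use-phase stream), while the never-released
#' complement leaves the product all at once `m` years after the cohort
#' year (end-of-life stream). Four series describe the system:
#' \describe{
#'   \item{use release}{`r_use(t) = sum_{j = t-m+1}^{t} I(j) / m`}
#'   \item{use stock}{in-circulation, not-yet-released mass
#'     `sum_j I(j) (m + j - t - 1)/m` over active cohorts}
#'   \item{EOL release}{`r_eol(t) = I_eol(t - m)`}
#'   \item{EOL stock}{mass waiting for end-of-life treatment,
#'     `sum_{j = t-m+1}^{t} I_eol(j)`}
#' }
#' The cohort year itself counts as the first release year, so a lifespan
#' of 1 releases the whole cohort in its own year and carries no stock.
#' Both stocks satisfy the exact bookkeeping identity
#' `stock(t) = cumulative input(t) - cumulative release(t)`.
#'
#' All functions accept a numeric vector (one series over consecutive
#' years) or an `iterations x years` matrix and return the same shape.
#'
#' @param I Cohort input series (t/a), vector or matrix.
#' @param m Product lifespan in years, integer >= 1.
#' @name release_series
NULL

as_row_matrix <- function(I) {
  if (is.matrix(I)) list(m = I, vec = FALSE)
  else list(m = matrix(I, nrow = 1), vec = TRUE)
}

# shift every row right by k, zero-filling on the left
shift_right <- function(M, k) {
  if (k == 0) return(M)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  if (k < ncol(M))
    out[, (k + 1):ncol(M)] <- M[, 1:(ncol(M) - k), drop = FALSE]
  out
}

row_cumsum <- function(M) {
  if (nrow(M) == 1) matrix(cumsum(M[1, ]), 1, ncol(M),
                           dimnames = dimnames(M))
  else t(apply(M, 1, cumsum))
}

#' @rdname release_series
#' @return `use_release()`: release to the use stream, t/a.
#' @export
use_release <- function(I, m) {
  stopifnot(m >= 1)
  x <- as_row_matrix(I)
  C <- row_cumsum(x$m)
  r <- (C - shift_right(C, m)) / m
  if (x$vec) drop(r) else r
}

#' @rdname release_series
#' @return `use_stock()`: in-circulation mass, t.
#' @export
use_stock <- function(I, m) {
  stopifnot(m >= 1)
  x <- as_row_matrix(I)
  s <- matrix(0, nrow(x$m), ncol(x$m), dimnames = dimnames(x$m))
  if (m > 1)
    for (k in 0:(m - 2))             # cohort aged k years holds (m-1-k)/m
      s <- s + shift_right(x$m, k) * ((m - 1 - k) / m)
  if (x$vec) drop(s) else s
}

#' @rdname release_series
#' @param I_eol Series of the cohort mass destined for end-of-life
#'   treatment (the never-released complement), t/a.
#' @return `eol_release()`: release to end-of-life treatment, t/a.
#' @export
eol_release <- function(I_eol, m) {
  stopifnot(m >= 1)
  x <- as_row_matrix(I_eol)
  r <- shift_right(x$m, m)
  if (x$vec) drop(r) else r
}

#' @rdname release_series
#' @return `eol_stock()`: mass waiting for end-of-life treatment, t.
#' @export
eol_stock <- function(I_eol, m) {
  stopifnot(m >= 1)
  x <- as_row_matrix(I_eol)
  C <- row_cumsum(x$m)
  s <- C - shift_right(C, m)
  if (x$vec) drop(s) else s
}

#' Total release across applications
#'
#' Elementwise sum of aligned release series; the system-level annual
#' release is the sum over all applications and their contributing
#' life-cycle years.
#'
#' @param series List of equally shaped numeric vectors/matrices.
#' @return Elementwise sum, same shape.
#' @export
total_release <- function(series) {
  if (!length(series)) stop("no series supplied")
  dims <- lapply(series, function(s) if (is.matrix(s)) dim(s)
                 else length(s))
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1)
    stop("release series have mismatched horizons")
  Reduce(`+`, series)
}

#' Accumulative release (persistence scenario)
#'
#' Running cumulative sum of an annual release series: the load present
#' when released material persists in the receiving compartment with no
#' degradation, so every year's release adds to all previous years'.
#'
#' @param r Annual release series (vector or `iterations x years`
#'   matrix), t/a.
#' @return Cumulative series, t; same shape as `r`.
#' @export
accumulative_release <- function(r) {
  x <- as_row_matrix(r)
  C <- row_cumsum(x$m)
  if (x$vec) drop(C) else C
}

sum_dists <- function(draws) if (length(draws)) Reduce(`+`, draws) else 0

#' Run the full Monte Carlo release simulation
#'
#' For each iteration: samples all parameters once (transfer coefficients
#' are held constant over the century; only growth rates vary by year),
#' builds cohort inputs, splits every cohort into a production-phase
#' release (emitted in the cohort year), a use-release-destined fraction
#' (emitted uniformly over the lifespan) and the end-of-life complement
#' (emitted `m` years after the cohort year), and evaluates the release
#' and stock series over the whole horizon. If a joint draw of production
#' plus use transfer coefficients exceeds 1, both are rescaled
#' proportionally so the cohort is never over-committed.
#'
#' Deterministic under a fixed seed: every parameter block is drawn under
#' its own substream seed keyed by substance, application and role.
#'
#' @param book A [parameter_book()].
#' @param n Iterations (default `book$sim$n_iterations`).
#' @param seed Master seed (default `book$sim$seed`).
#' @return Object of class `enm_simulation`: `years`, `n`, `book`,
#'   `inputs` (the [cohort_inputs()]), and per application id a list with
#'   the cohort matrix, TC draws, per-compartment flux matrices for the
#'   `production`, `use` and `eol` streams (t/a), and `stock_use` /
#'   `stock_eol` matrices (t).
#' @export
simulate_release <- function(book, n = NULL, seed = NULL) {
  if (is.null(n)) n <- book$sim$n_iterations
  if (is.null(seed)) seed <- book$sim$seed
  inputs <- cohort_inputs(book, n, seed)
  years <- inputs$years
  max_m <- max(vapply(book$applications, function(a) a$lifespan_m, 1L))
  if (length(years) < max_m)
    warning("simulation horizon shorter than the longest product ",
            "lifespan; tail cohorts are truncated")

  apps_out <- list()
  for (a in book$applications) {
    I <- inputs$substances[[a$substance]]$cohorts[[a$id]]
    m <- a$lifespan_m

    draw_tc <- function(tcs, phase) {
      out <- list()
      for (cm in names(tcs)) {
        set.seed(substream_seed(seed, paste(a$substance, a$id, phase, cm,
                                            sep = "/")))
        out[[cm]] <- sample_dist(tcs[[cm]], n)
      }
      out
    }
    tc_prod <- draw_tc(a$tc_production, "tc_production")
    tc_use <- draw_tc(a$tc_use, "tc_use")
    tc_eol <- draw_tc(a$tc_eol, "tc_eol")

    # EOL split must exhaust the stream: renormalize draws to sum to 1
    eol_sum <- sum_dists(tc_eol)
    for (cm in names(tc_eol)) tc_eol[[cm]] <- tc_eol[[cm]] / eol_sum

    f_prod <- sum_dists(tc_prod)
    f_use <- sum_dists(tc_use)
    over <- (f_prod + f_use) > 1
    if (any(over)) {
      sc <- 1 / (f_prod + f_use)[over]
      for (cm in names(tc_prod)) tc_prod[[cm]][over] <- tc_prod[[cm]][over] * sc
      for (cm in names(tc_use)) tc_use[[cm]][over] <- tc_use[[cm]][over] * sc
      f_prod <- sum_dists(tc_prod)
      f_use <- sum_dists(tc_use)
    }
    f_eol <- pmax(1 - f_prod - f_use, 0)

    r_use_unit <- use_release(I, m)          # release per unit TC
    I_eol <- I * f_eol
    flux <- list(production = list(), use = list(), eol = list())
    for (cm in names(tc_prod)) flux$production[[cm]] <- I * tc_prod[[cm]]
    for (cm in names(tc_use)) flux$use[[cm]] <- r_use_unit * tc_use[[cm]]
    r_eol_total <- eol_release(I_eol, m)
    for (cm in names(tc_eol)) flux$eol[[cm]] <- r_eol_total * tc_eol[[cm]]

    apps_out[[a$id]] <- list(
      substance = a$substance, lifespan_m = m, start_year = a$start_year,
      input = I, tc = list(production = tc_prod, use = tc_use,
                           eol = tc_eol),
      fractions = list(production = f_prod, use = f_use, eol = f_eol),
      flux = flux,
      stock_use = use_stock(I * f_use, m),
      stock_eol = eol_stock(I_eol, m))
  }
  structure(list(years = years, n = n, book = book, inputs = inputs,
                 applications = apps_out),
            class = "enm_simulation")
}

#' @export
print.enm_simulation <- function(x, ...) {
  cat(sprintf(paste0("<enm_simulation: %d iterations, years %d-%d, ",
                     "%d application(s), %d substance(s)>\n"),
              x$n, min(x$years), max(x$years), length(x$applications),
              length(x$book$substances)))
  invisible(x)
}
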