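#' Parametric specification of an uncertain scalar
#'
#' All uncertain model inputs (production volumes, application shares,
#' transfer coefficients, growth rates, assessment factors) are carried as
#' `dist_spec` objects: a distribution family, its parameters, and a hard
#' support interval outside which no draw may fall. Sampling truncates by
#' rejection, so a triangular transfer coefficient specified as +/-50%
#' around a literature value never leaves [0, 1].
#'
#' Supported families:
#' \describe{
#'   \item{point}{degenerate at `value`}
#'   \item{uniform}{on `[min, max]`}
#'   \item{triangular}{with `min`, `mode`, `max`}
#'   \item{trapezoidal}{with corners `a <= b <= c <= d` (flat on `[b, c]`)}
#'   \item{lognormal}{with `meanlog`, `sdlog` on the log scale}
#' }
#'
#' @param family Distribution family name.
#' @param ... Family parameters (see above).
#' @param support Optional length-2 numeric truncation interval; defaults
#'   to the family's natural support.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("point", "uniform", "triangular",
                                 "trapezoidal", "lognormal"),
                      ..., support = NULL) {
  family <- match.arg(family)
  params <- list(...)
  natural <- switch(family,
    point = {
      if (is.null(params$value)) stop("point distribution needs `value`")
      c(params$value, params$value)
    },
    uniform = {
      if (is.null(params$min) || is.null(params$max))
        stop("uniform distribution needs `min` and `max`")
      if (params$min > params$max) stop("uniform: min > max")
      c(params$min, params$max)
    },
    triangular = {
      p <- params
      if (any(vapply(p[c("min", "mode", "max")], is.null, TRUE)))
        stop("triangular distribution needs `min`, `mode`, `max`")
      if (!(p$min <= p$mode && p$mode <= p$max))
        stop("triangular: need min <= mode <= max")
      c(p$min, p$max)
    },
    trapezoidal = {
      p <- params
      if (any(vapply(p[c("a", "b", "c", "d")], is.null, TRUE)))
        stop("trapezoidal distribution needs `a`, `b`, `c`, `d`")
      if (!(p$a <= p$b && p$b <= p$c && p$c <= p$d))
        stop("trapezoidal: need a <= b <= c <= d")
      c(p$a, p$d)
    },
    lognormal = {
      p <- params
      if (is.null(p$meanlog) || is.null(p$sdlog))
        stop("lognormal distribution needs `meanlog` and `sdlog`")
      if (p$sdlog < 0) stop("lognormal: sdlog < 0")
      c(0, Inf)
    }
  )
  if (is.null(support)) support <- natural
  if (length(support) != 2 || support[1] > support[2])
    stop("support must be a length-2 increasing interval")
  structure(list(family = family, params = params,
                 support_low = support[1], support_high = support[2]),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @param value Point value.
#' @export
dist_point <- function(value) dist_spec("point", value = value)

#' @rdname dist_spec
#' @param min,max Interval bounds.
#' @export
dist_uniform <- function(min, max) dist_spec("uniform", min = min, max = max)

#' @rdname dist_spec
#' @param mode Most likely value.
#' @export
dist_triangular <- function(min, mode, max, support = NULL)
  dist_spec("triangular", min = min, mode = mode, max = max,
            support = support)

#' @rdname dist_spec
#' @param a,b,c,d Trapezoid corners.
#' @export
dist_trapezoidal <- function(a, b, c, d)
  dist_spec("trapezoidal", a = a, b = b, c = c, d = d)

#' @rdname dist_spec
#' @param meanlog,sdlog Log-scale mean and standard deviation.
#' @export
dist_lognormal <- function(meanlog, sdlog, support = NULL)
  dist_spec("lognormal", meanlog = meanlog, sdlog = sdlog, support = support)

#' Triangular distribution with a 50% spread on each side
#'
#' The reporting convention for "median x with 50% uncertainty/variability
#' on each side": triangular(0.5 x, x, 1.5 x). Used for growth rates,
#' single-value transfer coefficients, ecotox endpoints and assessment
#' factors. For fractions the support is clipped to [0, 1].
#'
#' @param x Central (modal) value.
#' @param spread Relative half-width, default 0.5.
#' @param clip_unit Clip the support to [0, 1] (for fractions)?
#' @return A `dist_spec`.
#' @export
dist_spread <- function(x, spread = 0.5, clip_unit = FALSE) {
  lo <- x * (1 - spread)
  hi <- x * (1 + spread)
  if (x < 0) { tmp <- lo; lo <- hi; hi <- tmp }
  sup <- NULL
  if (clip_unit) sup <- c(max(lo, 0), min(hi, 1))
  dist_triangular(lo, x, hi, support = sup)
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<dist_spec %s(%s) on [%g, %g]>\n", x$family, p,
              x$support_low, x$support_high))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Central (modal) value of a distribution specification
#'
#' Used for validation of transfer-coefficient sums and for median-path
#' computations: the point value, the uniform midpoint, the triangular
#' mode, the trapezoidal plateau midpoint, or exp(meanlog).
#'
#' @param spec A `dist_spec`.
#' @return A scalar.
#' @export
dist_central <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$params
  switch(spec$family,
    point = p$value,
    uniform = (p$min + p$max) / 2,
    triangular = p$mode,
    trapezoidal = (p$b + p$c) / 2,
    lognormal = exp(p$meanlog))
}

raw_draw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, n),
    uniform = stats::runif(n, p$min, p$max),
    triangular = {
      u <- stats::runif(n)
      qtri(u, p$min, p$mode, p$max)
    },
    trapezoidal = {
      u <- stats::runif(n)
      qtrap(u, p$a, p$b, p$c, p$d)
    },
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog))
}

# Inverse CDF of the triangular distribution.
qtri <- function(u, a, m, b) {
  if (b == a) return(rep(a, length(u)))
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

# Inverse CDF of the trapezoidal distribution with corners a<=b<=c<=d.
qtrap <- function(u, a, b, c, d) {
  if (a == d) return(rep(a, length(u)))
  h <- 2 / (d + c - b - a)        # plateau density
  u1 <- h * (b - a) / 2           # mass of the rising leg
  u2 <- u1 + h * (c - b)          # mass up to the plateau end
  out <- numeric(length(u))
  lo <- u <= u1 & b > a
  mid <- u > u1 & u <= u2
  hi <- !lo & !mid
  out[lo] <- a + sqrt(2 * u[lo] * (b - a) / h)
  out[mid] <- b + (u[mid] - u1) / h
  out[hi] <- d - sqrt(pmax(0, 2 * (1 - u[hi]) * (d - c) / h))
  out
}

#' Draw samples from a distribution specification
#'
#' Draws `n` values using the session RNG (seed it with [set.seed()] or let
#' [simulate_release()] manage substreams). Values falling outside the
#' declared support are re-drawn (rejection); if the support is so narrow
#' that rejection stalls, remaining values are clamped to the nearest
#' bound.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws, >= 1.
#' @return Numeric vector of length `n`, all within
#'   `[support_low, support_high]`.
#' @export
sample_dist <- function(spec, n) {
  if (!is_dist_spec(spec)) stop("`spec` must be a dist_spec")
  if (n < 1) stop("n must be >= 1")
  x <- raw_draw(spec, n)
  lo <- spec$support_low; hi <- spec$support_high
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- raw_draw(spec, length(bad))
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

#' Derive a reproducible substream seed from a master seed and a key
#'
#' The simulation samples each (substance, application, role) parameter
#' block under its own seed derived from the master seed and a string key,
#' so adding an application to a book never perturbs the draws of other
#' substances or applications.
#'
#' @param master Master integer seed.
#' @param key Character key, e.g. `"Ag/tires/tc_use"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, key) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; products stay < 2^53
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer((h + (as.numeric(master) %% m) * 48271) %% m)
}
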