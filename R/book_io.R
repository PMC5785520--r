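#' @keywords internal
dist_param_order <- list(point = "value", uniform = c("min", "max"),
                         triangular = c("min", "mode", "max"),
                         trapezoidal = c("a", "b", "c", "d"),
                         lognormal = c("meanlog", "sdlog"))

dist_to_list <- function(spec) {
  list(family = spec$family,
       params = spec$params[dist_param_order[[spec$family]]],
       support = c(spec$support_low, spec$support_high))
}

dist_from_list <- function(x, path = "distribution") {
  if (is.null(x$family) || !x$family %in% names(dist_param_order))
    stop(sprintf("%s: unknown or missing distribution family", path),
         call. = FALSE)
  sup <- if (!is.null(x$support)) as.numeric(unlist(x$support)) else NULL
  do.call(dist_spec, c(list(family = x$family), x$params,
                       list(support = sup)))
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v)
    format(v, digits = 15, trim = TRUE, scientific = NA), ""))
}

dist_to_cols <- function(spec) {
  p <- unlist(spec$params[dist_param_order[[spec$family]]])
  p <- c(p, rep(NA_real_, 4 - length(p)))
  list(family = spec$family, p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
       support_low = spec$support_low, support_high = spec$support_high)
}

dist_from_cols <- function(row, path) {
  fam <- row$family
  if (!fam %in% names(dist_param_order))
    stop(sprintf("%s: unknown family '%s'", path, fam), call. = FALSE)
  ord <- dist_param_order[[fam]]
  pv <- as.numeric(row[paste0("p", seq_along(ord))])
  if (anyNA(pv))
    stop(sprintf("%s: missing parameter(s) for family '%s'", path, fam),
         call. = FALSE)
  args <- as.list(pv); names(args) <- ord
  sup <- c(as.numeric(row$support_low), as.numeric(row$support_high))
  if (anyNA(sup)) sup <- NULL
  do.call(dist_spec, c(list(family = fam), args, list(support = sup)))
}

#' Write a parameter book to disk
#'
#' Writes the canonical on-disk form: a `book.yaml` master file plus three
#' CSV tables (`applications.csv`, `transfers.csv`, `estimates.csv`) in a
#' directory. Rows are sorted deterministically, so writing the same book
#' twice yields byte-identical files. The schema of the layout ships with
#' the package (`system.file("schema", "parameter_book.schema.json",
#' package = "nanoflow")`).
#'
#' @param book A [parameter_book()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_parameter_book <- function(book, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  apps <- book$applications[order(vapply(book$applications,
                                         function(a) paste(a$substance, a$id),
                                         ""))]
  app_df <- do.call(rbind, lapply(apps, function(a) {
    sh <- dist_to_cols(a$share)
    data.frame(id = a$id, substance = a$substance,
               start_year = a$start_year, lifespan_m = a$lifespan_m,
               share_family = sh$family, share_p1 = sh$p1, share_p2 = sh$p2,
               share_p3 = sh$p3, share_p4 = sh$p4,
               share_support_low = sh$support_low,
               share_support_high = sh$support_high,
               stringsAsFactors = FALSE)
  }))
  tr_rows <- list()
  for (a in apps) for (ph in c("production", "use", "eol")) {
    tcs <- a[[paste0("tc_", ph)]]
    for (cm in sort(names(tcs))) {
      d <- dist_to_cols(tcs[[cm]])
      tr_rows[[length(tr_rows) + 1L]] <-
        data.frame(application_id = a$id, phase = ph, compartment = cm,
                   family = d$family, p1 = d$p1, p2 = d$p2, p3 = d$p3,
                   p4 = d$p4, support_low = d$support_low,
                   support_high = d$support_high, stringsAsFactors = FALSE)
    }
  }
  tr_df <- if (length(tr_rows)) do.call(rbind, tr_rows) else
    data.frame(application_id = character(), phase = character(),
               compartment = character(), family = character(),
               p1 = numeric(), p2 = numeric(), p3 = numeric(),
               p4 = numeric(), support_low = numeric(),
               support_high = numeric())
  pe <- book$production_estimates
  pe <- pe[order(pe$substance, pe$source_tag, pe$year), , drop = FALSE]

  write_canonical_csv <- function(df, file) {
    for (cl in names(df))
      if (is.numeric(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]])
    utils::write.csv(df, file.path(dir, file), row.names = FALSE,
                     quote = TRUE, eol = "\n")
  }
  write_canonical_csv(app_df, "applications.csv")
  write_canonical_csv(tr_df, "transfers.csv")
  write_canonical_csv(pe, "estimates.csv")

  head <- list(
    substances = as.list(sort(book$substances)),
    trend = unclass(book$trend),
    regional = book$regional,
    fate = lapply(book$fate[sort(names(unclass(book$fate)))], dist_to_list),
    sim = book$sim[c("year_start", "year_end", "reference_year",
                     "n_iterations", "seed", "production_sampling")],
    geometry = unclass(book$geometry),
    files = list(applications = "applications.csv",
                 transfers = "transfers.csv",
                 estimates = "estimates.csv"))
  yaml::write_yaml(head, file.path(dir, "book.yaml"), precision = 15)
  invisible(dir)
}

#' Read a parameter book from disk
#'
#' Reads the directory layout written by [write_parameter_book()] and
#' validates every invariant; violations raise a single error listing the
#' offending field paths.
#'
#' @param path Directory containing `book.yaml`, or the `book.yaml` file
#'   itself.
#' @return A validated [parameter_book()].
#' @export
read_parameter_book <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "book.yaml")
  if (!file.exists(path)) stop("parameter book not found: ", path)
  dir <- dirname(path)
  head <- yaml::read_yaml(path)
  for (f in c("substances", "trend", "sim", "geometry", "files"))
    if (is.null(head[[f]]))
      stop(sprintf("book.yaml: missing section '%s'", f), call. = FALSE)

  read_tbl <- function(key) {
    fp <- file.path(dir, head$files[[key]])
    if (!file.exists(fp))
      stop(sprintf("files.%s: referenced file '%s' not found", key,
                   head$files[[key]]), call. = FALSE)
    utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  app_df <- read_tbl("applications")
  tr_df <- read_tbl("transfers")
  pe <- read_tbl("estimates")

  apps <- lapply(seq_len(nrow(app_df)), function(i) {
    r <- app_df[i, ]
    share <- dist_from_cols(
      data.frame(family = r$share_family, p1 = r$share_p1, p2 = r$share_p2,
                 p3 = r$share_p3, p4 = r$share_p4,
                 support_low = r$share_support_low,
                 support_high = r$share_support_high),
      sprintf("applications.%s.share", r$id))
    tcs <- list(production = list(), use = list(), eol = list())
    sub_tr <- tr_df[tr_df$application_id == r$id, , drop = FALSE]
    for (j in seq_len(nrow(sub_tr))) {
      tr <- sub_tr[j, ]
      tcs[[tr$phase]][[tr$compartment]] <- dist_from_cols(
        tr, sprintf("transfers.%s.%s.%s", r$id, tr$phase, tr$compartment))
    }
    application_profile(r$id, r$substance, r$start_year, r$lifespan_m,
                        share, tc_production = tcs$production,
                        tc_use = tcs$use, tc_eol = tcs$eol)
  })

  tr <- head$trend
  fate <- do.call(fate_params, lapply(head$fate, dist_from_list))
  parameter_book(
    substances = unlist(head$substances),
    applications = apps,
    production_estimates = pe,
    geometry = do.call(compartment_geometry, head$geometry),
    trend = growth_trend(tr$breakpoint_year, tr$median_rate_pre,
                         tr$median_rate_post, tr$relative_spread),
    regional = head$regional,
    fate = fate,
    sim = head$sim)
}
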