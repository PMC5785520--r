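make_app <- function(id = "app1", substance = "Ag", lifespan = 3,
                     tc_eol = list(landfill = dist_point(1)), ...) {
  application_profile(id = id, substance = substance, start_year = 2000,
                      lifespan_m = lifespan, share = dist_point(0.5),
                      tc_use = list(surface_water = dist_point(0.1)),
                      tc_eol = tc_eol, ...)
}

make_book <- function(apps = list(make_app()), validate = TRUE) {
  parameter_book(
    substances = "Ag", applications = apps,
    production_estimates = data.frame(substance = "Ag",
                                      source_tag = "survey", low = 10,
                                      high = 20, year = 2015,
                                      stringsAsFactors = FALSE),
    geometry = synthetic_geometry(), validate = validate)
}

test_that("a written book reads back and re-writes byte-identically", {
  book <- generate_parameter_book(fixture_config(seed = 5))
  d1 <- file.path(tempdir(), "book_a")
  d2 <- file.path(tempdir(), "book_b")
  write_parameter_book(book, d1)
  book2 <- read_parameter_book(d1)
  write_parameter_book(book2, d2)
  for (f in c("book.yaml", "applications.csv", "transfers.csv",
              "estimates.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("EOL transfer coefficients must sum to 1", {
  bad <- make_app(tc_eol = list(landfill = dist_point(0.9)))
  expect_error(make_book(list(bad)), "tc_eol.*0\\.9")
})

test_that("a zero lifespan is a validation error", {
  expect_error(make_book(list(make_app(lifespan = 0))),
               "lifespan_m: must be >= 1")
})

test_that("validation reports every violated field path at once", {
  bad <- application_profile(
    id = "appX", substance = "Au", start_year = 1900, lifespan_m = 0,
    share = dist_point(0.5),
    tc_use = list(surface_water = dist_point(0.1)),
    tc_eol = list(landfill = dist_point(0.5)))
  err <- tryCatch(make_book(list(make_app(), bad)),
                  error = conditionMessage)
  expect_match(err, "applications.appX.substance")
  expect_match(err, "applications.appX.lifespan_m")
  expect_match(err, "applications.appX.start_year")
  expect_match(err, "applications.appX.tc_eol")
})

test_that("share and TC supports must lie in [0, 1]", {
  bad <- make_app()
  bad$share <- dist_uniform(0, 2)
  expect_error(make_book(list(bad)), "share: support")
})

test_that("undeclared substances in estimates are caught", {
  book <- make_book(validate = FALSE)
  book$production_estimates$substance <- "Zn"
  expect_error(validate_parameter_book(book),
               "undeclared substance\\(s\\) Zn")
})

test_that("a missing referenced table file is a clear read error", {
  book <- make_book()
  d <- file.path(tempdir(), "book_missing")
  write_parameter_book(book, d)
  unlink(file.path(d, "transfers.csv"))
  expect_error(read_parameter_book(d), "transfers.csv' not found")
  unlink(d, recursive = TRUE)
})
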