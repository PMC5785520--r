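flat_rates <- function(years) {
  r <- rep(0, length(years)); names(r) <- years; r
}

test_that("a single point estimate yields identical draws", {
  est <- data.frame(substance = "Ag", source_tag = "s", low = 500,
                    high = 500, year = 2015)
  set.seed(1)
  g <- sample_global_production(est, 2015, 100, flat_rates(2000:2020))
  expect_true(all(g$mass == 500))
})

test_that("two sources are mixed with equal weight", {
  est <- data.frame(substance = "Ag", source_tag = c("a", "b"),
                    low = c(10, 30), high = c(20, 40),
                    year = c(2015, 2015))
  set.seed(2)
  g <- sample_global_production(est, 2015, 1e5, flat_rates(2000:2020))
  frac_low <- mean(g$mass >= 10 & g$mass <= 20)
  expect_lt(abs(frac_low - 0.5), 0.01)
})

test_that("draws stay inside their source range before trend scaling", {
  est <- data.frame(substance = "Ag", source_tag = "literature",
                    low = 5.5, high = 550, year = 2015)
  set.seed(3)
  g <- sample_global_production(est, 2015, 1e4, flat_rates(2000:2020))
  expect_true(all(g$mass >= 5.5 & g$mass <= 550))
})

test_that("log-scale sampling spreads mass evenly over decades", {
  est <- data.frame(substance = "Ag", source_tag = "s", low = 1,
                    high = 1e4, year = 2015)
  set.seed(4)
  g <- sample_global_production(est, 2015, 1e5, flat_rates(2000:2020),
                                scale = "log")
  expect_lt(abs(mean(g$mass <= 100) - 0.5), 0.01)
})

test_that("growth compounding matches the 5%/a median path", {
  years <- 2000:2020
  med <- median_growth_path(growth_trend(), years)
  expect_equal(apply_growth(100, 2015, 2015, med), 100)
  expect_equal(apply_growth(100, 2015, 2016, med), 105)
  expect_equal(apply_growth(100, 2015, 2013, med), 100 / 1.05^2)
})

test_that("median-path growth is invertible", {
  years <- 1950:2050
  med <- median_growth_path(growth_trend(), years)
  fwd <- apply_growth(123.4, 1980, 2040, med)
  expect_equal(apply_growth(fwd, 2040, 1980, med), 123.4)
})

test_that("the breakpoint separates the two rate regimes", {
  tr <- growth_trend(breakpoint_year = 2000, median_rate_pre = 1,
                     median_rate_post = 5, relative_spread = 0)
  med <- median_growth_path(tr, 1995:2005)
  expect_true(all(med[as.character(1996:2000)] == 1))
  expect_true(all(med[as.character(2001:2005)] == 5))
})

test_that("regional scaling is the demand/GDP ratio", {
  expect_equal(regional_share(1000, 0.04, 1), 40)
  expect_equal(regional_share(77, 5, 5), 77)
  expect_equal(regional_share(1000, 0, 10), 0)
  expect_error(regional_share(1000, 1, 0), "world_gdp")
})

test_that("share draws summing above 1 are renormalized 4/7 : 3/7", {
  sh <- renormalize_shares(matrix(c(0.8, 0.6), 1))
  expect_equal(drop(sh), c(4 / 7, 3 / 7))
  # sums below 1 are left untouched
  sh2 <- renormalize_shares(matrix(c(0.2, 0.3), 1))
  expect_equal(drop(sh2), c(0.2, 0.3))
})

test_that("cohort inputs split the regional mass by shares", {
  book <- toy_fixture()
  book$applications <- list(
    application_profile("a", "toyENM", 2000, 1, dist_point(0.3),
                        tc_eol = list(landfill = dist_point(1))),
    application_profile("b", "toyENM", 2000, 1, dist_point(0.7),
                        tc_eol = list(landfill = dist_point(1))))
  ci <- cohort_inputs(book, n = 1)
  expect_equal(drop(ci$substances$toyENM$cohorts$a),
               setNames(rep(30, 10), 2000:2009))
  expect_equal(drop(ci$substances$toyENM$cohorts$b),
               setNames(rep(70, 10), 2000:2009))
})

test_that("cohort masses never exceed the regional substance mass", {
  book <- generate_parameter_book(fixture_config(seed = 8))
  ci <- cohort_inputs(book, n = 50)
  for (sub in names(ci$substances)) {
    s <- ci$substances[[sub]]
    tot <- Reduce(`+`, s$cohorts)
    expect_true(all(tot <= s$production + 1e-9))
  }
})

test_that("years before start_year contribute exactly zero", {
  book <- toy_fixture()
  book$applications[[1]]$start_year <- 2004
  ci <- cohort_inputs(book, n = 1)
  cm <- drop(ci$substances$toyENM$cohorts$toy_app)
  expect_true(all(cm[as.character(2000:2003)] == 0))
  expect_true(all(cm[as.character(2004:2009)] > 0))
})
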