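test_that("a lifespan of one year releases each cohort immediately", {
  I <- c(3, 7, 0, 2)
  expect_equal(use_release(I, 1), I)
  expect_equal(use_stock(I, 1), rep(0, 4))
})

test_that("constant input with m = 2 ramps 5 then 10", {
  I <- rep(10, 6)
  expect_equal(use_release(I, 2), c(5, 10, 10, 10, 10, 10))
})

test_that("a single pulse spreads uniformly over m years", {
  I <- c(12, 0, 0, 0, 0)  # pulse in year 1 (2000), m = 3
  expect_equal(use_release(I, 3), c(4, 4, 4, 0, 0))
  expect_equal(use_stock(I, 3), c(8, 4, 0, 0, 0))
})

test_that("EOL release is the cohort shifted by m years", {
  I <- c(7, 0, 0, 0, 0)
  expect_equal(eol_release(I, 3), c(0, 0, 0, 7, 0))
  expect_equal(eol_stock(I, 3), c(7, 7, 7, 0, 0))
  I2 <- rep(4, 10)
  expect_equal(eol_release(I2, 5), c(rep(0, 5), rep(4, 5)))
})

test_that("cohort operations match the literal summation oracles", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    m <- sample(1:12, 1)
    I <- runif(n, 0, 100) * rbinom(n, 1, 0.8)
    expect_equal(use_release(I, m), ref_use_release(I, m))
    expect_equal(use_stock(I, m), ref_use_stock(I, m))
    expect_equal(eol_release(I, m), ref_eol_release(I, m))
    expect_equal(eol_stock(I, m), ref_eol_stock(I, m))
  }
})

test_that("stocks equal cumulative input minus cumulative release", {
  set.seed(22)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    m <- sample(1:15, 1)
    I <- rlnorm(n, 2, 1)
    expect_equal(use_stock(I, m), cumsum(I) - cumsum(use_release(I, m)))
    expect_equal(eol_stock(I, m), cumsum(I) - cumsum(eol_release(I, m)))
  }
})

test_that("delaying cohorts by k years shifts all series by k years", {
  set.seed(23)
  I <- c(runif(20, 0, 50), rep(0, 10))
  k <- 6; m <- 4
  Ik <- c(rep(0, k), I)[1:30]
  for (f in list(use_release, use_stock, eol_release, eol_stock))
    expect_equal(f(Ik, m)[(k + 1):30], f(I, m)[1:(30 - k)])
})

test_that("total release sums applications and enforces aligned axes", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(total_release(list(a, b)), c(5, 7, 9))
  expect_equal(total_release(list(a, a)), 2 * a)
  expect_error(total_release(list(a, c(1, 2))), "mismatched horizons")
})

test_that("accumulative release is the running cumulative sum", {
  expect_equal(accumulative_release(rep(0, 5)), rep(0, 5))
  expect_equal(accumulative_release(rep(3, 10))[10], 30)
  r2 <- accumulative_release(runif(20))
  expect_true(all(diff(r2) >= 0))
})

test_that("the toy fixture reproduces its documented closed forms", {
  sim <- simulate_release(toy_fixture())
  app <- sim$applications$toy_app
  yrs <- as.character(2000:2009)
  expect_equal(drop(app$flux$use$surface_water),
               setNames(c(10, 20, rep(30, 8)), yrs))
  expect_equal(drop(app$flux$eol$landfill),
               setNames(c(0, 0, 0, rep(70, 7)), yrs))
  expect_equal(drop(app$stock_use), setNames(c(20, rep(30, 9)), yrs))
  expect_equal(drop(app$stock_eol),
               setNames(c(70, 140, rep(210, 8)), yrs))
})

test_that("simulation is linear in the production input", {
  book <- toy_fixture()
  book2 <- book
  book2$production_estimates$low <- 200
  book2$production_estimates$high <- 200
  s1 <- simulate_release(book)
  s2 <- simulate_release(book2)
  for (stream in c("use", "eol"))
    for (cm in names(s1$applications$toy_app$flux[[stream]]))
      expect_equal(s2$applications$toy_app$flux[[stream]][[cm]],
                   2 * s1$applications$toy_app$flux[[stream]][[cm]])
})

test_that("a point-parameter simulation is identical across runs", {
  s1 <- simulate_release(toy_fixture())
  s2 <- simulate_release(toy_fixture())
  expect_identical(s1$applications, s2$applications)
})

test_that("raising a transfer coefficient never lowers its stream", {
  book <- toy_fixture()
  book$applications[[1]]$tc_use$surface_water <- dist_point(0.5)
  hi <- simulate_release(book)
  lo <- simulate_release(toy_fixture())
  expect_true(all(hi$applications$toy_app$flux$use$surface_water >=
                    lo$applications$toy_app$flux$use$surface_water))
})

test_that("a horizon shorter than a lifespan warns about truncation", {
  book <- toy_fixture()
  book$applications[[1]]$lifespan_m <- 15L
  expect_warning(simulate_release(book), "truncated")
})

test_that("overcommitted production + use TCs are rescaled, not negative", {
  book <- toy_fixture()
  book$applications[[1]]$tc_production <-
    list(air = dist_point(0.6))
  book$applications[[1]]$tc_use <- list(surface_water = dist_point(0.6))
  sim <- simulate_release(book)
  f <- sim$applications$toy_app$fractions
  expect_true(all(f$eol >= 0))
  expect_equal(unname(f$production + f$use + f$eol), rep(1, sim$n))
})
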