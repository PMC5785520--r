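test_that("endpoint transformation applies the right factor chain", {
  # spread 0 pins every factor at its median
  expect_equal(transform_endpoint(20, "chronic_noec", 5, spread = 0),
               rep(20, 5))
  expect_equal(transform_endpoint(100, "acute_effect", 3, spread = 0),
               rep(1, 3))   # /10 acute-to-chronic, /10 effect-to-noec
  expect_equal(transform_endpoint(50, "acute_noec", 3, spread = 0),
               rep(5, 3))
  expect_equal(transform_endpoint(50, "chronic_effect", 3, spread = 0),
               rep(5, 3))
  expect_error(transform_endpoint(1, "lc50", 1), "unknown endpoint_kind")
  expect_error(transform_endpoint(-1, "chronic_noec", 1), "> 0")
})

test_that("the 50% interval stays within its triangular bounds", {
  set.seed(31)
  x <- transform_endpoint(100, "chronic_noec", 1e4)
  expect_true(all(x >= 50 & x <= 150))
  expect_lt(abs(median(x) - 100), 2)
})

test_that("species distributions mix endpoints with equal weight", {
  ep <- data.frame(endpoint_kind = c("chronic_noec", "chronic_noec"),
                   concentration = c(1, 100))
  set.seed(32)
  x <- build_species_distribution(ep, 1e5, spread = 0)
  expect_lt(abs(mean(x == 1) - 0.5), 0.01)
  expect_lt(abs(mean(x == 100) - 0.5), 0.01)
  expect_true(all(x > 0))
})

test_that("degenerate two-species curves are the sorted pair", {
  sp <- list(a = rep(10, 100), b = rep(1, 100))
  set.seed(33)
  cs <- build_pssd_curves(sp, n_curves = 50)
  expect_equal(nrow(cs$curves), 50)
  expect_equal(cs$fractions, c(0.5, 1))
  expect_true(all(cs$curves[, 1] == 1))
  expect_true(all(cs$curves[, 2] == 10))
  expect_error(build_pssd_curves(list(a = 1:5), 10), "at least 2 species")
})

test_that("curves are strictly increasing even with tied draws", {
  sp <- list(a = rep(3, 50), b = rep(3, 50), c = rep(3, 50))
  set.seed(34)
  cs <- build_pssd_curves(sp, n_curves = 20)
  expect_true(all(cs$curves[, 2] > cs$curves[, 1]))
  expect_true(all(cs$curves[, 3] > cs$curves[, 2]))
})

test_that("curve minima reproduce the distribution of species minima", {
  set.seed(35)
  sp <- list(a = rlnorm(5000, 0, 1), b = rlnorm(5000, 1, 0.5),
             c = rlnorm(5000, -1, 0.3))
  cs <- build_pssd_curves(sp, n_curves = 5000)
  # brute-force oracle: minimum over one fresh draw per species
  ref <- pmin(sample(sp$a, 5000, TRUE), sample(sp$b, 5000, TRUE),
              sample(sp$c, 5000, TRUE))
  expect_lt(ks_distance(cs$curves[, 1], stats::ecdf(ref)), 0.05)
})

test_that("risk is 0 with no overlap and 100 with full overlap", {
  sp <- list(a = rep(100, 50), b = rep(200, 50))
  set.seed(36)
  cs <- build_pssd_curves(sp, 100)
  expect_equal(risk_percent(c(0.1, 0.2), cs)$risk_percent, 0)
  expect_equal(risk_percent(c(500, 600), cs)$risk_percent, 100)
})

test_that("uniform PEC against fixed curve minima yields 50%", {
  sp <- list(a = rep(1, 50), b = rep(5, 50))
  set.seed(37)
  cs <- build_pssd_curves(sp, 100)
  pec <- runif(1e5, 0, 2)
  r <- risk_percent(pec, cs)
  expect_lt(abs(r$p_critical_pec - 0.5), 0.01)
  expect_equal(r$p_critical_pssd, 1)
  expect_lt(abs(r$risk_percent - 50), 1)
})

test_that("risk is scale-equivariant and monotone", {
  set.seed(38)
  sp <- list(a = rlnorm(2000, 0, 1), b = rlnorm(2000, 0.5, 1))
  cs <- build_pssd_curves(sp, 500)
  pec <- rlnorm(2000, -1, 1)
  base <- risk_percent(pec, cs)$risk_percent
  cs_scaled <- cs
  cs_scaled$curves <- cs$curves * 7
  expect_equal(risk_percent(pec * 7, cs_scaled)$risk_percent, base)
  expect_gte(risk_percent(pec * 10, cs)$risk_percent, base)
  expect_lte(risk_percent(pec, cs_scaled)$risk_percent, base)
})

test_that("terrestrial compartments are refused for risk", {
  set.seed(39)
  sp <- list(a = rep(1, 10), b = rep(2, 10))
  cs <- build_pssd_curves(sp, 10)
  book <- toy_fixture()
  sim <- simulate_release(book)
  pec <- compute_pec(compartment_flux(sim), book$geometry)
  expect_error(risk_table(pec, cs, compartments = "soil_agricultural"),
               "no PSSD can be built")
})
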