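test_that("hourly integration gives the worked unit value", {
  ts <- as.POSIXct("2006-12-01 10:00:00", tz = "UTC")
  out <- cumulative_flux_carbon(ts, 1, area_m2 = 0.0278)
  expect_equal(out$g_c, 3600 * 12.011e-6 * 0.0278)
  expect_equal(out$g_c, 1.202e-3, tolerance = 1e-4)
})

test_that("integration is linear, cancels and handles zeros", {
  ts <- seq(as.POSIXct("2006-12-01 00:00:00", tz = "UTC"), by = "hour",
            length.out = 10)
  f <- c(1, -1, 2, -2, 0.5, -0.5, 3, -3, 1.5, -1.5)
  expect_equal(cumulative_flux_carbon(ts, f, 0.0278)$g_c, 0)
  expect_equal(cumulative_flux_carbon(ts, rep(0, 10), 0.0278)$g_c, 0)
  k <- 3.7
  expect_equal(cumulative_flux_carbon(ts, k * (f + 1), 0.0278)$g_c,
               k * cumulative_flux_carbon(ts, f + 1, 0.0278)$g_c)
})

test_that("short gaps are interpolated, long gaps are named errors", {
  ts <- seq(as.POSIXct("2006-12-01 00:00:00", tz = "UTC"), by = "hour",
            length.out = 24)
  f <- rep(2, 24)
  keep <- setdiff(1:24, 10:11)  # 2 h gap
  out <- cumulative_flux_carbon(ts[keep], f[keep], 0.0278)
  expect_equal(out$n_filled, 2)
  expect_equal(out$g_c, 24 * 2 * 3600 * 12.011e-6 * 0.0278)
  keep5 <- setdiff(1:24, 8:12)  # 5 h gap
  expect_error(cumulative_flux_carbon(ts[keep5], f[keep5], 0.0278,
                                      min_coverage = 0.5),
               "longer than 3 h")
  expect_error(cumulative_flux_carbon(ts[1:4], f[1:4], 0.0278,
                                      period = range(ts)),
               "coverage")
})

test_that("DOC carbon sums events order-invariantly", {
  expect_equal(doc_carbon(c(0.65, 0.85, 1.70), rep(20, 3)), 0.064)
  expect_equal(doc_carbon(numeric(0), numeric(0)), 0)
  v <- runif(5, 0, 2)
  cc <- runif(5, 10, 30)
  o <- sample(5)
  expect_equal(doc_carbon(v, cc), doc_carbon(v[o], cc[o]))
  expect_error(doc_carbon(-1, 20), "negative")
})

test_that("the stock balance reproduces the published worked example", {
  expect_equal(stock_balance(-0.017, 0.694, 0.856, 0.056, 1.299), -0.290)
  expect_equal(stock_balance(0, 0, 0, 0, 0), 0)
  expect_equal(stock_balance(0, 0, 0, 0, 1), 1)  # full seed loss = release
  expect_error(stock_balance(NA, 1, 1, 0, 1), "pool")
})

test_that("a growing mesocosm has a negative stock balance", {
  set.seed(3)
  for (i in 1:20) {
    seed <- runif(1, 0.5, 2)
    plant <- seed * runif(1, 1.05, 2)  # plant C gain exceeds seed C
    shoot <- plant * runif(1, 0.3, 0.7)
    expect_lt(stock_balance(0, shoot, plant - shoot, 0, seed), 0)
  }
})

test_that("carbon-content and sowing-density helpers give printed values", {
  expect_equal(pool_carbon(2500, 0.005), 12.50)
  expect_equal(round(pool_carbon(1.75, 0.405), 2), 0.71)
  expect_equal(round(sowing_density(3.1, 0.0278)), 112)
})

test_that("identical balances compare as a perfect 1:1 ensemble", {
  b <- tibble::tibble(collar_id = 1:6,
                      flux_balance = c(-0.31, -0.30, -0.29, -0.32, -0.28,
                                       -0.33),
                      stock_balance = c(-0.31, -0.30, -0.29, -0.32, -0.28,
                                        -0.33),
                      treatment = rep(c("+Ch +N", "+Ch -N"), each = 3))
  cmp <- compare_balances(b)
  expect_equal(cmp$rmse_1to1, 0)
  expect_equal(cmp$fit$slope, 1)
  expect_equal(cmp$paired$mean_difference, 0)
})

test_that("group means reproduce the published +Ch agreement", {
  # published +Ch group: flux -0.305 vs stock -0.305 -> difference 0.000
  b <- tibble::tibble(
    collar_id = 1:6,
    stock_balance = c(-0.320, -0.360, -0.280, -0.290, -0.340, -0.240),
    flux_balance = c(-0.310, -0.362, -0.258, -0.300, -0.340, -0.260),
    treatment = "+Ch"
  )
  cmp <- compare_balances(b)
  expect_equal(round(cmp$group_summary$flux_mean, 3), -0.305)
  expect_equal(round(cmp$group_summary$stock_mean, 3), -0.305)
  expect_equal(round(cmp$group_summary$mean_difference, 3), 0)
})

test_that("the treatment ANOVA F equals the sum-of-squares oracle", {
  set.seed(77)
  b <- tibble::tibble(
    collar_id = 1:12,
    flux_balance = rnorm(12, -0.3, 0.05),
    stock_balance = rnorm(12, -0.3, 0.05),
    treatment = rep(c("+Ch +N", "+Ch -N", "-Ch +N", "-Ch -N"), each = 3)
  )
  cmp <- compare_balances(b)
  expect_lt(rel_err(cmp$anova$flux$F,
                    oracle_anova_f(b$flux_balance, b$treatment)), 1e-10)
  expect_lt(rel_err(cmp$anova$stock$F,
                    oracle_anova_f(b$stock_balance, b$treatment)), 1e-10)
  b$treatment[1:3] <- paste("solo", 1:3)
  expect_error(compare_balances(b), "singleton")
})

test_that("budgets assemble components commensurably", {
  ts <- seq(as.POSIXct("2006-12-01 00:00:00", tz = "UTC"), by = "hour",
            length.out = 48)
  nee <- tibble::tibble(collar_id = rep(1:2, each = 48),
                        hour = rep(ts, 2),
                        nee = rep(c(-1, 0.5), each = 48))
  doc <- tibble::tibble(collar_id = 1:2, volume_l = c(2, 0),
                        conc_mg_l = c(20, 20))
  inv <- tibble::tibble(collar_id = 1:2, d_c_soil = 0, c_shoot = 0.1,
                        c_root = 0.1, c_doc = c(0.04, 0), c_seed = 0.5)
  b <- carbon_budgets(nee, doc, inv, area_m2 = 0.0278)
  expect_equal(b$c_doc_flux, c(0.04, 0))
  expect_equal(b$flux_balance,
               b$cum_nee_c + b$c_doc_flux)
  expect_equal(b$stock_balance,
               stock_balance(inv$d_c_soil, inv$c_shoot, inv$c_root,
                             inv$c_doc, inv$c_seed))
  expect_equal(b$coverage, c(1, 1))
})
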