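test_that("annual profit prices products, wastes and consumables", {
  m <- cost_model(product_prices = c(lauric = 2), waste_fee = 0.1,
                  consumable_prices = c(steam_mt = 10), enzyme_price = 5)
  p <- annual_profit(list(products = c(lauric = 1000),
                          wastes = c(ash = 100),
                          enzyme_kg = 20,
                          consumables = c(steam_mt = 38)),
                     m)
  expect_equal(p$revenue, 2000)
  expect_equal(p$operating_cost, 38 * 10 + 20 * 5 + 100 * 0.1)
  expect_equal(p$gross_profit, p$revenue - p$operating_cost)

  # zero prices: profit is minus the operating cost
  m0 <- cost_model(product_prices = c(lauric = 0), waste_fee = 0,
                   consumable_prices = c(steam_mt = 10), enzyme_price = 5)
  p0 <- annual_profit(list(products = c(lauric = 1000), wastes = c(ash = 1),
                           enzyme_kg = 20, consumables = c(steam_mt = 38)),
                      m0)
  expect_equal(p0$gross_profit, -p0$operating_cost)

  # linearity in masses
  bal <- list(products = c(lauric = 1000), wastes = c(ash = 100),
              enzyme_kg = 20, consumables = c(steam_mt = 38))
  bal2 <- lapply(bal, function(x) 2 * x)
  expect_equal(annual_profit(bal2, m)$revenue, 2 * p$revenue)
  expect_equal(annual_profit(bal2, m)$operating_cost, 2 * p$operating_cost)

  expect_error(annual_profit(list(products = c(unknownium = 5)), m),
               "no price")
})

test_that("cash-flow series applies the flat tax only to positive profit", {
  m <- cost_model(capital_cost = 1000, tax_rate = 0.06, project_years = 20)
  cf <- build_cashflows(100, m)
  expect_length(cf$yearly_net, 21)
  expect_equal(cf$yearly_net[1], -1000)
  expect_equal(unique(cf$yearly_net[-1]), 94)
  expect_equal(cf$tax_paid, 6)

  cf0 <- build_cashflows(0, m)
  expect_equal(unique(cf0$yearly_net[-1]), 0)

  cfneg <- build_cashflows(-50, m)
  expect_equal(cfneg$tax_paid, 0)
  expect_equal(unique(cfneg$yearly_net[-1]), -50)

  cfb <- build_cashflows(100, m, after_tax = FALSE)
  expect_equal(unique(cfb$yearly_net[-1]), 100)
})

test_that("npv matches closed forms", {
  expect_equal(npv(c(-100, 110), 0.10), 0, tolerance = 1e-12)
  cf <- c(-250, 40, 60, 80)
  expect_equal(npv(cf, 0), sum(cf))
  # annuity closed form
  annuity <- (1 - 1.07^-20) / 0.07
  expect_equal(npv(c(-1000, rep(300, 20)), 0.07), -1000 + 300 * annuity,
               tolerance = 1e-9)
  expect_error(npv(cf, -1), "> -1")
})

test_that("irr solves single-period and annuity cases and handles no-root series", {
  expect_equal(irr(c(-100, 110)), 0.10, tolerance = 1e-6)
  expect_true(is.na(irr(c(-100, -5, -5))))
  expect_true(is.na(irr(c(100, 5, 5))))
  expect_equal(irr_percent(NA_real_), -100)
  expect_equal(irr_percent(0.0773), 7.73)

  # cross-check against the polynomial-root oracle in x = 1/(1+r)
  cf <- c(-1000, 400, 400, 400, 400)
  roots <- polyroot(cf)
  real_roots <- Re(roots[abs(Im(roots)) < 1e-9])
  r_oracle <- 1 / real_roots[real_roots > 0] - 1
  expect_equal(irr(cf), r_oracle[1], tolerance = 1e-6)
})

test_that("npv(irr) vanishes on random viable cash-flow series", {
  for (seed in 1:300) {
    cf <- random_cashflow(seed)
    r <- irr(cf)
    expect_false(is.na(r))
    expect_lt(abs(npv(cf, r)), 1e-5 * abs(cf[1]))
  }
})

test_that("npv is strictly decreasing in the rate for conventional series", {
  cf <- c(-1000, rep(150, 20))
  rates <- seq(0, 0.5, by = 0.05)
  vals <- vapply(rates, function(r) npv(cf, r), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the flat tax orders IRR and the summary satisfies its invariant", {
  m <- cost_model(capital_cost = 1e6, tax_rate = 0.06)
  for (gp in c(1.2e5, 2e5, 5e5)) {
    tea <- tea_summary(gp, m)
    expect_true(tea$irr_after_tax <= tea$irr_before_tax)
    # NPV at the IRR is zero by definition
    after <- build_cashflows(gp, m)
    expect_lt(abs(npv(after, tea$irr_after_tax)), 1e-5 * m$capital_cost)
  }
  # non-profitable project: no IRR, rendered as -100%
  tea0 <- tea_summary(-1e5, m)
  expect_true(is.na(tea0$irr_before_tax))
  expect_equal(irr_percent(tea0$irr_before_tax), -100)
})
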