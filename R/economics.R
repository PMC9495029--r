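# Discounted-cash-flow feasibility: annual gross profit from the annualized
# material balance and a price/cost model, a 20-year cash-flow series under a
# flat tax, NPV at given discount rates and IRR by bracketed bisection.

#' Price/cost model for the plant economics
#'
#' None of the plant's prices are measured quantities here; the defaults are
#' order-of-magnitude commodity values (USD) chosen once and documented in the
#' methods vignette, and every field is overridable. Masses are priced per kg,
#' consumables per their natural unit (steam MT, cooling water m3,
#' electricity kWh, membrane m2 replaced per year).
#'
#' @param product_prices currency/kg for revenue components (the four fatty
#'   acids and the protein byproduct)
#' @param waste_fee currency/kg charged on every waste stream
#' @param consumable_prices currency per unit: \code{steam_mt},
#'   \code{cooling_water_m3}, \code{electricity_kwh}, \code{membrane_m2}
#' @param enzyme_price currency/kg alcalase
#' @param capital_cost total installed capital, currency
#' @param tax_rate flat tax on positive gross profit (default 0.06)
#' @param project_years payment period (default 20)
#' @param discount_rates rates at which NPV is reported (default 7/9/11%)
#' @return object of class \code{cost_model}
#' @export
cost_model <- function(product_prices = c(lauric = 1.5, myristic = 1.8,
                                          palmitic = 1.0, stearic = 1.2,
                                          protein = 0.7),
                       waste_fee = 0.05,
                       consumable_prices = c(steam_mt = 12,
                                             cooling_water_m3 = 0.05,
                                             electricity_kwh = 0.10,
                                             membrane_m2 = 100),
                       enzyme_price = 25,
                       capital_cost = 8e7,
                       tax_rate = 0.06,
                       project_years = 20,
                       discount_rates = c(0.07, 0.09, 0.11)) {
  if (any(c(product_prices, waste_fee, consumable_prices, enzyme_price,
            capital_cost) < 0))
    stop("all prices, fees and costs must be >= 0")
  if (tax_rate < 0 || tax_rate >= 1) stop("tax_rate must lie in [0, 1)")
  if (project_years < 1) stop("project_years must be >= 1")
  structure(list(product_prices = product_prices, waste_fee = waste_fee,
                 consumable_prices = consumable_prices,
                 enzyme_price = enzyme_price, capital_cost = capital_cost,
                 tax_rate = tax_rate, project_years = project_years,
                 discount_rates = discount_rates),
            class = "cost_model")
}

#' Annual gross profit from an annualized balance
#'
#' @param balance list with components \code{products} (named kg/yr, priced by
#'   \code{product_prices}), \code{wastes} (named kg/yr, charged
#'   \code{waste_fee}), \code{enzyme_kg} (kg/yr) and \code{consumables}
#'   (named quantities per year matching \code{consumable_prices})
#' @param model a \code{\link{cost_model}}
#' @return list with \code{revenue}, \code{operating_cost},
#'   \code{gross_profit} (currency/yr)
#' @export
#' @examples
#' annual_profit(list(products = c(lauric = 1000), wastes = c(ash = 0),
#'                    enzyme_kg = 0, consumables = numeric(0)),
#'               cost_model(product_prices = c(lauric = 2)))
annual_profit <- function(balance, model) {
  stopifnot(inherits(model, "cost_model"))
  products <- balance$products
  if (is.null(products)) products <- numeric(0)
  wastes <- if (is.null(balance$wastes)) numeric(0) else balance$wastes
  cons <- if (is.null(balance$consumables)) numeric(0) else balance$consumables
  enzyme <- if (is.null(balance$enzyme_kg)) 0 else balance$enzyme_kg

  unpriced <- setdiff(names(products)[products > 0], names(model$product_prices))
  if (length(unpriced))
    stop("no price configured for product(s): ", paste(unpriced, collapse = ", "))
  unpriced_c <- setdiff(names(cons)[cons > 0], names(model$consumable_prices))
  if (length(unpriced_c))
    stop("no price configured for consumable(s): ",
         paste(unpriced_c, collapse = ", "))

  revenue <- sum(products * model$product_prices[names(products)])
  opex <- sum(cons * model$consumable_prices[names(cons)]) +
    enzyme * model$enzyme_price + sum(wastes) * model$waste_fee
  list(revenue = revenue, operating_cost = opex,
       gross_profit = revenue - opex)
}

#' Build the project cash-flow series
#'
#' Year 0 carries the capital outlay; years 1..project_years carry the annual
#' gross profit net of a flat tax charged only on positive profit. There is
#' no depreciation schedule; the tax applies to gross profit directly.
#'
#' @param gross_profit currency/yr
#' @param model a \code{\link{cost_model}}
#' @param after_tax apply the flat tax (default TRUE); FALSE gives the
#'   before-tax series
#' @return object of class \code{cashflow_series}: list with
#'   \code{yearly_net} (length project_years + 1, year 0 first),
#'   \code{gross_profit} and \code{tax_paid}
#' @export
build_cashflows <- function(gross_profit, model, after_tax = TRUE) {
  stopifnot(inherits(model, "cost_model"))
  tax <- if (after_tax) model$tax_rate * max(gross_profit, 0) else 0
  net <- gross_profit - tax
  structure(list(yearly_net = c(-model$capital_cost,
                                rep(net, model$project_years)),
                 gross_profit = gross_profit, tax_paid = tax),
            class = "cashflow_series")
}

#' Net present value of a cash-flow series
#'
#' @param cashflows a \code{cashflow_series} or bare numeric vector whose
#'   first element is year 0
#' @param rate discount rate (> -1)
#' @return NPV in the series' currency
#' @export
#' @examples
#' npv(c(-100, 110), 0.10)  # 0
npv <- function(cashflows, rate) {
  cf <- if (inherits(cashflows, "cashflow_series")) cashflows$yearly_net
        else cashflows
  if (rate <= -1) stop("discount rate must be > -1")
  t <- seq_along(cf) - 1
  sum(cf / (1 + rate)^t)
}

#' Internal rate of return
#'
#' Deterministic bracketing scan over (-0.999, 10] followed by bisection,
#' refined until |NPV| < tol_scale x 1e-6 (tol_scale defaults to the
#' magnitude of the year-0 outlay). Returns \code{NA} when the series has no
#' sign change or no root in the scan range; the reporting layer renders that
#' as -100\%, the plant's convention for a non-profitable project.
#'
#' @param cashflows a \code{cashflow_series} or numeric vector (year 0 first)
#' @return the IRR as a fraction, or \code{NA_real_}
#' @export
#' @examples
#' irr(c(-100, 110))  # 0.10
irr <- function(cashflows) {
  cf <- if (inherits(cashflows, "cashflow_series")) cashflows$yearly_net
        else cashflows
  if (all(cf >= 0) || all(cf <= 0)) return(NA_real_)
  tol <- 1e-6 * max(abs(cf[1]), 1)
  f <- function(r) npv(cf, r)
  grid <- c(seq(-0.999, 1, by = 0.01), seq(1.1, 10, by = 0.1))
  v <- vapply(grid, f, numeric(1))
  i <- which(v[-length(v)] * v[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  lo <- grid[i]; hi <- grid[i + 1]
  flo <- v[i]
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) > tol) return(NA_real_)
  mid
}

#' Techno-economic summary
#'
#' IRR before and after the flat tax plus NPV of the after-tax series at each
#' configured discount rate.
#'
#' @param gross_profit currency/yr
#' @param model a \code{\link{cost_model}}
#' @return list of class \code{tea_summary}: \code{irr_before_tax},
#'   \code{irr_after_tax} (fractions; \code{NA} when non-profitable),
#'   \code{npv_by_rate} (named currency)
#' @export
tea_summary <- function(gross_profit, model) {
  before <- build_cashflows(gross_profit, model, after_tax = FALSE)
  after <- build_cashflows(gross_profit, model, after_tax = TRUE)
  rates <- model$discount_rates
  structure(list(
    irr_before_tax = irr(before),
    irr_after_tax = irr(after),
    npv_by_rate = setNames(vapply(rates, function(r) npv(after, r),
                                  numeric(1)),
                           paste0(format(100 * rates, trim = TRUE), "%"))
  ), class = "tea_summary")
}

#' @export
print.tea_summary <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "-100.00%" else sprintf("%.2f%%", 100 * v)
  cat("<tea_summary>\n")
  cat("  IRR Before Taxes ", pct(x$irr_before_tax), "\n")
  cat("  IRR After Taxes  ", pct(x$irr_after_tax), "\n")
  for (nm in names(x$npv_by_rate))
    cat(sprintf("  NPV @ %-6s %15.2f\n", nm, x$npv_by_rate[[nm]]))
  invisible(x)
}

#' Render an IRR fraction using the plant's reporting convention
#'
#' Non-profitable projects (no internal rate of return) are reported as
#' -100\%.
#'
#' @param x IRR fraction or \code{NA}
#' @return percent value (numeric)
#' @export
irr_percent <- function(x) if (is.na(x)) -100 else 100 * x
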