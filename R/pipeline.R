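# End-to-end pipeline: scenario composition -> feed stream -> flowsheet
# simulation -> schedule -> annualized material balance -> revenue split ->
# techno-economic summary, plus the report writers.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default per-batch utility consumption
#'
#' Steam, cooling water and electricity demands per batch are simulator-side
#' utility figures not derivable from the mass balance; these defaults are
#' plausible magnitudes for a 10-tonne batch and exist so the operating-cost
#' arithmetic is exercised end to end. All are overridable.
#'
#' @return named numeric vector: \code{steam_mt}, \code{cooling_water_m3},
#'   \code{electricity_kwh}
#' @export
default_consumables_per_batch <- function() {
  c(steam_mt = 2, cooling_water_m3 = 50, electricity_kwh = 800)
}

#' Annualized bulk-material balance table
#'
#' Table in the plant's reporting shape: one row per bulk material (alcalase
#' enzyme, fly larvae, water) with kg/batch and kg/yr, plus a Total row that
#' is the exact sum of the rows. Values are fixed to 2 decimals, the
#' precision the balance is reported at.
#'
#' @param bulk list with \code{alcalase_kg_per_batch},
#'   \code{larvae_kg_per_batch}, \code{water_kg_per_year} and
#'   \code{batches_per_year_basis} (the campaign size at which the annual
#'   water demand was computed)
#' @param n batches per year to annualize at
#' @return data.frame with columns \code{material}, \code{kg_per_year},
#'   \code{kg_per_batch}
#' @export
#' @examples
#' cfg <- read_plant_config()
#' material_balance_table(cfg$bulk_materials, n_batches(7919, 7.25, 2.75))
material_balance_table <- function(bulk, n) {
  water_per_batch <- bulk$water_kg_per_year / bulk$batches_per_year_basis
  per_batch <- c("Alcalase enzyme" = bulk$alcalase_kg_per_batch,
                 "Fly larvae" = bulk$larvae_kg_per_batch,
                 "Water" = water_per_batch)
  per_year <- annualize(per_batch, n)
  pb <- round(per_batch, 2)
  py <- round(per_year, 2)
  data.frame(
    material = c(names(per_batch), "Total"),
    kg_per_year = c(py, sum(py)),
    kg_per_batch = c(pb, sum(pb)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the full plant pipeline for one scenario
#'
#' Composes the whole analysis: wet-basis composition, feed stream, flowsheet
#' mass balance, batch schedule, annualized material balance, revenue split
#' and discounted-cash-flow summary. Deterministic for a fixed configuration
#' (randomness only enters through an externally sampled \code{composition}).
#'
#' @param scenario scenario label in the packaged scenario set (ignored when
#'   \code{composition} is supplied)
#' @param composition optional \code{proximate_composition} overriding the
#'   packaged scenario (e.g. a sample from
#'   \code{\link{sample_composition}})
#' @param plant plant configuration from \code{\link{read_plant_config}}
#' @param rec batch \code{\link{recipe}}
#' @param annual_operating_time h/yr (default 7919)
#' @param model \code{\link{cost_model}}
#' @param profile \code{\link{fatty_acid_profile}} of the crude fat
#' @param consumables_per_batch named utility demands per batch
#' @param registry component registry
#' @return object of class \code{run_report}: \code{scenario_label},
#'   \code{schedule}, \code{simulation}, \code{material_balance},
#'   \code{revenue_split}, \code{gantt}, \code{profit}, \code{tea},
#'   \code{warnings}
#' @export
#' @examples
#' rep <- run_pipeline("kitchen_waste")
#' rep$schedule$n_batches  # 2878
run_pipeline <- function(scenario = "kitchen_waste",
                         composition = NULL,
                         plant = read_plant_config(),
                         rec = default_recipe(),
                         annual_operating_time = 7919,
                         model = cost_model(),
                         profile = fatty_acid_profile(),
                         consumables_per_batch = default_consumables_per_batch(),
                         registry = default_components()) {
  pc <- composition %||% {
    scen <- feed_scenarios()
    if (!scenario %in% names(scen))
      stop("[composition] unknown scenario '", scenario, "'; available: ",
           paste(names(scen), collapse = ", "))
    scen[[scenario]]
  }
  cf <- wet_basis_fractions(pc)
  feed <- larvae_feed_stream(plant$batch_mass_kg, cf, profile)
  sim <- simulate_flowsheet(plant$flowsheet, feed, registry)
  sched <- schedule_summary(annual_operating_time, rec$batch_time_h,
                            rec$cycle_time_h)
  n <- sched$n_batches
  balance <- material_balance_table(plant$bulk_materials, n)
  gantt <- build_gantt(rec, max(n, 1))

  product_streams <- c(lauric = "Lauric acid product",
                       myristic = "Myristic acid product",
                       palmitic = "Palmitic acid product",
                       stearic = "Stearic acid product")
  fa_batch <- vapply(product_streams,
                     function(lab) total_mass(sim$streams[[lab]]), numeric(1))
  revenue_split <- data.frame(fatty_acid = names(fa_batch),
                              kg_per_batch = unname(fa_batch),
                              kg_per_year = unname(fa_batch) * n,
                              row.names = NULL, stringsAsFactors = FALSE)

  protein_batch <- total_mass(sim$streams[["Protein product"]])
  waste_labels <- c("Wastes 1", "Cellulose waste", "Ash waste", "Wastes 2")
  wastes_batch <- vapply(waste_labels,
                         function(lab) total_mass(sim$streams[[lab]]),
                         numeric(1))
  membrane_area <- sum(vapply(sim$units, function(u) u$area_m2 %||% 0,
                              numeric(1)))
  consumables_yr <- c(annualize(consumables_per_batch, n),
                      membrane_m2 = membrane_area)
  profit <- annual_profit(
    list(products = c(fa_batch * n, protein = protein_batch * n),
         wastes = wastes_batch * n,
         enzyme_kg = plant$bulk_materials$alcalase_kg_per_batch * n,
         consumables = consumables_yr),
    model)
  tea <- tea_summary(profit$gross_profit, model)

  warnings <- unlist(lapply(sim$units, function(u) u$warnings), use.names = TRUE)
  structure(list(scenario_label = pc$scenario_label, schedule = sched,
                 simulation = sim, material_balance = balance,
                 revenue_split = revenue_split, gantt = gantt,
                 profit = profit, tea = tea,
                 warnings = warnings %||% character(0)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$scenario_label, "\n\n")
  print(x$schedule)
  cat("\nBulk material balance:\n")
  print(x$material_balance, row.names = FALSE)
  cat("\nRevenue split (kg):\n")
  print(x$revenue_split, row.names = FALSE)
  cat(sprintf("\nGross profit: %.2f /yr (revenue %.2f, operating cost %.2f)\n",
              x$profit$gross_profit, x$profit$revenue, x$profit$operating_cost))
  print(x$tea)
  invisible(x)
}

#' Write the pipeline reports to disk
#'
#' Writes \code{material_balance.csv}, \code{streams.csv}, \code{gantt.csv},
#' \code{gantt.json}, \code{revenue_split.csv} and \code{tea_summary.json}.
#' kg columns are written with fixed 2-decimal formatting so re-reading a CSV
#' reproduces the report's (rounded) values exactly; JSON holds raw numbers.
#'
#' @param report a \code{run_report}
#' @param out_dir output directory (created if missing)
#' @return named character vector of the files written, invisibly
#' @export
write_reports <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt2 <- function(x) sprintf("%.2f", x)
  files <- c(
    material_balance = file.path(out_dir, "material_balance.csv"),
    streams = file.path(out_dir, "streams.csv"),
    gantt_csv = file.path(out_dir, "gantt.csv"),
    gantt_json = file.path(out_dir, "gantt.json"),
    revenue_split = file.path(out_dir, "revenue_split.csv"),
    tea = file.path(out_dir, "tea_summary.json")
  )

  mb <- report$material_balance
  mb$kg_per_year <- fmt2(mb$kg_per_year)
  mb$kg_per_batch <- fmt2(mb$kg_per_batch)
  utils::write.csv(mb, files["material_balance"], row.names = FALSE)

  st <- stream_table(report$simulation$streams)
  st$kg_per_batch <- fmt2(st$kg_per_batch)
  utils::write.csv(st, files["streams"], row.names = FALSE)

  utils::write.csv(report$gantt, files["gantt_csv"], row.names = FALSE)
  jsonlite::write_json(report$gantt, files["gantt_json"], dataframe = "rows",
                       digits = NA)

  rs <- report$revenue_split
  rs$kg_per_batch <- fmt2(round(rs$kg_per_batch, 2))
  rs$kg_per_year <- fmt2(round(rs$kg_per_year, 2))
  utils::write.csv(rs, files["revenue_split"], row.names = FALSE)

  tea <- list(irr_before_tax_pct = irr_percent(report$tea$irr_before_tax),
              irr_after_tax_pct = irr_percent(report$tea$irr_after_tax),
              npv_by_rate = as.list(report$tea$npv_by_rate),
              gross_profit = report$profit$gross_profit,
              revenue = report$profit$revenue,
              operating_cost = report$profit$operating_cost)
  jsonlite::write_json(tea, files["tea"], auto_unbox = TRUE, digits = NA)

  invisible(files)
}
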