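# Flowsheet assembly and sequential-modular simulation. The plant is a
# directed acyclic graph of unit operations connected by labelled streams;
# units are evaluated in topological order and every unit (and the plant as a
# whole) must close its mass balance to 1e-9 relative.

#' Build a flowsheet from unit specifications
#'
#' @param units named list (names are unit ids such as "WSH-101"); each
#'   element is a list with \code{kind}, \code{inputs} (character vector of
#'   stream labels), \code{outputs} (named list/vector mapping the unit
#'   model's output ports to stream labels) and \code{params} (kind-specific)
#' @param feed_streams labels of externally supplied feed streams
#' @return object of class \code{flowsheet}
#' @export
flowsheet <- function(units, feed_streams = "Larvae feed") {
  if (is.null(names(units)) || any(names(units) == ""))
    stop("units must be a named list keyed by unit id")
  fs <- structure(list(units = units, feed_streams = feed_streams),
                  class = "flowsheet")
  validate_flowsheet(fs)
  fs
}

#' @noRd
unit_kinds <- function() {
  c("washer", "grinder", "reactor", "membrane_filter", "centrifuge",
    "distillation", "condenser", "cooler", "adsorber", "freeze_dryer",
    "transport")
}

#' @noRd
required_params <- function(kind) {
  switch(kind,
    washer = c("wash_water_kg", "ash_removal", "cellulose_removal"),
    grinder = "throughput_kg_h",
    reactor = c("enzyme_kg", "conversion"),
    membrane_filter = c("rejected_component", "rejection"),
    centrifuge = character(0),
    distillation = c("heavy_key_cut_c", "reflux_ratio"),
    condenser = "outlet_temp_c",
    cooler = "outlet_temp_c",
    adsorber = "backwash_water_kg",
    freeze_dryer = "final_moisture",
    transport = character(0)
  )
}

#' @noRd
validate_flowsheet <- function(fs) {
  producers <- list()
  for (uid in names(fs$units)) {
    u <- fs$units[[uid]]
    if (is.null(u$kind) || !u$kind %in% unit_kinds())
      stop("unit ", uid, ": unknown kind '", u$kind, "'")
    miss <- setdiff(required_params(u$kind), names(u$params))
    if (length(miss))
      stop("unit ", uid, " (", u$kind, "): missing parameter(s) ",
           paste(miss, collapse = ", "))
    for (lab in unlist(u$outputs)) {
      if (!is.null(producers[[lab]]))
        stop("stream '", lab, "' has two producers: ", producers[[lab]],
             " and ", uid)
      producers[[lab]] <- uid
    }
  }
  for (uid in names(fs$units)) {
    for (lab in fs$units[[uid]]$inputs) {
      if (!lab %in% fs$feed_streams && is.null(producers[[lab]]))
        stop("unit ", uid, ": input stream '", lab, "' has no producer ",
             "and is not a declared feed")
    }
  }
  g <- flowsheet_graph(fs)
  if (!igraph::is_dag(g))
    stop("flowsheet graph contains a cycle; recycles are not supported")
  invisible(fs)
}

#' @noRd
flowsheet_graph <- function(fs) {
  producers <- list()
  for (uid in names(fs$units))
    for (lab in unlist(fs$units[[uid]]$outputs)) producers[[lab]] <- uid
  edges <- character(0)
  for (uid in names(fs$units)) {
    for (lab in fs$units[[uid]]$inputs) {
      p <- producers[[lab]]
      if (!is.null(p)) edges <- c(edges, p, uid)
    }
  }
  igraph::graph_from_data_frame(
    if (length(edges)) as.data.frame(matrix(edges, ncol = 2, byrow = TRUE))
    else data.frame(from = character(0), to = character(0)),
    directed = TRUE,
    vertices = data.frame(name = names(fs$units))
  )
}

#' Read a plant flowsheet configuration
#'
#' @param path YAML plant definition; defaults to the packaged plant
#' @return list with \code{flowsheet}, \code{batch_mass_kg} and
#'   \code{bulk_materials}
#' @export
read_plant_config <- function(path = system.file("extdata", "default_plant.yaml",
                                                 package = "bsfrefinery")) {
  cfg <- yaml::read_yaml(path)
  units <- lapply(cfg$units, function(u) {
    list(kind = u$kind, inputs = u$inputs, outputs = u$outputs,
         params = if (is.null(u$params)) list() else u$params)
  })
  list(flowsheet = flowsheet(units, feed_streams = cfg$feed_streams),
       batch_mass_kg = cfg$batch_mass_kg,
       bulk_materials = cfg$bulk_materials)
}

#' The default plant flowsheet
#' @return a \code{flowsheet}
#' @export
default_flowsheet <- function() read_plant_config()$flowsheet

#' @noRd
merge_streams <- function(streams, label) {
  m <- numeric(0)
  for (s in streams) m <- add_masses(m, s$masses)
  stream(label, m, temperature = streams[[1]]$temperature,
         pressure = streams[[1]]$pressure, phase = streams[[1]]$phase)
}

#' @noRd
evaluate_unit <- function(uid, u, ins, registry) {
  p <- u$params
  feed <- if (length(ins) == 1) ins[[1]] else merge_streams(ins, paste0(uid, " feed"))
  extras <- list()
  utility <- 0
  # an empty batch draws no utility charges: water/enzyme additions are
  # per-batch charges that only apply when material is actually processed
  idle <- total_mass(feed) == 0
  out <- switch(u$kind,
    washer = {
      ww <- if (idle) 0 else p$wash_water_kg
      r <- wash(feed, wash_water = ww,
                ash_removal = p$ash_removal,
                cellulose_removal = p$cellulose_removal)
      utility <- ww
      r
    },
    grinder = {
      r <- grind(feed, throughput = p$throughput_kg_h)
      extras$duration_h <- r$duration
      r["product"]
    },
    reactor = {
      dil <- if (idle || is.null(p$dilution_water_kg)) 0 else p$dilution_water_kg
      enz <- if (idle) 0 else p$enzyme_kg
      feed2 <- set_masses(feed, add_masses(feed$masses, c(water = dil)))
      utility <- enz + dil
      tc <- if (is.null(p$temperature_c)) 60 else p$temperature_c
      list(slurry = hydrolyze(feed2, enzyme = enz,
                              conversion = p$conversion, temperature_c = tc))
    },
    membrane_filter = {
      r <- membrane_filter(
        feed, rejected_component = p$rejected_component,
        rejection = p$rejection,
        denaturation = if (is.null(p$denaturation)) 0.05 else p$denaturation,
        flux = if (is.null(p$flux_lm2h)) 20 else p$flux_lm2h,
        max_density = if (is.null(p$max_density_gl)) 1100 else p$max_density_gl,
        registry = registry)
      extras$area_m2 <- r$area
      extras$warnings <- r$warnings
      r[c("permeate", "retentate")]
    },
    centrifuge = {
      pm <- if (is.null(p$phase_map)) default_phase_map() else unlist(p$phase_map)
      centrifuge(feed, phase_map = pm,
                 carryover = if (is.null(p$carryover)) 0 else p$carryover,
                 cake_moisture_ratio =
                   if (is.null(p$cake_moisture_ratio)) 1 else p$cake_moisture_ratio,
                 oil_entrained_water_ratio =
                   if (is.null(p$oil_entrained_water_ratio)) 0.02
                   else p$oil_entrained_water_ratio)
    },
    distillation = {
      r <- distill_sharp(feed, heavy_key_cut = p$heavy_key_cut_c,
                         reflux_ratio = p$reflux_ratio, stages = p$stages,
                         registry = registry)
      extras$condenser_duty_kj <- r$condenser_duty
      extras$reboiler_duty_kj <- r$reboiler_duty
      extras$warnings <- r$warnings
      r[c("distillate", "bottoms")]
    },
    condenser = {
      r <- condense(feed, outlet_temp = p$outlet_temp_c, registry = registry)
      extras$cooling_duty_kj <- r$cooling_duty
      r["liquid"]
    },
    cooler = {
      r <- cool_liquid(feed, outlet_temp = p$outlet_temp_c, registry = registry)
      extras$cooling_duty_kj <- r$cooling_duty
      r["liquid"]
    },
    adsorber = {
      bw <- if (idle) 0 else p$backwash_water_kg
      r <- adsorb_water(feed, backwash_water = bw)
      utility <- bw
      r
    },
    freeze_dryer = {
      r <- freeze_dry(
        feed, final_moisture = p$final_moisture,
        sublimation_rate =
          if (is.null(p$sublimation_rate_mm_h)) 10 else p$sublimation_rate_mm_h,
        tray_depth = if (is.null(p$tray_depth_mm)) 10 else p$tray_depth_mm)
      extras$duration_h <- r$duration
      extras$warnings <- r$warnings
      r[c("meal", "exhaust")]
    },
    transport = {
      size <- if (is.null(p$shipment_size_kg)) 20000 else p$shipment_size_kg
      extras$shipments <- ceiling(total_mass(feed) / size)
      list(product = set_masses(feed, feed$masses))
    },
    stop("unit ", uid, ": unknown kind")
  )
  streams_out <- out[!vapply(out, is.null, logical(1))]
  streams_out <- streams_out[vapply(streams_out, inherits, logical(1), "stream")]
  # per-unit mass closure
  m_in <- sum(vapply(ins, total_mass, numeric(1))) + utility
  m_out <- sum(vapply(streams_out, total_mass, numeric(1)))
  scale <- max(m_in, 1)
  if (abs(m_in - m_out) > 1e-9 * scale)
    stop("unit ", uid, ": mass balance violation (in ", m_in, " kg, out ",
         m_out, " kg)")
  list(streams = streams_out, extras = extras, utility_in = utility)
}

#' Default centrifuge phase map for the plant's component set
#'
#' Fatty acids report to the light (oil) phase, all protein species and the
#' enzyme to the heavy cake, cellulose, ash, other organics and water to the
#' aqueous outlet.
#' @return named character vector component -> light/heavy/aqueous
#' @export
default_phase_map <- function() {
  c(lauric = "light", myristic = "light", palmitic = "light",
    stearic = "light",
    protein = "heavy", hydrolyzed_protein = "heavy",
    denatured_protein = "heavy", alcalase = "heavy",
    cellulose = "aqueous", ash = "aqueous", other_organics = "aqueous",
    water = "aqueous")
}

#' Simulate a flowsheet
#'
#' Evaluates every unit in topological order, starting from the feed
#' stream(s), and checks per-unit and plant-wide mass closure.
#'
#' @param fs a \code{\link{flowsheet}}
#' @param feed the larvae feed \code{stream} (its label must match one of the
#'   flowsheet's declared feed streams)
#' @param registry component registry
#' @return list of class \code{plant_simulation} with elements
#'   \code{streams} (all streams by label, feeds included), \code{units}
#'   (per-unit extras: durations, duties, areas, warnings),
#'   \code{terminal_streams} (labels leaving the plant), \code{utilities_kg}
#'   (named water/enzyme utility inputs by unit) and \code{closure}
#'   (plant-level in/out totals and relative residual)
#' @export
#' @examples
#' cf <- wet_basis_fractions(feed_scenarios()[["control"]])
#' feed <- larvae_feed_stream(10000, cf)
#' sim <- simulate_flowsheet(default_flowsheet(), feed)
#' sim$closure$residual_rel
simulate_flowsheet <- function(fs, feed, registry = default_components()) {
  validate_flowsheet(fs)
  if (!feed$label %in% fs$feed_streams)
    stop("feed stream label '", feed$label,
         "' is not declared in the flowsheet feeds")
  streams <- setNames(list(feed), feed$label)
  order <- names(igraph::topo_sort(flowsheet_graph(fs), mode = "out"))
  units_out <- list()
  utilities <- numeric(0)
  for (uid in order) {
    u <- fs$units[[uid]]
    ins <- lapply(u$inputs, function(lab) {
      s <- streams[[lab]]
      if (is.null(s)) stop("unit ", uid, ": input stream '", lab,
                           "' not available at evaluation time")
      s
    })
    r <- tryCatch(evaluate_unit(uid, u, ins, registry),
                  error = function(e) stop("[", uid, "] ", conditionMessage(e),
                                           call. = FALSE))
    for (port in names(u$outputs)) {
      s <- r$streams[[port]]
      if (is.null(s)) stop("unit ", uid, ": model produced no '", port, "' port")
      s$label <- u$outputs[[port]]
      streams[[s$label]] <- s
    }
    units_out[[uid]] <- r$extras
    if (r$utility_in > 0) utilities[uid] <- r$utility_in
  }
  consumed <- unique(unlist(lapply(fs$units, `[[`, "inputs")))
  terminal <- setdiff(names(streams), consumed)
  m_in <- total_mass(feed) + sum(utilities)
  m_out <- sum(vapply(streams[terminal], total_mass, numeric(1)))
  residual <- abs(m_in - m_out) / max(m_in, 1)
  if (residual > 1e-9)
    stop("plant-level mass closure violated: in ", m_in, " kg, out ", m_out,
         " kg")
  structure(list(streams = streams, units = units_out,
                 terminal_streams = terminal, utilities_kg = utilities,
                 closure = list(mass_in_kg = m_in, mass_out_kg = m_out,
                                residual_rel = residual)),
            class = "plant_simulation")
}

#' @export
print.plant_simulation <- function(x, ...) {
  cat("<plant_simulation>", length(x$streams), "streams,",
      length(x$units), "units\n")
  cat(sprintf("  mass in %.2f kg, out %.2f kg, residual %.2e (relative)\n",
              x$closure$mass_in_kg, x$closure$mass_out_kg,
              x$closure$residual_rel))
  cat("  terminal streams:", paste(x$terminal_streams, collapse = ", "), "\n")
  invisible(x)
}

#' Expected component sets of the plant's active flows
#'
#' Reference contract for the default plant: which component classes each
#' named stream may contain (protein species are collapsed into one class,
#' the enzyme is its own class). Trace leaks below a mass-fraction threshold
#' are ignored by \code{\link{check_stream_contents}} because the membranes
#' are modelled with a finite (0.999) rejection.
#'
#' @return named list: stream label -> character vector of allowed classes
#' @export
expected_stream_contents <- function() {
  fa <- fatty_acid_names()
  list(
    "Larvae feed" = c("water", "ash", "protein", "cellulose", fa),
    "Wastes 1" = c("ash", "cellulose", "water"),
    "Crude suspension" = c("water", "ash", "protein", "cellulose", fa),
    "S-104" = c("water", "ash", "protein", "cellulose", fa),
    "Sludge" = c("water", "ash", "protein", "cellulose", "enzyme", fa),
    "Cellulose waste" = c("cellulose", "water"),
    "S-108" = c("water", "ash", "protein", "enzyme", fa),
    "Ash waste" = c("ash", "water"),
    "Slurry" = c("water", "protein", "enzyme", fa),
    "Oil feed" = c(fa, "water"),
    "Wet protein meals" = c("protein", "water", "enzyme"),
    "S-112" = c("cellulose", "water"),
    "Impure product 1" = c("lauric", "water"),
    "S-110" = c("lauric", "water"),
    "Lauric acid product" = "lauric",
    "Reusable water 2" = "water",
    "S-103" = c("myristic", "palmitic", "stearic"),
    "S-105" = "myristic",
    "Myristic acid product" = "myristic",
    "S-107" = c("palmitic", "stearic"),
    "Impure product 2" = "palmitic",
    "Palmitic acid product" = "palmitic",
    "S-111" = "stearic",
    "Stearic acid product" = "stearic",
    "Protein meal" = c("protein", "water", "enzyme"),
    "Protein product" = c("protein", "water", "enzyme"),
    "FD exhaust" = "water",
    "Reusable water 1" = "water",
    "Wastes 2" = c("cellulose", "water")
  )
}

#' @noRd
component_class <- function(comps) {
  cls <- comps
  cls[comps %in% protein_class()] <- "protein"
  cls[comps == "alcalase"] <- "enzyme"
  cls
}

#' Check simulated streams against the expected content contract
#'
#' @param sim a \code{plant_simulation}
#' @param expected contract from \code{\link{expected_stream_contents}}
#' @param trace_tol components below this mass fraction of their stream are
#'   ignored (finite-rejection leaks)
#' @return data.frame of violations (zero rows when the contract holds)
#' @export
check_stream_contents <- function(sim, expected = expected_stream_contents(),
                                  trace_tol = 0.005) {
  bad <- list()
  for (lab in intersect(names(expected), names(sim$streams))) {
    s <- sim$streams[[lab]]
    if (!length(s$masses)) next
    frac <- s$masses / total_mass(s)
    major <- names(s$masses)[frac >= trace_tol]
    extra <- setdiff(unique(component_class(major)), expected[[lab]])
    if (length(extra))
      bad[[lab]] <- data.frame(label = lab,
                               unexpected = paste(extra, collapse = ", "))
  }
  out <- do.call(rbind, bad)
  if (is.null(out)) out <- data.frame(label = character(0),
                                      unexpected = character(0))
  rownames(out) <- NULL
  out
}
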