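# Unit-operation models. Every model is a pure split-fraction mass balance:
# output component masses are linear in the feed, conservation holds exactly,
# and temperature/pressure/phase are metadata. Energy duties (condenser,
# reboiler, cooler) are shortcut estimates from configurable latent heats and
# heat capacities and never feed back into the mass balance.

#' @noRd
check_fraction <- function(x, what) {
  if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a fraction in [0, 1], got ", x)
  x
}

#' Cold-water larvae washer
#'
#' Removes a fixed fraction of the feed's ash and cellulose into a waste
#' stream together with all wash water; everything else passes through.
#'
#' @param feed feed \code{stream}
#' @param wash_water wash water added, kg per batch (>= 0)
#' @param ash_removal fraction of feed ash removed (plant default 0.66)
#' @param cellulose_removal fraction of feed cellulose removed (default 0.38)
#' @return list with \code{washed} and \code{waste} streams; total mass in
#'   (feed + wash water) equals total mass out
#' @export
#' @examples
#' f <- stream("feed", c(ash = 100, cellulose = 200, water = 700))
#' w <- wash(f, wash_water = 500)
#' component_mass(w$waste, "ash")  # 66
wash <- function(feed, wash_water, ash_removal = 0.66,
                 cellulose_removal = 0.38) {
  validate_stream(feed)
  check_fraction(ash_removal, "ash_removal")
  check_fraction(cellulose_removal, "cellulose_removal")
  if (wash_water < 0) stop("wash_water must be >= 0")
  ash_out <- ash_removal * component_mass(feed, "ash")
  cel_out <- cellulose_removal * component_mass(feed, "cellulose")
  waste_m <- c(ash = ash_out, cellulose = cel_out, water = wash_water)
  washed_m <- feed$masses
  washed_m["ash"] <- component_mass(feed, "ash") - ash_out
  washed_m["cellulose"] <- component_mass(feed, "cellulose") - cel_out
  list(
    washed = set_masses(feed, washed_m, label = "Crude suspension",
                        phase = "solid-slurry"),
    waste = stream("Wastes 1", waste_m, temperature = feed$temperature,
                   phase = "solid-slurry")
  )
}

#' Mechanical grinder
#'
#' Composition-preserving size reduction; the only model output besides the
#' pass-through stream is the occupancy duration at the unit's calculated
#' throughput.
#'
#' @param feed feed \code{stream}
#' @param throughput kg/h (> 0); plant default 9174 kg/h
#' @return list with \code{product} stream and \code{duration} (h)
#' @export
grind <- function(feed, throughput = 9174) {
  validate_stream(feed)
  if (length(throughput) != 1 || is.na(throughput) || throughput <= 0)
    stop("throughput must be > 0")
  list(product = set_masses(feed, feed$masses, label = "Sludge"),
       duration = total_mass(feed) / throughput)
}

#' Enzymatic hydrolysis reactor
#'
#' Adds the alcalase charge to the slurry and re-labels a \code{conversion}
#' fraction of the native protein as hydrolyzed protein (same mass; the
#' species split is book-keeping for downstream reporting). Outlet at the
#' incubation temperature.
#'
#' @param feed feed \code{stream}
#' @param enzyme alcalase charge, kg per batch (plant default 100)
#' @param conversion fraction of protein hydrolyzed in [0, 1]
#' @param temperature_c outlet temperature, degC (default 60)
#' @return hydrolysate \code{stream}; total out = total in + enzyme
#' @export
hydrolyze <- function(feed, enzyme = 100, conversion = 0.9,
                      temperature_c = 60) {
  validate_stream(feed)
  if (enzyme < 0) stop("enzyme mass must be >= 0")
  check_fraction(conversion, "conversion")
  m <- feed$masses
  prot <- component_mass(feed, "protein")
  hyd <- conversion * prot
  m["protein"] <- prot - hyd
  m <- add_masses(m, c(hydrolyzed_protein = hyd, alcalase = enzyme))
  set_masses(feed, m, label = "Slurry", phase = "solid-slurry",
             temperature = temperature_c)
}

#' Membrane filter (micro- or ultrafiltration)
#'
#' Rejects one solid component into the retentate at the given rejection
#' rate. The retentate carries the minimum water that keeps its solids
#' concentration at or below \code{max_density}; all other components pass
#' to the permeate. A \code{denaturation} fraction of the protein crossing
#' the membrane is re-labelled denatured protein (mass conserving). Membrane
#' area is sized from the feed volumetric flow and the design flux.
#'
#' @param feed feed \code{stream}
#' @param rejected_component component name retained (e.g. "cellulose")
#' @param rejection rejection rate in [0, 1] (plant default 0.999)
#' @param denaturation fraction of permeating protein denatured (default 0.05)
#' @param flux design permeate flux, L/m2/h (default 20)
#' @param max_density maximum retentate solids concentration, g/L
#'   (kg/m3; plant defaults 1100 for MF, 1200 for UF)
#' @param duration_h filtration step duration used to convert the per-batch
#'   feed volume into a volumetric flow for area sizing (default 1 h)
#' @param registry component registry (densities), see
#'   \code{\link{default_components}}
#' @return list with \code{permeate} and \code{retentate} streams,
#'   \code{area} (m2) and \code{warnings} (character)
#' @export
#' @examples
#' f <- stream("feed", c(cellulose = 1000, water = 9000))
#' mf <- membrane_filter(f, "cellulose", rejection = 0.999)
#' component_mass(mf$retentate, "cellulose")  # 999
membrane_filter <- function(feed, rejected_component, rejection = 0.999,
                            denaturation = 0.05, flux = 20,
                            max_density = 1100, duration_h = 1,
                            registry = default_components()) {
  validate_stream(feed)
  check_fraction(rejection, "rejection")
  check_fraction(denaturation, "denaturation")
  if (flux <= 0) stop("flux must be > 0")
  if (!rejected_component %in% registry$name)
    stop("unknown rejected_component: ", rejected_component)
  warnings <- character(0)

  solids <- rejection * component_mass(feed, rejected_component)
  rho_s <- comp_field(registry, rejected_component, "density")
  rho_w <- comp_field(registry, "water", "density")
  # minimum retentate water W s.t. solids/(solids/rho_s + W/rho_w) <= max_density
  water_needed <- if (solids > 0 && max_density < rho_s) {
    rho_w * solids * (1 / max_density - 1 / rho_s)
  } else 0
  water_avail <- component_mass(feed, "water")
  if (water_needed > water_avail) {
    warnings <- c(warnings, sprintf(
      "retentate solids concentration exceeds max density %g g/L (needs %.1f kg water, %.1f kg available)",
      max_density, water_needed, water_avail))
    water_needed <- water_avail
  }

  ret_m <- setNames(c(solids, water_needed), c(rejected_component, "water"))
  perm_m <- feed$masses
  perm_m[rejected_component] <- component_mass(feed, rejected_component) - solids
  perm_m["water"] <- water_avail - water_needed
  # denaturation of protein crossing the membrane
  p_cross <- sum(pmax(perm_m[intersect(c("protein", "hydrolyzed_protein"),
                                       names(perm_m))], 0), na.rm = TRUE)
  if (p_cross > 0 && denaturation > 0) {
    den <- denaturation * p_cross
    for (sp in c("protein", "hydrolyzed_protein")) {
      if (!is.na(perm_m[sp]) && perm_m[sp] > 0)
        perm_m[sp] <- perm_m[sp] * (1 - denaturation)
    }
    perm_m <- add_masses(perm_m, c(denatured_protein = den))
  }

  vol_L <- sum(feed$masses / comp_field(registry, names(feed$masses), "density")) * 1000
  area <- (vol_L / duration_h) / flux

  list(
    permeate = set_masses(feed, perm_m, label = paste0(feed$label, " permeate"),
                          phase = "liquid"),
    retentate = stream(paste0(rejected_component, " retentate"), ret_m,
                       temperature = feed$temperature, phase = "solid-slurry"),
    area = area, warnings = warnings
  )
}

#' Disc-stack centrifuge
#'
#' Routes every component to the light (oil), heavy (wet protein cake) or
#' aqueous outlet per \code{phase_map}. Two physical side-flows refine the
#' water routing beyond the map: the cake retains \code{cake_moisture_ratio}
#' kg water per kg heavy solids, and the light phase entrains
#' \code{oil_entrained_water_ratio} kg water per kg oil; the remaining water
#' follows its mapped outlet. A \code{carryover} fraction of the fatty acids
#' leaks into the heavy outlet (default 0, ideal split).
#'
#' @param feed feed \code{stream}
#' @param phase_map named character vector, component -> one of
#'   \code{"light"}, \code{"heavy"}, \code{"aqueous"}; must cover every
#'   component present in the feed
#' @param carryover fraction of light-phase (fatty acid) mass leaking into
#'   the heavy outlet
#' @param cake_moisture_ratio kg water per kg heavy solids (default 1)
#' @param oil_entrained_water_ratio kg water per kg light phase (default 0.02)
#' @return list of streams \code{oil_feed}, \code{wet_protein},
#'   \code{water_cellulose}; the three outputs sum to the feed
#' @export
centrifuge <- function(feed, phase_map, carryover = 0,
                       cake_moisture_ratio = 1,
                       oil_entrained_water_ratio = 0.02) {
  validate_stream(feed)
  check_fraction(carryover, "carryover")
  if (cake_moisture_ratio < 0 || oil_entrained_water_ratio < 0)
    stop("moisture/entrainment ratios must be >= 0")
  present <- names(feed$masses)
  unmapped <- setdiff(present, names(phase_map))
  if (length(unmapped))
    stop("centrifuge phase_map does not cover component(s): ",
         paste(unmapped, collapse = ", "))
  bad <- setdiff(unique(phase_map), c("light", "heavy", "aqueous"))
  if (length(bad)) stop("invalid phase_map target(s): ", paste(bad, collapse = ", "))

  out <- list(light = numeric(0), heavy = numeric(0), aqueous = numeric(0))
  for (comp in present) {
    if (comp == "water") next
    tgt <- phase_map[[comp]]
    m <- feed$masses[[comp]]
    if (tgt == "light" && carryover > 0) {
      out$heavy <- add_masses(out$heavy, setNames(carryover * m, comp))
      m <- (1 - carryover) * m
    }
    out[[tgt]] <- add_masses(out[[tgt]], setNames(m, comp))
  }
  water <- component_mass(feed, "water")
  cake_w <- min(water, cake_moisture_ratio * sum(out$heavy))
  oil_w <- min(water - cake_w, oil_entrained_water_ratio * sum(out$light))
  rest_w <- water - cake_w - oil_w
  if (cake_w > 0) out$heavy <- add_masses(out$heavy, c(water = cake_w))
  if (oil_w > 0) out$light <- add_masses(out$light, c(water = oil_w))
  if (rest_w > 0) {
    tgt <- if (!is.na(phase_map["water"])) phase_map[["water"]] else "aqueous"
    out[[tgt]] <- add_masses(out[[tgt]], c(water = rest_w))
  }
  list(
    oil_feed = stream("Oil feed", out$light, temperature = feed$temperature,
                      phase = "liquid"),
    wet_protein = stream("Wet protein meals", out$heavy,
                         temperature = feed$temperature, phase = "solid-slurry"),
    water_cellulose = stream("S-112", out$aqueous,
                             temperature = feed$temperature, phase = "liquid")
  )
}

#' Sharp-split fractional distillation
#'
#' Shortcut column model: every component boiling strictly below the
#' heavy-key cut temperature reports entirely to the (vapor) distillate, the
#' rest to the (liquid) bottoms. Condenser duty is
#' \code{(reflux_ratio + 1) x distillate mass x mass-weighted latent heat};
#' the reboiler duty equals the condenser duty plus a configurable offset
#' (total-condenser shortcut).
#'
#' @param feed feed \code{stream} (nonempty)
#' @param heavy_key_cut cut temperature, degC; must fall strictly between
#'   component boiling points present in the feed
#' @param reflux_ratio dimensionless (>= 0)
#' @param stages stage count (metadata only; no tray-by-tray model)
#' @param reboiler_offset additive offset on the reboiler duty, kJ
#' @param registry component registry (boiling points, latent heats)
#' @return list with \code{distillate}, \code{bottoms}, \code{condenser_duty}
#'   (kJ), \code{reboiler_duty} (kJ), \code{warnings}
#' @export
#' @examples
#' f <- stream("oil", c(water = 10, lauric = 20, myristic = 30,
#'                      palmitic = 15, stearic = 25), phase = "liquid")
#' d <- distill_sharp(f, heavy_key_cut = 310, reflux_ratio = 14.404)
#' names(d$distillate$masses)  # water, lauric
distill_sharp <- function(feed, heavy_key_cut, reflux_ratio, stages = NULL,
                          reboiler_offset = 0,
                          registry = default_components()) {
  validate_stream(feed)
  if (reflux_ratio < 0) stop("reflux_ratio must be >= 0")
  if (!length(feed$masses)) {
    # an empty feed is a degenerate case, not an error: the whole plant must
    # simulate cleanly on an empty batch
    return(list(distillate = stream(paste0(feed$label, " distillate"),
                                    temperature = heavy_key_cut, phase = "vapor"),
                bottoms = stream(paste0(feed$label, " bottoms"),
                                 temperature = heavy_key_cut, phase = "liquid"),
                condenser_duty = 0, reboiler_duty = reboiler_offset,
                warnings = "degenerate cut: distillation feed is empty"))
  }
  bp <- comp_field(registry, names(feed$masses), "boiling_point")
  if (anyNA(bp))
    stop("non-volatile component(s) in distillation feed: ",
         paste(names(feed$masses)[is.na(bp)], collapse = ", "))
  if (any(abs(bp - heavy_key_cut) < 1e-9))
    stop("ambiguous cut: temperature ", heavy_key_cut,
         " degC coincides with a component boiling point")
  light <- bp < heavy_key_cut
  warnings <- character(0)
  if (all(light) || all(!light))
    warnings <- "degenerate cut: one product stream is empty"

  dist_m <- feed$masses[light]
  bot_m <- feed$masses[!light]
  lambda <- comp_field(registry, names(dist_m), "latent_heat")
  dist_mass <- sum(dist_m)
  lam_bar <- if (dist_mass > 0) sum(dist_m * lambda) / dist_mass else 0
  cond <- (reflux_ratio + 1) * dist_mass * lam_bar
  list(
    distillate = stream(paste0(feed$label, " distillate"), dist_m,
                        temperature = heavy_key_cut, phase = "vapor"),
    bottoms = stream(paste0(feed$label, " bottoms"), bot_m,
                     temperature = heavy_key_cut, phase = "liquid"),
    condenser_duty = cond,
    reboiler_duty = cond + reboiler_offset,
    warnings = warnings
  )
}

#' Total condenser / product cooler
#'
#' Condenses a vapor stream to liquid at the outlet temperature. Cooling
#' duty is the latent heat of condensation plus sensible cooling from each
#' component's boiling point down to the outlet temperature.
#'
#' @param vapor a vapor-phase \code{stream}
#' @param outlet_temp degC (plant condensers run at 80 degC)
#' @param registry component registry
#' @return list with \code{liquid} stream and \code{cooling_duty} (kJ)
#' @export
condense <- function(vapor, outlet_temp = 80, registry = default_components()) {
  validate_stream(vapor)
  if (vapor$phase != "vapor")
    stop("condense() requires a vapor-phase stream, got '", vapor$phase, "'")
  list(liquid = set_masses(vapor, vapor$masses,
                           label = sub(" distillate$", " condensate", vapor$label),
                           phase = "liquid", temperature = outlet_temp),
       cooling_duty = sensible_plus_latent_duty(vapor$masses, outlet_temp,
                                                registry, latent = TRUE))
}

#' Sensible-heat product cooler (no phase change)
#'
#' @param feed a liquid \code{stream}
#' @param outlet_temp degC
#' @param registry component registry
#' @return list with \code{liquid} stream and \code{cooling_duty} (kJ)
#' @export
cool_liquid <- function(feed, outlet_temp = 80, registry = default_components()) {
  validate_stream(feed)
  dT <- pmax(feed$temperature - outlet_temp, 0)
  cp <- comp_field(registry, names(feed$masses), "cp")
  list(liquid = set_masses(feed, feed$masses, phase = "liquid",
                           temperature = outlet_temp),
       cooling_duty = sum(feed$masses * cp * dT))
}

#' @noRd
sensible_plus_latent_duty <- function(masses, outlet_temp, registry, latent) {
  if (!length(masses)) return(0)
  bp <- comp_field(registry, names(masses), "boiling_point")
  lam <- comp_field(registry, names(masses), "latent_heat")
  cp <- comp_field(registry, names(masses), "cp")
  bp[is.na(bp)] <- outlet_temp
  lam[is.na(lam)] <- 0
  sum(masses * (if (latent) lam else 0) + masses * cp * pmax(bp - outlet_temp, 0))
}

#' Backwash adsorption column (water removal)
#'
#' Removes all water from a liquid product into a reusable-water stream,
#' together with the backwash water charge.
#'
#' @param feed liquid \code{stream}
#' @param backwash_water backwash charge, kg per batch (>= 0)
#' @return list with \code{dry_product} and \code{reusable_water} streams
#' @export
adsorb_water <- function(feed, backwash_water = 0) {
  validate_stream(feed)
  if (backwash_water < 0) stop("backwash_water must be >= 0")
  w <- component_mass(feed, "water")
  dry_m <- feed$masses[setdiff(names(feed$masses), "water")]
  list(
    dry_product = set_masses(feed, dry_m, phase = "liquid"),
    reusable_water = stream("Reusable water 2",
                            c(water = w + backwash_water),
                            temperature = feed$temperature, phase = "liquid")
  )
}

#' Tray freeze dryer
#'
#' Sublimates water off the wet protein cake down to a target final moisture
#' fraction. Drying time follows a receding-front layer model:
#' tray depth / sublimation rate.
#'
#' @param feed wet cake \code{stream}
#' @param final_moisture target water mass fraction of the dried meal, in
#'   [0, 1)
#' @param sublimation_rate front recession rate, mm/h (plant default 10)
#' @param tray_depth product layer depth, mm (default 10)
#' @return list with \code{meal}, \code{exhaust} (water vapor) streams,
#'   \code{duration} (h) and \code{warnings}
#' @export
#' @examples
#' fd <- freeze_dry(stream("cake", c(protein = 950, water = 950)),
#'                  final_moisture = 0.05)
#' component_mass(fd$meal, "water")  # 50
freeze_dry <- function(feed, final_moisture = 0.05, sublimation_rate = 10,
                       tray_depth = 10) {
  validate_stream(feed)
  if (final_moisture < 0 || final_moisture >= 1)
    stop("final_moisture must lie in [0, 1)")
  if (sublimation_rate <= 0 || tray_depth <= 0)
    stop("sublimation_rate and tray_depth must be > 0")
  warnings <- character(0)
  w <- component_mass(feed, "water")
  solids <- total_mass(feed) - w
  # water kept: w_keep / (solids + w_keep) = final_moisture
  w_keep <- final_moisture * solids / (1 - final_moisture)
  if (w <= w_keep) {
    warnings <- "feed already at or below target moisture; freeze dryer is a no-op"
    w_keep <- w
  }
  removed <- w - w_keep
  meal_m <- feed$masses
  meal_m["water"] <- w_keep
  list(
    meal = set_masses(feed, meal_m, label = "Protein meal", phase = "solid-slurry",
                      temperature = 12),
    exhaust = stream("FD exhaust", c(water = removed), temperature = 12,
                     phase = "vapor"),
    duration = tray_depth / sublimation_rate,
    warnings = warnings
  )
}
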