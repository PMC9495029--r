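#' Default simulation component registry
#'
#' The plant tracks a fixed set of pure components: water, ash, cellulose,
#' three protein book-keeping species (native, hydrolyzed, denatured), the
#' alcalase enzyme, and the four fatty acids that make up the crude-fat
#' fraction of the larvae. Boiling points drive the sharp-split distillation
#' model and must be strictly ordered lauric < myristic < palmitic < stearic.
#' Latent heats and heat capacities feed only the condenser/reboiler duty
#' estimates, never the mass balance; densities are used for membrane area
#' sizing and retentate water demand.
#'
#' @param overrides optional named list; each element is itself a named list
#'   of fields to replace for that component (e.g.
#'   \code{list(lauric = list(latent_heat = 350))}).
#' @return a data.frame with columns \code{name}, \code{boiling_point} (degC,
#'   \code{NA} for non-volatile solids), \code{density} (kg/m3),
#'   \code{latent_heat} (kJ/kg), \code{cp} (kJ/kg/K) and \code{role} (one of
#'   \code{"revenue"}, \code{"byproduct"}, \code{"waste"}, \code{"process"}).
#' @export
#' @examples
#' reg <- default_components()
#' reg[reg$role == "revenue", c("name", "boiling_point")]
default_components <- function(overrides = NULL) {
  reg <- data.frame(
    name = c("water", "ash", "cellulose", "protein", "hydrolyzed_protein",
             "denatured_protein", "alcalase", "other_organics",
             "lauric", "myristic", "palmitic", "stearic"),
    boiling_point = c(100, NA, NA, NA, NA, NA, NA, NA,
                      298.8, 326.2, 348.0, 361.1),
    density = c(1000, 1500, 1500, 1300, 1300, 1300, 1300, 1200,
                900, 900, 900, 900),
    latent_heat = c(2257, rep(NA_real_, 7), rep(200, 4)),
    cp = c(4.18, rep(1.5, 7), rep(2.1, 4)),
    role = c("process", "waste", "waste", "byproduct", "byproduct",
             "byproduct", "process", "process",
             rep("revenue", 4)),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, reg$name)
      if (is.na(i)) stop("unknown component in overrides: ", nm)
      for (f in names(overrides[[nm]])) reg[i, f] <- overrides[[nm]][[f]]
    }
  }
  validate_components(reg)
  reg
}

#' @noRd
validate_components <- function(reg) {
  stopifnot(is.data.frame(reg), all(c("name", "boiling_point", "density",
                                      "latent_heat", "cp", "role") %in% names(reg)))
  if (anyDuplicated(reg$name)) stop("duplicate component names in registry")
  if (any(reg$density <= 0, na.rm = TRUE)) stop("component densities must be > 0")
  fa <- fatty_acid_names()
  bp <- reg$boiling_point[match(fa, reg$name)]
  if (anyNA(bp) || any(diff(bp) <= 0)) {
    stop("fatty-acid boiling points must be strictly increasing: ",
         paste(fa, collapse = " < "))
  }
  invisible(reg)
}

#' Names of the four revenue fatty acids, in boiling-point order
#' @return character vector of length 4
#' @export
fatty_acid_names <- function() c("lauric", "myristic", "palmitic", "stearic")

#' @noRd
protein_class <- function() c("protein", "hydrolyzed_protein", "denatured_protein")

#' @noRd
comp_field <- function(registry, comps, field) {
  i <- match(comps, registry$name)
  if (anyNA(i)) stop("unknown component(s): ", paste(comps[is.na(i)], collapse = ", "))
  registry[[field]][i]
}
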