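#' Proximate composition of a larval feed scenario
#'
#' Holds one row set of the larval proximate analysis for a feed scenario:
#' dry matter as % of wet mass, and ash, crude protein, neutral/acid
#' detergent fiber, ether extract and organic matter as % of dry matter,
#' each with a standard deviation. Organic matter and ADF overlap the other
#' fractions (OM subsumes protein/fiber/fat; ADF is contained in NDF), so
#' they are carried for reporting only and never enter the wet-basis
#' conversion.
#'
#' @param scenario_label scenario name, e.g. \code{"kitchen_waste"}
#' @param dry_matter_pct,ash_pct,crude_protein_pct,ndf_pct,adf_pct,ether_extract_pct,organic_matter_pct
#'   percentages (see description for basis)
#' @param sd named numeric vector of standard deviations for any subset of
#'   the percentage fields (same units); missing entries default to 0
#' @return object of class \code{proximate_composition}
#' @export
#' @examples
#' control <- proximate_composition("control", 32.7, 15.9, 44.7, 10.6, 19, 9.7, 84,
#'                                  sd = c(dry_matter_pct = 5))
#' wet_basis_fractions(control)$water
proximate_composition <- function(scenario_label, dry_matter_pct, ash_pct,
                                  crude_protein_pct, ndf_pct, adf_pct,
                                  ether_extract_pct, organic_matter_pct,
                                  sd = numeric(0)) {
  pct <- c(dry_matter_pct = dry_matter_pct, ash_pct = ash_pct,
           crude_protein_pct = crude_protein_pct, ndf_pct = ndf_pct,
           adf_pct = adf_pct, ether_extract_pct = ether_extract_pct,
           organic_matter_pct = organic_matter_pct)
  sds <- setNames(numeric(length(pct)), names(pct))
  if (length(sd)) {
    unknown <- setdiff(names(sd), names(pct))
    if (length(unknown)) stop("unknown sd field(s): ", paste(unknown, collapse = ", "))
    sds[names(sd)] <- sd
  }
  pc <- structure(list(scenario_label = scenario_label, pct = pct, sd = sds),
                  class = "proximate_composition")
  validate_proximate(pc)
  pc
}

#' @noRd
validate_proximate <- function(pc) {
  if (any(pc$pct < 0 | pc$pct > 100))
    stop("scenario '", pc$scenario_label,
         "': all percentages must lie in [0, 100]")
  if (any(pc$sd < 0)) stop("standard deviations must be >= 0")
  dm_sum <- sum(pc$pct[c("ash_pct", "crude_protein_pct", "ndf_pct",
                         "ether_extract_pct")])
  # soft sanity bound: measured rows sum near 100% of dry matter before
  # renormalization (the spent-grain scenario reaches 112.5%)
  if (dm_sum > 115)
    warning("scenario '", pc$scenario_label, "': measured dry-matter ",
            "components sum to ", round(dm_sum, 1),
            "% (> 115%); check the composition")
  invisible(pc)
}

#' @export
print.proximate_composition <- function(x, ...) {
  cat(sprintf("<proximate_composition> %s\n", x$scenario_label))
  for (nm in names(x$pct))
    cat(sprintf("  %-22s %6.1f +/- %.1f\n", nm, x$pct[[nm]], x$sd[[nm]]))
  invisible(x)
}

#' Convert a proximate composition to wet-basis component fractions
#'
#' Water is \code{1 - dry_matter/100}. The four measured dry-matter
#' components (ash, crude protein, NDF mapped to cellulose, ether extract
#' mapped to crude fat) are renormalized to exactly fill the dry matter;
#' \code{other_organics} is zero under this default. The renormalization is
#' needed because the measured components do not sum exactly to 100% of dry
#' matter, and the overlapping OM/ADF rows are excluded.
#'
#' @param pc a \code{proximate_composition}
#' @return a named list of class \code{component_fractions} with elements
#'   \code{water}, \code{ash}, \code{protein}, \code{cellulose},
#'   \code{crude_fat}, \code{other_organics}; fractions sum to 1
#' @export
#' @examples
#' kw <- proximate_composition("kitchen_waste", 87.7, 9.6, 33.0, 20.4, 13.2, 34.3, 90.4)
#' cf <- wet_basis_fractions(kw)
#' sum(unlist(cf))  # 1
wet_basis_fractions <- function(pc) {
  validate_proximate(pc)
  dm <- pc$pct[["dry_matter_pct"]] / 100
  parts <- pc$pct[c("ash_pct", "crude_protein_pct", "ndf_pct",
                    "ether_extract_pct")]
  S <- sum(parts)
  if (dm > 0 && S == 0)
    stop("scenario '", pc$scenario_label,
         "': degenerate composition (all measured dry-matter components are 0)")
  share <- if (S > 0) parts / S else parts * 0
  cf <- structure(list(
    water = 1 - dm,
    ash = dm * share[["ash_pct"]],
    protein = dm * share[["crude_protein_pct"]],
    cellulose = dm * share[["ndf_pct"]],
    crude_fat = dm * share[["ether_extract_pct"]],
    other_organics = 0
  ), class = "component_fractions")
  validate_fractions(cf)
  cf
}

#' @noRd
validate_fractions <- function(cf) {
  v <- unlist(cf)
  if (any(v < -1e-12 | v > 1 + 1e-12)) stop("component fractions must lie in [0, 1]")
  if (abs(sum(v) - 1) > 1e-9) stop("component fractions must sum to 1")
  invisible(cf)
}

#' Fatty-acid profile of the crude-fat fraction
#'
#' Mass fractions of the four fatty acids within crude fat. The plant's
#' product spectrum is not measured here; the default is lauric-dominant,
#' the lead product of the fractionation train.
#'
#' @param lauric,myristic,palmitic,stearic mass fractions summing to 1
#' @return named numeric vector of class \code{fatty_acid_profile}
#' @export
fatty_acid_profile <- function(lauric = 0.50, myristic = 0.20,
                               palmitic = 0.20, stearic = 0.10) {
  p <- c(lauric = lauric, myristic = myristic, palmitic = palmitic,
         stearic = stearic)
  if (any(p < 0 | p > 1)) stop("fatty-acid fractions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) stop("fatty-acid fractions must sum to 1")
  structure(p, class = c("fatty_acid_profile", "numeric"))
}

#' Split a crude-fat mass into the four fatty acids
#'
#' @param fat_mass crude-fat mass, kg (>= 0)
#' @param profile a \code{\link{fatty_acid_profile}}
#' @return named numeric vector of the four fatty-acid masses (kg), summing
#'   to \code{fat_mass}
#' @export
#' @examples
#' split_crude_fat(3430, fatty_acid_profile(0.5, 0.2, 0.2, 0.1))
split_crude_fat <- function(fat_mass, profile = fatty_acid_profile()) {
  if (length(fat_mass) != 1 || is.na(fat_mass) || fat_mass < 0)
    stop("fat_mass must be a single non-negative number")
  if (!inherits(profile, "fatty_acid_profile"))
    profile <- do.call(fatty_acid_profile, as.list(profile))
  out <- fat_mass * unclass(profile)
  # force exact closure against rounding in the fractions
  out[length(out)] <- fat_mass - sum(out[-length(out)])
  out
}

#' Build the larvae feed stream for one batch
#'
#' Expands a wet-basis composition into the plant's component basis: water,
#' ash, protein, cellulose, and the crude fat split into the four fatty
#' acids via \code{\link{split_crude_fat}}.
#'
#' @param batch_mass wet larvae mass per batch, kg (> 0); the plant default
#'   is 10,000 kg
#' @param cf \code{component_fractions} from \code{\link{wet_basis_fractions}}
#' @param profile \code{\link{fatty_acid_profile}} of the crude fat
#' @return a \code{\link{stream}} labelled "Larvae feed" whose total mass is
#'   \code{batch_mass}
#' @export
larvae_feed_stream <- function(batch_mass, cf, profile = fatty_acid_profile()) {
  if (length(batch_mass) != 1 || is.na(batch_mass) || batch_mass <= 0)
    stop("batch_mass must be a single positive number")
  validate_fractions(cf)
  masses <- c(water = batch_mass * cf$water,
              ash = batch_mass * cf$ash,
              protein = batch_mass * cf$protein,
              cellulose = batch_mass * cf$cellulose,
              other_organics = batch_mass * cf$other_organics,
              split_crude_fat(batch_mass * cf$crude_fat, profile))
  stream("Larvae feed", masses, temperature = 25, phase = "solid-slurry")
}
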