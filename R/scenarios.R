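# Feed-scenario fixtures and the synthetic-scenario generator used for
# sensitivity analysis: larval compositions sampled around the measured
# means, and mean-preserving log-normal price perturbations.

#' Larval proximate compositions by feed scenario
#'
#' Reads the packaged scenario fixture (chicken manure, kitchen waste, spent
#' grain, control) into \code{\link{proximate_composition}} objects. The
#' chicken-manure organic-matter value (59.8) is internally inconsistent with
#' its other rows; it is carried as reporting metadata only and never enters
#' the wet-basis conversion.
#'
#' @param path YAML fixture; defaults to the packaged scenario set
#' @return named list of \code{proximate_composition}
#' @export
#' @examples
#' names(feed_scenarios())
feed_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                                package = "bsfrefinery")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg$scenarios), function(lab) {
    s <- cfg$scenarios[[lab]]
    m <- function(f) s[[f]]$mean
    sd <- vapply(s, function(f) f$sd, numeric(1))
    names(sd) <- c(dry_matter = "dry_matter_pct", ash = "ash_pct",
                   organic_matter = "organic_matter_pct",
                   crude_protein = "crude_protein_pct", ndf = "ndf_pct",
                   adf = "adf_pct",
                   ether_extract = "ether_extract_pct")[names(s)]
    proximate_composition(lab,
                          dry_matter_pct = m("dry_matter"),
                          ash_pct = m("ash"),
                          crude_protein_pct = m("crude_protein"),
                          ndf_pct = m("ndf"), adf_pct = m("adf"),
                          ether_extract_pct = m("ether_extract"),
                          organic_matter_pct = m("organic_matter"),
                          sd = sd)
  })
  names(out) <- names(cfg$scenarios)
  out
}

#' Sample a proximate composition around its measured means
#'
#' Each percentage is drawn independently from a normal with the scenario's
#' mean and SD, truncated to [0, 100] (no covariance structure is available
#' for the measurements; independence is a documented limitation).
#'
#' @param pc a \code{\link{proximate_composition}} (means and SDs)
#' @param seed integer seed; the draw is reproducible given the seed
#' @return a \code{proximate_composition} with the sampled values and zero SDs
#' @export
sample_composition <- function(pc, seed = NULL) {
  validate_proximate(pc)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  v <- stats::rnorm(length(pc$pct), mean = pc$pct, sd = pc$sd)
  v <- pmin(pmax(v, 0), 100)
  names(v) <- names(pc$pct)
  proximate_composition(pc$scenario_label,
                        dry_matter_pct = v[["dry_matter_pct"]],
                        ash_pct = v[["ash_pct"]],
                        crude_protein_pct = v[["crude_protein_pct"]],
                        ndf_pct = v[["ndf_pct"]], adf_pct = v[["adf_pct"]],
                        ether_extract_pct = v[["ether_extract_pct"]],
                        organic_matter_pct = v[["organic_matter_pct"]])
}

#' Generate a synthetic scenario set for sensitivity analysis
#'
#' Draws \code{n} composition samples per scenario plus mean-preserving
#' log-normal perturbations of the product prices
#' (\code{price x exp(rnorm(0, sigma) - sigma^2/2)} with sigma chosen so the
#' coefficient of variation equals \code{price_cv}). Deterministic under the
#' seed.
#'
#' @param n samples per scenario (>= 1)
#' @param scenarios named list of \code{proximate_composition} (default: the
#'   packaged scenario set)
#' @param base_prices a \code{\link{cost_model}} supplying the base product
#'   prices
#' @param price_cv coefficient of variation of the price perturbation (>= 0)
#' @param seed integer master seed
#' @return list of scenario samples; each has \code{scenario_label},
#'   \code{composition}, \code{profile}, \code{prices} (perturbed named
#'   vector) and \code{seed} (the child seed used)
#' @export
generate_scenario_set <- function(n, scenarios = feed_scenarios(),
                                  base_prices = cost_model(),
                                  price_cv = 0, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (price_cv < 0) stop("price_cv must be >= 0")
  stopifnot(inherits(base_prices, "cost_model"))
  total <- n * length(scenarios)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, total)
  sigma <- sqrt(log(1 + price_cv^2))
  out <- vector("list", total)
  i <- 0
  for (lab in names(scenarios)) {
    for (k in seq_len(n)) {
      i <- i + 1
      comp <- sample_composition(scenarios[[lab]], seed = child_seeds[i])
      prices <- base_prices$product_prices
      if (price_cv > 0) {
        set.seed(child_seeds[i] %% 1000003L + 7L)
        prices <- prices * exp(stats::rnorm(length(prices), 0, sigma) -
                                 sigma^2 / 2)
      }
      out[[i]] <- list(scenario_label = lab, composition = comp,
                       profile = fatty_acid_profile(), prices = prices,
                       seed = child_seeds[i])
    }
  }
  out
}

#' Write a sampled scenario set to the pipeline's config format
#'
#' @param samples output of \code{\link{generate_scenario_set}}
#' @param path output YAML file
#' @return \code{path}, invisibly
#' @export
write_scenario_set <- function(samples, path) {
  doc <- list(samples = lapply(samples, function(s) {
    list(scenario_label = s$scenario_label,
         seed = s$seed,
         composition = as.list(s$composition$pct),
         profile = as.list(unclass(s$profile)),
         product_prices = as.list(s$prices))
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}
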