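# Shared fixtures: random feeds and compositions built in code.

# random larvae-like feed stream over the full component set
random_feed <- function(seed, max_kg = 10000) {
  set.seed(seed)
  comps <- c("water", "ash", "protein", "cellulose",
             "lauric", "myristic", "palmitic", "stearic")
  masses <- stats::runif(length(comps), 0, max_kg)
  names(masses) <- comps
  stream("Larvae feed", masses, phase = "solid-slurry")
}

# random valid proximate composition (percentages renormalizable)
random_proximate <- function(seed) {
  set.seed(seed)
  proximate_composition(
    paste0("random-", seed),
    dry_matter_pct = stats::runif(1, 5, 95),
    ash_pct = stats::runif(1, 1, 20),
    crude_protein_pct = stats::runif(1, 10, 45),
    ndf_pct = stats::runif(1, 1, 25),
    adf_pct = stats::runif(1, 1, 15),
    ether_extract_pct = stats::runif(1, 1, 20),
    organic_matter_pct = stats::runif(1, 50, 95)
  )
}

# random conventional (viable) cash-flow series: one sign change
random_cashflow <- function(seed) {
  set.seed(seed)
  capital <- stats::runif(1, 1e5, 1e8)
  years <- sample(5:30, 1)
  profit <- stats::runif(1, 0.05, 0.5) * capital
  c(-capital, profit * stats::runif(years, 0.5, 1.5))
}

plant_cfg <- read_plant_config()
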