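# Proximate composition of black soldier fly larvae by rearing feed scenario.
# dry_matter is % of wet mass; the remaining rows are % of dry matter.
# Each value is mean and standard deviation. organic_matter and adf overlap
# the other fractions and are carried for reporting only.
scenarios:
  chicken_manure:
    dry_matter: {mean: 80.7, sd: 1.2}
    ash: {mean: 9.3, sd: 1.8}
    organic_matter: {mean: 59.8, sd: 0.4}
    crude_protein: {mean: 41.1, sd: 0.3}
    ndf: {mean: 21.9, sd: 0.6}
    adf: {mean: 12.6, sd: 0.3}
    ether_extract: {mean: 30.1, sd: 0.4}
  kitchen_waste:
    dry_matter: {mean: 87.7, sd: 1.0}
    ash: {mean: 9.6, sd: 1.6}
    organic_matter: {mean: 90.4, sd: 1.6}
    crude_protein: {mean: 33.0, sd: 1.0}
    ndf: {mean: 20.4, sd: 0.6}
    adf: {mean: 13.2, sd: 0.1}
    ether_extract: {mean: 34.3, sd: 0.4}
  spent_grain:
    dry_matter: {mean: 83.1, sd: 1.6}
    ash: {mean: 11.6, sd: 0.5}
    organic_matter: {mean: 88.4, sd: 0.5}
    crude_protein: {mean: 41.3, sd: 0.5}
    ndf: {mean: 28.6, sd: 1.0}
    adf: {mean: 15.0, sd: 0.8}
    ether_extract: {mean: 31.0, sd: 0.4}
  control:
    dry_matter: {mean: 32.7, sd: 5.0}
    ash: {mean: 15.9, sd: 3.1}
    organic_matter: {mean: 84.0, sd: 1.4}
    crude_protein: {mean: 44.7, sd: 3.4}
    ndf: {mean: 10.6, sd: 4.2}
    adf: {mean: 19.0, sd: 2.2}
    ether_extract: {mean: 9.7, sd: 3.3}
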