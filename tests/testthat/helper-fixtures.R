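# Shared fixture builders. Everything is generated in code; no binary data.

# Noiseless observations straight from the generating curve, for
# parameter-recovery oracles.
noiseless_obs <- function(region = "NC", a = 2000, b = 1e-4, n = 20,
                          grain = seq(1000, 9000, length.out = n)) {
  data.frame(
    region = region,
    grain_yield_kg_ha = grain,
    straw_yield_kg_ha = a * exp(b * grain),
    harvest_index = grain / (grain + a * exp(b * grain)),
    stringsAsFactors = FALSE
  )
}

# One fitted model per region from a small synthetic run.
fitted_models <- function(seed = 11, n_obs = 120, noise_cv = 0.05) {
  cfg <- synthetic_config(seed = seed, n_obs_per_region = n_obs,
                          noise_cv = noise_cv)
  stats::setNames(lapply(region_codes(), function(r)
    fit_straw_model(generate_observations(cfg, r), r)), region_codes())
}

# A deliberately mixed city table: ok, zero and missing rows across regions.
mixed_city_table <- function() {
  data.frame(
    city_id = c("c1", "c1", "c2", "c3", "c4"),
    province = c("Henan", "Henan", "Shaanxi", "Jiangsu", "Sichuan"),
    year = c(2011, 2012, 2011, 2011, 2011),
    area_1000ha = c(100, 110, 50, NA, 0),
    grain_yield_kg_ha = c(6000, 6100, 4000, NA, 0),
    stringsAsFactors = FALSE
  )
}

global_shares <- function() disposal_shares(0.55, 0.20, 0.25)
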