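# Independent oracles used across the suite. Each re-derives the target
# quantity by a different route (different published constant fits, numeric
# root-finding, literal rule transcription) from the implementation under
# test.

# Carbonate-system oracle: Lueker et al. (2000) apparent K1/K2 fits, with
# total CO2 recovered by numerically inverting the carbonate-alkalinity
# speciation (uniroot on DIC), instead of the closed-form bicarbonate
# factorisation the package uses.
oracle_carbonate_K <- function(temperature_C, salinity_psu) {
  TK <- temperature_C + 273.15
  S <- salinity_psu
  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * log(TK) -
    0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * log(TK) -
    0.01781 * S + 0.0001122 * S^2
  list(K1 = 10^(-pK1), K2 = 10^(-pK2))
}

oracle_total_co2 <- function(temperature_C, salinity_psu, pH,
                             specific_alkalinity_factor = 0.068) {
  K <- oracle_carbonate_K(temperature_C, salinity_psu)
  ca <- specific_alkalinity_factor * salinity_psu
  h <- 10^(-pH)
  # carbonate alkalinity implied by a trial DIC at this pH
  ca_of_dic <- function(dic) {
    denom <- h^2 + K$K1 * h + K$K1 * K$K2
    hco3 <- dic * K$K1 * h / denom
    co3 <- dic * K$K1 * K$K2 / denom
    hco3 + 2 * co3
  }
  stats::uniroot(function(dic) ca_of_dic(dic) - ca,
                 interval = c(1e-6, 100), tol = 1e-10)$root
}

# Water-mass oracle: literal transcription of the classification boxes as
# nested conditionals, independent of the shipped ruleset table.
oracle_water_mass <- function(t, s) {
  if (s < 34.00 && t > 1) return("SW")
  if (t > 3 && s > 34.9) return("AW")
  if (t > 1 && s > 34.7 && s <= 34.9) return("TAW")
  if (t > 1 && s >= 34.0 && s <= 34.7) return("IW")
  if (t >= -1.5 && t <= 1.0 && s >= 34.3 && s <= 34.8) return("ArW")
  if (t >= -0.5 && t <= 1.0 && s >= 34.3 && s <= 34.85) return("LW")
  "Unclassified"
}

# A minimal well-formed cast table built in code (three levels, one cast).
make_fixture_cast <- function(cast_id = "fix01", fjord = "Hornsund",
                              zone = "Glacier",
                              depth_m = c(0, 3, 7),
                              temp_C = c(4.0, 3.5, 2.0),
                              sal_psu = c(30.3, 32.0, 34.4),
                              pH = 8.1,
                              dpm_light_mean = c(5000, 9000, 1500),
                              dpm_dark_mean = 100,
                              dpm_added = 8 * 2.22e6) {
  tibble::tibble(
    cast_id = cast_id, fjord = fjord, zone = zone, date = "2019-07-15",
    depth_m = depth_m, temp_C = temp_C, sal_psu = sal_psu, pH = pH,
    dpm_light_mean = dpm_light_mean, dpm_dark_mean = dpm_dark_mean,
    dpm_added = dpm_added,
    chl_A665 = 0.05, chl_A750 = 0.005,
    extract_vol_ml = 10, filtered_vol_l = 1, cuvette_cm = 1
  )
}
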