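#' Define a synthetic zone scenario
#'
#' A scenario fixes the statistical and vertical structure of one
#' (fjord, zone) stratum: a logistic halocline/thermocline between drawn
#' surface values and fixed deep values, exponential light attenuation with
#' a turbidity-controlled diffuse attenuation coefficient kd, a Gaussian
#' subsurface chlorophyll maximum over a background, and a saturating
#' (hyperbolic-tangent) photosynthesis-irradiance response
#' Pe(z) = Chl(z) * Pbmax * tanh(alpha * PAR(z) / Pbmax). Bottle activities
#' and extract absorbances are back-computed by inverting the production and
#' chlorophyll equations, with multiplicative mean-one log-normal noise of
#' coefficient `noise_cv` on the measured activities and absorbances.
#'
#' @param fjord,zone Stratum labels (e.g. "Hornsund", "Glacier").
#' @param n_casts Number of casts to generate for the stratum.
#' @param surface_salinity_mean,surface_salinity_sd Between-cast surface
#'   salinity distribution.
#' @param deep_salinity Salinity below the halocline.
#' @param surface_temp_mean,surface_temp_sd Between-cast surface
#'   temperature distribution (degC).
#' @param deep_temp_C Temperature below the thermocline (degC).
#' @param halocline_depth_m,halocline_width_m Logistic transition centre
#'   and width (m); shared by the thermocline.
#' @param kd_per_m Diffuse attenuation coefficient (m-1).
#' @param chl_max_depth_m,chl_max_mgm3,chl_background_mgm3,chl_sigma_m
#'   Gaussian chlorophyll-peak depth (m), peak value, background (mg m-3)
#'   and peak width (m).
#' @param pbmax_mgC_per_mgchl_h Assimilation number (mgC mgChl-1 h-1).
#' @param alpha_pi Initial P-I slope (mgC mgChl-1 h-1 per PAR unit).
#' @param surface_par Surface irradiance (relative PAR units).
#' @param pH Water-column pH (total scale), held uniform.
#' @param noise_cv Coefficient of variation of the measurement noise.
#' @param depths Sampled depth set (m).
#' @param dpm_added Tracer activity per subsample (dpm); default the dpm
#'   equivalent of 8 uCi.
#' @param exposure_hours Incubation duration (h).
#' @param dark_dpm Baseline dark-bottle activity (dpm).
#' @param n_replicates Bottle replicates per treatment.
#' @param extract_vol_ml,filtered_vol_l,cuvette_cm Pigment protocol values.
#' @param chl_coefficient Specific absorption coefficient used when
#'   back-computing absorbances (L g-1 cm-1).
#' @return A list of class `zone_scenario`.
#' @export
zone_scenario <- function(fjord, zone, n_casts = 30,
                          surface_salinity_mean, surface_salinity_sd,
                          deep_salinity,
                          surface_temp_mean, surface_temp_sd,
                          deep_temp_C,
                          halocline_depth_m = 5, halocline_width_m = 1.5,
                          kd_per_m, chl_max_depth_m, chl_max_mgm3,
                          chl_background_mgm3, chl_sigma_m = 4,
                          pbmax_mgC_per_mgchl_h, alpha_pi = 0.05,
                          surface_par = 600, pH = 8.10, noise_cv = 0.1,
                          depths = c(0, 2, 3, 5, 7, 10, 15, 20, 30, 50),
                          dpm_added = 8 * 2.22e6, exposure_hours = 2,
                          dark_dpm = 100, n_replicates = 2,
                          extract_vol_ml = 10, filtered_vol_l = 1,
                          cuvette_cm = 1, chl_coefficient = 83.4) {
  sc <- as.list(environment())
  stopifnot(nzchar(fjord), nzchar(zone), n_casts >= 1,
            kd_per_m > 0, chl_max_depth_m >= 0,
            surface_salinity_sd >= 0, surface_temp_sd >= 0, noise_cv >= 0,
            chl_max_mgm3 > 0, chl_background_mgm3 > 0,
            chl_sigma_m > 0, pbmax_mgC_per_mgchl_h > 0, alpha_pi > 0,
            surface_par > 0, halocline_width_m > 0,
            dpm_added > 0, exposure_hours > 0, n_replicates >= 1)
  if (is.unsorted(depths, strictly = TRUE) || any(depths < 0)) {
    stop("depths must be non-negative and strictly increasing")
  }
  if (chl_max_depth_m > max(depths)) {
    stop("inconsistent scenario: chlorophyll maximum deeper than deepest level")
  }
  structure(sc, class = "zone_scenario")
}

# logistic transition normalised so the surface value is met exactly at 0 m
.logistic_profile <- function(z, surface, deep, centre, width) {
  p0 <- stats::plogis(-centre / width)
  f <- (stats::plogis((z - centre) / width) - p0) / (1 - p0)
  surface + (deep - surface) * f
}

#' True (noise-free) scenario fields at arbitrary depth
#'
#' Closed-form chlorophyll and volumetric production of a scenario,
#' evaluated at any depth — the generator's hidden truth, usable as a
#' high-resolution quadrature target.
#'
#' @param scenario A [zone_scenario()].
#' @param depth_m Depths (m), any resolution.
#' @return A tibble with `depth_m`, `chl_mgm3`, `par_rel`, `pe_mgC_m3_h`.
#' @export
scenario_truth <- function(scenario, depth_m) {
  chl <- scenario$chl_background_mgm3 +
    (scenario$chl_max_mgm3 - scenario$chl_background_mgm3) *
    exp(-(depth_m - scenario$chl_max_depth_m)^2 / (2 * scenario$chl_sigma_m^2))
  par <- scenario$surface_par * exp(-scenario$kd_per_m * depth_m)
  pb <- scenario$pbmax_mgC_per_mgchl_h
  pe <- chl * pb * tanh(scenario$alpha_pi * par / pb)
  tibble::tibble(depth_m = depth_m, chl_mgm3 = chl, par_rel = par,
                 pe_mgC_m3_h = pe)
}

# mean-one log-normal multiplier
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic cast with its hidden truth record
#'
#' Draws surface temperature and salinity for the cast, builds the vertical
#' structure, and back-computes observable bottle activities and pigment
#' absorbances by inverting the production and chlorophyll equations at the
#' cast's own carbonate state, so that the analysis pipeline recovers the
#' true profile exactly when `noise_cv = 0`. Uses the current RNG state.
#'
#' @param scenario A [zone_scenario()].
#' @param cast_id Identifier for the cast.
#' @param date Calendar date string recorded in the table.
#' @return A list with `cast` (one row per level, standard cast-table
#'   columns) and `truth` (non-observational: true Pe at the sampled depths,
#'   surface Pe, depth of maximum Pe, true Pi over 0-30 m at 24 h/day, and
#'   the chlorophyll-maximum depth).
#' @export
generate_cast <- function(scenario, cast_id = "cast01", date = "2019-07-15") {
  z <- scenario$depths
  s0 <- min(max(stats::rnorm(1, scenario$surface_salinity_mean,
                             scenario$surface_salinity_sd), 0.5), 36)
  t0 <- min(max(stats::rnorm(1, scenario$surface_temp_mean,
                             scenario$surface_temp_sd), -2), 15)
  sal <- .logistic_profile(z, s0, scenario$deep_salinity,
                           scenario$halocline_depth_m,
                           scenario$halocline_width_m)
  temp <- .logistic_profile(z, t0, scenario$deep_temp_C,
                            scenario$halocline_depth_m,
                            scenario$halocline_width_m)
  truth <- scenario_truth(scenario, z)
  carb <- total_co2(temp, sal, scenario$pH)

  k2 <- 1 / scenario$exposure_hours
  excess <- truth$pe_mgC_m3_h * scenario$dpm_added /
    (carb$total_co2_mM * composite_constant() * 1 * k2 * 1000)
  nl <- scenario$n_replicates
  light_mean <- dark_mean <- numeric(length(z))
  for (i in seq_along(z)) {
    light_mean[i] <- mean((scenario$dark_dpm + excess[i]) *
                            .lognoise(nl, scenario$noise_cv))
    dark_mean[i] <- mean(scenario$dark_dpm * .lognoise(nl, scenario$noise_cv))
  }

  dA_true <- truth$chl_mgm3 * scenario$chl_coefficient * scenario$cuvette_cm *
    scenario$filtered_vol_l * 1e3 / (1e6 * scenario$extract_vol_ml)
  A750 <- rep(0.005, length(z))
  A665 <- A750 + dA_true * .lognoise(length(z), scenario$noise_cv)

  cast <- tibble::tibble(
    cast_id = cast_id,
    fjord = scenario$fjord,
    zone = scenario$zone,
    date = date,
    exposure_start_utc = "10:00",
    exposure_end_utc = sprintf("%02d:00", 10 + round(scenario$exposure_hours)),
    depth_m = z,
    temp_C = temp,
    sal_psu = sal,
    pH = scenario$pH,
    dpm_light_mean = light_mean,
    dpm_dark_mean = dark_mean,
    dpm_added = scenario$dpm_added,
    chl_A665 = A665,
    chl_A750 = A750,
    extract_vol_ml = scenario$extract_vol_ml,
    filtered_vol_l = scenario$filtered_vol_l,
    cuvette_cm = scenario$cuvette_cm
  )
  pi_true <- stats::integrate(
    function(zz) scenario_truth(scenario, zz)$pe_mgC_m3_h,
    lower = 0, upper = 30, subdivisions = 500L)$value * 24
  list(
    cast = cast,
    truth = list(
      cast_id = cast_id,
      pe_true = truth,
      pe0_true = truth$pe_mgC_m3_h[z == 0][1],
      z_max_pe_true = depth_of_maximum(z, truth$pe_mgC_m3_h),
      pi_true_mgC_m2_day = pi_true,
      chl_max_depth_true = scenario$chl_max_depth_m
    )
  )
}

#' Default six-scenario campaign calibrated to the bundled references
#'
#' One scenario per (fjord, zone), with surface temperature, salinity,
#' surface production and surface chlorophyll calibrated to the published
#' zone summaries ([zone_surface_reference()]): the assimilation number is
#' set to the target surface Pe divided by the target surface chlorophyll,
#' and the chlorophyll background is solved so the Gaussian-peak profile
#' meets the target surface chlorophyll. Vertical structure encodes the
#' zonation the strata exhibit: turbid Glacier zones (kd = 0.8 m-1, shallow
#' halocline, chlorophyll maximum at 7 m, production pushed to the top
#' metres), intermediate Inner zones (kd = 0.35, peak at 10 m) and clear
#' Outer zones (kd = 0.12, peak at 15 m), with deep water masses chosen so
#' classification recovers Local Water under the glaciers, Intermediate
#' Water in the Inner/Outer strata and Atlantic Water in outer
#' Kongsfjorden.
#'
#' @param n_casts Casts per stratum.
#' @param noise_cv Measurement-noise coefficient of variation.
#' @return A list of six [zone_scenario()] objects.
#' @export
default_campaign_scenarios <- function(n_casts = 30, noise_cv = 0.1) {
  ref <- zone_surface_reference()
  get_ref <- function(fj, zn, var, field) {
    ref[[field]][ref$fjord == fj & ref$zone == zn & ref$variable == var]
  }
  structure_by_zone <- list(
    Glacier = list(kd = 0.8, halocline = 3, chl_peak_depth = 7,
                   deep_sal = 34.6, deep_temp = 0.5, chl_sigma = 4),
    Inner = list(kd = 0.35, halocline = 5, chl_peak_depth = 10,
                 deep_sal = 34.5, deep_temp = 1.5, chl_sigma = 4),
    Outer = list(kd = 0.12, halocline = 8, chl_peak_depth = 15,
                 deep_sal = 34.5, deep_temp = 1.5, chl_sigma = 4)
  )
  chl_peaks <- list(
    Hornsund = c(Glacier = 3.0, Inner = 8.61, Outer = 6.5),
    Kongsfjorden = c(Glacier = 1.5, Inner = 2.5, Outer = 3.0)
  )
  scenarios <- list()
  for (fj in c("Hornsund", "Kongsfjorden")) {
    for (zn in c("Glacier", "Inner", "Outer")) {
      st <- structure_by_zone[[zn]]
      if (fj == "Kongsfjorden" && zn == "Outer") {   # Atlantic Water below
        st$deep_sal <- 35.0
        st$deep_temp <- 4.0
      }
      pe0 <- get_ref(fj, zn, "pe0_mgC_m3_h", "mean")
      ca0 <- get_ref(fj, zn, "ca0_mgm3", "mean")
      peak <- chl_peaks[[fj]][[zn]]
      w0 <- exp(-st$chl_peak_depth^2 / (2 * st$chl_sigma^2))
      bg <- (ca0 - w0 * peak) / (1 - w0)   # surface chl meets the target
      stopifnot(bg > 0)
      scenarios[[paste(fj, zn, sep = "_")]] <- zone_scenario(
        fjord = fj, zone = zn, n_casts = n_casts,
        surface_salinity_mean = get_ref(fj, zn, "sal0_psu", "mean"),
        surface_salinity_sd = get_ref(fj, zn, "sal0_psu", "sd"),
        deep_salinity = st$deep_sal,
        surface_temp_mean = get_ref(fj, zn, "t0_C", "mean"),
        surface_temp_sd = get_ref(fj, zn, "t0_C", "sd"),
        deep_temp_C = st$deep_temp,
        halocline_depth_m = st$halocline,
        kd_per_m = st$kd,
        chl_max_depth_m = st$chl_peak_depth,
        chl_max_mgm3 = peak,
        chl_background_mgm3 = bg,
        chl_sigma_m = st$chl_sigma,
        pbmax_mgC_per_mgchl_h = pe0 / ca0,
        noise_cv = noise_cv
      )
    }
  }
  scenarios
}

#' Generate a full synthetic campaign
#'
#' Runs [generate_cast()] for every scenario, with an independent RNG
#' substream per scenario derived deterministically from the master seed, so
#' campaigns are bit-reproducible and per-scenario output is invariant to
#' the presence of other scenarios' draws.
#'
#' @param scenarios List of [zone_scenario()] objects; duplicate
#'   (fjord, zone) pairs are an error.
#' @param seed Master seed (integer).
#' @return A list with `casts` (all levels, standard cast-table columns) and
#'   `truth` (a tibble of per-cast hidden truth: surface Pe, depth of
#'   maximum Pe, Pi, chlorophyll-maximum depth).
#' @export
generate_campaign <- function(scenarios = default_campaign_scenarios(),
                              seed = 1) {
  stopifnot(length(scenarios) >= 1L)
  keys <- vapply(scenarios, function(s) paste(s$fjord, s$zone), character(1))
  if (anyDuplicated(keys)) stop("duplicate (fjord, zone) scenarios")
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, length(scenarios))
  casts <- list()
  truths <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    set.seed(subseeds[i])
    for (j in seq_len(sc$n_casts)) {
      id <- sprintf("%s_%s_%02d", sc$fjord, sc$zone, j)
      g <- generate_cast(sc, cast_id = id)
      casts[[id]] <- g$cast
      truths[[id]] <- tibble::tibble(
        cast_id = id, fjord = sc$fjord, zone = sc$zone,
        pe0_true = g$truth$pe0_true,
        z_max_pe_true = g$truth$z_max_pe_true,
        pi_true_mgC_m2_day = g$truth$pi_true_mgC_m2_day,
        chl_max_depth_true = g$truth$chl_max_depth_true
      )
    }
  }
  list(casts = dplyr::bind_rows(casts), truth = dplyr::bind_rows(truths))
}
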