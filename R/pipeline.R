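.parse_clock_hours <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) + as.numeric(p[2]) / 60,
         numeric(1))
}

.exposure_hours <- function(casts, default = 2) {
  if (all(c("exposure_start_utc", "exposure_end_utc") %in% names(casts))) {
    h <- .parse_clock_hours(casts$exposure_end_utc) -
      .parse_clock_hours(casts$exposure_start_utc)
    if (any(h <= 0)) stop("exposure end must be after exposure start")
    h
  } else {
    rep(default, nrow(casts))
  }
}

#' Per-level processing: chlorophyll, total CO2, production, water mass
#'
#' Runs the level-wise stages of the workflow on a validated cast table:
#' spectrophotometric chlorophyll-a from the extract absorbances, total
#' inorganic carbon from (T, S, pH), volumetric production Pe from the
#' bottle activities, and water-mass classification from (T, S). The time
#' factor k2 is derived from the exposure window columns when present,
#' otherwise from `exposure_hours`.
#'
#' @param casts Cast table (validated with [validate_casts()]).
#' @param k1 Subsampling correction.
#' @param exposure_hours Fallback incubation duration (h) when the table
#'   carries no exposure window.
#' @param specific_alkalinity_factor,constant_set Carbonate-system options,
#'   see [total_co2()].
#' @param solvent,chl_coefficient Pigment options, see [chlorophyll_a()].
#' @param clamp_negative Clamp negative production to zero (flagged)?
#' @param rules Water-mass ruleset.
#' @return The table with added columns `chl_mgm3`, `total_co2_mM`,
#'   `pe_mgC_m3_h`, `pe_raw_mgC_m3_h`, `pe_clamped`, `water_mass`.
#' @export
process_casts <- function(casts, k1 = 1, exposure_hours = 2,
                          specific_alkalinity_factor = 0.068,
                          constant_set = "dickson_millero_1987",
                          solvent = "ethanol96", chl_coefficient = NULL,
                          clamp_negative = TRUE,
                          rules = default_watermass_rules()) {
  casts <- validate_casts(casts)
  chl <- chlorophyll_a(casts$chl_A665, casts$chl_A750,
                       extract_vol_ml = casts$extract_vol_ml,
                       filtered_vol_l = casts$filtered_vol_l,
                       cuvette_cm = casts$cuvette_cm,
                       solvent = solvent, coefficient = chl_coefficient)
  carb <- total_co2(casts$temp_C, casts$sal_psu, casts$pH,
                    specific_alkalinity_factor = specific_alkalinity_factor,
                    constant_set = constant_set)
  k2 <- 1 / .exposure_hours(casts, default = exposure_hours)
  pe <- pe_volumetric(casts$dpm_light_mean - casts$dpm_dark_mean,
                      carb$total_co2_mM, casts$dpm_added,
                      k1 = k1, k2 = k2, clamp_negative = clamp_negative)
  out <- casts
  out$chl_mgm3 <- as.numeric(chl)
  out$total_co2_mM <- carb$total_co2_mM
  out$pe_mgC_m3_h <- pe$pe_mgC_m3_h
  out$pe_raw_mgC_m3_h <- pe$pe_raw_mgC_m3_h
  out$pe_clamped <- pe$pe_clamped
  out$water_mass <- classify_water_mass(casts$temp_C, casts$sal_psu, rules)
  out
}

#' Per-cast production profile statistics
#'
#' Surface production Pe(0) (with substitution flag when 0 m was not
#' sampled), depth of the production maximum, and depth-integrated daily
#' production Pi for every cast of a processed level table.
#'
#' @param levels Output of [process_casts()].
#' @param z_bottom,day_factor,below_deepest Integration options, see
#'   [integrate_pi()].
#' @return A tibble, one row per cast: cast_id, fjord, zone,
#'   `pe0_mgC_m3_h`, `pe0_substituted`, `z_max_pe_m`, `pi_mgC_m2_day`,
#'   `chl_max_depth_m`.
#' @export
cast_profiles <- function(levels, z_bottom = 30, day_factor = 24,
                          below_deepest = "extend_zero") {
  stopifnot(all(c("cast_id", "depth_m", "pe_mgC_m3_h") %in% names(levels)))
  per_cast <- split(levels, levels$cast_id)
  rows <- lapply(per_cast, function(cc) {
    cc <- cc[order(cc$depth_m), ]
    sv <- surface_value(cc$depth_m, cc$pe_mgC_m3_h)
    tibble::tibble(
      cast_id = cc$cast_id[1],
      fjord = cc$fjord[1],
      zone = cc$zone[1],
      pe0_mgC_m3_h = sv$value,
      pe0_substituted = sv$substituted,
      z_max_pe_m = depth_of_maximum(cc$depth_m, cc$pe_mgC_m3_h),
      pi_mgC_m2_day = integrate_pi(cc$depth_m, cc$pe_mgC_m3_h,
                                   z_bottom = z_bottom,
                                   day_factor = day_factor,
                                   below_deepest = below_deepest)$pi_mgC_m2_day,
      chl_max_depth_m = if ("chl_mgm3" %in% names(cc))
        depth_of_maximum(cc$depth_m, cc$chl_mgm3) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline on a cast table
#'
#' Orchestrates all stages — chlorophyll, carbonate system, production,
#' water-mass classification, depth integration, zone summaries, mean Pe per
#' water mass, and the gated between-zone comparison of Pi within each fjord
#' (run when every zone has at least three casts). Outputs carry a
#' provenance attribute recording the package version and option values.
#'
#' @param casts Cast table.
#' @param ... Level-stage options forwarded to [process_casts()].
#' @param z_bottom,day_factor Integration options.
#' @param alpha Significance level of the zone comparisons.
#' @return A list: `levels`, `profiles`, `zone_pe0`, `zone_pi`,
#'   `watermass_pe` (mean, SD, standard error of Pe per fjord and water
#'   mass), `comparisons` (per fjord, or NULL when too sparse).
#' @export
run_pipeline <- function(casts, ..., z_bottom = 30, day_factor = 24,
                         alpha = 0.05) {
  levels <- process_casts(casts, ...)
  profiles <- cast_profiles(levels, z_bottom = z_bottom,
                            day_factor = day_factor)
  zone_sum <- function(var) {
    dplyr::bind_rows(lapply(
      split(profiles, list(profiles$fjord, profiles$zone), drop = TRUE),
      function(g) summarize_zone(g[[var]], fjord = g$fjord[1],
                                 zone = g$zone[1], variable = var)))
  }
  wm <- levels |>
    dplyr::group_by(.data$fjord, .data$water_mass) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pe_mgC_m3_h = mean(.data$pe_mgC_m3_h),
      sd_pe = stats::sd(.data$pe_mgC_m3_h),
      se_pe = stats::sd(.data$pe_mgC_m3_h) / sqrt(dplyr::n()),
      .groups = "drop")
  comparisons <- lapply(split(profiles, profiles$fjord), function(pf) {
    groups <- split(pf$pi_mgC_m2_day, pf$zone)
    if (length(groups) < 2L || any(vapply(groups, length, 1L) < 3L)) {
      return(NULL)
    }
    compare_zones(groups, alpha = alpha)
  })
  out <- list(levels = levels, profiles = profiles,
              zone_pe0 = zone_sum("pe0_mgC_m3_h"),
              zone_pi = zone_sum("pi_mgC_m2_day"),
              watermass_pe = wm,
              comparisons = comparisons)
  attr(out, "provenance") <- list(
    package_version = as.character(utils::packageVersion("fjordpp")),
    z_bottom = z_bottom, day_factor = day_factor, alpha = alpha,
    options = list(...))
  out
}
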