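#' Correction factors of the carbon-14 production equation
#'
#' The volumetric production equation multiplies the mean light-minus-dark
#' activity by the atomic weight of carbon (12), an isotope-discrimination
#' correction (1.05: uptake of the heavy tracer is 5% slower than that of
#' natural carbon-12) and a respiration correction (1.06: 6% of the organic
#' matter produced during the incubation is respired at optimal
#' photosynthesis). Their product is the composite constant 13.356.
#'
#' @param c_atomic Atomic weight of carbon.
#' @param f_discrimination Isotope-discrimination correction.
#' @param f_respiration Respiration correction.
#' @return A list of class `production_constants`.
#' @export
production_constants <- function(c_atomic = 12,
                                 f_discrimination = 1.05,
                                 f_respiration = 1.06) {
  stopifnot(c_atomic > 0, f_discrimination > 0, f_respiration > 0)
  structure(
    list(c_atomic = c_atomic,
         f_discrimination = f_discrimination,
         f_respiration = f_respiration),
    class = "production_constants"
  )
}

#' Composite constant of the production equation
#'
#' @param constants A [production_constants()] object.
#' @return The product of the three factors, rounded to three decimals
#'   (13.356 at the defaults).
#' @export
#' @examples
#' composite_constant()  # 13.356
composite_constant <- function(constants = production_constants()) {
  round(constants$c_atomic * constants$f_discrimination * constants$f_respiration, 3)
}

#' Mean light-minus-dark bottle activity
#'
#' With equal replicate counts, the mean of pairwise (light - dark)
#' differences; with unequal counts, the difference of the replicate means.
#' The two conventions have identical expectation; the choice is fixed for
#' determinism. The result may be negative (dark exceeding light is
#' measurement noise) and is handled downstream.
#'
#' @param dpm_light,dpm_dark Replicate bottle activities (dpm).
#' @return Mean excess activity (dpm).
#' @export
#' @examples
#' mean_dpm_excess(c(1000, 1200), c(100, 100))  # 1000
mean_dpm_excess <- function(dpm_light, dpm_dark) {
  if (length(dpm_light) == 0L || length(dpm_dark) == 0L) {
    stop("bottle replicate list is empty")
  }
  stopifnot(all(dpm_light >= 0), all(dpm_dark >= 0))
  if (length(dpm_light) == length(dpm_dark)) {
    mean(dpm_light - dpm_dark)
  } else {
    mean(dpm_light) - mean(dpm_dark)
  }
}

#' Convert a tracer activity from microcuries to dpm
#'
#' 1 uCi = 2.22e6 disintegrations per minute (standard definition).
#'
#' @param uCi Activity in microcuries.
#' @return Activity in dpm.
#' @export
uCi_to_dpm <- function(uCi) uCi * 2.22e6

# Apparent dissociation constants of carbonic acid in seawater at 1 atm.
# T in Kelvin, practical salinity; constants on the seawater pH scale.
.carbonate_K <- function(temperature_C, salinity_psu,
                         constant_set = "dickson_millero_1987") {
  TK <- temperature_C + 273.15
  if (constant_set == "dickson_millero_1987") {
    pK1 <- 3670.7 / TK - 62.008 + 9.7944 * log(TK) -
      0.0118 * salinity_psu + 0.000116 * salinity_psu^2
    pK2 <- 1394.7 / TK + 4.777 -
      0.0184 * salinity_psu + 0.000118 * salinity_psu^2
  } else {
    stop("unknown carbonate constant set: ", constant_set)
  }
  list(K1 = 10^(-pK1), K2 = 10^(-pK2))
}

#' Total inorganic carbon from temperature, salinity and pH
#'
#' Carbonate alkalinity is estimated from salinity via a specific-alkalinity
#' factor (default 0.068 meq per litre per salinity unit), then partitioned
#' into bicarbonate and carbonate with apparent dissociation constants
#' evaluated at the in-situ temperature and salinity, and summed with
#' dissolved CO2 to total CO2 in mM per dm3:
#' with h = 10^(-pH), HCO3 = CA / (1 + 2 K2 / h) and
#' totalCO2 = HCO3 (h/K1 + 1 + K2/h).
#'
#' The constant set and alkalinity factor are configuration, recorded in the
#' output, because field campaigns rarely print them.
#'
#' @param temperature_C,salinity_psu,pH In-situ values (vectorised). pH must
#'   lie in \[6, 9\]; salinity must be positive (alkalinity is estimated from
#'   salinity and is undefined at S = 0).
#' @param specific_alkalinity_factor meq L-1 per salinity unit.
#' @param constant_set Named apparent-constant fit; currently
#'   `"dickson_millero_1987"`.
#' @return A tibble with the inputs, `carbonate_alkalinity_meq_l`, `K1_app`,
#'   `K2_app`, `total_co2_mM` and `constant_set`.
#' @export
#' @examples
#' total_co2(5, 34, 8.1)
total_co2 <- function(temperature_C, salinity_psu, pH,
                      specific_alkalinity_factor = 0.068,
                      constant_set = "dickson_millero_1987") {
  n <- max(length(temperature_C), length(salinity_psu), length(pH))
  temperature_C <- rep_len(temperature_C, n)
  salinity_psu <- rep_len(salinity_psu, n)
  pH <- rep_len(pH, n)
  if (any(!is.finite(temperature_C) | !is.finite(salinity_psu) | !is.finite(pH))) {
    stop("non-finite carbonate-system input")
  }
  if (any(salinity_psu <= 0)) stop("alkalinity undefined from salinity (S <= 0)")
  if (any(pH < 6 | pH > 9)) stop("pH out of carbonate-routine range [6, 9]")
  K <- .carbonate_K(temperature_C, salinity_psu, constant_set)
  ca <- specific_alkalinity_factor * salinity_psu       # meq L-1
  h <- 10^(-pH)
  hco3 <- ca / (1 + 2 * K$K2 / h)                       # mM (meq ~ mmol for HCO3)
  dic <- hco3 * (h / K$K1 + 1 + K$K2 / h)
  tibble::tibble(
    temperature_C = temperature_C,
    salinity_psu = salinity_psu,
    pH = pH,
    carbonate_alkalinity_meq_l = ca,
    K1_app = K$K1,
    K2_app = K$K2,
    total_co2_mM = dic,
    constant_set = constant_set
  )
}

#' Volumetric primary production from mean excess activity (vectorised core)
#'
#' Pe = mean_excess * totalCO2 * 13.356 * k1 * k2 * k3 / dpm_added, in
#' mgC m-3 h-1. `k2` converts the per-incubation uptake to an hourly rate
#' (0.5 for a two-hour exposure); `k3 = 1000` converts mgC dm-3 to mgC m-3;
#' `k1` corrects for subsampling. Negative rates (dark bottle exceeding
#' light) are clamped to zero and flagged, keeping the raw value.
#'
#' @param mean_excess_dpm Mean light-minus-dark activity (dpm).
#' @param total_co2_mM Total inorganic carbon (mM dm-3).
#' @param dpm_added Activity of the inoculated tracer (dpm); must be > 0.
#' @param k1,k2,k3 Subsampling, time and dimension factors.
#' @param composite The composite correction constant.
#' @param clamp_negative Clamp negative rates to zero (flagged)?
#' @return A tibble with `pe_mgC_m3_h`, `pe_raw_mgC_m3_h`, `pe_clamped`.
#' @export
pe_volumetric <- function(mean_excess_dpm, total_co2_mM, dpm_added,
                          k1 = 1, k2 = 0.5, k3 = 1000,
                          composite = composite_constant(),
                          clamp_negative = TRUE) {
  if (any(dpm_added <= 0)) stop("dpm_added must be positive")
  stopifnot(all(k1 > 0), all(k2 > 0), all(k3 > 0))
  if (any(!is.finite(total_co2_mM))) stop("missing carbonate state")
  raw <- mean_excess_dpm * total_co2_mM * composite * k1 * k2 * k3 / dpm_added
  clamped <- clamp_negative & raw < 0
  tibble::tibble(
    pe_mgC_m3_h = ifelse(clamped, 0, raw),
    pe_raw_mgC_m3_h = raw,
    pe_clamped = clamped
  )
}

#' Volumetric primary production at one depth from bottle replicates
#'
#' Convenience wrapper over [mean_dpm_excess()] and [pe_volumetric()] for a
#' single incubation level. The time factor defaults to `1/exposure_hours`,
#' so a two-hour exposure gives k2 = 0.5.
#'
#' @param dpm_light,dpm_dark Replicate bottle activities (dpm).
#' @param dpm_added Tracer activity; interpreted per `dpm_added_unit`.
#' @param total_co2_mM Total inorganic carbon (mM dm-3) at the level.
#' @param exposure_hours Incubation duration (h).
#' @param k1 Subsampling correction (dimensionless).
#' @param k2 Time factor; default `1/exposure_hours`.
#' @param k3 Dimension factor (default 1000, mgC dm-3 to mgC m-3).
#' @param constants A [production_constants()] object.
#' @param dpm_added_unit `"dpm"` or `"uCi"` (converted at 2.22e6 dpm/uCi).
#' @param clamp_negative Clamp negative rates to zero (flagged)?
#' @return A list with `pe_mgC_m3_h`, `pe_raw_mgC_m3_h`, `pe_clamped`,
#'   `mean_excess_dpm` and the factors used.
#' @export
#' @examples
#' compute_pe(c(1000), c(0), dpm_added = 8 * 2.22e6, total_co2_mM = 2,
#'            exposure_hours = 2)
compute_pe <- function(dpm_light, dpm_dark, dpm_added, total_co2_mM,
                       exposure_hours = 2, k1 = 1, k2 = NULL, k3 = 1000,
                       constants = production_constants(),
                       dpm_added_unit = c("dpm", "uCi"),
                       clamp_negative = TRUE) {
  dpm_added_unit <- match.arg(dpm_added_unit)
  if (dpm_added_unit == "uCi") dpm_added <- uCi_to_dpm(dpm_added)
  if (is.null(k2)) {
    stopifnot(exposure_hours > 0)
    k2 <- 1 / exposure_hours
  }
  excess <- mean_dpm_excess(dpm_light, dpm_dark)
  pe <- pe_volumetric(excess, total_co2_mM, dpm_added,
                      k1 = k1, k2 = k2, k3 = k3,
                      composite = composite_constant(constants),
                      clamp_negative = clamp_negative)
  list(
    pe_mgC_m3_h = pe$pe_mgC_m3_h,
    pe_raw_mgC_m3_h = pe$pe_raw_mgC_m3_h,
    pe_clamped = pe$pe_clamped,
    mean_excess_dpm = excess,
    k1 = k1, k2 = k2, k3 = k3
  )
}
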