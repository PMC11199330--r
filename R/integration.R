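#' Depth-integrated daily primary production
#'
#' Trapezoidal integration of a volumetric production profile Pe(z)
#' (mgC m-3 h-1) over \[z_top, z_bottom\] (default 0-30 m), converted to a
#' daily areal rate Pi (mgC m-2 day-1) with a configurable hours-per-day
#' factor.
#'
#' Boundary handling: a missing surface sample is filled by constant
#' extension of the shallowest value up to `z_top`; samples straddling
#' `z_bottom` are linearly interpolated at the boundary; when the deepest
#' sample lies above `z_bottom` the gap is handled per `below_deepest`
#' (`"extend_zero"`, the default, counts no production below the deepest
#' sample — conservative where deep light is extinguished;
#' `"extend_constant"` holds the deepest value to `z_bottom`; `"truncate"`
#' stops the integral at the deepest sample, numerically identical to
#' `"extend_zero"` but semantically an integral over a shorter column).
#'
#' The day factor is the single largest unstated scale in hourly-to-daily
#' conversion and is therefore explicit configuration: 24 h/day assumes the
#' polar day of high-Arctic midsummer; 12 h/day (a daytime exposure window)
#' is the documented alternative.
#'
#' @param depth_m Sampled depths (m), positive down.
#' @param pe Volumetric production at those depths (mgC m-3 h-1),
#'   non-negative.
#' @param z_top,z_bottom Integration bounds (m).
#' @param day_factor Hours of production per day (h day-1), in (0, 24].
#' @param below_deepest Gap policy below the deepest sample (see Details).
#' @return A list with `pi_mgC_m2_day`, the hourly areal rate
#'   `pi_mgC_m2_h`, and the options used.
#' @export
#' @examples
#' integrate_pi(seq(0, 30, 5), rep(1, 7))  # 720 mgC m-2 day-1
integrate_pi <- function(depth_m, pe, z_top = 0, z_bottom = 30,
                         day_factor = 24,
                         below_deepest = c("extend_zero", "extend_constant",
                                           "truncate")) {
  below_deepest <- match.arg(below_deepest)
  stopifnot(length(depth_m) == length(pe), z_bottom > z_top,
            day_factor > 0, day_factor <= 24)
  ok <- is.finite(depth_m) & is.finite(pe)
  depth_m <- depth_m[ok]; pe <- pe[ok]
  if (any(pe < 0)) stop("Pe must be non-negative (clamp upstream)")
  o <- order(depth_m)
  depth_m <- depth_m[o]; pe <- pe[o]

  # clip to the integration window, interpolating at a straddled bottom
  if (any(depth_m > z_bottom) && any(depth_m <= z_bottom)) {
    pe_bot <- stats::approx(depth_m, pe, xout = z_bottom, ties = mean)$y
    keep <- depth_m < z_bottom
    depth_m <- c(depth_m[keep], z_bottom)
    pe <- c(pe[keep], pe_bot)
  }
  keep <- depth_m >= z_top & depth_m <= z_bottom
  depth_m <- depth_m[keep]; pe <- pe[keep]
  if (length(depth_m) < 2L) stop("profile too sparse to integrate")

  if (depth_m[1L] > z_top) {            # constant extension to the surface
    depth_m <- c(z_top, depth_m)
    pe <- c(pe[1L], pe)
  }
  if (max(depth_m) < z_bottom && below_deepest == "extend_constant") {
    depth_m <- c(depth_m, z_bottom)
    pe <- c(pe, pe[length(pe)])
  }
  # extend_zero: no area below the deepest sample, same sum as truncate

  hourly <- pracma::trapz(depth_m, pe)
  list(
    pi_mgC_m2_day = hourly * day_factor,
    pi_mgC_m2_h = hourly,
    z_top = z_top, z_bottom = z_bottom,
    day_factor = day_factor, below_deepest = below_deepest
  )
}
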