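#' Chlorophyll-a concentration from extract absorbances
#'
#' Monochromatic spectrophotometric determination: the turbidity-corrected
#' absorbance (A665 - A750) of the pigment extract is converted to
#' chlorophyll-a in the filtered seawater,
#'
#'   Ca = 1e6 (A665 - A750) v / (a * l * V * 1e3)  \[mg m-3\]
#'
#' with extract volume v (mL), filtered volume V (L), cuvette path l (cm) and
#' specific absorption coefficient a (L g-1 cm-1). The coefficient defaults
#' by solvent (96% ethanol 83.4, 90% acetone 87.67) and is configurable: the
#' extraction solvent determines which published coefficient applies. A
#' negative corrected absorbance is clamped to zero and flagged.
#'
#' @param A665,A750 Extract absorbances at 665 nm and 750 nm (turbidity
#'   blank). Vectorised.
#' @param extract_vol_ml Extract volume (mL).
#' @param filtered_vol_l Filtered seawater volume (L); must be > 0.
#' @param cuvette_cm Cuvette path length (cm).
#' @param solvent `"ethanol96"` or `"acetone90"`; selects the default
#'   coefficient.
#' @param coefficient Specific absorption coefficient (L g-1 cm-1);
#'   overrides the solvent default when given.
#' @return Numeric vector of chlorophyll-a (mg m-3) with a logical
#'   `clamped` attribute marking samples whose corrected absorbance was
#'   negative.
#' @export
#' @examples
#' chlorophyll_a(0.100, 0.005, extract_vol_ml = 10, filtered_vol_l = 1,
#'               cuvette_cm = 1)  # ~11.39 mg m-3
chlorophyll_a <- function(A665, A750, extract_vol_ml, filtered_vol_l,
                          cuvette_cm = 1,
                          solvent = c("ethanol96", "acetone90"),
                          coefficient = NULL) {
  solvent <- match.arg(solvent)
  if (is.null(coefficient)) {
    coefficient <- c(ethanol96 = 83.4, acetone90 = 87.67)[[solvent]]
  }
  stopifnot(coefficient > 0)
  if (any(filtered_vol_l <= 0)) stop("filtered volume must be positive")
  if (any(extract_vol_ml <= 0)) stop("extract volume must be positive")
  if (any(cuvette_cm <= 0)) stop("cuvette path length must be positive")
  if (any(A665 < 0 | A750 < 0)) stop("absorbances must be non-negative")
  dA <- A665 - A750
  clamped <- dA < 0
  dA[clamped] <- 0
  ca <- 1e6 * dA * extract_vol_ml / (coefficient * cuvette_cm * filtered_vol_l * 1e3)
  attr(ca, "clamped") <- clamped
  ca
}
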