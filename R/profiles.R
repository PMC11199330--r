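#' Surface value of a vertical profile
#'
#' Extracts the value at 0 m from an ordered (depth, value) series. When the
#' surface itself was not sampled the shallowest sample is substituted and
#' flagged; "surface" always means the 0 m sample when present, never an
#' interpolation.
#'
#' @param depth_m Numeric vector of depths (m, positive down), sorted
#'   ascending.
#' @param value Numeric vector of the profiled variable, same length.
#' @return A list with `value`, `depth_m` (depth actually used) and
#'   `substituted` (`TRUE` when the shallowest sample stood in for 0 m).
#' @export
#' @examples
#' surface_value(c(0, 3, 7), c(2.18, 5.0, 0.4))
#' surface_value(c(1, 5), c(4.0, 1.0))  # substituted
surface_value <- function(depth_m, value) {
  if (length(depth_m) == 0L) stop("no levels")
  stopifnot(length(depth_m) == length(value))
  if (is.unsorted(depth_m, strictly = TRUE)) {
    o <- order(depth_m)
    depth_m <- depth_m[o]
    value <- value[o]
  }
  list(
    value = value[[1L]],
    depth_m = depth_m[[1L]],
    substituted = depth_m[[1L]] > 0
  )
}

#' Depth of the profile maximum
#'
#' Depth at which the largest value of a profile occurs. Ties are broken by
#' the shallowest tied depth, a deterministic convention that is conservative
#' in light-limited water columns.
#'
#' @inheritParams surface_value
#' @return The depth (m) of the maximum; always one of the sampled depths.
#' @export
#' @examples
#' depth_of_maximum(c(0, 3, 7), c(1, 9, 2))  # 3
depth_of_maximum <- function(depth_m, value) {
  if (length(depth_m) == 0L) stop("no levels")
  stopifnot(length(depth_m) == length(value))
  keep <- is.finite(value)
  if (!any(keep)) stop("all profile values missing")
  depth_m <- depth_m[keep]
  value <- value[keep]
  o <- order(depth_m)
  depth_m <- depth_m[o]
  value <- value[o]
  depth_m[[which.max(value)]]
}

#' Median/min-max envelope of a set of profiles on a common depth grid
#'
#' Each cast is linearly interpolated onto the grid (no extrapolation beyond
#' its sampled span); at every grid depth the median, minimum and maximum are
#' taken over the casts that span it, with the contributing count reported.
#'
#' @param profiles A data frame with one row per sampled level, containing an
#'   identifier column, a depth column and a value column.
#' @param grid Numeric vector of target depths (m), strictly increasing.
#' @param value_col Name of the value column.
#' @param depth_col,id_col Names of the depth and cast-identifier columns.
#' @return A tibble with columns `depth_m`, `median`, `min`, `max`,
#'   `n_casts`.
#' @export
profile_envelope <- function(profiles, grid, value_col,
                             depth_col = "depth_m", id_col = "cast_id") {
  if (nrow(profiles) == 0L) stop("empty cast list")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  for (col in c(id_col, depth_col, value_col)) {
    if (!col %in% names(profiles)) stop("missing column: ", col)
  }
  split_casts <- split(profiles, profiles[[id_col]])
  mat <- vapply(split_casts, function(cc) {
    d <- cc[[depth_col]]
    v <- cc[[value_col]]
    ok <- is.finite(d) & is.finite(v)
    d <- d[ok]; v <- v[ok]
    if (length(d) < 2L) return(rep(NA_real_, length(grid)))
    stats::approx(d, v, xout = grid, method = "linear", rule = 1, ties = mean)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  tibble::tibble(
    depth_m = grid,
    median = apply(mat, 1L, stats::median, na.rm = TRUE),
    min = apply(mat, 1L, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
    max = apply(mat, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    n_casts = apply(mat, 1L, function(x) sum(!is.na(x)))
  )
}
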