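#' Standard cast-table schema
#'
#' The canonical interchange format is a comma-separated table, one row per
#' sampled level, UTF-8, decimal point, with a mandatory header.
#'
#' @return Character vector of mandatory column names.
#' @export
cast_table_columns <- function() {
  c("cast_id", "fjord", "zone", "date", "depth_m", "temp_C", "sal_psu",
    "pH", "dpm_light_mean", "dpm_dark_mean", "dpm_added",
    "chl_A665", "chl_A750", "extract_vol_ml", "filtered_vol_l",
    "cuvette_cm")
}

.numeric_cast_columns <- function() {
  setdiff(cast_table_columns(), c("cast_id", "fjord", "zone", "date"))
}

#' Validate a cast table against the level invariants
#'
#' Checks mandatory columns, numeric types, physical ranges (-2 <= T <= 15,
#' 0 <= S <= 36, 6 <= pH <= 9, non-negative activities and depths) and
#' per-cast strictly increasing depths. Errors name the offending column and
#' rows.
#'
#' @param casts A cast-table data frame.
#' @return The table, invisibly, sorted by cast and depth.
#' @export
validate_casts <- function(casts) {
  missing <- setdiff(cast_table_columns(), names(casts))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  for (col in .numeric_cast_columns()) {
    if (!is.numeric(casts[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(casts[[col]]))) &
                     !is.na(casts[[col]]))
      stop("non-numeric value in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  check_range <- function(col, lo, hi) {
    x <- casts[[col]]
    bad <- which(is.finite(x) & (x < lo | x > hi))
    if (length(bad)) {
      stop("column '", col, "' outside [", lo, ", ", hi, "] at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (cast ", casts$cast_id[bad[1L]], ")")
    }
  }
  check_range("temp_C", -2, 15)
  check_range("sal_psu", 0, 36)
  check_range("pH", 6, 9)
  check_range("depth_m", 0, Inf)
  for (col in c("dpm_light_mean", "dpm_dark_mean", "chl_A665", "chl_A750")) {
    check_range(col, 0, Inf)
  }
  casts <- casts[order(casts$cast_id, casts$depth_m), , drop = FALSE]
  dup <- unlist(lapply(split(casts$depth_m, casts$cast_id),
                       function(d) anyDuplicated(d) > 0L))
  if (any(dup)) {
    stop("duplicate depths within cast(s): ",
         paste(names(dup)[dup], collapse = ", "))
  }
  invisible(tibble::as_tibble(casts))
}

#' Read a cast table from delimited text
#'
#' @param path Path to a comma-separated cast table (see
#'   [cast_table_columns()]).
#' @return A validated tibble, sorted by cast and depth.
#' @export
read_casts <- function(path) {
  if (!file.exists(path)) stop("cast table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_casts(raw)
  tibble::as_tibble(raw[order(raw$cast_id, raw$depth_m), , drop = FALSE])
}

#' Write a cast table as delimited text
#'
#' @param casts Cast table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_casts <- function(casts, path) {
  utils::write.csv(casts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
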