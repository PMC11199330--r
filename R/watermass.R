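#' Water-mass classification ruleset
#'
#' The fjord water-mass taxonomy is a set of rectangular boxes in
#' temperature-salinity space evaluated in priority order. Surface water
#' (SW) is defined exactly as salinity below 34.00 with temperature above
#' 1 degC (strict inequalities) and takes top priority so no other box can
#' shadow it. The remaining boxes (AW Atlantic Water, TAW Transformed
#' Atlantic Water, IW Intermediate Water, ArW Arctic Water, LW Local Water)
#' follow the Cottier-type fjord classification; their boundaries are
#' configuration defaults shipped as an editable table, since the fjord
#' literature revises them.
#'
#' @param path Path to a ruleset CSV (columns: label, t_min, t_max, s_min,
#'   s_max, t_min_incl, t_max_incl, s_min_incl, s_max_incl, priority).
#' @return A tibble of rules ordered by priority.
#' @export
read_watermass_rules <- function(path) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("label", "t_min", "t_max", "s_min", "s_max",
              "t_min_incl", "t_max_incl", "s_min_incl", "s_max_incl",
              "priority")
  missing <- setdiff(needed, names(rules))
  if (length(missing)) stop("ruleset missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(rules$priority)) stop("rule priorities must be distinct")
  stopifnot(all(rules$t_min < rules$t_max), all(rules$s_min < rules$s_max))
  tibble::as_tibble(rules[order(rules$priority), ])
}

#' @rdname read_watermass_rules
#' @export
default_watermass_rules <- function() {
  read_watermass_rules(system.file("extdata", "watermass_rules.csv",
                                   package = "fjordpp", mustWork = TRUE))
}

.rule_matches <- function(rule, t, s) {
  tlo <- if (rule$t_min_incl) t >= rule$t_min else t > rule$t_min
  thi <- if (rule$t_max_incl) t <= rule$t_max else t < rule$t_max
  slo <- if (rule$s_min_incl) s >= rule$s_min else s > rule$s_min
  shi <- if (rule$s_max_incl) s <= rule$s_max else s < rule$s_max
  tlo & thi & slo & shi
}

#' Classify temperature-salinity observations into water masses
#'
#' Each observation receives the label of the first matching rule in
#' priority order, or `"Unclassified"` when no box matches; every finite
#' (T, S) pair therefore receives exactly one label.
#'
#' @param temperature_C,salinity_psu In-situ values (vectorised).
#' @param rules A ruleset from [default_watermass_rules()] or
#'   [read_watermass_rules()].
#' @return Character vector of labels.
#' @export
#' @examples
#' classify_water_mass(4.0, 30.0)  # "SW"
classify_water_mass <- function(temperature_C, salinity_psu,
                                rules = default_watermass_rules()) {
  n <- max(length(temperature_C), length(salinity_psu))
  t <- rep_len(temperature_C, n)
  s <- rep_len(salinity_psu, n)
  if (any(!is.finite(t) | !is.finite(s))) stop("non-finite temperature or salinity")
  out <- rep("Unclassified", n)
  open <- rep(TRUE, n)
  for (i in seq_len(nrow(rules))) {
    hit <- open & .rule_matches(rules[i, ], t, s)
    out[hit] <- rules$label[i]
    open <- open & !hit
  }
  out
}

#' Classify every level of a cast and inventory the labels present
#'
#' @param cast A cast-table data frame (one row per level) with `temp_C` and
#'   `sal_psu` columns.
#' @param rules Ruleset, as for [classify_water_mass()].
#' @return A list with `labels` (per level, cast order) and `inventory`
#'   (named integer vector of level counts per label present).
#' @export
classify_cast <- function(cast, rules = default_watermass_rules()) {
  stopifnot(all(c("temp_C", "sal_psu") %in% names(cast)))
  labels <- classify_water_mass(cast$temp_C, cast$sal_psu, rules)
  counts <- table(labels)
  list(labels = labels,
       inventory = stats::setNames(as.integer(counts), names(counts)))
}
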