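#' Published campaign summary statistics (calibration references)
#'
#' Zone-wise summary statistics of a multi-decadal Svalbard fjord campaign
#' (Hornsund and Kongsfjorden; Glacier, Inner and Outer zones), bundled as
#' plain tables. `zone_surface_reference()` holds surface values — primary
#' production Pe(0) (mgC m-3 h-1), temperature (degC), salinity and
#' chlorophyll-a (mg m-3) — as min/max/mean/SD per (fjord, zone);
#' `zone_pi_reference()` holds the mean and SD of depth-integrated daily
#' production Pi (mgC m-2 day-1). They calibrate the synthetic campaign and
#' feed the published fold-ratio recomputations.
#'
#' @return A tibble.
#' @export
zone_surface_reference <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "zone_surface_summary.csv",
                package = "fjordpp", mustWork = TRUE),
    stringsAsFactors = FALSE))
}

#' @rdname zone_surface_reference
#' @export
zone_pi_reference <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "zone_pi_summary.csv",
                package = "fjordpp", mustWork = TRUE),
    stringsAsFactors = FALSE))
}

#' Zone summary of a variable
#'
#' Range, arithmetic mean and sample standard deviation (n - 1 denominator)
#' of the values observed in one (fjord, zone) stratum. A singleton sample
#' gets sd = 0 by convention and is flagged.
#'
#' @param values Numeric vector, non-empty.
#' @param fjord,zone,variable Stratum labels carried into the output.
#' @return A one-row tibble: fjord, zone, variable, n, min, max, mean, sd,
#'   singleton.
#' @export
summarize_zone <- function(values, fjord = NA_character_,
                           zone = NA_character_,
                           variable = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no values to summarize")
  n <- length(values)
  tibble::tibble(
    fjord = fjord, zone = zone, variable = variable,
    n = n,
    min = min(values), max = max(values),
    mean = mean(values),
    sd = if (n > 1L) stats::sd(values) else 0,
    singleton = n == 1L
  )
}

.fold_mean <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("mean" %in% names(x), nrow(x) == 1L)
    x$mean
  } else {
    stopifnot(is.numeric(x), length(x) == 1L)
    x
  }
}

#' Between-fjord fold ratio of zone means
#'
#' Ratio of two zone means, rounded the way such ratios are conventionally
#' printed: one decimal for surface-production ratios, nearest 0.5 for
#' integrated-production ratios.
#'
#' @param numerator,denominator Zone summaries (one-row tibbles from
#'   [summarize_zone()]) or bare means.
#' @param rounding `"one_decimal"` or `"nearest_half"`.
#' @return A list with `ratio` (rounded), `ratio_raw` and `rounding`.
#' @export
#' @examples
#' fold_ratio(6.0, 2.18)                        # 2.8
#' fold_ratio(740.4, 111.5, "nearest_half")     # 6.5
fold_ratio <- function(numerator, denominator,
                       rounding = c("one_decimal", "nearest_half")) {
  rounding <- match.arg(rounding)
  a <- .fold_mean(numerator)
  b <- .fold_mean(denominator)
  if (b <= 0) stop("denominator mean must be positive")
  raw <- a / b
  ratio <- switch(rounding,
                  one_decimal = round(raw, 1),
                  nearest_half = round(raw * 2) / 2)
  list(ratio = ratio, ratio_raw = raw, rounding = rounding)
}

#' Gated zone comparison: ANOVA or Kruskal-Wallis
#'
#' The parametric route is taken only when its assumptions hold: Shapiro-
#' Wilk normality in every group and Levene homogeneity of variances
#' (classical Levene, deviations from the group means) must all exceed
#' `alpha`; then a one-way ANOVA (equal-variance F test) compares the
#' groups. Otherwise the Kruskal-Wallis rank test is the non-parametric
#' alternative. The gate alpha equals the test alpha.
#'
#' @param groups Named list of numeric vectors, at least two groups with at
#'   least three values each.
#' @param alpha Significance level for both the assumption gates and the
#'   main test.
#' @return A list: `test_used` ("ANOVA" or "KruskalWallis"), `normality_p`
#'   (named per group), `variance_homogeneity_p`, `statistic`, `p_value`,
#'   `alpha`, `significant`.
#' @export
compare_zones <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L, alpha > 0, alpha < 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 3L)) {
    stop("groups too small for the comparison: ",
         paste(names(groups)[sizes < 3L], collapse = ", "))
  }
  norm_p <- vapply(groups, function(g) stats::shapiro.test(g)$p.value,
                   numeric(1))
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), sizes))
  lev <- car::leveneTest(values ~ grp, center = mean)
  lev_p <- lev[["Pr(>F)"]][1L]
  parametric <- all(norm_p > alpha) && lev_p > alpha
  if (parametric) {
    fit <- stats::oneway.test(values ~ grp, var.equal = TRUE)
    test_used <- "ANOVA"
  } else {
    fit <- stats::kruskal.test(values, grp)
    test_used <- "KruskalWallis"
  }
  list(
    test_used = test_used,
    normality_p = norm_p,
    variance_homogeneity_p = lev_p,
    statistic = unname(fit$statistic),
    p_value = fit$p.value,
    alpha = alpha,
    significant = fit$p.value < alpha
  )
}
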