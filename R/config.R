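#' Quality-control configuration for the cleaning cascade
#'
#' Thresholds of the catalog and observation filters. Defaults reproduce the
#' published cleaning protocol: a lab is kept when at least 70% of its numeric
#' observations share one (canonical) unit, it has at least 100 patients and
#' at least 1000 numeric observations; observation cleaning removes
#' non-numeric and non-finite entries and then, in a single pass, values more
#' than 4 sample standard deviations from the overall lab mean.
#'
#' @param min_modal_unit_fraction Minimum fraction of numeric observations in
#'   the modal canonical unit, in (0, 1]. Applied inclusively (exactly 0.70
#'   passes). Default 0.70.
#' @param min_patients Minimum number of patients with numeric observations.
#'   Default 100.
#' @param min_numeric_observations Minimum number of finite numeric
#'   observations. Default 1000.
#' @param outlier_sd_multiplier Half-width of the retained band in sample
#'   standard deviations around the lab mean. Default 4.
#' @param int_offset Rank offset c of the inverse normal transformation
#'   \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))}, in [0, 0.5]. Default 3/8 (Blom).
#' @param keep_modal_unit_only Drop observations not recorded in the lab's
#'   modal canonical unit before computing medians? Default TRUE, so a median
#'   is never computed over mixed units.
#' @param same_day_event_excluded In [filter_pre_event()], drop observations
#'   taken on the same day (age) as the first event mention? Default TRUE.
#' @return An object of class `qc_config` (a validated list).
#' @export
#' @examples
#' qc_config()
#' qc_config(min_patients = 10, min_numeric_observations = 50)
qc_config <- function(min_modal_unit_fraction = 0.70,
                      min_patients = 100L,
                      min_numeric_observations = 1000L,
                      outlier_sd_multiplier = 4.0,
                      int_offset = 3 / 8,
                      keep_modal_unit_only = TRUE,
                      same_day_event_excluded = TRUE) {
  cfg <- list(
    min_modal_unit_fraction = as.numeric(min_modal_unit_fraction),
    min_patients = as.integer(min_patients),
    min_numeric_observations = as.integer(min_numeric_observations),
    outlier_sd_multiplier = as.numeric(outlier_sd_multiplier),
    int_offset = as.numeric(int_offset),
    keep_modal_unit_only = isTRUE(keep_modal_unit_only),
    same_day_event_excluded = isTRUE(same_day_event_excluded)
  )
  validate_qc_config(cfg)
  structure(cfg, class = "qc_config")
}

validate_qc_config <- function(cfg) {
  chk <- function(ok, key, constraint) {
    if (!ok) stop("invalid qc_config: `", key, "` ", constraint, call. = FALSE)
  }
  chk(is.numeric(cfg$min_modal_unit_fraction) &&
        cfg$min_modal_unit_fraction > 0 && cfg$min_modal_unit_fraction <= 1,
      "min_modal_unit_fraction", "must be in (0, 1]")
  chk(!is.na(cfg$min_patients) && cfg$min_patients > 0L,
      "min_patients", "must be a strictly positive count")
  chk(!is.na(cfg$min_numeric_observations) && cfg$min_numeric_observations > 0L,
      "min_numeric_observations", "must be a strictly positive count")
  chk(is.finite(cfg$outlier_sd_multiplier) && cfg$outlier_sd_multiplier > 0,
      "outlier_sd_multiplier", "must be strictly positive")
  chk(is.finite(cfg$int_offset) && cfg$int_offset >= 0 && cfg$int_offset <= 0.5,
      "int_offset", "must be in [0, 0.5]")
  invisible(cfg)
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Stratification specification
#'
#' Factor levels for the optional stratified summaries: sex by age-at-draw
#' group by EHR-recorded race, each factor carrying a pooled level so every
#' observation contributes to marginal strata as well. The published pipeline
#' reported 72 subsets from one site-specific factorization; the levels here
#' are configuration, not constants.
#'
#' @param sex_levels Character vector of non-pooled sex levels.
#' @param age_groups Named list of `c(min, max)` half-open `[min, max)`
#'   age-at-draw intervals in years; must not overlap.
#' @param race_levels Character vector of non-pooled race levels.
#' @param pooled_label Label of the pooled level added to each factor.
#' @return An object of class `stratum_spec`.
#' @export
#' @examples
#' stratum_spec(age_groups = list(pediatric = c(0, 18), adult = c(18, Inf)))
stratum_spec <- function(sex_levels = c("F", "M"),
                         age_groups = list("0-18" = c(0, 18),
                                           "18-65" = c(18, 65),
                                           "65+" = c(65, Inf)),
                         race_levels = c("A", "B", "C"),
                         pooled_label = "all") {
  stopifnot(length(sex_levels) >= 1, length(race_levels) >= 1,
            length(age_groups) >= 1, !is.null(names(age_groups)))
  for (g in age_groups) {
    if (length(g) != 2 || !is.numeric(g) || g[1] >= g[2])
      stop("each age group must be a numeric c(min, max) with min < max",
           call. = FALSE)
  }
  ## non-overlap check on the non-pooled intervals
  lo <- vapply(age_groups, `[`, numeric(1), 1)
  hi <- vapply(age_groups, `[`, numeric(1), 2)
  o <- order(lo)
  if (any(hi[o][-length(o)] > lo[o][-1] + 1e-12))
    stop("age groups must be non-overlapping half-open intervals",
         call. = FALSE)
  if (pooled_label %in% c(sex_levels, race_levels, names(age_groups)))
    stop("pooled_label collides with a non-pooled level", call. = FALSE)
  structure(list(sex_levels = as.character(sex_levels),
                 age_groups = age_groups,
                 race_levels = as.character(race_levels),
                 pooled_label = as.character(pooled_label)),
            class = "stratum_spec")
}

#' Scan configuration for the lab-wide association scan
#'
#' @param min_n Minimum complete-case sample size for a lab to be tested.
#'   Default 100.
#' @param alpha Family-wise error level. Default 0.05.
#' @param n_scans Number of scans in the multiple-testing family (the
#'   published lipid/CAD analysis used 4: three lipid scores plus CAD).
#'   Default 1.
#' @param n_knots Number of knots of the restricted cubic spline of median
#'   EHR age. Default 4.
#' @param spline_columns Number of leading spline basis columns to use, or
#'   `NULL` for all `n_knots - 1` (one replication site used only the first
#'   two). Default `NULL`.
#' @param adjust Character vector of extra covariate-table columns to adjust
#'   for (e.g., a diagnosis flag). Default none.
#' @return An object of class `labwas_config`.
#' @export
labwas_config <- function(min_n = 100L, alpha = 0.05, n_scans = 1L,
                          n_knots = 4L, spline_columns = NULL,
                          adjust = character()) {
  stopifnot(min_n >= 1, alpha > 0, alpha < 1, n_scans >= 1, n_knots >= 3)
  if (!is.null(spline_columns))
    stopifnot(spline_columns >= 1, spline_columns <= n_knots - 1)
  structure(list(min_n = as.integer(min_n), alpha = as.numeric(alpha),
                 n_scans = as.integer(n_scans), n_knots = as.integer(n_knots),
                 spline_columns = if (is.null(spline_columns)) NULL
                                  else as.integer(spline_columns),
                 adjust = as.character(adjust)),
            class = "labwas_config")
}
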