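#' Per-patient median lab value and age at median
#'
#' For each patient, observations are sorted by value with ties broken by
#' age-at-draw ascending and then input order. With an odd number of
#' observations the median is the middle order statistic and the age at
#' median is that observation's age; with an even number the median is the
#' mean of the two middle order statistics and the age at median is the
#' midpoint of those two observations' ages. A single observation is valid
#' (median = value, age = its age).
#'
#' @param observations Cleaned observations of one lab, carrying a numeric
#'   `value_num` column (see [clean_observations()]).
#' @return A `data.table`, one row per patient: `patient_id`, `lab_id`,
#'   `median_value`, `age_at_median`, `n_obs` and an unset `int_value`
#'   (filled by [inverse_normal_transform()] over the whole lab).
#' @export
compute_patient_medians <- function(observations) {
  obs <- data.table::as.data.table(observations)
  if (!"value_num" %in% names(obs))
    obs[, value_num := parse_lab_values(raw_value)]
  if (any(!is.finite(obs$value_num)))
    stop("compute_patient_medians() requires finite cleaned values",
         call. = FALSE)
  obs[, pos := .I]  # input order, the final tie-break
  out <- obs[order(value_num, age_at_draw, pos),
    {
      n <- .N
      if (n %% 2L == 1L) {
        mid <- (n + 1L) %/% 2L
        list(median_value = value_num[mid], age_at_median = age_at_draw[mid],
             n_obs = n)
      } else {
        i <- n %/% 2L
        list(median_value = (value_num[i] + value_num[i + 1L]) / 2,
             age_at_median = (age_at_draw[i] + age_at_draw[i + 1L]) / 2,
             n_obs = n)
      }
    },
    by = .(patient_id, lab_id)]
  out[, int_value := NA_real_]
  data.table::setkey(out, lab_id, patient_id)
  out[]
}

#' Rank-based inverse normal transformation
#'
#' Replaces each value with the standard-normal quantile of its (offset)
#' rank: \eqn{\Phi^{-1}((r_i - c)/(n - 2c + 1))} with average ranks for ties
#' and offset `c` (default 3/8, the Blom scores). Tied inputs map to
#' identical outputs and rank order is preserved; a single value maps to 0.
#'
#' @param values Numeric vector, all finite, length >= 1.
#' @param offset Rank offset `c` in [0, 0.5]. Default 3/8.
#' @return Numeric vector of the same length: approximate z-scores.
#' @export
#' @examples
#' inverse_normal_transform(c(10, 20, 30, 40))
inverse_normal_transform <- function(values, offset = 3 / 8) {
  n <- length(values)
  if (n < 1) stop("empty input", call. = FALSE)
  bad <- !is.finite(values)
  if (any(bad))
    stop("non-finite value at index ", which(bad)[1], call. = FALSE)
  stopifnot(offset >= 0, offset <= 0.5)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Restrict observations to those before a per-patient event age
#'
#' Used to compute pre-medication lab summaries: for patients with a recorded
#' first-event age (e.g., first mention of a lipid-altering medication),
#' observations after the event are removed; same-age observations are
#' removed iff `config$same_day_event_excluded`. Patients without an event
#' age keep all observations.
#'
#' @param observations Observation table.
#' @param event_ages `data.table`/data.frame with columns `patient_id` and
#'   `event_age` (years, >= 0), at most one row per patient.
#' @param config A [qc_config()].
#' @return The filtered observations.
#' @export
filter_pre_event <- function(observations, event_ages,
                             config = qc_config()) {
  obs <- data.table::as.data.table(observations)
  ev <- data.table::as.data.table(event_ages)
  stopifnot(all(c("patient_id", "event_age") %in% names(ev)))
  if (anyDuplicated(ev$patient_id))
    stop("event_ages must have at most one row per patient", call. = FALSE)
  if (any(ev$event_age < 0, na.rm = TRUE))
    stop("event ages must be non-negative", call. = FALSE)
  e <- ev$event_age[match(obs$patient_id, ev$patient_id)]
  keep <- is.na(e) |
    (if (isTRUE(config$same_day_event_excluded)) obs$age_at_draw < e
     else obs$age_at_draw <= e)
  obs[keep]
}

#' Remove excluded patients from a per-patient table
#'
#' E.g., dropping diagnosed cases (phecode-defined) before a scan of
#' pre-disease biology. The number of removed records is reported.
#'
#' @param table Per-patient table (e.g., the clean median table).
#' @param excluded_ids Character vector of patient ids to remove.
#' @return The table without the excluded patients.
#' @export
exclude_patients <- function(table, excluded_ids) {
  dt <- data.table::as.data.table(table)
  drop <- dt$patient_id %in% excluded_ids
  message(sum(drop), " record(s) removed for ",
          length(unique(dt$patient_id[drop])), " excluded patient(s)")
  out <- dt[!drop]
  if (nrow(out) == 0L && nrow(dt) > 0L)
    warning("all patients excluded; table is empty", call. = FALSE)
  out
}

#' Split observations into demographic strata
#'
#' One subset per cell of sex x age-group x race, pooled levels included, so
#' a spec with 3 x 3 x 8 levels (pooled counted) yields 72 subsets. Age-group
#' membership is decided per observation from `age_at_draw` against the
#' half-open `[min, max)` intervals; observations whose age falls outside
#' every non-pooled group contribute only to the pooled age level (counted
#' and reported).
#'
#' @param observations Observation table.
#' @param demographics Per-patient table with `patient_id`, `sex`, `race`.
#' @param spec A [stratum_spec()].
#' @return A named list of observation `data.table`s keyed
#'   `"sex=<s>|age=<a>|race=<r>"`, with attribute `n_unbinned_age` (count of
#'   observations outside all non-pooled age groups).
#' @export
stratify <- function(observations, demographics, spec = stratum_spec()) {
  obs <- data.table::as.data.table(observations)
  dem <- data.table::as.data.table(demographics)
  miss <- setdiff(unique(obs$patient_id), dem$patient_id)
  if (length(miss))
    stop("demographics missing for patient(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  sex <- dem$sex[match(obs$patient_id, dem$patient_id)]
  race <- dem$race[match(obs$patient_id, dem$patient_id)]
  pl <- spec$pooled_label
  age_lab <- rep(NA_character_, nrow(obs))
  for (g in names(spec$age_groups)) {
    iv <- spec$age_groups[[g]]
    hit <- obs$age_at_draw >= iv[1] & obs$age_at_draw < iv[2]
    age_lab[hit] <- g
  }
  n_unbinned <- sum(is.na(age_lab))
  if (n_unbinned > 0)
    message(n_unbinned, " observation(s) outside all non-pooled age groups; ",
            "assigned only to the pooled age level")
  out <- list()
  for (s in c(spec$sex_levels, pl)) {
    s_ok <- if (s == pl) rep(TRUE, nrow(obs)) else sex == s
    for (a in c(names(spec$age_groups), pl)) {
      a_ok <- if (a == pl) rep(TRUE, nrow(obs)) else !is.na(age_lab) & age_lab == a
      for (r in c(spec$race_levels, pl)) {
        r_ok <- if (r == pl) rep(TRUE, nrow(obs)) else race == r
        out[[sprintf("sex=%s|age=%s|race=%s", s, a, r)]] <-
          obs[s_ok & a_ok & r_ok]
      }
    }
  }
  data.table::setattr(out, "n_unbinned_age", n_unbinned)
  out
}

#' Summary statistics of per-patient medians within one stratum
#'
#' @param summaries `PatientLabSummary` records of one stratum (output of
#'   [compute_patient_medians()], possibly subset).
#' @return A `data.table`, one row per lab: `n_patients`, `mean`, `sd`
#'   (sample; `NA` for a single record), `min`, `q25`, `q50`, `q75`, `max` of
#'   `median_value`. An empty input yields a zero-row table.
#' @export
summarize_stratum <- function(summaries) {
  dt <- data.table::as.data.table(summaries)
  if (nrow(dt) == 0L)
    return(data.table::data.table(
      lab_id = character(0), n_patients = integer(0), mean = numeric(0),
      sd = numeric(0), min = numeric(0), q25 = numeric(0), q50 = numeric(0),
      q75 = numeric(0), max = numeric(0)))
  dt[, {
    q <- stats::quantile(median_value, c(0.25, 0.5, 0.75), names = FALSE)
    list(n_patients = .N, mean = mean(median_value),
         sd = stats::sd(median_value), min = min(median_value),
         q25 = q[1], q50 = q[2], q75 = q[3], max = max(median_value))
  }, by = lab_id][order(lab_id)]
}
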