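#' Profile every lab in the catalog
#'
#' Computes, per lab, the counts and modal-unit statistics that drive the
#' catalog-level keep/drop decision. Numeric-ness of a raw value is decided by
#' the strict parse of [parse_lab_values()]; infinite values do not count as
#' numeric observations. Modal-unit statistics are computed over numeric
#' observations only. Two patient counts are carried: `n_patients_total`
#' (distinct patients administered the lab at all, which drives the
#' single-patient filter) and `n_patients` (distinct patients with numeric
#' observations, which drives the minimum-patients threshold).
#'
#' @param observations Observation table with canonicalized units
#'   (see [canonicalize_units()]).
#' @return A `data.table`, one row per `lab_id`, with columns
#'   `n_observations_total`, `n_numeric_observations`, `n_patients_total`,
#'   `n_patients`, `unit_counts` (list of named integer vectors),
#'   `modal_unit`, `modal_unit_fraction`, and unset `decision`/`drop_reasons`
#'   (filled by [select_quantitative_labs()]).
#' @export
profile_labs <- function(observations) {
  obs <- data.table::as.data.table(observations)
  v <- parse_lab_values(obs$raw_value)
  fin <- is.finite(v)
  prof <- obs[, {
    f <- fin[.I]
    uc <- if (any(f)) {
      tab <- table(unit[f])
      stats::setNames(as.integer(tab), names(tab))
    } else stats::setNames(integer(0), character(0))
    if (length(uc)) {
      ## deterministic tie-break: largest count, then lexicographic
      best <- names(uc)[order(-uc, names(uc))][1]
      frac <- uc[[best]] / sum(uc)
    } else {
      best <- NA_character_
      frac <- NA_real_
    }
    list(n_observations_total = .N,
         n_numeric_observations = sum(f),
         n_patients_total = data.table::uniqueN(patient_id),
         n_patients = data.table::uniqueN(patient_id[f]),
         unit_counts = list(uc),
         modal_unit = best,
         modal_unit_fraction = frac)
  }, by = lab_id]
  prof[, decision := NA_character_]
  prof[, drop_reasons := list(list(character(0)))]
  data.table::setkey(prof, lab_id)
  prof[]
}

#' Apply catalog-level filters and record keep/drop decisions
#'
#' Assembles `drop_reasons` in a fixed order without short-circuiting —
#' every applicable reason is recorded — and sets `decision = "keep"` iff no
#' reason applies. Thresholds are inclusive: a modal-unit fraction of exactly
#' `min_modal_unit_fraction` passes, as do labs with exactly `min_patients`
#' patients or `min_numeric_observations` numeric observations.
#'
#' @param profiles Output of [profile_labs()].
#' @param config A [qc_config()].
#' @return The profiles with `decision` and `drop_reasons` filled. Reasons,
#'   in order: `non_numeric_only`, `single_patient`, `unit_discordant`,
#'   `too_few_patients`, `too_few_observations`.
#' @export
select_quantitative_labs <- function(profiles, config = qc_config()) {
  validate_qc_config(config)
  prof <- data.table::copy(data.table::as.data.table(profiles))
  reasons <- lapply(seq_len(nrow(prof)), function(i) {
    r <- character(0)
    if (prof$n_numeric_observations[i] == 0L) r <- c(r, "non_numeric_only")
    if (prof$n_patients_total[i] <= 1L) r <- c(r, "single_patient")
    if (prof$n_numeric_observations[i] > 0L &&
        prof$modal_unit_fraction[i] < config$min_modal_unit_fraction)
      r <- c(r, "unit_discordant")
    if (prof$n_patients[i] < config$min_patients) r <- c(r, "too_few_patients")
    if (prof$n_numeric_observations[i] < config$min_numeric_observations)
      r <- c(r, "too_few_observations")
    r
  })
  prof[, drop_reasons := reasons]
  prof[, decision := ifelse(vapply(reasons, length, 1L) == 0L, "keep", "drop")]
  prof[]
}

#' Clean the observations of one kept lab
#'
#' Two non-iterated stages. Stage 1 removes non-numeric and non-finite
#' values and (when `keep_modal_unit_only`) observations not in the lab's
#' modal canonical unit. Stage 2 computes the mean and sample (n-1) standard
#' deviation of the stage-1 survivors in a single pass and removes
#' observations outside `outlier_sd_multiplier` standard deviations of that
#' mean. The filter is deliberately not iterated: re-running it on its own
#' output may remove further points only if survivors lie outside 4 SD of the
#' survivors' own mean.
#'
#' @param observations Observations of a single lab, units canonicalized.
#' @param config A [qc_config()].
#' @param modal_unit Canonical modal unit; computed from the numeric
#'   observations when `NULL`.
#' @return A list of class `labscan_cleaned`: `observations` (survivors, with
#'   numeric `value_num` column) and `ledger` (named counts: `n_input`,
#'   `n_non_numeric`, `n_non_finite`, `n_off_unit`, `n_outlier`, `n_output`,
#'   plus the stage-2 `mean` and `sd`). If no observation survives stage 1
#'   the lab is flagged via `empty_after_cleaning = TRUE`.
#' @export
clean_observations <- function(observations, config = qc_config(),
                               modal_unit = NULL) {
  validate_qc_config(config)
  obs <- data.table::as.data.table(observations)
  if (data.table::uniqueN(obs$lab_id) > 1)
    stop("clean_observations() expects observations of a single lab",
         call. = FALSE)
  v <- parse_lab_values(obs$raw_value)
  n_input <- nrow(obs)
  non_numeric <- is.na(v)
  non_finite <- !non_numeric & !is.finite(v)
  keep1 <- !non_numeric & !non_finite
  n_off_unit <- 0L
  if (isTRUE(config$keep_modal_unit_only)) {
    if (is.null(modal_unit)) {
      uc <- table(obs$unit[keep1])
      modal_unit <- if (length(uc)) names(uc)[order(-uc, names(uc))][1]
                    else NA_character_
    }
    off <- keep1 & !is.na(modal_unit) & obs$unit != modal_unit
    n_off_unit <- sum(off)
    keep1 <- keep1 & !off
  }
  ledger <- list(n_input = n_input,
                 n_non_numeric = sum(non_numeric),
                 n_non_finite = sum(non_finite),
                 n_off_unit = n_off_unit,
                 n_outlier = 0L, n_output = 0L,
                 mean = NA_real_, sd = NA_real_)
  if (!any(keep1)) {
    res <- list(observations = obs[keep1][, value_num := numeric(0)][],
                ledger = ledger, empty_after_cleaning = TRUE,
                modal_unit = modal_unit)
    class(res) <- "labscan_cleaned"
    return(res)
  }
  x <- v[keep1]
  m <- mean(x)
  s <- stats::sd(x)  # NA for a single observation
  out2 <- if (is.na(s) || s == 0) rep(FALSE, length(x))
          else abs(x - m) > config$outlier_sd_multiplier * s
  ledger$mean <- m
  ledger$sd <- s
  ledger$n_outlier <- sum(out2)
  survivors <- obs[keep1][!out2]
  survivors[, value_num := x[!out2]]
  ledger$n_output <- nrow(survivors)
  res <- list(observations = survivors[], ledger = ledger,
              empty_after_cleaning = FALSE, modal_unit = modal_unit)
  class(res) <- "labscan_cleaned"
  res
}

#' @export
print.labscan_cleaned <- function(x, ...) {
  l <- x$ledger
  cat(sprintf(
    "<labscan_cleaned> %d in -> %d out (non-numeric %d, non-finite %d, off-unit %d, >SD %d)\n",
    l$n_input, l$n_output, l$n_non_numeric, l$n_non_finite, l$n_off_unit,
    l$n_outlier))
  invisible(x)
}
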