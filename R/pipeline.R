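#' Run the full QualityLab cleaning cascade
#'
#' Catalog filters first (numeric-ness, single patient, unit concordance,
#' minimum patients/observations), then per-lab observation cleaning
#' (non-numeric/non-finite removal, modal-unit restriction, single-pass SD
#' filter), per-patient medians with age at median, and the inverse normal
#' transformation within each lab. Optionally restricts to pre-event
#' observations and removes excluded patients before summarization.
#'
#' @param observations Raw observation table (see [read_lab_observations()]).
#' @param synonyms Optional [unit_synonym_table()].
#' @param config A [qc_config()].
#' @param event_ages Optional per-patient first-event ages for
#'   [filter_pre_event()].
#' @param exclude_ids Optional patient ids removed from the clean table.
#' @return A list of class `qualitylab_result`:
#'   \describe{
#'     \item{clean_table}{per patient x kept lab: `patient_id`, `lab_id`,
#'       `median_value`, `age_at_median`, `n_obs`, `int_value`.}
#'     \item{profiles}{catalog profiles with decisions and drop reasons.}
#'     \item{ledgers}{per kept lab, the per-stage removal counts.}
#'     \item{config}{the configuration used (echoed for provenance).}
#'   }
#' @export
qualitylab_run <- function(observations, synonyms = NULL,
                           config = qc_config(), event_ages = NULL,
                           exclude_ids = NULL) {
  obs <- canonicalize_units(observations, synonyms)
  if (!is.null(event_ages)) obs <- filter_pre_event(obs, event_ages, config)
  profiles <- select_quantitative_labs(profile_labs(obs), config)
  kept <- profiles[decision == "keep", lab_id]
  ledgers <- list()
  pieces <- vector("list", length(kept))
  names(pieces) <- kept
  for (lab in kept) {
    cl <- clean_observations(obs[lab_id == lab], config,
                             modal_unit = profiles[lab_id == lab, modal_unit])
    ledgers[[lab]] <- cl$ledger
    if (isTRUE(cl$empty_after_cleaning)) {
      message("lab ", lab, " empty after cleaning; excluded downstream")
      next
    }
    med <- compute_patient_medians(cl$observations)
    med[, int_value := inverse_normal_transform(median_value,
                                                offset = config$int_offset)]
    pieces[[lab]] <- med
  }
  clean_table <- data.table::rbindlist(pieces[!vapply(pieces, is.null,
                                                      logical(1))])
  if (nrow(clean_table) && !is.null(exclude_ids) && length(exclude_ids))
    clean_table <- exclude_patients(clean_table, exclude_ids)
  data.table::setkey(clean_table, lab_id, patient_id)
  structure(list(clean_table = clean_table[], profiles = profiles,
                 ledgers = ledgers, config = config),
            class = "qualitylab_result")
}

#' @export
print.qualitylab_result <- function(x, ...) {
  cat("<qualitylab_result>\n")
  cat("  labs in catalog : ", nrow(x$profiles), "\n", sep = "")
  cat("  labs kept       : ", sum(x$profiles$decision == "keep"), "\n",
      sep = "")
  cat("  patient x lab   : ", nrow(x$clean_table), "\n", sep = "")
  invisible(x)
}

#' Write QualityLab outputs to a directory
#'
#' Clean per-patient table (tab-delimited) and a QC report (JSON) carrying
#' every per-lab profile, decision, drop reasons, per-stage removal counts
#' and the thresholds used, for provenance.
#'
#' @param result A `qualitylab_result`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qualitylab <- function(result, out_dir) {
  stopifnot(inherits(result, "qualitylab_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clean_path <- file.path(out_dir, "clean_table.tsv")
  data.table::fwrite(result$clean_table, clean_path, sep = "\t")
  prof <- data.table::as.data.table(result$profiles)
  report <- list(
    config = unclass(result$config),
    labs = lapply(seq_len(nrow(prof)), function(i) {
      p <- as.list(prof[i, !c("unit_counts", "drop_reasons")])
      p$unit_counts <- as.list(prof$unit_counts[[i]])
      p$drop_reasons <- prof$drop_reasons[[i]]
      p$cleaning <- result$ledgers[[prof$lab_id[i]]]
      p
    })
  )
  report_path <- file.path(out_dir, "qc_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(clean_table = clean_path, qc_report = report_path))
}
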