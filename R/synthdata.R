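#' Configuration of the synthetic EHR generator
#'
#' Describes a cohort and a roster of labs with known ground truth. Per-lab
#' base distributions are normal or lognormal (EHR labs are typically
#' right-skewed); the continuous predictor acts on each lab's latent
#' standardized (liability) scale with the configured effect, so generator
#' truth is directly comparable to scan betas on the INT scale. Defaults
#' deliberately include pathological labs — a single-patient lab, a
#' non-numeric (qualitative) lab, and a unit-discordant lab — plus unit
#' dialects, contamination, and a medication-sensitive lab whose values shift
#' after a per-patient event age.
#'
#' @param n_patients Cohort size. Default 1000.
#' @param n_labs Number of labs in the roster. Default 20.
#' @param effects Numeric vector (recycled over ordinary labs) of true
#'   standardized per-lab predictor effects on the latent scale.
#' @param obs_rate Mean extra observations per patient per lab; draws per
#'   patient are `1 + Poisson(obs_rate)`. Default 2.
#' @param p_non_numeric,p_infinite,p_outlier Per-observation contamination
#'   rates: free-text/comparator strings, "inf" entries, gross outliers
#'   planted at 10 latent SD. Defaults 0.01, 0.002, 0.005.
#' @param med_fraction Approximate fraction of patients with a medication
#'   event age. Default 0.3.
#' @param med_shift Additive latent-scale shift applied to draws at/after the
#'   event age on medication-sensitive labs. Default -0.8 (a lowering
#'   therapy).
#' @param med_confounded Should medication uptake increase with the
#'   predictor (confounding by indication, as for lipid-lowering therapy)?
#'   Default TRUE.
#' @param n_pcs Number of principal-component columns. Default 10.
#' @param sex_ratio Probability of level "F". Default 0.54 (EHR cohorts skew
#'   female).
#' @param within_noise Latent-scale SD of draw-to-draw variation within a
#'   patient. Default 0.2 (small relative to the between-patient SD of 1, so
#'   patient medians track the liability).
#' @param special_labs Include the pathological labs (single-patient,
#'   non-numeric, unit-discordant, medication-sensitive)? Default TRUE.
#' @param binary_predictor If not `NULL`, generate a binary predictor with
#'   this prevalence instead of a continuous score.
#' @return An object of class `generator_config` with a per-lab `labs`
#'   `data.table`.
#' @export
generator_config <- function(n_patients = 1000L, n_labs = 20L,
                             effects = c(0, 0, 0.05, 0.1, 0.3),
                             obs_rate = 2, p_non_numeric = 0.01,
                             p_infinite = 0.002, p_outlier = 0.005,
                             med_fraction = 0.3, med_shift = -0.8,
                             med_confounded = TRUE, n_pcs = 10L,
                             sex_ratio = 0.54, within_noise = 0.2,
                             special_labs = TRUE, binary_predictor = NULL) {
  stopifnot(n_patients >= 2, n_labs >= 1, obs_rate >= 0,
            p_non_numeric >= 0, p_non_numeric <= 1,
            p_infinite >= 0, p_infinite <= 1,
            p_outlier >= 0, p_outlier <= 1,
            p_non_numeric + p_infinite + p_outlier <= 1,
            med_fraction >= 0, med_fraction <= 1,
            n_pcs >= 0, sex_ratio >= 0, sex_ratio <= 1, within_noise >= 0,
            all(abs(effects) < 1))
  n_special <- if (special_labs) min(3L, n_labs) else 0L
  n_ordinary <- n_labs - n_special
  ids <- sprintf("lab_%03d", seq_len(n_labs))
  fam <- rep(c("lognormal", "normal"), length.out = n_labs)
  eff <- numeric(n_labs)
  if (n_ordinary > 0)
    eff[seq_len(n_ordinary)] <- rep(effects, length.out = n_ordinary)
  labs <- data.table::data.table(
    lab_id = ids, family = fam,
    location = rep(c(4.5, 100), length.out = n_labs),
    scale = rep(c(0.4, 15), length.out = n_labs),
    effect = eff,
    patient_fraction = 1,
    p_non_numeric = p_non_numeric, p_infinite = p_infinite,
    p_outlier = p_outlier,
    med_sensitive = FALSE,
    dialects = rep(list(c("mg/dl" = 1)), n_labs))
  labs$dialects <- rep(list(c("mg/dl" = 0.7, "MG/DL" = 0.2, "mg/dL " = 0.1)),
                       n_labs)
  if (n_special >= 1) {      # single-patient lab
    i <- n_labs
    labs[i, `:=`(patient_fraction = 0, effect = 0)]
  }
  if (n_special >= 2) {      # qualitative, non-numeric-only lab
    i <- n_labs - 1L
    labs[i, `:=`(p_non_numeric = 1, effect = 0)]
  }
  if (n_special >= 3) {      # unit-discordant lab (55/45 split of units)
    i <- n_labs - 2L
    labs$dialects[[i]] <- c("mg/dl" = 0.55, "g/l" = 0.45)
    labs[i, effect := 0]
  }
  if (n_ordinary > 0) labs[1, med_sensitive := TRUE]
  cfg <- list(n_patients = as.integer(n_patients), n_labs = as.integer(n_labs),
              labs = labs, obs_rate = obs_rate,
              med_fraction = med_fraction, med_shift = med_shift,
              med_confounded = isTRUE(med_confounded),
              n_pcs = as.integer(n_pcs), sex_ratio = sex_ratio,
              within_noise = within_noise,
              binary_predictor = binary_predictor)
  structure(cfg, class = "generator_config")
}

## independent per-stream substreams from one global seed, so changing one
## rate does not reshuffle unrelated draws
stream_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + stream * 104729L) %% 2147483647L
}

#' Generate the synthetic cohort
#'
#' Demographics, covariates (sex, median EHR age, PCs), a predictor with the
#' configured kind, medication event ages, and the per-patient latent score
#' used downstream. Reproducible given `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (mandatory).
#' @return List: `demographics` (patient_id, sex, race), `covariates`
#'   (patient_id, sex, median_age, pc1..pck), `predictor` (patient_id,
#'   value), `event_ages` (patient_id, event_age; medicated patients only),
#'   `truth` (per-patient latent score `g`, EHR entry age `a0`, span, and
#'   medication flags).
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"), !missing(seed))
  n <- config$n_patients
  set.seed(stream_seed(seed, 1L))
  pid <- sprintf("pt_%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  race <- sample(c("A", "B", "C"), n, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  a0 <- stats::runif(n, 18, 70)
  span <- stats::runif(n, 1, 15)
  g <- stats::rnorm(n)
  value <- if (is.null(config$binary_predictor)) g
           else as.numeric(stats::runif(n) < config$binary_predictor)
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  colnames(pcs) <- paste0("pc", seq_len(max(config$n_pcs, 0)))[
    seq_len(config$n_pcs)]
  ## medication uptake, optionally increasing in g (indication bias)
  set.seed(stream_seed(seed, 2L))
  p_med <- if (config$med_confounded)
    stats::plogis(stats::qlogis(pmin(pmax(config$med_fraction, 1e-6),
                                     1 - 1e-6)) + g)
  else rep(config$med_fraction, n)
  is_med <- stats::runif(n) < p_med
  event_age <- rep(NA_real_, n)
  event_age[is_med] <- a0[is_med] + stats::runif(sum(is_med)) * span[is_med]
  covariates <- data.table::data.table(patient_id = pid, sex = sex,
                                       median_age = a0 + span / 2)
  if (config$n_pcs > 0) covariates <- cbind(covariates, pcs)
  list(
    demographics = data.table::data.table(patient_id = pid, sex = sex,
                                          race = race),
    covariates = covariates,
    predictor = data.table::data.table(patient_id = pid, value = value),
    event_ages = data.table::data.table(
      patient_id = pid[is_med], event_age = event_age[is_med]),
    truth = data.table::data.table(patient_id = pid, g = g, a0 = a0,
                                   span = span, is_med = is_med,
                                   event_age = event_age)
  )
}

#' Generate raw lab observations with a ground-truth ledger
#'
#' Per patient x lab, `1 + Poisson(obs_rate)` draws at increasing ages over
#' the patient's EHR span. The latent value of a draw is
#' `effect * g + sqrt(1 - effect^2) * liability + within_noise * noise`,
#' plus the configured medication shift for draws at/after the event age on
#' medication-sensitive labs; the recorded raw value is the base
#' distribution's quantile at that latent z. Contaminants (non-numeric
#' strings, "inf" entries, gross 10-SD outliers) replace clean draws at the
#' configured rates and are recorded — every observation is classified
#' exactly once in the ledger.
#'
#' @param cohort Output of [generate_cohort()].
#' @param config The same [generator_config()].
#' @param seed Integer seed.
#' @return List: `observations` (patient_id, lab_id, value, unit, age
#'   columns as character/numeric raw table), `ledger` (`obs_id`, `lab_id`,
#'   `patient_id`, `label` in clean/non_numeric/infinite/outlier), and
#'   `truth` (per-lab true effects and the cohort truth carried through).
#' @export
generate_observations <- function(cohort, config, seed) {
  stopifnot(inherits(config, "generator_config"))
  labs <- config$labs
  tr <- cohort$truth
  n <- nrow(tr)
  set.seed(stream_seed(seed, 3L))
  pieces <- vector("list", nrow(labs))
  for (i in seq_len(nrow(labs))) {
    L <- labs[i]
    keep <- if (L$patient_fraction >= 1) rep(TRUE, n)
            else if (L$patient_fraction <= 0) seq_len(n) == sample.int(n, 1)
            else stats::runif(n) < L$patient_fraction
    sub <- tr[keep]
    m <- nrow(sub)
    if (m == 0L) next
    k <- 1L + stats::rpois(m, config$obs_rate)
    liab <- stats::rnorm(m)
    z_pat <- L$effect * sub$g + sqrt(1 - L$effect^2) * liab
    rows <- rep(seq_len(m), k)
    ages <- sub$a0[rows] + stats::runif(length(rows)) * sub$span[rows]
    ## increasing ages within each patient
    ord <- order(rows, ages)
    rows <- rows[ord]; ages <- ages[ord]
    z <- z_pat[rows] + config$within_noise * stats::rnorm(length(rows))
    if (L$med_sensitive) {
      e <- sub$event_age[rows]
      z <- z + ifelse(!is.na(e) & ages >= e, config$med_shift, 0)
    }
    dial <- labs$dialects[[i]]
    units <- sample(names(dial), length(rows), replace = TRUE, prob = dial)
    u <- stats::runif(length(rows))
    label <- rep("clean", length(rows))
    label[u < L$p_non_numeric] <- "non_numeric"
    label[u >= L$p_non_numeric &
            u < L$p_non_numeric + L$p_infinite] <- "infinite"
    label[u >= L$p_non_numeric + L$p_infinite &
            u < L$p_non_numeric + L$p_infinite + L$p_outlier] <- "outlier"
    z[label == "outlier"] <- 10
    val <- if (L$family == "lognormal") exp(L$location + L$scale * z)
           else L$location + L$scale * z
    raw <- formatC(val, format = "g", digits = 15)
    raw[label == "non_numeric"] <-
      sample(c("positive", "negative", "<5", ">100", "see note", "TNP"),
             sum(label == "non_numeric"), replace = TRUE)
    raw[label == "infinite"] <-
      sample(c("inf", "-inf", "Inf"), sum(label == "infinite"),
             replace = TRUE)
    pieces[[i]] <- data.table::data.table(
      patient_id = sub$patient_id[rows], lab_id = L$lab_id, value = raw,
      unit = units, age = ages, label = label)
  }
  big <- data.table::rbindlist(pieces)
  big[, obs_id := .I]
  obs <- big[, .(patient_id, lab_id, value, unit, age)]
  ledger <- big[, .(obs_id, lab_id, patient_id, label)]
  list(observations = obs, ledger = ledger,
       truth = list(effects = labs[, .(lab_id, effect)],
                    labs = labs, cohort = cohort$truth,
                    med_shift = config$med_shift))
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: cohort plus observations under one seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List combining [generate_cohort()] and [generate_observations()]
#'   outputs: `demographics`, `covariates`, `predictor`, `event_ages`,
#'   `observations`, `ledger`, `truth`.
#' @export
generate_labwas_dataset <- function(config = generator_config(), seed) {
  cohort <- generate_cohort(config, seed)
  gen <- generate_observations(cohort, config, seed)
  c(cohort[c("demographics", "covariates", "predictor", "event_ages")],
    gen)
}

#' Independent oracle for the cleaning cascade
#'
#' Re-derives every catalog decision and per-stage removal count from the
#' raw observation table by brute force, using plain base-R loops and
#' `as.numeric()` parsing — deliberately sharing no code with the pipeline —
#' so the pipeline's QC report can be cross-checked lab-for-lab.
#'
#' @param observations Raw observation table (generator dialect: columns
#'   `patient_id`, `lab_id`, `value`, `unit`, `age`).
#' @param qc A [qc_config()].
#' @param synonyms Optional [unit_synonym_table()] applied as in the
#'   pipeline run under check.
#' @return A `data.table`, one row per lab: expected `decision`,
#'   `drop_reasons` (comma-joined), and for kept labs the expected stage-1
#'   (`exp_removed_stage1`) and stage-2 (`exp_removed_stage2`) removal
#'   counts and final observation count `exp_n_output`.
#' @export
expected_pipeline_counts <- function(observations, qc = qc_config(),
                                     synonyms = NULL) {
  df <- as.data.frame(observations, stringsAsFactors = FALSE)
  out <- list()
  for (lab in sort(unique(df$lab_id))) {
    d <- df[df$lab_id == lab, ]
    v <- suppressWarnings(as.numeric(d$value))
    ## as.numeric parses "inf"/"Inf"/"NaN"; comparator strings become NA
    fin <- !is.na(v) & is.finite(v)
    units <- tolower(gsub("[[:space:]]+", "", d$unit))
    if (!is.null(synonyms)) {
      hit <- match(units, names(synonyms))
      units[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
    }
    reasons <- character(0)
    if (sum(fin) == 0) reasons <- c(reasons, "non_numeric_only")
    if (length(unique(d$patient_id)) <= 1)
      reasons <- c(reasons, "single_patient")
    frac <- if (sum(fin) > 0) max(table(units[fin])) / sum(fin) else NA
    if (sum(fin) > 0 && frac < qc$min_modal_unit_fraction)
      reasons <- c(reasons, "unit_discordant")
    if (length(unique(d$patient_id[fin])) < qc$min_patients)
      reasons <- c(reasons, "too_few_patients")
    if (sum(fin) < qc$min_numeric_observations)
      reasons <- c(reasons, "too_few_observations")
    row <- data.frame(lab_id = lab,
                      decision = if (length(reasons)) "drop" else "keep",
                      drop_reasons = paste(reasons, collapse = ","),
                      exp_removed_stage1 = NA_integer_,
                      exp_removed_stage2 = NA_integer_,
                      exp_n_output = NA_integer_,
                      stringsAsFactors = FALSE)
    if (length(reasons) == 0) {
      tab <- table(units[fin])
      modal <- names(tab)[order(-tab, names(tab))][1]
      keep1 <- fin & (!qc$keep_modal_unit_only | units == modal)
      x <- v[keep1]
      m <- sum(x) / length(x)
      s <- sqrt(sum((x - m)^2) / (length(x) - 1))
      out2 <- abs(x - m) > qc$outlier_sd_multiplier * s
      row$exp_removed_stage1 <- nrow(d) - sum(keep1)
      row$exp_removed_stage2 <- sum(out2)
      row$exp_n_output <- sum(!out2)
    }
    out[[lab]] <- row
  }
  data.table::rbindlist(out)
}

#' Write a synthetic dataset to files in the dialects the pipeline reads
#'
#' @param dataset Output of [generate_labwas_dataset()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_synth <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(observations = file.path(out_dir, "observations.tsv"),
             demographics = file.path(out_dir, "demographics.tsv"),
             covariates = file.path(out_dir, "covariates.tsv"),
             predictor = file.path(out_dir, "predictor.tsv"),
             event_ages = file.path(out_dir, "event_ages.tsv"),
             ledger = file.path(out_dir, "truth_ledger.json"))
  data.table::fwrite(dataset$observations, paths["observations"], sep = "\t")
  data.table::fwrite(dataset$demographics, paths["demographics"], sep = "\t")
  data.table::fwrite(dataset$covariates, paths["covariates"], sep = "\t")
  data.table::fwrite(dataset$predictor, paths["predictor"], sep = "\t")
  data.table::fwrite(dataset$event_ages, paths["event_ages"], sep = "\t")
  jsonlite::write_json(
    list(effects = dataset$truth$effects,
         ledger_counts = as.list(table(dataset$ledger$label)),
         n_observations = nrow(dataset$observations)),
    paths["ledger"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
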