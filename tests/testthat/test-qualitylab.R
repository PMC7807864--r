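test_that("read_lab_observations parses identity, preserves strings, enforces invariants", {
  p <- write_tmp(c("patient_id,lab_id,value,unit,age",
                   "p1,chol,199.5,mg/dL,45.2",
                   "p2,chol,<5,mg/dL,50",
                   "p3,na,positive,,33.3"))
  obs <- read_lab_observations(p)
  expect_equal(nrow(obs), 3)
  expect_identical(obs$raw_value, c("199.5", "<5", "positive"))
  expect_identical(obs$unit, c("mg/dL", "mg/dL", ""))
  expect_equal(obs$age_at_draw, c(45.2, 50, 33.3))

  bad <- write_tmp(c("patient_id,lab_id,value,unit,age",
                     "p1,chol,1,mg/dL,-1"))
  expect_error(read_lab_observations(bad), "row 1")

  expect_error(
    read_lab_observations(p, column_map = c(patient_id = "patient_id",
                                            lab_id = "lab_id",
                                            value = "value", unit = "unit",
                                            age = "nope")),
    "missing column")
  expect_error(
    read_lab_observations(p, column_map = c(patient_id = "patient_id")),
    "column_map")
})

test_that("read_lab_observations round-trips a generator file at the ledger count", {
  ds <- generate_labwas_dataset(generator_config(n_patients = 200,
                                                 n_labs = 6), seed = 11)
  dir <- tempfile(); dir.create(dir)
  paths <- write_synth(ds, dir)
  obs <- read_lab_observations(paths[["observations"]])
  expect_equal(nrow(obs), nrow(ds$ledger))
})

test_that("canonicalize_units folds case/whitespace and applies synonyms", {
  syn <- unit_synonym_table(c("mcg/L", "ug/L"), c("μg/l", "μg/l"))
  obs <- make_obs(c("p1", "p2", "p3"), "se",
                  c("1", "2", "3"),
                  c("mcg/L", "MG/DL ", "μg/l"),
                  c(40, 41, 42))
  out <- canonicalize_units(obs, syn)
  expect_identical(out$unit, c("μg/l", "mg/dl", "μg/l"))
  expect_equal(nrow(out), nrow(obs))
  ## unmapped units pass through case-folded, not as an error
  expect_identical(canonicalize_units(make_obs("p", "l", "1", "Weird Unit",
                                               1))$unit, "weirdunit")
})

test_that("strict numeric parse: decimals/scientific in, comparators/text out", {
  v <- parse_lab_values(c("1.0", "2e1", "inf", "-Inf", "NaN", "<5", ">100",
                          "positive", ".5", "-3.2E-2", "1,000", ""))
  expect_equal(v[1:2], c(1, 20))
  expect_identical(v[3:4], c(Inf, -Inf))
  expect_true(is.nan(v[5]))
  expect_true(all(is.na(v[6:8]) & !is.nan(v[6:8])))
  expect_equal(v[9:10], c(0.5, -0.032))
  expect_true(all(is.na(v[11:12])))
})

test_that("profile_labs computes per-lab counts and modal-unit statistics", {
  obs <- rbind(
    make_obs(c("a", "b"), "qual", c("positive", "negative"), "", c(1, 2)),
    make_obs(c("a", "a", "b"), "mix", c("1.0", "2e1", "inf"), "mg/dl",
             c(1, 2, 3)),
    make_obs(c("a", "b", "c", "d"), "units", c("1", "2", "3", "4"),
             c("mg/dl", "mg/dl", "mg/dl", "g/l"), c(1, 2, 3, 4)))
  prof <- profile_labs(canonicalize_units(obs))
  expect_equal(nrow(prof), 3)
  expect_equal(prof[lab_id == "qual", n_numeric_observations], 0L)
  expect_equal(prof[lab_id == "mix", n_numeric_observations], 2L)
  expect_equal(prof[lab_id == "units", modal_unit], "mg/dl")
  expect_equal(prof[lab_id == "units", modal_unit_fraction], 0.75)
  expect_equal(prof[lab_id == "mix", n_patients], 1L)
  expect_equal(prof[lab_id == "mix", n_patients_total], 2L)
})

test_that("select_quantitative_labs applies inclusive thresholds in fixed order", {
  mkprof <- function(n_num, n_pat_tot, n_pat, frac) {
    data.table(lab_id = "x", n_observations_total = n_num + 1L,
               n_numeric_observations = as.integer(n_num),
               n_patients_total = as.integer(n_pat_tot),
               n_patients = as.integer(n_pat),
               unit_counts = list(c("mg/dl" = n_num)),
               modal_unit = "mg/dl", modal_unit_fraction = frac,
               decision = NA_character_,
               drop_reasons = list(character(0)))
  }
  cfg <- qc_config()
  ## 99 patients, 2000 numeric obs, one unit -> only too_few_patients
  d <- select_quantitative_labs(mkprof(2000, 99, 99, 1), cfg)
  expect_identical(d$drop_reasons[[1]], "too_few_patients")
  expect_identical(d$decision, "drop")
  ## modal fraction exactly 0.70 passes ("at least 70%" is inclusive)
  d <- select_quantitative_labs(mkprof(2000, 200, 200, 0.70), cfg)
  expect_identical(d$decision, "keep")
  expect_length(d$drop_reasons[[1]], 0)
  ## boundary: exactly min counts keep
  d <- select_quantitative_labs(mkprof(1000, 100, 100, 0.9), cfg)
  expect_identical(d$decision, "keep")
  ## all applicable reasons recorded in the fixed order, no short-circuit
  d <- select_quantitative_labs(mkprof(0, 1, 0, NA), cfg)
  expect_identical(d$drop_reasons[[1]],
                   c("non_numeric_only", "single_patient",
                     "too_few_patients", "too_few_observations"))
})

test_that("filter monotonicity: stricter thresholds never keep more labs", {
  set.seed(402)
  prof <- data.table(
    lab_id = sprintf("l%02d", 1:40),
    n_observations_total = 5000L,
    n_numeric_observations = as.integer(sample(0:3000, 40, replace = TRUE)),
    n_patients_total = as.integer(sample(0:300, 40, replace = TRUE)),
    modal_unit = "mg/dl",
    modal_unit_fraction = runif(40, 0.4, 1),
    decision = NA_character_)
  prof[, n_patients := pmin(n_patients_total,
                            as.integer(n_numeric_observations))]
  prof[, unit_counts := list(list(c("mg/dl" = 1L)))]
  prof[, drop_reasons := list(list(character(0)))]
  kept <- function(cfg) sum(select_quantitative_labs(prof, cfg)$decision ==
                              "keep")
  base <- qc_config(min_patients = 50, min_numeric_observations = 500,
                    min_modal_unit_fraction = 0.6)
  n0 <- kept(base)
  expect_lte(kept(qc_config(min_patients = 120,
                            min_numeric_observations = 500,
                            min_modal_unit_fraction = 0.6)), n0)
  expect_lte(kept(qc_config(min_patients = 50,
                            min_numeric_observations = 1500,
                            min_modal_unit_fraction = 0.6)), n0)
  expect_lte(kept(qc_config(min_patients = 50,
                            min_numeric_observations = 500,
                            min_modal_unit_fraction = 0.9)), n0)
})

test_that("clean_observations: stage-1 parse filter, single-pass 4-SD stage 2", {
  cfg <- qc_config()
  ## constant lab: sd 0, everything retained
  const <- make_obs(paste0("p", 1:4), "c", rep("7", 4), "mg/dl", 1:4)
  out <- clean_observations(const, cfg)
  expect_equal(nrow(out$observations), 4)
  expect_equal(out$ledger$n_outlier, 0L)

  ## parse rule: {inf, abc} removed before the SD stage
  mixed <- make_obs(paste0("p", 1:4), "m", c("inf", "3.2", "abc", "4.0"),
                    "mg/dl", 1:4)
  out <- clean_observations(mixed, cfg)
  expect_equal(sort(out$observations$value_num), c(3.2, 4.0))
  expect_equal(out$ledger$n_non_numeric, 1L)
  expect_equal(out$ledger$n_non_finite, 1L)

  ## 100 zeros + one 50: brute-force m, s say the 50 goes
  x <- c(rep(0, 100), 50)
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_true(abs(50 - m) > 4 * s)       # oracle confirms the example
  obs <- make_obs(paste0("p", seq_along(x)), "z", as.character(x), "mg/dl",
                  seq_along(x))
  out <- clean_observations(obs, cfg)
  expect_equal(out$ledger$n_outlier, 1L)
  expect_false(50 %in% out$observations$value_num)
  expect_equal(out$ledger$mean, m)
  expect_equal(out$ledger$sd, s)

  ## modal-unit restriction removes off-unit observations when enabled
  two_units <- make_obs(paste0("p", 1:4), "u", c("1", "2", "3", "100"),
                        c("mg/dl", "mg/dl", "mg/dl", "g/l"), 1:4)
  out <- clean_observations(canonicalize_units(two_units), cfg)
  expect_equal(out$ledger$n_off_unit, 1L)
  out2 <- clean_observations(canonicalize_units(two_units),
                             qc_config(keep_modal_unit_only = FALSE))
  expect_equal(out2$ledger$n_off_unit, 0L)

  ## zero stage-1 survivors flags the lab, no crash
  empty <- clean_observations(make_obs("p", "e", "positive", "", 1), cfg)
  expect_true(empty$empty_after_cleaning)
})

test_that("the SD filter is single-pass: iteration would remove more", {
  ## 100 zeros, a 5 and a 1000: pass one removes only the 1000; on the
  ## survivors the 5 now lies beyond 4 SD, so an iterated filter would
  ## remove it too -- the implementation must not.
  x <- c(rep(0, 100), 5, 1000)
  obs <- make_obs(paste0("p", seq_along(x)), "s", as.character(x), "mg/dl",
                  seq_along(x))
  out1 <- clean_observations(obs, qc_config())
  expect_equal(out1$ledger$n_outlier, 1L)
  expect_true(5 %in% out1$observations$value_num)
  out2 <- clean_observations(out1$observations, qc_config())
  expect_equal(out2$ledger$n_outlier, 1L)   # iteration would remove the 5
  expect_false(5 %in% out2$observations$value_num)
})

test_that("accounting conservation: in = out + removed per stage", {
  ds <- generate_labwas_dataset(generator_config(n_patients = 300,
                                                 n_labs = 8), seed = 5)
  obs <- canonicalize_units(as_pipeline_obs(ds$observations))
  for (lab in unique(obs$lab_id)) {
    out <- clean_observations(obs[lab_id == lab], qc_config())
    l <- out$ledger
    expect_equal(l$n_input,
                 l$n_output + l$n_non_numeric + l$n_non_finite +
                   l$n_off_unit + l$n_outlier)
  }
})

test_that("patient medians follow the order-statistic and age-midpoint rules", {
  ## even count: midpoint of the two middle observations' ages
  even <- make_obs(rep("p", 2), "l", c("100", "110"), "u", c(40, 50))
  even[, value_num := c(100, 110)]
  s <- compute_patient_medians(even)
  expect_equal(s$median_value, 105)
  expect_equal(s$age_at_median, 45)
  expect_equal(s$n_obs, 2L)

  ## odd count: the middle order statistic carries its own age
  odd <- make_obs(rep("p", 3), "l", c("90", "100", "120"), "u", c(30, 40, 50))
  odd[, value_num := c(90, 100, 120)]
  s <- compute_patient_medians(odd)
  expect_equal(s$median_value, 100)
  expect_equal(s$age_at_median, 40)

  ## ties broken by age: sorted obs 2 and 3 have ages 20 and 30
  tie <- make_obs(rep("p", 4), "l", c("5", "5", "5", "8"), "u",
                  c(10, 20, 30, 40))
  tie[, value_num := c(5, 5, 5, 8)]
  s <- compute_patient_medians(tie)
  expect_equal(s$median_value, 5)
  expect_equal(s$age_at_median, 25)

  ## single observation is valid
  one <- make_obs("p", "l", "9", "u", 33)
  one[, value_num := 9]
  s <- compute_patient_medians(one)
  expect_equal(s$median_value, 9)
  expect_equal(s$age_at_median, 33)
})

test_that("inverse normal transform: Blom scores, ties, symmetry, contract", {
  expect_equal(inverse_normal_transform(42), 0)
  z <- inverse_normal_transform(c(5, 7, 9))
  expect_equal(z[2], 0)
  expect_equal(z[1], -z[3])
  expect_gt(z[3], 0)
  ## Blom scores for n = 4 against the quantile formula evaluated directly
  got <- inverse_normal_transform(c(10, 20, 30, 40))
  expect_equal(got, qnorm(((1:4) - 0.375) / 4.25), tolerance = 1e-12)
  ## tied inputs share an output; rank order preserved
  zt <- inverse_normal_transform(c(3, 1, 3, 2))
  expect_equal(zt[1], zt[3])
  expect_identical(order(zt), order(c(3, 1, 3, 2) + 1e-9 * c(1, 2, 3, 4)))
  ## contract for n >= 30 distinct values
  set.seed(9)
  for (x in list(rlnorm(50), rt(200, df = 2), exp(rnorm(31)))) {
    z <- inverse_normal_transform(x)
    expect_lt(abs(mean(z)), 0.02)
    expect_gte(sd(z), 0.9); expect_lte(sd(z), 1.1)
    expect_equal(cor(x, z, method = "spearman"), 1)
  }
  expect_error(inverse_normal_transform(c(1, Inf, 3)), "index 2")
})

test_that("pre-event filtering honors the same-day switch", {
  obs <- make_obs(rep("p", 3), "l", c("1", "2", "3"), "u", c(45, 50, 55))
  ev <- data.table(patient_id = "p", event_age = 50)
  expect_equal(filter_pre_event(obs, ev, qc_config())$age_at_draw, 45)
  expect_equal(
    filter_pre_event(obs, ev,
                     qc_config(same_day_event_excluded = FALSE))$age_at_draw,
    c(45, 50))
  ## a patient without an event keeps everything
  obs2 <- make_obs(rep("q", 5), "l", as.character(1:5), "u", 41:45)
  expect_equal(nrow(filter_pre_event(obs2, ev, qc_config())), 5)
  expect_error(filter_pre_event(obs, data.table(patient_id = "p",
                                                event_age = -2)),
               "non-negative")
})

test_that("exclude_patients removes exactly the listed ids", {
  tab <- data.table(patient_id = sprintf("p%02d", 1:10), v = 1:10)
  expect_equal(suppressMessages(exclude_patients(tab, character(0))), tab)
  out <- suppressMessages(exclude_patients(tab, c("p01", "p05", "p09")))
  expect_identical(out$patient_id, sprintf("p%02d", c(2:4, 6:8, 10)))
  expect_warning(suppressMessages(exclude_patients(tab, tab$patient_id)),
                 "all patients excluded")
})

test_that("stratify builds the full factor grid with pooled levels", {
  dem <- data.table(patient_id = c("p1", "p2"), sex = c("F", "M"),
                    race = c("A", "B"))
  obs <- make_obs(c("p1", "p1", "p2"), "l", c("1", "2", "3"), "u",
                  c(17.9, 30, 70))
  spec <- stratum_spec(sex_levels = c("F", "M"),
                       age_groups = list(pediatric = c(0, 18),
                                         adult = c(18, Inf)),
                       race_levels = c("A", "B"))
  subsets <- stratify(obs, dem, spec)
  expect_length(subsets, 27)       # 3 x 3 x 3 with pooled levels
  ## the 17.9-year draw is pediatric (half-open interval), not adult
  expect_equal(nrow(subsets[["sex=F|age=pediatric|race=A"]]), 1)
  expect_equal(nrow(subsets[["sex=F|age=adult|race=A"]]), 1)
  expect_equal(nrow(subsets[["sex=all|age=all|race=all"]]), 3)
  ## 3 sex x 3 age x 8 race (pooled included) -> 72 subsets
  spec72 <- stratum_spec(sex_levels = c("F", "M"),
                         age_groups = list(a = c(0, 18), b = c(18, Inf)),
                         race_levels = paste0("r", 1:7))
  expect_length(stratify(obs[1:2],
                         data.table(patient_id = "p1", sex = "F",
                                    race = "r1"), spec72), 72)
  ## ages outside every non-pooled group go only to the pooled level
  spec_gap <- stratum_spec(age_groups = list(adult = c(18, 65)),
                           sex_levels = c("F", "M"),
                           race_levels = c("A", "B"))
  msg <- capture_messages(subsets <- stratify(obs, dem, spec_gap))
  expect_match(paste(msg, collapse = ""), "pooled age")
  expect_equal(nrow(subsets[["sex=all|age=adult|race=all"]]), 1)
  expect_equal(nrow(subsets[["sex=all|age=all|race=all"]]), 3)
})

test_that("stratum summaries match an independent summation oracle", {
  s <- summarize_stratum(data.table(patient_id = c("a", "b", "c"),
                                    lab_id = "l", median_value = c(1, 2, 3)))
  expect_equal(s$mean, 2); expect_equal(s$min, 1); expect_equal(s$max, 3)
  s1 <- summarize_stratum(data.table(patient_id = "a", lab_id = "l",
                                     median_value = 7))
  expect_true(is.na(s1$sd))
  expect_equal(s1$min, 7); expect_equal(s1$max, 7); expect_equal(s1$mean, 7)
  expect_equal(nrow(summarize_stratum(data.table())), 0)

  set.seed(31)
  recs <- data.table(patient_id = sprintf("p%04d", 1:1000),
                     lab_id = rep(c("x", "y"), 500),
                     median_value = rlnorm(1000))
  s <- summarize_stratum(recs)
  for (lab in c("x", "y")) {
    v <- recs[lab_id == lab, median_value]
    m <- sum(v) / length(v)                       # independent summation
    expect_equal(s[lab_id == lab, mean], m, tolerance = 1e-12)
    expect_equal(s[lab_id == lab, sd],
                 sqrt(sum((v - m)^2) / (length(v) - 1)), tolerance = 1e-12)
    expect_equal(s[lab_id == lab, n_patients], length(v))
    expect_true(s[lab_id == lab, min] <= s[lab_id == lab, q25] &&
                  s[lab_id == lab, q25] <= s[lab_id == lab, q75] &&
                  s[lab_id == lab, q75] <= s[lab_id == lab, max])
  }
})

test_that("the cascade is deterministic: identical inputs, identical outputs", {
  ds <- generate_labwas_dataset(generator_config(n_patients = 250,
                                                 n_labs = 6), seed = 3)
  obs <- as_pipeline_obs(ds$observations)
  cfg <- qc_config(min_patients = 30, min_numeric_observations = 100)
  r1 <- qualitylab_run(obs, config = cfg)
  r2 <- qualitylab_run(obs, config = cfg)
  expect_identical(r1$clean_table, r2$clean_table)
  expect_identical(r1$profiles$decision, r2$profiles$decision)
  ## INT ranks equal median ranks within each lab (ties share a value)
  for (lab in unique(r1$clean_table$lab_id)) {
    sub <- r1$clean_table[lab_id == lab]
    expect_equal(rank(sub$int_value), rank(sub$median_value))
  }
})
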