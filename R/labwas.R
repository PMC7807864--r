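#' Standardize a continuous predictor to mean zero, SD one
#'
#' Polygenic scores are scaled before testing so that effect estimates read
#' as change in INT lab value per SD of the score. Affine (rank-preserving).
#'
#' @param values Numeric vector, length >= 2, SD > 0.
#' @return `(values - mean) / sd(values)` (sample SD).
#' @export
#' @examples
#' standardize_predictor(c(1, 2, 3))
standardize_predictor <- function(values) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite predictor value", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero-variance predictor", call. = FALSE)
  (values - mean(values)) / s
}

harrell_knot_probs <- function(k) {
  switch(as.character(k),
    "3" = c(0.10, 0.50, 0.90),
    "4" = c(0.05, 0.35, 0.65, 0.95),
    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
    "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583, 0.8167, 0.975),
    seq(0.05, 0.95, length.out = k))
}

rcs_eval <- function(x, knots) {
  k <- length(knots)
  kd <- (knots[k] - knots[1])^2
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  pp <- function(u) pmax(u, 0)^3
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pp(x - knots[j]) -
      pp(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      pp(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])
    ) / kd
  }
  colnames(out) <- c("age", paste0("age", strrep("'", seq_len(k - 2))))
  out
}

#' Restricted cubic spline basis of age
#'
#' Natural (restricted) cubic spline in the Harrell truncated-power
#' parameterization: `n_knots - 1` columns (the linear term plus
#' `n_knots - 2` nonlinear terms), knots at the conventional quantiles of the
#' observed ages (for 4 knots: the 5th, 35th, 65th and 95th percentiles).
#' Any linear function of age lies in the column span and the fitted function
#' is linear beyond the boundary knots, which keeps the age adjustment
#' well-behaved in the thin tails of an EHR age distribution.
#'
#' @param ages Numeric vector of ages in years.
#' @param n_knots Number of knots (>= 3). Default 4.
#' @param knots Optional explicit knot locations (overrides quantiles).
#' @param n_columns_used Number of leading basis columns retained (default
#'   all; set 2 to reproduce a "first two splines" adjustment).
#' @return An object of class `spline_basis`: list with `knots`, `basis`
#'   (matrix, rows = ages), `n_knots`, `n_columns_used`.
#' @export
build_spline_basis <- function(ages, n_knots = 4L, knots = NULL,
                               n_columns_used = NULL) {
  if (n_knots < 3) stop("n_knots must be >= 3", call. = FALSE)
  if (any(!is.finite(ages))) stop("non-finite age", call. = FALSE)
  if (is.null(knots)) {
    if (length(unique(ages)) < n_knots)
      stop("fewer distinct ages (", length(unique(ages)),
           ") than knots (", n_knots, ")", call. = FALSE)
    knots <- unname(stats::quantile(ages, harrell_knot_probs(n_knots),
                                    type = 7))
    if (length(unique(knots)) < n_knots)
      stop("degenerate age distribution: duplicated knots", call. = FALSE)
  }
  knots <- sort(as.numeric(knots))
  basis <- rcs_eval(ages, knots)
  if (is.null(n_columns_used)) n_columns_used <- ncol(basis)
  stopifnot(n_columns_used >= 1, n_columns_used <= ncol(basis))
  structure(list(knots = knots, basis = basis, n_knots = as.integer(n_knots),
                 n_columns_used = as.integer(n_columns_used)),
            class = "spline_basis")
}

#' Evaluate a spline basis at new ages
#' @param object A `spline_basis`.
#' @param ages Ages at which to evaluate.
#' @param ... Unused.
#' @return Basis matrix at the new ages (same columns).
#' @export
predict.spline_basis <- function(object, ages, ...) {
  rcs_eval(ages, object$knots)
}

#' OLS association of one lab with the predictor
#'
#' Ordinary least squares of the INT lab values on
#' `[intercept, predictor, covariates]`. The reported `beta`/`se` are the
#' predictor coefficient and its standard error; `p_value` is the two-sided t
#' test with residual degrees of freedom and the 95% CI is
#' `beta +/- t(0.975, df) * se`. Rows must already be complete cases.
#'
#' @param y Numeric outcome vector (INT values).
#' @param x Numeric predictor vector (standardized if continuous).
#' @param covariates Optional numeric matrix / data.frame of adjustment
#'   columns (no intercept).
#' @return One-row `data.table`: `n`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `direction` (`"up"` iff beta > 0), and `skipped_reason`
#'   (`"degenerate_fit"` when the design is rank-deficient, `NA` otherwise).
#' @export
fit_single_lab <- function(y, x, covariates = NULL) {
  n <- length(y)
  stopifnot(length(x) == n)
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == n)
    X <- cbind(X, cv)
  }
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("fit_single_lab() requires complete, finite cases", call. = FALSE)
  p <- ncol(X)
  skipped <- function(reason) data.table::data.table(
    n = n, beta = NA_real_, se = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, p_value = NA_real_, direction = NA_character_,
    skipped_reason = reason)
  if (n <= p) return(skipped("degenerate_fit"))
  qx <- qr(X)
  if (qx$rank < p) return(skipped("degenerate_fit"))
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  df <- n - p
  sigma2 <- sum(res^2) / df
  ## (X'X)^{-1} from the R factor; columns may be pivoted
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  unpiv <- order(qx$pivot)
  var_x <- sigma2 * xtx_inv[unpiv[2], unpiv[2]]
  beta <- unname(coefs["x"])
  se <- sqrt(var_x)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(0.975, df)
  data.table::data.table(
    n = n, beta = beta, se = se,
    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
    p_value = pval, direction = if (beta > 0) "up" else "down",
    skipped_reason = NA_character_)
}

#' Bonferroni threshold across the scan family
#'
#' `alpha / (n_labs * n_scans)`: with 315 labs tested in each of 4 scans at
#' alpha = 0.05 this is 3.97e-5.
#'
#' @param n_labs Number of labs actually tested.
#' @param n_scans Number of scans in the family.
#' @param alpha Family-wise error level.
#' @return The per-test significance threshold.
#' @export
#' @examples
#' bonferroni_threshold(315, 4)
bonferroni_threshold <- function(n_labs, n_scans = 1L, alpha = 0.05) {
  if (n_labs < 1 || n_scans < 1)
    stop("n_labs and n_scans must be positive counts", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  alpha / (n_labs * n_scans)
}

#' Lab-wide association scan
#'
#' One covariate-adjusted linear model per retained lab: INT median lab value
#' on the standardized predictor, adjusting for sex, a restricted cubic
#' spline of median EHR age (knots shared across labs, computed on the
#' scanned sample), principal components, and any extra adjustment columns
#' (e.g., a diagnosis flag). Complete-case per lab; labs with fewer than
#' `config$min_n` complete cases are reported as skipped (never silently
#' dropped) and do not enter the Bonferroni denominator.
#'
#' @param clean_table Output table of [qualitylab_run()] (needs `patient_id`,
#'   `lab_id`, `int_value`).
#' @param predictor data.frame/`data.table` with `patient_id`, `value`;
#'   continuous predictors are standardized over the scanned sample if not
#'   already (binary 0/1 predictors are left as category contrasts).
#' @param covariates data.frame with `patient_id`, `sex`, `median_age`,
#'   `pc1..pck` and any extra adjustment columns named in `config$adjust`.
#' @param lab_allowlist Optional character vector: only these labs are
#'   eligible for testing (e.g., the heritable-lab allowlist).
#' @param config A [labwas_config()].
#' @param lab_categories Optional data.frame `lab_id`, `category` used for
#'   ordering and plotting; defaults to a single `"lab"` category.
#' @return An object of class `labwas_scan`: list with `records` (one
#'   `AssociationRecord` row per eligible lab, ordered by category then
#'   lab id), `n_labs_tested`, `n_scans`, `alpha`, `threshold`, `config`.
#' @export
run_labwas <- function(clean_table, predictor, covariates,
                       lab_allowlist = NULL, config = labwas_config(),
                       lab_categories = NULL) {
  ct <- data.table::as.data.table(clean_table)
  pred <- data.table::as.data.table(predictor)
  cov <- data.table::as.data.table(covariates)
  stopifnot(all(c("patient_id", "value") %in% names(pred)),
            all(c("patient_id", "sex", "median_age") %in% names(cov)))
  if (!is.null(lab_allowlist)) ct <- ct[lab_id %in% lab_allowlist]

  pc_cols <- grep("^pc\\d+$", names(cov), value = TRUE)
  extra <- config$adjust
  miss_extra <- setdiff(extra, names(cov))
  if (length(miss_extra))
    stop("adjust column(s) not in covariates: ",
         paste(miss_extra, collapse = ", "), call. = FALSE)

  ## scanned sample: patients with predictor and complete covariates
  cov_cols <- c("sex", "median_age", pc_cols, extra)
  cov_ok <- cov[stats::complete.cases(cov[, cov_cols, with = FALSE])]
  base <- merge(pred, cov_ok, by = "patient_id")
  base <- base[is.finite(value)]
  if (nrow(base) == 0L || !any(ct$patient_id %in% base$patient_id))
    stop("no patients shared between clean table and predictor/covariates",
         call. = FALSE)

  uv <- sort(unique(base$value))
  is_binary <- length(uv) == 2L && all(uv %in% c(0, 1))
  xval <- base$value
  if (!is_binary) {
    already <- abs(mean(xval)) < 1e-8 && abs(stats::sd(xval) - 1) < 1e-8
    if (!already) xval <- standardize_predictor(xval)
  }

  sb <- build_spline_basis(base$median_age, n_knots = config$n_knots,
                           n_columns_used = if (is.null(config$spline_columns))
                             NULL else config$spline_columns)
  spl <- sb$basis[, seq_len(sb$n_columns_used), drop = FALSE]
  sex_num <- if (is.numeric(base$sex)) base$sex
             else as.numeric(factor(base$sex)) - 1
  cvmat <- cbind(sex = sex_num, spl)
  for (pc in pc_cols) cvmat <- cbind(cvmat, stats::setNames(base[[pc]], NULL))
  if (length(pc_cols))
    colnames(cvmat)[(ncol(cvmat) - length(pc_cols) + 1):ncol(cvmat)] <- pc_cols
  for (ex in extra) {
    v <- base[[ex]]
    cvmat <- cbind(cvmat, if (is.numeric(v)) v else as.numeric(factor(v)) - 1)
    colnames(cvmat)[ncol(cvmat)] <- ex
  }
  rownames(cvmat) <- NULL
  idx <- stats::setNames(seq_len(nrow(base)), base$patient_id)

  labs <- sort(unique(ct$lab_id))
  recs <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    sub <- ct[lab_id == labs[i] & is.finite(int_value)]
    rows <- idx[sub$patient_id]
    ok <- !is.na(rows)
    n_cc <- sum(ok)
    if (n_cc < config$min_n) {
      recs[[i]] <- data.table::data.table(
        lab_id = labs[i], n = n_cc, beta = NA_real_, se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        direction = NA_character_, skipped_reason = "too_few_patients")
      next
    }
    r <- rows[ok]
    fit <- fit_single_lab(sub$int_value[ok], xval[r],
                          cvmat[r, , drop = FALSE])
    fit[, lab_id := labs[i]]
    data.table::setcolorder(fit, "lab_id")
    recs[[i]] <- fit
  }
  records <- data.table::rbindlist(recs, fill = TRUE)
  if (is.null(lab_categories)) {
    records[, category := "lab"]
  } else {
    lc <- data.table::as.data.table(lab_categories)
    records[, category := lc$category[match(lab_id, lc$lab_id)]]
    records[is.na(category), category := "lab"]
  }
  n_tested <- records[is.na(skipped_reason), .N]
  threshold <- if (n_tested > 0)
    bonferroni_threshold(n_tested, config$n_scans, config$alpha) else NA_real_
  records[, significant := !is.na(p_value) & p_value < threshold]
  data.table::setorder(records, category, lab_id)
  data.table::setcolorder(records, c("lab_id", "category", "n", "beta", "se",
                                     "ci_low", "ci_high", "p_value",
                                     "direction", "significant",
                                     "skipped_reason"))
  structure(list(records = records[], n_labs_tested = n_tested,
                 n_scans = config$n_scans, alpha = config$alpha,
                 threshold = threshold, config = config,
                 spline_knots = sb$knots),
            class = "labwas_scan")
}

#' @export
print.labwas_scan <- function(x, ...) {
  cat("<labwas_scan> ", x$n_labs_tested, " labs tested (",
      nrow(x$records) - x$n_labs_tested, " skipped); threshold ",
      signif(x$threshold, 3), " = ", x$alpha, "/(", x$n_labs_tested, " x ",
      x$n_scans, ")\n", sep = "")
  sig <- x$records[significant == TRUE]
  cat("  significant: ", nrow(sig), "\n", sep = "")
  invisible(x)
}

#' Write scan results and manifest
#'
#' Tab-delimited results table plus a JSON manifest echoing alpha, the
#' number of labs tested, the family size and the threshold.
#'
#' @param scan A `labwas_scan`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_labwas <- function(scan, out_dir) {
  stopifnot(inherits(scan, "labwas_scan"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(out_dir, "scan_results.tsv")
  data.table::fwrite(scan$records, res_path, sep = "\t")
  man_path <- file.path(out_dir, "scan_manifest.json")
  jsonlite::write_json(
    list(alpha = scan$alpha, n_labs_tested = scan$n_labs_tested,
         n_scans = scan$n_scans, threshold = scan$threshold,
         spline_knots = scan$spline_knots,
         config = unclass(scan$config)),
    man_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(results = res_path, manifest = man_path))
}

#' Manhattan-style scan plot
#'
#' -log10(p) per lab grouped by category; upward triangles for labs the
#' predictor raises, downward for labs it lowers; a red line at the
#' Bonferroni threshold and a blue line at p = 0.05; significant labs
#' labelled.
#'
#' @param result A `labwas_scan` with at least one tested lab.
#' @param output_path Optional file path (`.png`/`.pdf`); when given the
#'   figure is written there.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly.
#' @export
render_scan_plot <- function(result, output_path = NULL, width = 9,
                             height = 5) {
  stopifnot(inherits(result, "labwas_scan"))
  dat <- result$records[is.na(skipped_reason)]
  if (nrow(dat) == 0L) stop("zero tested labs; nothing to plot",
                            call. = FALSE)
  dat <- data.table::copy(dat)
  data.table::setorder(dat, category, lab_id)
  dat[, pos := .I]
  dat[, neglog10p := -log10(p_value)]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = pos, y = neglog10p,
                                         shape = direction,
                                         colour = category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(up = 24, down = 25)) +
    ggplot2::geom_hline(yintercept = -log10(result$threshold),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(0.05), colour = "blue") +
    ggplot2::geom_text(data = dat[significant == TRUE],
                       ggplot2::aes(label = lab_id), vjust = -0.8, size = 2.5,
                       show.legend = FALSE) +
    ggplot2::labs(x = "lab", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(output_path))
    ggplot2::ggsave(output_path, p, width = width, height = height)
  invisible(p)
}
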