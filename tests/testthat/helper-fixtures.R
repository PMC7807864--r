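library(data.table)

## observation table in the canonical in-memory dialect
make_obs <- function(patient_id, lab_id, raw_value, unit, age_at_draw) {
  data.table(patient_id = as.character(patient_id),
             lab_id = as.character(lab_id),
             raw_value = as.character(raw_value),
             unit = as.character(unit),
             age_at_draw = as.numeric(age_at_draw))
}

## rename a generator observation table to the pipeline's column names
as_pipeline_obs <- function(obs) {
  out <- data.table::copy(obs)
  data.table::setnames(out, c("value", "age"), c("raw_value", "age_at_draw"))
  out
}

## write a small delimited file and return its path
write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

## closed-form OLS oracle: normal equations, t-based inference
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tval <- beta / se
  list(beta = as.vector(beta), se = as.vector(se),
       p = as.vector(2 * pt(-abs(tval), df)), df = df)
}
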