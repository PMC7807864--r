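#' Read long-format lab observations from delimited text
#'
#' One row per patient x lab x draw. Raw value and unit strings are preserved
#' byte-for-byte (read as character, never coerced); row order is preserved.
#' The delimiter (comma or tab) is sniffed unless given.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical fields
#'   (`patient_id`, `lab_id`, `value`, `unit`, `age`) to column names in the
#'   file header.
#' @param sep Field separator, or `NULL` to sniff (`\\t` vs `,`).
#' @return A `data.table` with columns `patient_id`, `lab_id`, `raw_value`,
#'   `unit` (character) and `age_at_draw` (numeric years). The number of rows
#'   skipped for unparseable ages is attached as attribute `n_skipped` and
#'   reported via a warning (never silently dropped).
#' @export
read_lab_observations <- function(path,
                                  column_map = c(patient_id = "patient_id",
                                                 lab_id = "lab_id",
                                                 value = "value",
                                                 unit = "unit",
                                                 age = "age"),
                                  sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c("patient_id", "lab_id", "value", "unit", "age")
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map))
    stop("configuration error: column_map lacks field(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  dt <- data.table::fread(path, sep = if (is.null(sep)) "auto" else sep,
                          header = TRUE, colClasses = "character",
                          encoding = "UTF-8", keepLeadingZeros = TRUE)
  absent <- setdiff(unname(column_map[required]), names(dt))
  if (length(absent))
    stop("configuration error: missing column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- dt[, unname(column_map[required]), with = FALSE]
  data.table::setnames(out, c("patient_id", "lab_id", "raw_value", "unit",
                              "age_at_draw"))
  age <- suppressWarnings(as.numeric(out$age_at_draw))
  bad_age <- is.na(age) | !is.finite(age)
  if (any(bad_age)) {
    warning(sum(bad_age), " row(s) with unreadable age skipped (first: row ",
            which(bad_age)[1], ")", call. = FALSE)
  }
  neg <- !bad_age & age < 0
  if (any(neg))
    stop("validation error: negative age_at_draw at row ", which(neg)[1],
         call. = FALSE)
  empty_id <- !bad_age & (out$patient_id == "" | out$lab_id == "")
  if (any(empty_id))
    stop("validation error: empty patient_id/lab_id at row ",
         which(empty_id)[1], call. = FALSE)
  out[, age_at_draw := age]
  out <- out[!bad_age]
  data.table::setattr(out, "n_skipped", sum(bad_age))
  out[]
}

#' Build a unit-synonym table
#'
#' Maps raw unit spellings to a canonical spelling (e.g., the trace-element
#' dialects "mcg/L" and "ug/L" both to the SI micro sign form). Keys and
#' values are case-folded and whitespace-stripped; every canonical unit maps
#' to itself, and the mapping must be a function (one canonical form per raw
#' unit).
#'
#' @param raw Character vector of raw unit spellings.
#' @param canonical Character vector, same length, of canonical spellings.
#' @return A named character vector (class `unit_synonym_table`); names are
#'   normalized raw units, values canonical units.
#' @export
#' @examples
#' unit_synonym_table(c("mcg/L", "ug/L"), c("μg/l", "μg/l"))
unit_synonym_table <- function(raw = character(), canonical = character()) {
  stopifnot(length(raw) == length(canonical))
  key <- normalize_unit(raw)
  val <- normalize_unit(canonical)
  tab <- c(stats::setNames(val, key),
           stats::setNames(unique(val), unique(val)))  # canonical self-maps
  ## function property: each key maps to exactly one value
  if (length(tab)) {
    dup <- tapply(unname(tab), names(tab), function(v) length(unique(v)))
    if (any(dup > 1))
      stop("unit synonym table is not a function; conflicting raw unit(s): ",
           paste(names(dup)[dup > 1], collapse = ", "), call. = FALSE)
  }
  tab <- tab[!duplicated(names(tab))]
  structure(tab, class = "unit_synonym_table")
}

normalize_unit <- function(u) {
  tolower(gsub("[[:space:]]+", "", u))
}

#' Canonicalize unit strings
#'
#' Every unit is case-folded and whitespace-stripped, then replaced by its
#' canonical form when present in the synonym table; unmapped units pass
#' through in normalized form (a distinct canonical unit, not an error).
#' The observation count is unchanged.
#'
#' @param observations Observation `data.table` (see
#'   [read_lab_observations()]).
#' @param synonyms A [unit_synonym_table()], or `NULL` for normalization only.
#' @return The observations with `unit` replaced by its canonical form.
#' @export
canonicalize_units <- function(observations, synonyms = NULL) {
  obs <- data.table::as.data.table(observations)
  u <- normalize_unit(obs$unit)
  if (!is.null(synonyms)) {
    hit <- match(u, names(synonyms))
    u[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  obs[, unit := u]
  obs[]
}

#' Strict numeric parse of raw lab value strings
#'
#' Decimal or scientific notation parses to its value; the words
#' "inf"/"infinity"/"nan" (any case, optional sign) parse but are non-finite;
#' everything else — including comparator-prefixed values such as `"<5"` —
#' is non-numeric and returns `NA`.
#'
#' @param x Character vector of raw values.
#' @return Numeric vector: finite numbers for parseable values, `Inf`/`-Inf`/
#'   `NaN` for the infinite/undefined words, `NA` for non-numeric text.
#' @export
#' @examples
#' parse_lab_values(c("1.0", "2e1", "inf", "<5", "positive"))
parse_lab_values <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  num <- grepl("^[+-]?(\\d+(\\.\\d*)?|\\.\\d+)([eE][+-]?\\d+)?$", x)
  out[num] <- as.numeric(x[num])
  low <- tolower(x)
  out[low %in% c("inf", "+inf", "infinity", "+infinity")] <- Inf
  out[low %in% c("-inf", "-infinity")] <- -Inf
  out[low %in% c("nan", "+nan", "-nan")] <- NaN
  out
}
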