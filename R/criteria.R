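# TyG index, unit conversion, and the three established MetS definitions
# (IDF, NCEP-ATP III, WHO) with South Asian waist cutoffs where applicable.

# mg/dL per mmol/L
.ms_unit_factor <- c(glucose = 18.0, tg = 88.5, hdl = 38.67)

#' Convert analyte concentrations between mg/dL and mmol/L
#'
#' Conversion factors (mg/dL per mmol/L): glucose 18.0, triglycerides 88.5,
#' HDL-C 38.67. Round trips recover the input to within 1e-9 relative error.
#'
#' @param value Positive concentration(s).
#' @param analyte `"glucose"`, `"tg"` or `"hdl"`.
#' @param from,to `"mgdl"` or `"mmol"`.
#' @return Converted value(s).
#' @examples
#' convert_units(150, "tg", "mgdl", "mmol")  # ~1.70 mmol/L
#' @export
convert_units <- function(value, analyte, from, to) {
  analyte <- match.arg(analyte, names(.ms_unit_factor))
  from <- match.arg(from, c("mgdl", "mmol"))
  to <- match.arg(to, c("mgdl", "mmol"))
  if (any(!is.finite(value)) || any(value <= 0))
    ms_stop("concentrations must be positive", "ms_domain_error")
  if (from == to) return(value)
  f <- .ms_unit_factor[[analyte]]
  if (from == "mmol") value * f else value / f
}

#' Triglyceride-glucose (TyG) index
#'
#' `ln(TG[mg/dL] x FBG[mg/dL] / 2)`, a validated surrogate marker of insulin
#' resistance; strictly increasing in both arguments.
#'
#' @param tg Fasting triglycerides in mg/dL (> 0).
#' @param fbg Fasting blood glucose in mg/dL (> 0).
#' @return Unitless index value(s).
#' @examples
#' tyg_index(150, 100)  # ln(7500) = 8.92
#' @export
tyg_index <- function(tg, fbg) {
  if (any(!is.finite(tg)) || any(!is.finite(fbg)) ||
      any(tg <= 0) || any(fbg <= 0))
    ms_stop("tg and fbg must be positive and finite", "ms_domain_error")
  log(tg * fbg / 2)
}

#' MetS component flags for one record
#'
#' The five IDF / NCEP-ATP III components at their printed sex-specific
#' cutoffs: central obesity (WC >= 90 cm men / >= 80 cm women, South Asian),
#' TG >= 150 mg/dL, HDL-C < 40 (men) / < 50 (women) mg/dL, BP >= 130 systolic
#' or >= 85 diastolic, FBG >= 100 mg/dL.
#'
#' @param rec A participant record (canonical mg/dL units).
#' @return Named logical vector `central_obesity`, `high_tg`, `low_hdl`,
#'   `high_bp`, `high_fbg`.
#' @export
mets_component_flags <- function(rec) {
  rec <- as.list(rec)
  sex <- rec$sex
  c(central_obesity =
      record_field(rec, "wc_cm") >= if (sex == "male") 90 else 80,
    high_tg = record_field(rec, "tg") >= 150,
    low_hdl = record_field(rec, "hdl") < if (sex == "male") 40 else 50,
    high_bp = record_field(rec, "sbp_mmhg") >= 130 ||
      record_field(rec, "dbp_mmhg") >= 85,
    high_fbg = record_field(rec, "fbg") >= 100)
}

#' Classify a record under the IDF definition
#'
#' MetS under IDF requires central obesity (mandatory) plus at least two of:
#' elevated TG, low HDL-C, elevated BP, elevated FBG. Without central obesity
#' the result is negative regardless of the other components.
#'
#' @inheritParams mets_component_flags
#' @return Logical, with the component flags attached as attribute `flags`.
#' @export
classify_idf <- function(rec) {
  fl <- mets_component_flags(rec)
  res <- unname(fl["central_obesity"]) &&
    sum(fl[c("high_tg", "low_hdl", "high_bp", "high_fbg")]) >= 2
  structure(res, flags = fl)
}

#' Classify a record under the NCEP-ATP III definition
#'
#' MetS under NCEP-ATP III requires at least three of the five component
#' flags; no component is mandatory.
#'
#' @inheritParams mets_component_flags
#' @return Logical, with the component flags attached as attribute `flags`.
#' @export
classify_ncep <- function(rec) {
  fl <- mets_component_flags(rec)
  structure(sum(fl) >= 3, flags = fl)
}

#' Classify a record under the WHO definition
#'
#' WHO requires diabetes, impaired glucose tolerance or insulin resistance
#' (mandatory) plus at least two of: hypertension (BP >= 140/90 mmHg or
#' antihypertensive medication), dyslipidemia (TG >= 1.7 mmol/L and/or
#' HDL-C < 0.91 mmol/L men / < 1.01 mmol/L women), obesity (BMI >= 30 kg/m2
#' and/or waist-to-hip ratio > 0.90 men / > 0.85 women), or microalbuminuria
#' (urinary albumin excretion >= 20 ug/min). When the decidable factors
#' cannot determine the outcome (e.g. one factor positive, microalbuminuria
#' unknown), the result is `NA` (indeterminate).
#'
#' @inheritParams mets_component_flags
#' @param diabetes_igt_ir Logical; the mandatory glucose-metabolism
#'   component. If `NULL`, taken from the record's `diabetes_igt_ir` field
#'   when present, else derived by the documented convention FBG >= 126
#'   mg/dL.
#' @param microalbuminuria Logical or `NA`; defaults to the record field.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate), with factor flags
#'   attached as attribute `flags`.
#' @export
classify_who <- function(rec, diabetes_igt_ir = NULL,
                         microalbuminuria = NULL) {
  rec <- as.list(rec)
  if (is.null(diabetes_igt_ir)) {
    diabetes_igt_ir <- rec$diabetes_igt_ir
    if (is.null(diabetes_igt_ir) || is.na(diabetes_igt_ir))
      diabetes_igt_ir <- record_field(rec, "fbg") >= 126
  }
  if (is.null(microalbuminuria))
    microalbuminuria <- rec$microalbuminuria %||% NA
  sex <- rec$sex
  meds <- isTRUE(rec$antihypertensive_meds)
  fl <- c(
    who_bp = record_field(rec, "sbp_mmhg") >= 140 ||
      record_field(rec, "dbp_mmhg") >= 90 || meds,
    who_dyslipidemia = record_field(rec, "tg") >=
      convert_units(1.7, "tg", "mmol", "mgdl") ||
      record_field(rec, "hdl") <
        convert_units(if (sex == "male") 0.91 else 1.01, "hdl", "mmol", "mgdl"),
    who_obesity = record_field(rec, "bmi") >= 30 ||
      record_field(rec, "whr") > (if (sex == "male") 0.90 else 0.85),
    microalbuminuria = as.logical(microalbuminuria)
  )
  if (!isTRUE(diabetes_igt_ir)) return(structure(FALSE, flags = fl))
  n_true <- sum(fl, na.rm = TRUE)
  n_unknown <- sum(is.na(fl))
  res <- if (n_true >= 2) TRUE
         else if (n_true + n_unknown < 2) FALSE
         else NA  # indeterminate: unknown factors could tip the count
  structure(res, flags = fl)
}

#' Classify every row of a cohort table
#'
#' @param cohort Data frame in the cohort schema (canonical mg/dL units).
#' @param criteria Character subset of `c("idf", "ncep", "who")`.
#' @return `cohort` with logical columns `mets_idf`, `mets_ncep`, `mets_who`
#'   (the WHO column may contain `NA` for indeterminate rows) and `tyg`
#'   appended.
#' @export
classify_cohort <- function(cohort, criteria = c("idf", "ncep", "who")) {
  stopifnot(is.data.frame(cohort))
  criteria <- match.arg(criteria, several.ok = TRUE)
  rows <- lapply(seq_len(nrow(cohort)),
                 function(i) as.list(cohort[i, , drop = FALSE]))
  if ("idf" %in% criteria)
    cohort$mets_idf <- vapply(rows, function(r) as.logical(classify_idf(r)), TRUE)
  if ("ncep" %in% criteria)
    cohort$mets_ncep <- vapply(rows, function(r) as.logical(classify_ncep(r)), TRUE)
  if ("who" %in% criteria)
    cohort$mets_who <- vapply(rows, function(r) as.logical(classify_who(r)), TRUE)
  cohort$tyg <- tyg_index(cohort$tg, cohort$fbg)
  cohort
}
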