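# Participant records: field registry, validation and derived measures.
# Canonical internal units are mg/dL (FBG, TG, HDL-C), cm, kg and mmHg.

.ms_levels <- list(
  sex            = c("male", "female"),
  fruit_days     = c("gt5", "d2_4", "rarely"),
  veg_days       = c("ge4", "d2_3", "d0_1"),
  activity_days  = c("ge4", "d2_3", "d0_1"),
  sleep_duration = c("ge7", "lt6"),
  sleep_quality  = c("good", "poor"),
  high_fat_meals = c("infrequent", "frequent"),
  smoking        = c("never", "occasional", "daily"),
  alcohol        = c("never", "monthly", "weekly", "daily"),
  stress         = c("low", "moderate", "high")
)

.ms_numeric_fields <- c("age", "height_cm", "weight_kg", "wc_cm", "hip_cm",
                        "sbp_mmhg", "dbp_mmhg", "fbg", "tg", "hdl")

.ms_flag_fields <- c("fam_diabetes", "fam_htn_cvd",
                     "gdm", "pcos", "postmenopausal")

.ms_optional_fields <- c("antihypertensive_meds", "microalbuminuria",
                         "diabetes_igt_ir", "outcome")

#' Required cohort columns
#'
#' Column names a cohort table must carry to be scored and classified:
#' identifier, demographics, anthropometry, blood pressure, fasting
#' biochemistry (mg/dL canonical), the lifestyle/questionnaire categories and
#' family-history / female-specific flags. `unit_system` ("mgdl" or "mmol")
#' declares the units of `fbg`, `tg` and `hdl` for each row at I/O time.
#'
#' @return Character vector of required column names.
#' @export
cohort_required_columns <- function() {
  c("id", "sex", .ms_numeric_fields, names(.ms_levels)[-1],
    .ms_flag_fields, "unit_system")
}

#' Build a single participant record
#'
#' Convenience constructor for one subject's raw measurements and
#' questionnaire responses, validated on construction. Female-specific flags
#' (`gdm`, `pcos`, `postmenopausal`) are accepted but ignored for male
#' records.
#'
#' @param id Participant identifier.
#' @param age Age in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param height_cm,weight_kg,wc_cm,hip_cm Anthropometry (cm, kg, cm, cm).
#' @param sbp_mmhg,dbp_mmhg Systolic and diastolic blood pressure (mmHg).
#' @param fbg,tg,hdl Fasting glucose, triglycerides and HDL-C in mg/dL.
#' @param fruit_days Fruit intake (>=2 servings/day) frequency band:
#'   `"gt5"` (>5 days/week), `"d2_4"` (2-4 days), `"rarely"`.
#' @param veg_days Vegetable intake band: `"ge4"`, `"d2_3"`, `"d0_1"`.
#' @param activity_days Days/week with >=30 min physical activity:
#'   `"ge4"`, `"d2_3"`, `"d0_1"`.
#' @param sleep_duration `"ge7"` (>= 7 h) or `"lt6"` (< 6 h).
#' @param sleep_quality `"good"` or `"poor"`.
#' @param high_fat_meals `"infrequent"` or `"frequent"`.
#' @param smoking `"never"`, `"occasional"` or `"daily"`.
#' @param alcohol `"never"`, `"monthly"`, `"weekly"` or `"daily"`.
#' @param stress Perceived stress band: `"low"`, `"moderate"`, `"high"`.
#' @param fam_diabetes,fam_htn_cvd Family history flags (logical).
#' @param gdm,pcos,postmenopausal Female-specific flags (logical).
#' @param antihypertensive_meds Optional logical; current antihypertensive
#'   medication use (used by the WHO classifier).
#' @param microalbuminuria Optional logical (or `NA`); used by the WHO
#'   classifier.
#' @param diabetes_igt_ir Optional logical; diabetes / impaired glucose
#'   tolerance / insulin resistance status for the WHO classifier.
#' @return A named list of class `participant_record`.
#' @examples
#' r <- participant_record(id = "p1", age = 50, sex = "female",
#'   height_cm = 155, weight_kg = 65, wc_cm = 85, hip_cm = 100,
#'   sbp_mmhg = 132, dbp_mmhg = 86, fbg = 112, tg = 180, hdl = 42)
#' @export
participant_record <- function(id, age, sex, height_cm, weight_kg, wc_cm,
                               hip_cm, sbp_mmhg, dbp_mmhg, fbg, tg, hdl,
                               fruit_days = "gt5", veg_days = "ge4",
                               activity_days = "ge4", sleep_duration = "ge7",
                               sleep_quality = "good",
                               high_fat_meals = "infrequent",
                               smoking = "never", alcohol = "never",
                               stress = "low", fam_diabetes = FALSE,
                               fam_htn_cvd = FALSE, gdm = FALSE, pcos = FALSE,
                               postmenopausal = FALSE,
                               antihypertensive_meds = FALSE,
                               microalbuminuria = NA,
                               diabetes_igt_ir = NA) {
  rec <- list(id = as.character(id), age = age, sex = sex,
              height_cm = height_cm, weight_kg = weight_kg, wc_cm = wc_cm,
              hip_cm = hip_cm, sbp_mmhg = sbp_mmhg, dbp_mmhg = dbp_mmhg,
              fbg = fbg, tg = tg, hdl = hdl, fruit_days = fruit_days,
              veg_days = veg_days, activity_days = activity_days,
              sleep_duration = sleep_duration, sleep_quality = sleep_quality,
              high_fat_meals = high_fat_meals, smoking = smoking,
              alcohol = alcohol, stress = stress,
              fam_diabetes = fam_diabetes, fam_htn_cvd = fam_htn_cvd,
              gdm = gdm, pcos = pcos, postmenopausal = postmenopausal,
              antihypertensive_meds = antihypertensive_meds,
              microalbuminuria = microalbuminuria,
              diabetes_igt_ir = diabetes_igt_ir,
              unit_system = "mgdl")
  problems <- validate_record(rec)
  if (length(problems))
    ms_stop(paste0("invalid participant record: ",
                   paste(problems, collapse = "; ")),
            "ms_record_error")
  structure(rec, class = "participant_record")
}

#' Validate one participant record
#'
#' Checks positivity of continuous measurements, `sbp > dbp`, `age >= 18` and
#' categorical levels. Returns a character vector of problems (empty when the
#' record is valid) rather than throwing, so batch readers can collect
#' row-level diagnostics.
#'
#' @param rec A named list or one-row data frame of record fields.
#' @return Character vector describing each violated constraint.
#' @export
validate_record <- function(rec) {
  rec <- as.list(rec)
  problems <- character()
  for (f in .ms_numeric_fields) {
    v <- rec[[f]]
    if (is.null(v) || !is_scalar_number(v)) {
      problems <- c(problems, sprintf("field '%s' missing or non-numeric", f))
    } else if (v <= 0) {
      problems <- c(problems, sprintf("field '%s' must be strictly positive", f))
    }
  }
  if (is_scalar_number(rec$age) && rec$age < 18)
    problems <- c(problems, "age >= 18 violated")
  if (is_scalar_number(rec$sbp_mmhg) && is_scalar_number(rec$dbp_mmhg) &&
      rec$sbp_mmhg <= rec$dbp_mmhg)
    problems <- c(problems, "sbp > dbp violated")
  for (f in names(.ms_levels)) {
    v <- rec[[f]]
    if (is.null(v) || is.na(v) || !v %in% .ms_levels[[f]])
      problems <- c(problems,
                    sprintf("field '%s' must be one of {%s}", f,
                            paste(.ms_levels[[f]], collapse = ", ")))
  }
  for (f in .ms_flag_fields) {
    v <- rec[[f]]
    # female-specific flags are ignored, not required, for males
    if (f %in% c("gdm", "pcos", "postmenopausal") &&
        identical(rec$sex, "male")) next
    if (is.null(v) || is.na(v) || !is.logical(v))
      problems <- c(problems, sprintf("field '%s' must be TRUE/FALSE", f))
  }
  problems
}

# Field accessor used by the scoring and classification engines; resolves
# derived measures (bmi, whr) and raises a missing-data error naming the
# field otherwise.
record_field <- function(rec, field) {
  rec <- as.list(rec)
  v <- switch(field,
    bmi = {
      h <- record_field(rec, "height_cm")
      record_field(rec, "weight_kg") / (h / 100)^2
    },
    whr = record_field(rec, "wc_cm") / record_field(rec, "hip_cm"),
    rec[[field]]
  )
  if (is.null(v) || (length(v) == 1L && is.na(v))) ms_stop_missing(field)
  v
}

#' Body-mass index and waist-to-hip ratio
#'
#' @param rec A participant record (named list or one-row data frame).
#' @return BMI in kg/m^2, or the unitless waist-to-hip ratio.
#' @export
bmi <- function(rec) record_field(rec, "bmi")

#' @rdname bmi
#' @export
waist_hip_ratio <- function(rec) record_field(rec, "whr")
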