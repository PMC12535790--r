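# Shared fixtures: records built in code.

# A fully unremarkable record; override any field via ...
make_record <- function(...) {
  defaults <- list(
    id = "t1", age = 25, sex = "female", height_cm = 160, weight_kg = 52,
    wc_cm = 70, hip_cm = 95, sbp_mmhg = 110, dbp_mmhg = 70, fbg = 85,
    tg = 90, hdl = 60, fruit_days = "gt5", veg_days = "ge4",
    activity_days = "ge4", sleep_duration = "ge7", sleep_quality = "good",
    high_fat_meals = "infrequent", smoking = "never", alcohol = "never",
    stress = "low", fam_diabetes = FALSE, fam_htn_cvd = FALSE, gdm = FALSE,
    pcos = FALSE, postmenopausal = FALSE, antihypertensive_meds = FALSE,
    microalbuminuria = NA, diabetes_igt_ir = NA, unit_system = "mgdl")
  utils::modifyList(defaults, list(...))
}

# Record engineered to show a chosen IDF/NCEP component-flag combination.
flags_record <- function(obesity, tg, hdl, bp, fbg, sex = "male") {
  make_record(
    sex = sex,
    wc_cm = if (obesity) (if (sex == "male") 95 else 85) else 70,
    tg = if (tg) 200 else 100,
    hdl = if (hdl) (if (sex == "male") 35 else 45) else 65,
    sbp_mmhg = if (bp) 140 else 115,
    dbp_mmhg = if (bp) 90 else 70,
    fbg = if (fbg) 110 else 90)
}

# Random but valid record under a deterministic RNG state.
random_record <- function() {
  sex <- sample(c("male", "female"), 1)
  make_record(
    id = paste0("r", sample.int(1e6, 1)),
    age = runif(1, 18, 80), sex = sex,
    height_cm = runif(1, 145, 190), weight_kg = runif(1, 40, 110),
    wc_cm = runif(1, 60, 120), hip_cm = runif(1, 80, 130),
    sbp_mmhg = runif(1, 100, 180), dbp_mmhg = runif(1, 55, 95),
    fbg = runif(1, 70, 200), tg = runif(1, 50, 400),
    hdl = runif(1, 25, 80),
    fruit_days = sample(c("gt5", "d2_4", "rarely"), 1),
    veg_days = sample(c("ge4", "d2_3", "d0_1"), 1),
    activity_days = sample(c("ge4", "d2_3", "d0_1"), 1),
    sleep_duration = sample(c("ge7", "lt6"), 1),
    sleep_quality = sample(c("good", "poor"), 1),
    high_fat_meals = sample(c("infrequent", "frequent"), 1),
    smoking = sample(c("never", "occasional", "daily"), 1),
    alcohol = sample(c("never", "monthly", "weekly", "daily"), 1),
    stress = sample(c("low", "moderate", "high"), 1),
    fam_diabetes = sample(c(TRUE, FALSE), 1),
    fam_htn_cvd = sample(c(TRUE, FALSE), 1),
    gdm = sample(c(TRUE, FALSE), 1), pcos = sample(c(TRUE, FALSE), 1),
    postmenopausal = sample(c(TRUE, FALSE), 1))
}

# Columns with exact empirical variance 1 and chosen empirical correlation,
# for analytic reliability cases.
exact_cor_pair <- function(n = 40, rho = 0.5) {
  set.seed(99)
  u <- rnorm(n); v <- rnorm(n)
  u <- u - mean(u)
  v <- stats::residuals(stats::lm(v ~ u))
  u <- u / stats::sd(u); v <- v / stats::sd(v)
  cbind(x1 = u, x2 = rho * u + sqrt(1 - rho^2) * v)
}
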