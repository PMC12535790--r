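# The 23-item instrument: matrix loading/validation, item scoring, totals,
# band assignment.

test_that("bundled default matrix loads with the documented structure", {
  m <- load_scoring_matrix()
  expect_s3_class(m, "scoring_matrix")
  expect_length(m$items, 23)
  expect_equal(m$max_score, 28)
  tiers <- table(vapply(m$items, `[[`, "", "tier"))
  expect_equal(as.vector(tiers[c("high", "moderate", "demographic")]),
               c(5L, 16L, 2L))
  expect_false(anyDuplicated(vapply(m$items, `[[`, "", "item_id")) > 0)
})

test_that("matrix validation rejects malformed configurations", {
  cfg <- yaml::read_yaml(default_matrix_path())
  short <- cfg; short$items <- short$items[-1]
  expect_error(load_scoring_matrix(short), "23 items")

  dup <- cfg; dup$items[[2]]$id <- dup$items[[1]]$id
  expect_error(load_scoring_matrix(dup), "duplicate item_id")

  unreachable <- cfg
  unreachable$bands <- list(list(band = "low", min = 0, max = 9),
                            list(band = "moderate", min = 10, max = 28),
                            list(band = "very_high", min = 29, max = Inf))
  expect_error(load_scoring_matrix(unreachable), "unreachable")

  gap <- cfg
  gap$bands <- list(list(band = "low", min = 0, max = 9),
                    list(band = "moderate", min = 11, max = 28))
  expect_error(load_scoring_matrix(gap), "contiguous")

  capped <- cfg
  capped$bands <- list(list(band = "low", min = 0, max = 25))
  expect_error(load_scoring_matrix(capped), "maximum attainable")

  overweight <- cfg
  overweight$items[[8]]$rule$points$d0_1 <- 2  # moderate tier awards > 1
  expect_error(load_scoring_matrix(overweight), "points must lie")
})

test_that("individual items score per the published cutoffs", {
  m <- load_scoring_matrix()
  wc <- m$items$wc
  expect_identical(score_item(wc, make_record(sex = "female", wc_cm = 85)), 2L)
  expect_identical(score_item(wc, make_record(sex = "female", wc_cm = 70)), 0L)
  expect_identical(score_item(wc, make_record(sex = "male", wc_cm = 85)), 0L)
  expect_identical(score_item(wc, make_record(sex = "male", wc_cm = 90)), 2L)
  expect_identical(
    score_item(m$items$sleep_duration, make_record(sleep_duration = "lt6")), 1L)
  # BP fires on either branch of the OR
  expect_identical(score_item(m$items$bp, make_record(sbp_mmhg = 131)), 2L)
  expect_identical(
    score_item(m$items$bp, make_record(sbp_mmhg = 120, dbp_mmhg = 86)), 2L)
  # female-specific item on a male record: 0, not an error
  expect_identical(score_item(m$items$pcos, make_record(sex = "male",
                                                        pcos = NA)), 0L)
  rec <- make_record(); rec$fbg <- NULL
  expect_error(score_item(m$items$fbg, rec), "fbg",
               class = "ms_missing_data_error")
})

test_that("participant totals match hand-applied scoring", {
  m <- load_scoring_matrix()
  # all-normal young female with favorable lifestyle: nothing fires
  r0 <- score_participant(m, make_record())
  expect_identical(r0$total_score, 0L)
  expect_identical(r0$band, "low")

  # 50-year-old woman with all five clinical factors and nothing else:
  # 5 x 2 + age 1 = 11, moderate
  r11 <- score_participant(m, make_record(
    age = 50, sex = "female", wc_cm = 85, hip_cm = 105, fbg = 112, tg = 180,
    hdl = 42, sbp_mmhg = 132, dbp_mmhg = 86, height_cm = 155, weight_kg = 50))
  expect_identical(r11$total_score, 11L)
  expect_identical(r11$band, "moderate")
  expect_identical(sum(r11$item_points), 11L)

  # every item at its maximum for one person: a female reaches 27 (the
  # male-sex point is unattainable for her), landing in very_high;
  # the matrix-level maximum over all items is 28
  rmax <- score_participant(m, make_record(
    age = 55, sex = "female", wc_cm = 95, hip_cm = 95, fbg = 140, tg = 250,
    hdl = 30, sbp_mmhg = 150, dbp_mmhg = 95, height_cm = 150, weight_kg = 75,
    fruit_days = "rarely", veg_days = "d0_1", activity_days = "d0_1",
    sleep_duration = "lt6", sleep_quality = "poor",
    high_fat_meals = "frequent", smoking = "daily", alcohol = "weekly",
    stress = "high", fam_diabetes = TRUE, fam_htn_cvd = TRUE, gdm = TRUE,
    pcos = TRUE, postmenopausal = TRUE))
  expect_identical(rmax$total_score, 27L)
  expect_identical(rmax$band, "very_high")
  expect_equal(m$max_score, 28)

  # missing lifestyle response: hard error by default, zero-with-warning
  # under the opt-in flag, never for high-tier items
  rec <- make_record(); rec$stress <- NULL
  expect_error(score_participant(m, rec), "stress")
  expect_warning(out <- score_participant(m, rec,
                                          missing_lifestyle_zero = TRUE),
                 "stress")
  expect_identical(out$total_score, 0L)
  rec2 <- make_record(); rec2$hdl <- NULL
  expect_error(score_participant(m, rec2, missing_lifestyle_zero = TRUE),
               "hdl")
})

test_that("band assignment closes the published gaps and bounds the range", {
  m <- load_scoring_matrix()
  expect_identical(assign_band(5, m), "low")
  expect_identical(assign_band(12, m), "moderate")
  expect_identical(assign_band(9, m), "low")        # gap score 9 -> low
  expect_identical(assign_band(26, m), "very_high") # gap score 26 -> very_high
  # boundary oracle over the full attainable range
  oracle <- function(s) if (s <= 9) "low" else if (s <= 17) "moderate"
                        else if (s <= 25) "high" else "very_high"
  for (s in 0:28) expect_identical(assign_band(s, m), oracle(s))
  expect_error(assign_band(-1, m), class = "ms_range_error")
  expect_error(assign_band(29, m), class = "ms_range_error")
  # band index is non-decreasing in the total
  idx <- match(vapply(0:28, assign_band, "", matrix = m), band_levels())
  expect_true(all(diff(idx) >= 0))
})

test_that("totals are additive, deterministic, and monotone in risk factors", {
  m <- load_scoring_matrix()
  set.seed(424)
  for (i in 1:25) {
    rec <- random_record()
    res <- score_participant(m, rec)
    by_item <- vapply(m$items, score_item, 0L, rec = rec)
    expect_identical(res$total_score, as.integer(sum(by_item)))
    expect_identical(res, score_participant(m, rec))  # determinism
  }
  # worsening one field across its cutoff never lowers the total
  worsenings <- list(
    function(r) { r$wc_cm <- 130; r }, function(r) { r$fbg <- 250; r },
    function(r) { r$tg <- 450; r }, function(r) { r$hdl <- 20; r },
    function(r) { r$sbp_mmhg <- 190; r }, function(r) { r$stress <- "high"; r },
    function(r) { r$sleep_duration <- "lt6"; r },
    function(r) { r$fam_diabetes <- TRUE; r },
    function(r) { r$activity_days <- "d0_1"; r })
  set.seed(77)
  for (i in 1:15) {
    rec <- random_record()
    base <- score_participant(m, rec)$total_score
    for (w in worsenings)
      expect_gte(score_participant(m, w(rec))$total_score, base)
  }
})

test_that("vectorized cohort scoring agrees with per-record scoring", {
  m <- load_scoring_matrix()
  coh <- generate_cohort(cohort_spec(n = 60, seed = 5))
  sc <- score_cohort(m, coh, keep_items = TRUE)
  for (i in c(1, 7, 33, 60)) {
    res <- score_participant(m, coh[i, , drop = FALSE])
    expect_identical(sc$total_score[i], res$total_score)
    expect_identical(as.character(sc$band[i]), res$band)
  }
  item_cols <- grep("^item_", names(sc), value = TRUE)
  expect_identical(as.integer(rowSums(sc[item_cols])), sc$total_score)
})
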