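# Applying the instrument: per-item points, totals, bands.

.resolve_cutoff <- function(cutoff, sex) {
  if (is.list(cutoff)) as.numeric(cutoff[[sex]]) else as.numeric(cutoff)
}

.eval_condition <- function(cond, rec) {
  v <- record_field(rec, cond$field)
  cut <- .resolve_cutoff(cond$cutoff, as.list(rec)$sex)
  switch(cond$op,
         ">=" = v >= cut, ">" = v > cut, "<=" = v <= cut, "<" = v < cut)
}

#' Score one instrument item for one participant
#'
#' Applies a single item's response-to-points rule to a record. Items marked
#' female-specific award 0 points to male records (this is not an error).
#' A missing required field raises a missing-data error naming the field.
#'
#' @param item One element of `scoring_matrix$items`.
#' @param rec A participant record (named list or one-row data frame).
#' @return Integer points awarded, in `[0, item$weight]`.
#' @export
score_item <- function(item, rec) {
  rec <- as.list(rec)
  if (item$applies_to_sex == "female" && identical(rec$sex, "male"))
    return(0L)
  rule <- item$rule
  pts <- switch(rule$kind,
    threshold = if (.eval_condition(rule, rec)) item$weight else 0L,
    any_of = if (any(vapply(rule$conditions, .eval_condition, TRUE,
                            rec = rec))) item$weight else 0L,
    categorical = {
      v <- record_field(rec, rule$field)
      p <- rule$points[[v]]
      if (is.null(p)) 0L else as.integer(p)
    },
    flag = if (isTRUE(record_field(rec, rule$field))) item$weight else 0L
  )
  as.integer(pts)
}

#' Score one participant on the full instrument
#'
#' Applies every item of the scoring matrix to a record, sums the awarded
#' points exactly, and assigns the risk band.
#'
#' @param matrix A `scoring_matrix`.
#' @param rec A participant record.
#' @param missing_lifestyle_zero If `TRUE`, a missing response on a
#'   moderate-tier lifestyle item scores 0 with a warning instead of raising
#'   an error. Never applied to high-tier clinical items.
#' @return A `spectrum_result`: list with `participant_id`, `item_points`
#'   (named integer vector over the 23 items), `total_score`, `band`.
#' @examples
#' m <- load_scoring_matrix()
#' r <- participant_record(id = "p1", age = 50, sex = "female",
#'   height_cm = 155, weight_kg = 50, wc_cm = 85, hip_cm = 102,
#'   sbp_mmhg = 132, dbp_mmhg = 86, fbg = 112, tg = 180, hdl = 42)
#' score_participant(m, r)$total_score
#' @export
score_participant <- function(matrix, rec, missing_lifestyle_zero = FALSE) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  rec <- as.list(rec)
  pts <- vapply(matrix$items, function(item) {
    tryCatch(score_item(item, rec),
             ms_missing_data_error = function(e) {
               if (missing_lifestyle_zero && item$tier != "high") {
                 warning(sprintf(
                   "participant %s: item '%s' missing (%s); scored 0",
                   rec$id %||% "?", item$item_id, conditionMessage(e)),
                   call. = FALSE)
                 0L
               } else {
                 ms_stop(sprintf("item '%s': %s", item$item_id,
                                 conditionMessage(e)),
                         "ms_missing_data_error")
               }
             })
  }, integer(1))
  total <- as.integer(sum(pts))
  structure(list(participant_id = rec$id %||% NA_character_,
                 item_points = pts, total_score = total,
                 band = assign_band(total, matrix)),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("participant %s: total score %d, band %s\n",
              x$participant_id, x$total_score, x$band))
  fired <- x$item_points[x$item_points > 0]
  if (length(fired))
    cat("  points:", paste(sprintf("%s=%d", names(fired), fired),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Score every row of a cohort table
#'
#' @param matrix A `scoring_matrix`.
#' @param cohort Data frame with the columns of [cohort_required_columns()]
#'   (values already in canonical mg/dL units, as produced by
#'   [generate_cohort()] or [read_cohort()]).
#' @param keep_items If `TRUE`, append one `item_<id>` column per instrument
#'   item with the awarded points.
#' @inheritParams score_participant
#' @return `cohort` with `total_score` (integer) and `band` (factor with
#'   levels [band_levels()]) columns appended.
#' @export
score_cohort <- function(matrix, cohort, keep_items = FALSE,
                         missing_lifestyle_zero = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (missing_lifestyle_zero) {
    # per-record path so the per-item warning policy applies
    res <- lapply(seq_len(nrow(cohort)), function(i)
      score_participant(matrix, cohort[i, , drop = FALSE],
                        missing_lifestyle_zero = TRUE))
    ip <- do.call(rbind, lapply(res, `[[`, "item_points"))
  } else {
    ip <- vapply(matrix$items, .score_item_vec, integer(nrow(cohort)),
                 cohort = cohort)
    if (nrow(cohort) == 1L) ip <- matrix(ip, nrow = 1L,
                                         dimnames = list(NULL, names(matrix$items)))
  }
  total <- as.integer(rowSums(ip))
  if (any(total > matrix$max_score))
    ms_stop("total score above maximum attainable", "ms_range_error")
  cohort$total_score <- total
  b <- matrix$bands
  cohort$band <- factor(
    b$band[findInterval(total, b$min)], levels = band_levels())
  if (keep_items) {
    colnames(ip) <- paste0("item_", colnames(ip))
    cohort <- cbind(cohort, as.data.frame(ip))
  }
  cohort
}

# Column-wise evaluation of one item over a whole cohort; agrees with
# score_item record by record (asserted in the test suite).
.cohort_field <- function(cohort, field) {
  v <- switch(field,
    bmi = cohort$weight_kg / (cohort$height_cm / 100)^2,
    whr = cohort$wc_cm / cohort$hip_cm,
    cohort[[field]])
  if (is.null(v) || anyNA(v)) ms_stop_missing(field)
  v
}

.score_item_vec <- function(item, cohort) {
  rule <- item$rule
  n_all <- nrow(cohort)
  applicable <- if (item$applies_to_sex == "female")
    cohort$sex == "female" else rep(TRUE, n_all)
  cohort <- cohort[applicable, , drop = FALSE]
  if (nrow(cohort) == 0L) return(integer(n_all))
  cond_vec <- function(cond) {
    v <- .cohort_field(cohort, cond$field)
    cut <- if (is.list(cond$cutoff)) {
      ifelse(cohort$sex == "male", as.numeric(cond$cutoff$male),
             as.numeric(cond$cutoff$female))
    } else as.numeric(cond$cutoff)
    switch(cond$op, ">=" = v >= cut, ">" = v > cut,
           "<=" = v <= cut, "<" = v < cut)
  }
  pts <- switch(rule$kind,
    threshold = item$weight * cond_vec(rule),
    any_of = item$weight *
      (Reduce(`|`, lapply(rule$conditions, cond_vec))),
    categorical = {
      v <- .cohort_field(cohort, rule$field)
      p <- unlist(rule$points)
      out <- p[v]
      out[is.na(out)] <- 0
      out
    },
    flag = item$weight * (.cohort_field(cohort, rule$field) %in% TRUE))
  out <- integer(n_all)
  out[applicable] <- as.integer(pts)
  out
}
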