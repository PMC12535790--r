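# Cohort CSV reader/writer with unit handling, and the end-to-end pipeline
# (simulate -> score -> classify -> validate). CSV dialect is fixed:
# UTF-8, comma-delimited, '.' decimal.

#' Read a cohort CSV
#'
#' Parses a cohort table, converts rows recorded in mmol/L to the canonical
#' mg/dL units (glucose x18.0, TG x88.5, HDL-C x38.67), validates every row
#' against the record invariants, and separates invalid rows into a
#' row-numbered rejection log -- rows are never silently dropped.
#'
#' @param path CSV file with the columns of [cohort_required_columns()];
#'   optional columns (`antihypertensive_meds`, `microalbuminuria`,
#'   `diabetes_igt_ir`, `outcome`) are carried through when present.
#' @return List with `cohort` (valid rows, canonical units), `rejected`
#'   (data frame with `row`, `id`, `reason`), and `n_in`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    ms_stop(sprintf("file not found: %s", path), "ms_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  required <- cohort_required_columns()
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    ms_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")), "ms_schema_error")
  if (anyDuplicated(names(df)))
    ms_stop("duplicate column names", "ms_schema_error")
  for (f in .ms_flag_fields)
    df[[f]] <- as.logical(df[[f]])
  for (f in intersect(.ms_optional_fields, names(df)))
    if (f != "outcome") df[[f]] <- as.logical(df[[f]])

  bad_unit <- !df$unit_system %in% c("mgdl", "mmol")
  mmol <- df$unit_system == "mmol" & !bad_unit
  if (any(mmol)) {
    df$fbg[mmol] <- convert_units(df$fbg[mmol], "glucose", "mmol", "mgdl")
    df$tg[mmol] <- convert_units(df$tg[mmol], "tg", "mmol", "mgdl")
    df$hdl[mmol] <- convert_units(df$hdl[mmol], "hdl", "mmol", "mgdl")
    df$unit_system[mmol] <- "mgdl"
  }

  reasons <- vapply(seq_len(nrow(df)), function(i) {
    if (bad_unit[i]) return("unit_system must be 'mgdl' or 'mmol'")
    paste(validate_record(df[i, , drop = FALSE]), collapse = "; ")
  }, "")
  ok <- !nzchar(reasons)
  rejected <- data.frame(row = which(!ok),
                         id = as.character(df$id[!ok]),
                         reason = reasons[!ok], stringsAsFactors = FALSE)
  cohort <- df[ok, , drop = FALSE]
  rownames(cohort) <- NULL
  if (nrow(rejected))
    message(sprintf("read_cohort: rejected %d of %d row(s)",
                    nrow(rejected), nrow(df)))
  list(cohort = cohort, rejected = rejected, n_in = nrow(df))
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full simulate-score-classify-validate pipeline
#'
#' Generates (or reads) a cohort, scores it with the instrument, classifies
#' every record under the IDF/NCEP/WHO definitions, runs the known-groups
#' validation, and writes the artifacts: `cohort.csv`, `scored.csv`,
#' `report.json` and `report.txt`, each stamped with the matrix version and
#' seed. Deterministic under a fixed seed. Any stage failure aborts with the
#' stage name in the error message.
#'
#' @param out_dir Output directory (created if absent).
#' @param n,seed Cohort size and root seed (ignored when `input` is given).
#' @param input Optional path to an existing cohort CSV instead of
#'   simulation.
#' @param matrix_source Scoring-matrix config; default the bundled matrix.
#' @return Invisibly, a list with the report, the scored cohort and the
#'   artifact paths.
#' @export
run_pipeline <- function(out_dir, n = 148, seed = 1, input = NULL,
                         matrix_source = default_matrix_path()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ms_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "ms_pipeline_error"))
  }
  matrix <- stage("load_matrix", load_scoring_matrix(matrix_source))
  cohort <- if (is.null(input)) {
    stage("simulate", generate_cohort(cohort_spec(n = n, seed = seed)))
  } else {
    rd <- stage("read", read_cohort(input))
    stopifnot(rd$n_in == nrow(rd$cohort) + nrow(rd$rejected))
    rd$cohort
  }
  message(sprintf("pipeline: seed=%d matrix=%s rows=%d",
                  seed, matrix$version, nrow(cohort)))
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)

  scored <- stage("score", score_cohort(matrix, cohort))
  scored <- stage("classify", classify_cohort(scored))
  scored_path <- file.path(out_dir, "scored.csv")
  write_cohort(scored, scored_path)

  report <- stage("validate", run_known_groups_validation(cohort, matrix))

  json <- list(
    meta = list(matrix_version = matrix$version, seed = seed,
                n = report$n),
    band_distribution = report$band_distribution,
    markers = lapply(report$markers, function(a)
      list(F = a$F, df = c(a$df_between, a$df_within), p = a$p,
           eta_squared = a$eta_squared, group_stats = a$group_stats,
           tukey = a$tukey)),
    score_tyg = report$score_tyg,
    mets_prevalence = list(idf = mean(scored$mets_idf),
                           ncep = mean(scored$mets_ncep),
                           who = mean(scored$mets_who, na.rm = TRUE))
  )
  report_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, report_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  report_txt <- file.path(out_dir, "report.txt")
  txt <- c(sprintf("metspectrum pipeline report (matrix %s, seed %d)",
                   matrix$version, seed),
           utils::capture.output(print(report)))
  writeLines(txt, report_txt)
  invisible(list(report = report, scored = scored,
                 paths = c(cohort = cohort_path, scored = scored_path,
                           report_json = report_json,
                           report_txt = report_txt)))
}
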