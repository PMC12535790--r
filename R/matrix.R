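# The configurable scoring matrix: loading, validation, band assignment.

.ms_tier_weight <- c(high = 2L, moderate = 1L, demographic = 1L)
.ms_bands <- c("low", "moderate", "high", "very_high")

#' Load and validate a scoring matrix
#'
#' Reads a scoring-matrix configuration (YAML or JSON) declaring the
#' instrument items, their tiers and response-to-point rules, and the risk
#' band cutoffs, and validates it: 23 items with unique ids, per-response
#' points within the tier weight, strictly increasing contiguous bands that
#' cover 0 up to the maximum attainable total, and a reachable top band.
#'
#' @param source Path to a YAML/JSON file, a YAML string, or an already
#'   parsed list with elements `version`, `items`, `bands`. The default loads
#'   the instrument bundled with the package.
#' @return A `scoring_matrix` object: list with `version`, `items` (each a
#'   validated item definition), `bands` (data frame with `band`, `min`,
#'   `max`) and `max_score`, the maximum attainable total (28 for the default
#'   instrument).
#' @examples
#' m <- load_scoring_matrix()
#' m$max_score
#' @export
load_scoring_matrix <- function(source = default_matrix_path()) {
  cfg <- if (is.list(source)) {
    source
  } else if (length(source) == 1L && file.exists(source)) {
    if (grepl("\\.json$", source)) jsonlite::read_json(source,
                                                      simplifyVector = FALSE)
    else yaml::read_yaml(source)
  } else {
    yaml::yaml.load(source)
  }
  if (is.null(cfg$items) || is.null(cfg$bands))
    ms_stop("scoring-matrix config must declare 'items' and 'bands'",
            "ms_matrix_error")

  items <- lapply(cfg$items, .validate_item)
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids))
    ms_stop(sprintf("duplicate item_id: %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
            "ms_matrix_error")
  if (length(items) != 23L)
    ms_stop(sprintf("the instrument defines 23 items; config declares %d",
                    length(items)), "ms_matrix_error")
  names(items) <- ids
  max_score <- sum(vapply(items, `[[`, 0L, "weight"))

  bands <- do.call(rbind, lapply(cfg$bands, function(b) {
    data.frame(band = as.character(b$band), min = as.numeric(b$min),
               max = as.numeric(b$max))
  }))
  if (!all(bands$band %in% .ms_bands) || anyDuplicated(bands$band))
    ms_stop(sprintf("bands must be distinct names among {%s}",
                    paste(.ms_bands, collapse = ", ")), "ms_matrix_error")
  bands <- bands[order(bands$min), , drop = FALSE]
  rownames(bands) <- NULL
  if (bands$min[1] != 0)
    ms_stop("lowest band must start at score 0", "ms_matrix_error")
  if (any(bands$max < bands$min))
    ms_stop("each band needs max >= min", "ms_matrix_error")
  if (nrow(bands) > 1 &&
      any(bands$min[-1] != bands$max[-nrow(bands)] + 1))
    ms_stop("band cutoffs must be contiguous and strictly increasing",
            "ms_matrix_error")
  if (max(bands$max) < max_score)
    ms_stop(sprintf("bands top out at %d but maximum attainable score is %d",
                    max(bands$max), max_score), "ms_matrix_error")
  if (bands$min[nrow(bands)] > max_score)
    ms_stop(sprintf(
      "top band '%s' starts at %d, above the maximum attainable score %d (unreachable)",
      bands$band[nrow(bands)], bands$min[nrow(bands)], max_score),
      "ms_matrix_error")

  structure(list(version = as.character(cfg$version %||% "unversioned"),
                 items = items, bands = bands, max_score = max_score),
            class = "scoring_matrix")
}

#' @rdname load_scoring_matrix
#' @export
default_matrix_path <- function() {
  system.file("extdata", "default_matrix.yaml", package = "metspectrum",
              mustWork = TRUE)
}

.validate_item <- function(item) {
  for (f in c("id", "domain", "tier", "rule"))
    if (is.null(item[[f]]))
      ms_stop(sprintf("item is missing '%s'", f), "ms_matrix_error")
  tier <- match.arg(item$tier, names(.ms_tier_weight))
  weight <- .ms_tier_weight[[tier]]
  rule <- item$rule
  kind <- match.arg(rule$kind, c("threshold", "any_of", "categorical", "flag"))
  field <- if (kind == "any_of") {
    vapply(rule$conditions, `[[`, "", "field")
  } else rule$field
  if (kind == "categorical") {
    pts <- unlist(rule$points)
    if (any(pts < 0) || any(pts > weight))
      ms_stop(sprintf("item '%s': points must lie in [0, %d]", item$id, weight),
              "ms_matrix_error")
    lv <- .ms_levels[[rule$field]]
    if (!is.null(lv) && !all(names(pts) %in% lv))
      ms_stop(sprintf("item '%s': unknown response categories %s", item$id,
                      paste(setdiff(names(pts), lv), collapse = ", ")),
              "ms_matrix_error")
    # levels absent from the map award 0, so the map is exhaustive by default
  }
  if (kind %in% c("threshold", "any_of")) {
    conds <- if (kind == "any_of") rule$conditions else list(rule)
    for (cond in conds) {
      if (is.null(cond$op) || !cond$op %in% c(">=", ">", "<=", "<"))
        ms_stop(sprintf("item '%s': op must be one of >=, >, <=, <", item$id),
                "ms_matrix_error")
      if (is.null(cond$cutoff))
        ms_stop(sprintf("item '%s': threshold rule needs a cutoff", item$id),
                "ms_matrix_error")
    }
  }
  list(item_id = as.character(item$id), domain = as.character(item$domain),
       tier = tier, weight = weight,
       applies_to_sex = match.arg(item$applies_to_sex %||% "all",
                                  c("all", "female")),
       rule = rule, field = field)
}

#' Assign a risk band to a total score
#'
#' Maps an integer total score onto the instrument's risk bands. With the
#' default matrix: low for scores 0-9, moderate 10-17, high 18-25,
#' very high 26 and above (the published cutoffs leave 9 and 26 unassigned;
#' they are absorbed into the adjacent lower and upper bands respectively so
#' the intervals are contiguous).
#'
#' @param total_score Integer total in `[0, matrix$max_score]`.
#' @param matrix A `scoring_matrix`.
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very_high"` (a factor
#'   level ordering is available via [band_levels()]).
#' @examples
#' assign_band(12, load_scoring_matrix())
#' @export
assign_band <- function(total_score, matrix = load_scoring_matrix()) {
  stopifnot(inherits(matrix, "scoring_matrix"))
  if (!is_scalar_number(total_score) || total_score != round(total_score))
    ms_stop("total_score must be a single integer", "ms_range_error")
  if (total_score < 0 || total_score > matrix$max_score)
    ms_stop(sprintf("total_score %d outside attainable range [0, %d]",
                    total_score, matrix$max_score), "ms_range_error")
  b <- matrix$bands
  b$band[total_score >= b$min & total_score <= b$max][1]
}

#' @rdname assign_band
#' @export
band_levels <- function() .ms_bands

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("MetS spectrum scoring matrix (version %s)\n", x$version))
  cat(sprintf("  %d items, maximum attainable score %d\n",
              length(x$items), x$max_score))
  tiers <- table(vapply(x$items, `[[`, "", "tier"))
  cat("  tiers:", paste(sprintf("%s=%d", names(tiers), tiers), collapse = ", "),
      "\n")
  apply(x$bands, 1, function(b)
    cat(sprintf("  band %-9s %s-%s\n", b["band"], b["min"], b["max"])))
  invisible(x)
}
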