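# Known-groups and power analyses: one-way ANOVA with Tukey HSD and
# eta-squared, chi-square, Pearson correlation with Fisher-z intervals, and
# the two sample-size calculators (Fisher-z correlation design and
# noncentral-F ANOVA design).

#' Required sample size for detecting a Pearson correlation
#'
#' Fisher-z design: `n = ceil((z_{1-a/2} + z_{1-b})^2 / atanh(r)^2) + 3`.
#' With the planning values r = 0.30, two-sided alpha = 0.05 and power 0.80
#' this returns 85.
#'
#' @param r Assumed population correlation, 0 < |r| < 1.
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @return Required sample size (integer).
#' @examples
#' n_for_correlation(0.30)  # 85
#' @export
n_for_correlation <- function(r, alpha = 0.05, power = 0.80) {
  if (!is_scalar_number(r) || abs(r) >= 1)
    ms_stop("r must satisfy |r| < 1", "ms_spec_error")
  if (r == 0)
    ms_stop("r = 0 requires an infinite sample size", "ms_spec_error")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1 ||
      !is_scalar_number(power) || power <= 0 || power >= 1)
    ms_stop("alpha and power must lie strictly in (0, 1)", "ms_spec_error")
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2
  as.integer(ceiling(z / atanh(r)^2) + 3L)
}

#' Power of a one-way ANOVA at a given total sample size
#'
#' Noncentral-F power with equal allocation: noncentrality `lambda = f^2 N`,
#' degrees of freedom `(k-1, N-k)`.
#'
#' @param N Total sample size (equal allocation over `k` groups).
#' @param f Cohen's f effect size (> 0).
#' @param k Number of groups (>= 2).
#' @param alpha Two-sided type-I error level.
#' @return Power in (0, 1).
#' @export
anova_power <- function(N, f, k, alpha = 0.05) {
  stopifnot(N > k)
  1 - stats::pf(stats::qf(1 - alpha, k - 1, N - k), k - 1, N - k,
                ncp = f^2 * N)
}

#' Required total sample size for a one-way ANOVA
#'
#' Smallest total N divisible by `k` (equal allocation) whose noncentral-F
#' power reaches the target. With Cohen's f = 0.25, k = 3, alpha = 0.05 and
#' power 0.80 this returns 159.
#'
#' @param f Cohen's f effect size (> 0).
#' @param k Number of groups (>= 2).
#' @param alpha Two-sided type-I error level.
#' @param power Target power.
#' @param n_max Search ceiling; exceeding it raises an error.
#' @return Required total sample size (integer, divisible by `k`).
#' @examples
#' n_for_anova(0.25, 3)  # 159
#' @export
n_for_anova <- function(f, k, alpha = 0.05, power = 0.80, n_max = 1e6) {
  if (!is_scalar_number(f) || f <= 0)
    ms_stop("f must be positive", "ms_spec_error")
  if (!is_scalar_number(k) || k < 2 || k != round(k))
    ms_stop("k must be an integer >= 2", "ms_spec_error")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1 ||
      !is_scalar_number(power) || power <= 0 || power >= 1)
    ms_stop("alpha and power must lie strictly in (0, 1)", "ms_spec_error")
  N <- k * 2L
  while (N <= n_max) {
    if (anova_power(N, f, k, alpha) >= power) return(as.integer(N))
    N <- N + k
  }
  ms_stop(sprintf("target power not reached by N = %d", as.integer(n_max)),
          "ms_spec_error")
}

#' Classical one-way ANOVA with Tukey HSD and eta-squared
#'
#' Fixed-effects decomposition (`stats::aov`) with all-pairs Tukey honest
#' significant differences from the studentized-range distribution, group
#' summaries and the effect size `eta^2 = SS_between / SS_total`.
#'
#' @param groups List of two or more numeric vectors (each with >= 2
#'   values), or a numeric vector plus `g`, a grouping factor.
#' @param g Optional grouping factor when `groups` is a single vector.
#' @param welch If `TRUE`, additionally report the Welch-corrected test
#'   (`stats::oneway.test`) as `welch_F` / `welch_p`.
#' @return An `ms_anova` object: `F`, `df_between`, `df_within`, `p`,
#'   `eta_squared`, `group_stats` (n/mean/sd per group), `tukey` (per-pair
#'   difference, interval and adjusted p).
#' @examples
#' a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
#' a$F; a$eta_squared
#' @export
anova_oneway <- function(groups, g = NULL, welch = FALSE) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2)
    ms_stop("need at least two groups", "ms_insufficient_groups_error")
  if (any(vapply(groups, length, 0L) < 2))
    ms_stop("each group needs at least two values", "ms_insufficient_groups_error")
  if (all(vapply(groups, stats::var, 0) == 0))
    ms_stop("zero within-group variance in every group", "ms_degenerate_error")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    grp = factor(rep(names(groups), vapply(groups, length, 0L)),
                 levels = names(groups)))
  fit <- stats::aov(y ~ grp, data = dat)
  tab <- stats::anova(fit)
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  tk <- stats::TukeyHSD(fit)$grp
  group_stats <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0), row.names = NULL)
  out <- list(F = tab$`F value`[1], df_between = tab$Df[1],
              df_within = tab$Df[2], p = tab$`Pr(>F)`[1],
              eta_squared = ssb / (ssb + ssw), group_stats = group_stats,
              tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                                 lwr = tk[, "lwr"], upr = tk[, "upr"],
                                 p_adj = tk[, "p adj"], row.names = NULL))
  if (welch) {
    w <- stats::oneway.test(y ~ grp, data = dat)
    out$welch_F <- unname(w$statistic); out$welch_p <- w$p.value
  }
  structure(out, class = "ms_anova")
}

#' @export
print.ms_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta_squared))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Standard product-moment correlation; the confidence interval is
#' `tanh(atanh(r) +/- z_{1-a/2} / sqrt(n-3))` and the p-value is from the
#' t distribution on n-2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, n >= 4, each with nonzero variance.
#' @param conf_level Confidence level for the interval.
#' @return List with `r`, `ci` (length 2), `p`, `n`.
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (n < 4) ms_stop("need at least 4 complete pairs", "ms_spec_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ms_stop("correlation undefined for constant input", "ms_degenerate_error")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = n)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c contingency table with
#' `(r-1)(c-1)` degrees of freedom.
#'
#' @param tab Matrix (or table) of nonnegative counts, at least 2 x 2, with
#'   no all-zero row or column margin.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @examples
#' chi_square_independence(matrix(c(10, 20, 20, 10), 2))$statistic  # 6.667
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    ms_stop("contingency table must be at least 2 x 2", "ms_spec_error")
  if (any(tab < 0)) ms_stop("counts must be nonnegative", "ms_spec_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    ms_stop("zero row or column margin", "ms_degenerate_error")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Known-groups validation of the instrument on a cohort
#'
#' Scores the cohort, assigns risk bands, then runs a one-way ANOVA (with
#' Tukey HSD and eta-squared) of each metabolic marker (SBP, DBP, WC, FBG,
#' TG, HDL-C and the TyG index) across the occupied bands, reports the band
#' distribution, and the Pearson correlation (with Fisher-z interval) of the
#' total score with the TyG index.
#'
#' @param cohort Cohort data frame in canonical units.
#' @param matrix A `scoring_matrix`.
#' @param min_band_n Bands with fewer members are dropped from the ANOVAs.
#' @return A `mets_validation_report`: `band_distribution` (n and percent per
#'   band), `markers` (named list of `ms_anova`), `score_tyg` (Pearson
#'   result), `n`, `matrix_version`, and the scored cohort as `scored`.
#' @export
run_known_groups_validation <- function(cohort, matrix = load_scoring_matrix(),
                                        min_band_n = 2L) {
  scored <- score_cohort(matrix, cohort)
  scored$tyg <- tyg_index(scored$tg, scored$fbg)
  counts <- table(scored$band)
  band_distribution <- data.frame(
    band = names(counts), n = as.integer(counts),
    percent = 100 * as.integer(counts) / nrow(scored))
  keep <- names(counts)[counts >= min_band_n]
  if (length(keep) < 2)
    ms_stop("fewer than two occupied risk bands; known-groups ANOVA undefined",
            "ms_insufficient_groups_error")
  sub <- scored[scored$band %in% keep, ]
  sub$band <- droplevels(sub$band)
  markers <- c(sbp = "sbp_mmhg", dbp = "dbp_mmhg", wc = "wc_cm",
               fbg = "fbg", tg = "tg", hdl = "hdl", tyg = "tyg")
  anovas <- lapply(markers, function(col)
    anova_oneway(split(sub[[col]], sub$band)))
  structure(list(band_distribution = band_distribution, markers = anovas,
                 score_tyg = pearson_with_ci(scored$total_score, scored$tyg),
                 n = nrow(scored), matrix_version = matrix$version,
                 scored = scored),
            class = "mets_validation_report")
}

#' @export
print.mets_validation_report <- function(x, ...) {
  cat(sprintf("Known-groups validation (n = %d, matrix %s)\n",
              x$n, x$matrix_version))
  cat("Band distribution:\n")
  print(x$band_distribution, row.names = FALSE)
  cat("\nMarker ANOVAs across bands:\n")
  for (nm in names(x$markers)) {
    a <- x$markers[[nm]]
    cat(sprintf("  %-4s F(%d,%d) = %7.2f  p = %.3g  eta^2 = %.3f  means: %s\n",
                nm, a$df_between, a$df_within, a$F, a$p, a$eta_squared,
                paste(sprintf("%.2f", a$group_stats$mean), collapse = " / ")))
  }
  cat(sprintf("\nScore vs TyG: r = %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
              x$score_tyg$r, x$score_tyg$ci[1], x$score_tyg$ci[2],
              x$score_tyg$p))
  invisible(x)
}
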