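# Pilot-evaluation statistics: Cronbach's alpha, Cohen's kappa, corrected
# item-total correlations, and ROC AUC with a DeLong interval.
# Sample (n-1) variance denominators throughout.

.check_item_table <- function(x, min_items = 2L, min_rows = 3L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) ms_stop("item table must be numeric", "ms_spec_error")
  if (anyNA(x)) ms_stop("item table must have no missing cells", "ms_spec_error")
  if (ncol(x) < min_items)
    ms_stop(sprintf("need at least %d items", min_items), "ms_spec_error")
  if (nrow(x) < min_rows)
    ms_stop(sprintf("need at least %d participants", min_rows), "ms_spec_error")
  x
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total))`, with
#' sample (n-1) variances.
#'
#' @param x Participants-by-items numeric matrix or data frame (>= 2 items,
#'   >= 3 participants, no missing cells).
#' @return Alpha (<= 1; can be negative for incoherent scales).
#' @examples
#' set.seed(1)
#' z <- rnorm(50)
#' cronbach_alpha(cbind(z + rnorm(50), z + rnorm(50), z + rnorm(50)))
#' @export
cronbach_alpha <- function(x) {
  x <- .check_item_table(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0)
    ms_stop("total-score variance is zero", "ms_degenerate_error")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between two raters,
#' with expected agreement from the marginal products. Unweighted by
#' default; linear weights available for ordered categories.
#'
#' @param a,b Paired categorical ratings (equal length >= 2). Factor levels
#'   are pooled across both raters.
#' @param weights `"none"` (default) or `"linear"`.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(rep(c("x", "y"), 10), rep(c("x", "y"), 10))  # 1
#' @export
cohen_kappa <- function(a, b, weights = c("none", "linear")) {
  weights <- match.arg(weights)
  if (length(a) != length(b) || length(a) < 2)
    ms_stop("ratings must be paired with length >= 2", "ms_spec_error")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  tab <- table(factor(a, levels = lev), factor(b, levels = lev))
  p <- tab / sum(tab)
  k <- length(lev)
  w <- if (weights == "none") diag(k)
       else 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (abs(1 - pe) < 1e-12)
    ms_stop("expected agreement is 1 (both raters constant); kappa undefined",
            "ms_degenerate_error")
  (po - pe) / (1 - pe)
}

#' Corrected item-total correlations
#'
#' Pearson correlation of each item with the sum of the remaining items
#' (rest score). The uncorrected form (item vs full total, which inflates
#' the correlation by including the item itself) is available via
#' `corrected = FALSE`. A constant item (or constant rest score) yields `NA`
#' for that item with a warning rather than an error.
#'
#' @param x Participants-by-items numeric matrix or data frame (>= 3 items).
#' @param corrected Use the rest score (default) or the full total.
#' @return Named numeric vector, one correlation per item.
#' @export
item_total_correlations <- function(x, corrected = TRUE) {
  x <- .check_item_table(x, min_items = 3L)
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  total <- rowSums(x)
  out <- vapply(seq_len(ncol(x)), function(j) {
    ref <- if (corrected) total - x[, j] else total
    if (stats::sd(x[, j]) == 0 || stats::sd(ref) == 0) return(NA_real_)
    stats::cor(x[, j], ref)
  }, 0)
  names(out) <- colnames(x)
  if (anyNA(out))
    warning(sprintf("undefined item-total correlation for: %s",
                    paste(names(out)[is.na(out)], collapse = ", ")),
            call. = FALSE)
  out
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC by pair counting: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, ties counted 1/2 (the Mann-Whitney
#' statistic, equal to the trapezoidal area under the empirical ROC curve).
#' The confidence interval uses the DeLong placement-value variance on the
#' logit-free scale, clipped to `[0, 1]`.
#'
#' @param scores Numeric predictor (higher = more likely positive).
#' @param labels Binary outcome (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @param conf_level Confidence level.
#' @return List with `auc`, `ci` (length 2), `se`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  scores <- as.numeric(scores)
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    ms_stop("scores and labels must be complete and paired", "ms_spec_error")
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0)
    ms_stop("both outcome classes must be present", "ms_spec_error")
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  # DeLong: placement values of each positive among negatives and vice versa
  v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n, 0)
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / m, 0)
  var0 <- function(v) if (length(v) < 2) 0 else stats::var(v)
  se <- sqrt(max(var0(v10) / m + var0(v01) / n, 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc,
       ci = c(max(0, auc - zq * se), min(1, auc + zq * se)),
       se = se, n_pos = m, n_neg = n)
}
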