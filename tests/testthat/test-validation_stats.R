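# Sample-size calculators, ANOVA/Tukey/eta-squared, Pearson with Fisher-z
# interval, chi-square, and the assembled known-groups report.

test_that("Fisher-z sample-size calculator matches hand evaluation", {
  expect_identical(n_for_correlation(0.30, 0.05, 0.80), 85L)
  # hand oracle: ceil((qnorm(.975)+qnorm(.8))^2 / atanh(r)^2) + 3
  hand <- function(r) as.integer(
    ceiling((qnorm(0.975) + qnorm(0.80))^2 / atanh(r)^2) + 3)
  for (r in c(0.1, 0.2, 0.5, 0.7, 0.9))
    expect_identical(n_for_correlation(r), hand(r))
  expect_identical(n_for_correlation(0.50), 30L)
  # monotone decreasing in |r|, small near |r| -> 1
  ns <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 0.999), n_for_correlation, 1L)
  expect_true(all(diff(ns) < 0))
  expect_lte(ns[length(ns)], 5L)
  expect_error(n_for_correlation(0), "infinite")
  expect_error(n_for_correlation(1.1), class = "ms_spec_error")
})

test_that("noncentral-F sample-size search brackets the power target", {
  expect_identical(n_for_anova(0.25, 3), 159L)
  expect_lt(anova_power(156, 0.25, 3), 0.80)
  expect_gte(anova_power(159, 0.25, 3), 0.80)
  # lambda = f^2 N scaling: doubling f roughly quarters N
  n_half <- n_for_anova(0.50, 3)
  expect_lt(n_half, 159 / 3)
  expect_identical(n_half %% 3L, 0L)
  expect_error(n_for_anova(0.25, 3, power = 0.999999, n_max = 300),
               class = "ms_spec_error")
})

test_that("one-way ANOVA reproduces the hand decomposition", {
  a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$F, 3)          # SSB = 6, SSW = 6, df = (2, 6)
  expect_equal(a$eta_squared, 0.5)
  expect_identical(c(a$df_between, a$df_within), c(2L, 6L))
  expect_equal(nrow(a$tukey), 3)

  same <- anova_oneway(list(c(1, 5, 2), c(1, 5, 2), c(1, 5, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$eta_squared, 0)

  # two groups: F equals the square of the pooled t statistic
  set.seed(12)
  x <- rnorm(14); y <- rnorm(17, mean = 0.8)
  tt <- t.test(x, y, var.equal = TRUE)
  a2 <- anova_oneway(list(x, y))
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)

  expect_error(anova_oneway(list(c(1, 1), c(2, 2))),
               class = "ms_degenerate_error")
  expect_error(anova_oneway(list(rnorm(5))),
               class = "ms_insufficient_groups_error")
})

test_that("ANOVA is order-invariant, eta-squared bounded, Tukey conservative", {
  set.seed(41)
  for (i in 1:10) {
    g <- replicate(3, rnorm(sample(5:12, 1), mean = runif(1, 0, 2)),
                   simplify = FALSE)
    a <- anova_oneway(g)
    expect_gte(a$eta_squared, 0)
    expect_lte(a$eta_squared, 1)
    perm <- anova_oneway(g[c(3, 1, 2)])
    expect_equal(perm$F, a$F, tolerance = 1e-12)
    expect_equal(perm$eta_squared, a$eta_squared, tolerance = 1e-12)
    # Tukey-adjusted pairwise p >= unadjusted pooled-variance pairwise p
    dat <- data.frame(y = unlist(g),
                      grp = rep(paste0("g", 1:3), lengths(g)))
    raw <- pairwise.t.test(dat$y, dat$grp, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    raw_p <- c(raw[1, 1], raw[2, 1], raw[2, 2])  # g2-g1, g3-g1, g3-g2
    expect_true(all(a$tukey$p_adj >= raw_p - 1e-10))
  }
  # Welch flag reports the corrected test alongside
  aw <- anova_oneway(list(rnorm(10), rnorm(10, 1), rnorm(10, 2)),
                     welch = TRUE)
  expect_true(is.numeric(aw$welch_F) && is.numeric(aw$welch_p))
})

test_that("Pearson correlation and interval match the Fisher-z construction", {
  x <- 1:5
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1)
  set.seed(14)
  xa <- rnorm(400); ya <- rnorm(400)
  ind <- pearson_with_ci(xa, ya)
  expect_lt(abs(ind$r), 0.12)
  expect_true(ind$ci[1] < 0 && ind$ci[2] > 0)
  # n = 5 brute-force oracle: covariance over product of SDs, z interval
  xs <- c(1.2, 3.4, 2.2, 5.0, 4.1); ys <- c(0.7, 2.9, 1.1, 4.2, 4.4)
  r_hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  got <- pearson_with_ci(xs, ys)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$ci,
               tanh(atanh(r_hand) + c(-1, 1) * qnorm(0.975) / sqrt(5 - 3)),
               tolerance = 1e-9)
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)),
               class = "ms_degenerate_error")
  expect_error(pearson_with_ci(1:3, 3:1), class = "ms_spec_error")
})

test_that("chi-square independence matches hand-computed expectations", {
  # table proportional to the outer product of its margins
  indep <- outer(c(10, 30), c(2, 8)) / 2
  expect_equal(chi_square_independence(indep)$statistic, 0, tolerance = 1e-12)
  got <- chi_square_independence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(got$statistic, 20 / 3, tolerance = 1e-9)  # hand: sum (O-E)^2/E
  expect_identical(got$df, 1L)
  expect_identical(chi_square_independence(matrix(1:6, 2))$df, 2L)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2,
                                              byrow = TRUE)),
               class = "ms_degenerate_error")
  expect_error(chi_square_independence(matrix(1:3, 1)),
               class = "ms_spec_error")
})

test_that("known-groups validation assembles a complete report", {
  # comfortable n so every analysed band is well occupied
  coh <- generate_cohort(cohort_spec(n = 400, seed = 8))
  rep <- run_known_groups_validation(coh)
  expect_s3_class(rep, "mets_validation_report")
  expect_setequal(names(rep$markers),
                  c("sbp", "dbp", "wc", "fbg", "tg", "hdl", "tyg"))
  expect_equal(sum(rep$band_distribution$n), 400)
  expect_equal(sum(rep$band_distribution$percent), 100)
  # markers rise with band; HDL-C falls
  for (mk in c("sbp", "dbp", "wc", "fbg", "tg", "tyg"))
    expect_true(all(diff(rep$markers[[mk]]$group_stats$mean) > 0),
                label = paste(mk, "means increase across bands"))
  expect_true(all(diff(rep$markers$hdl$group_stats$mean) < 0))
  expect_gt(rep$score_tyg$r, 0.4)
  # a cohort of identical records occupies one band only
  one <- coh[rep(1, 20), ]
  expect_error(run_known_groups_validation(one),
               class = "ms_insufficient_groups_error")
})
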