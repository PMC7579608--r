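make_table <- function(y1, y2, g) {
  N <- length(y1)
  data.frame(participant = rep(sprintf("s%02d", seq_len(N)), 2),
             group = rep(g, 2),
             condition = rep(c("c1", "c2"), each = N),
             value = c(y1, y2), stringsAsFactors = FALSE)
}

test_that("mixed ANOVA returns zero F on null data and matches oracles", {
  g <- rep(c("g1", "g2"), each = 4)
  flat <- make_table(rep(1, 8), rep(1, 8), g)
  an <- mixed_anova_2x2(flat)
  expect_equal(an$effects$F, rep(0, 3))
  set.seed(101)
  for (i in 1:5) {
    tab <- make_table(rnorm(8), rnorm(8), g)
    an <- mixed_anova_2x2(tab)
    # brute-force cell/subject-mean decomposition
    oracle <- anova_ss_oracle(tab)
    expect_equal(an$effects$F[an$effects$effect == "group"],
                 unname(oracle$F_group), tolerance = 1e-8)
    expect_equal(an$effects$F[an$effects$effect == "condition"],
                 unname(oracle$F_cond), tolerance = 1e-8)
    expect_equal(an$effects$F[an$effects$effect == "group:condition"],
                 unname(oracle$F_int), tolerance = 1e-8)
    # independent route: aov with an Error stratum
    fit <- summary(stats::aov(value ~ group * condition +
                                Error(participant / condition), data = tab))
    btw <- fit[["Error: participant"]][[1]]
    wth <- fit[["Error: participant:condition"]][[1]]
    expect_equal(an$effects$F[1], btw["group", "F value"], tolerance = 1e-8)
    expect_equal(an$effects$F[2], wth["condition", "F value"], tolerance = 1e-8)
    expect_equal(an$effects$F[3], wth["group:condition", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("ANOVA sums of squares decompose the total variance", {
  set.seed(7)
  tab <- make_table(rnorm(12), rnorm(12), rep(c("g1", "g2"), each = 6))
  an <- mixed_anova_2x2(tab)
  oracle <- anova_ss_oracle(tab)
  ss_total <- sum((tab$value - mean(tab$value))^2)
  expect_equal(sum(oracle$ss), ss_total, tolerance = 1e-8 * ss_total)
  # partial eta squared uses the effect's own error stratum
  e <- an$effects
  expect_equal(e$partial_eta_sq,
               e$ss / (e$ss + e$ss_error), tolerance = 1e-12)
  expect_true(all(e$partial_eta_sq >= 0 & e$partial_eta_sq <= 1))
})

test_that("ANOVA on a constructed textbook 2x2 dataset", {
  # n = 4 per group; cell means: g1 (10, 12), g2 (10, 18): interaction = 6
  y1 <- c(9, 10, 11, 10, 9, 11, 10, 10)
  y2 <- c(11, 13, 12, 12, 17, 19, 18, 18)
  tab <- make_table(y1, y2, rep(c("g1", "g2"), each = 4))
  an <- mixed_anova_2x2(tab)
  oracle <- anova_ss_oracle(tab)
  expect_equal(an$effects$F,
               unname(c(oracle$F_group, oracle$F_cond, oracle$F_int)),
               tolerance = 1e-10)
  expect_equal(an$effects$df2, rep(6, 3))
  expect_lt(an$effects$p[3], 0.01)      # the large interaction is detected
})

test_that("ANOVA rejects incomplete or unsupported designs", {
  g <- rep(c("g1", "g2"), each = 4)
  tab <- make_table(rnorm(8), rnorm(8), g)
  expect_error(mixed_anova_2x2(tab[-1, ]), "both conditions|incomplete")
  tab3 <- rbind(tab, data.frame(participant = "s01", group = "g1",
                                condition = "c3", value = 0))
  expect_error(mixed_anova_2x2(tab3), "two groups and two conditions")
})

test_that("observed power follows the noncentral-F convention", {
  expect_equal(observed_power(0, 1, 24), 0.05, tolerance = 1e-9)
  fs <- c(0.5, 2, 5, 12.248, 30)
  pw <- sapply(fs, observed_power, df1 = 1, df2 = 24)
  expect_true(all(diff(pw) > 0))
  for (f in fs)
    expect_equal(observed_power(f, 1, 24), power_series_oracle(f, 1, 24),
                 tolerance = 1e-4)
  expect_equal(observed_power(3.5, 2, 40), power_series_oracle(3.5, 2, 40),
               tolerance = 1e-4)
})

test_that("post hocs use the Bonferroni-corrected 0.0125 threshold", {
  g <- rep(c("g1", "g2"), each = 5)
  tab <- make_table(rep(1, 10), rep(1, 10), g)
  ph <- posthoc_bonferroni(tab)
  expect_equal(nrow(ph), 4)
  expect_equal(unique(ph$alpha_corrected), 0.0125)
  expect_true(all(ph$t == 0 | is.nan(ph$t)))
  expect_false(any(ph$significant, na.rm = TRUE))
  # paired data with constant unit difference: certain effect
  y1 <- rnorm(10)
  tab2 <- make_table(y1 + 1, y1, g)
  ph2 <- posthoc_bonferroni(tab2)
  paired <- ph2[ph2$type == "paired", ]
  expect_true(all(paired$p_raw < 1e-10))
  expect_true(all(paired$significant))
})

test_that("paired post hoc equals a one-sample t on the differences", {
  set.seed(55)
  g <- rep("g1", 6)
  y1 <- rnorm(6); y2 <- rnorm(6)
  tab <- rbind(make_table(y1, y2, g),
               make_table(rnorm(6), rnorm(6), rep("g2", 6)))
  tab$participant <- paste0(tab$group, tab$participant)
  ph <- posthoc_bonferroni(tab)
  ref <- t.test(y1 - y2)
  row <- ph[ph$contrast == "g1: c1 vs c2", ]
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p_raw, ref$p.value, tolerance = 1e-12)
})

test_that("log(x+1) correlation transforms only the covariate", {
  x <- c(0, exp(1) - 1, exp(2) - 1)
  expect_equal(log1p(x), c(0, 1, 2))
  x2 <- runif(10, 0, 50)
  y <- log1p(x2)
  r <- log_transform_correlate(x2, y)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_error(log_transform_correlate(c(-1, 2, 3), rnorm(3)), "non-negative")
  expect_error(log_transform_correlate(rep(1, 5), rnorm(5)), "zero variance")
  # Bonferroni adjustment over the declared family
  set.seed(3)
  r4 <- log_transform_correlate(runif(10), rnorm(10), n_family = 4)
  expect_equal(r4$p_adjusted, min(1, 4 * r4$p))
})

test_that("the correlation test keeps its nominal size under the null", {
  set.seed(77)
  n_sim <- 500
  hits <- 0
  for (i in seq_len(n_sim)) {
    res <- log_transform_correlate(runif(13, 0, 40), rnorm(13))
    hits <- hits + (res$p < 0.05)
  }
  expect_gte(hits / n_sim, 0.02)
  expect_lte(hits / n_sim, 0.08)
})
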