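#' Two-group by two-condition mixed-design ANOVA
#'
#' Classical repeated-measures decomposition for one between-subject factor
#' (group, 2 levels) and one within-subject factor (condition, 2 levels):
#' the group effect is tested against subjects-within-group variation, the
#' condition and interaction effects against the condition-by-subject
#' residual. Reports F, degrees of freedom, p, partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) and retrospective observed power
#' for each effect, plus cell means and SDs. Complete cases only: every
#' participant must have both conditions (no imputation).
#'
#' @param data data.frame with columns `participant`, `group`, `condition`
#'   and the dependent variable.
#' @param dv Name of the dependent-variable column (default `"value"`).
#' @param alpha Significance level used for the observed-power computation.
#' @return An object of class `ms_anova`: list with `effects` (data.frame of
#'   the three tests) and `cells` (cell means/SDs).
#' @export
mixed_anova_2x2 <- function(data, dv = "value", alpha = 0.05) {
  d <- data.frame(participant = as.character(data$participant),
                  group = as.character(data$group),
                  condition = as.character(data$condition),
                  y = as.numeric(data[[dv]]))
  if (anyNA(d$y)) stop("missing values in the dependent variable", call. = FALSE)
  groups <- sort(unique(d$group)); conds <- sort(unique(d$condition))
  if (length(groups) != 2 || length(conds) != 2)
    stop("exactly two groups and two conditions are required", call. = FALSE)
  wide <- stats::reshape(d, idvar = c("participant", "group"),
                         timevar = "condition", direction = "wide")
  y1 <- wide[[paste0("y.", conds[1])]]
  y2 <- wide[[paste0("y.", conds[2])]]
  if (anyNA(y1) || anyNA(y2))
    stop("incomplete within-subject data: every participant needs both conditions",
         call. = FALSE)
  g <- wide$group
  N <- nrow(wide)
  if (N < 4) stop("too few participants", call. = FALSE)
  y <- cbind(y1, y2)

  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- as.numeric(tapply(subj_mean, g, mean)[g])
  cond_mean <- as.numeric(colMeans(y))
  cell_mean <- rbind(tapply(y1, g, mean), tapply(y2, g, mean))  # cond x group

  ss_group <- 2 * sum(tapply(subj_mean, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_subj <- 2 * sum((subj_mean - grp_mean)^2)
  ss_cond <- N * sum((cond_mean - grand)^2)
  cell_fit <- matrix(0, N, 2)
  for (cc in 1:2) cell_fit[, cc] <- cell_mean[cc, match(g, colnames(cell_mean))]
  ss_int <- sum((t(t(cell_fit) - cond_mean) - (grp_mean - grand))^2)
  ss_werr <- sum((y - subj_mean - cell_fit + grp_mean)^2)

  df_sub <- N - 2
  df_werr <- N - 2
  eff <- function(name, ss_e, ss_err, df2) {
    ms_e <- ss_e / 1; ms_err <- ss_err / df2
    f <- if (ms_err > 0) ms_e / ms_err else ifelse(ms_e > 0, Inf, 0)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
    data.frame(effect = name, df1 = 1, df2 = df2, ss = ss_e, ss_error = ss_err,
               F = f, p = p,
               partial_eta_sq = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               observed_power = observed_power(f, 1, df2, alpha = alpha),
               stringsAsFactors = FALSE)
  }
  effects <- rbind(
    eff("group", ss_group, ss_subj, df_sub),
    eff("condition", ss_cond, ss_werr, df_werr),
    eff("group:condition", ss_int, ss_werr, df_werr)
  )
  cells <- expand.grid(condition = conds, group = colnames(cell_mean),
                       stringsAsFactors = FALSE)
  cells$mean <- as.numeric(cell_mean)
  cells$sd <- as.numeric(rbind(tapply(y1, g, stats::sd), tapply(y2, g, stats::sd)))
  cells$n <- as.numeric(rbind(tapply(y1, g, length), tapply(y2, g, length)))
  structure(list(effects = effects, cells = cells,
                 groups = colnames(cell_mean), conditions = conds),
            class = "ms_anova")
}

#' @export
print.ms_anova <- function(x, ...) {
  cat("<ms_anova> 2x2 mixed design\n")
  print(x$effects[, c("effect", "df1", "df2", "F", "p", "partial_eta_sq",
                      "observed_power")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Retrospective observed power of an F test
#'
#' Computes the power of the F test assuming the observed effect is the true
#' one, using the noncentral F distribution with noncentrality
#' `lambda = F * df1` (the convention of mainstream statistics packages):
#' `power = P(F'(df1, df2, lambda) > F_crit(alpha))`. A central effect
#' (F = 0) returns the alpha-level false-positive floor. Retrospective power
#' is descriptive of the observed sample, not of future replications.
#'
#' @param f Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param alpha Test level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
observed_power <- function(f, df1, df2, alpha = 0.05) {
  stopifnot(f >= 0, df1 >= 1, df2 >= 1)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f * df1, lower.tail = FALSE)
}

#' Bonferroni-corrected post hoc contrasts for a 2x2 mixed design
#'
#' Decomposes a group x condition interaction into the four simple effects:
#' within each group, condition 1 vs condition 2 (paired t on
#' within-participant differences); within each condition, group 1 vs group 2
#' (two-sample t, equal-variance by default). Significance is judged at
#' `alpha / 4` (0.0125 for the default family-wise 0.05).
#'
#' @param data data.frame with `participant`, `group`, `condition` and the dv.
#' @param dv Dependent-variable column name.
#' @param alpha Family-wise error rate (default 0.05, so each contrast is
#'   tested at 0.0125).
#' @param var_equal Use the pooled-variance two-sample t (default TRUE);
#'   FALSE gives Welch.
#' @return data.frame with one row per contrast: `contrast`, `type`, `t`,
#'   `df`, `p_raw`, `alpha_corrected`, `significant`, `direction`.
#' @export
posthoc_bonferroni <- function(data, dv = "value", alpha = 0.05,
                               var_equal = TRUE) {
  d <- data.frame(participant = as.character(data$participant),
                  group = as.character(data$group),
                  condition = as.character(data$condition),
                  y = as.numeric(data[[dv]]))
  groups <- sort(unique(d$group)); conds <- sort(unique(d$condition))
  stopifnot(length(groups) == 2, length(conds) == 2)
  a_corr <- alpha / 4
  rows <- list()
  for (gr in groups) {
    sub <- d[d$group == gr, ]
    w <- stats::reshape(sub[, c("participant", "condition", "y")],
                        idvar = "participant", timevar = "condition",
                        direction = "wide")
    diffs <- w[[paste0("y.", conds[1])]] - w[[paste0("y.", conds[2])]]
    if (length(diffs) < 2) stop("need n >= 2 per cell", call. = FALSE)
    tt <- t_one_sample(diffs)
    rows[[length(rows) + 1]] <- data.frame(
      contrast = sprintf("%s: %s vs %s", gr, conds[1], conds[2]),
      type = "paired", t = tt$t, df = tt$df,
      p_raw = tt$p, stringsAsFactors = FALSE,
      direction = ifelse(mean(diffs) > 0,
                         sprintf("%s > %s", conds[1], conds[2]),
                         sprintf("%s < %s", conds[1], conds[2])))
  }
  for (cc in conds) {
    sub <- d[d$condition == cc, ]
    a <- sub$y[sub$group == groups[1]]
    b <- sub$y[sub$group == groups[2]]
    if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per cell", call. = FALSE)
    tt <- t_two_sample(a, b, var_equal)
    rows[[length(rows) + 1]] <- data.frame(
      contrast = sprintf("%s: %s vs %s", cc, groups[1], groups[2]),
      type = "independent", t = tt$t,
      df = tt$df, p_raw = tt$p, stringsAsFactors = FALSE,
      direction = ifelse(mean(a) > mean(b),
                         sprintf("%s > %s", groups[1], groups[2]),
                         sprintf("%s < %s", groups[1], groups[2])))
  }
  out <- do.call(rbind, rows)
  out$alpha_corrected <- a_corr
  out$significant <- out$p_raw < a_corr
  out[, c("contrast", "type", "t", "df", "p_raw", "alpha_corrected",
          "significant", "direction")]
}

# one-sample / paired t with explicit handling of zero-variance data:
# a certain zero difference gives t = 0 (p = 1); a certain nonzero
# difference gives |t| = Inf (p = 0)
t_one_sample <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  df <- n - 1
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

t_two_sample <- function(a, b, var_equal = TRUE) {
  n1 <- length(a); n2 <- length(b)
  m <- mean(a) - mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (v1 + v2 == 0) n1 + n2 - 2 else
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- if (se == 0) { if (m == 0) 0 else sign(m) * Inf } else m / se
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson correlation after a log(x+1) transform of the covariate
#'
#' Skewed psychometric covariates are transformed as `log(x + 1)` before
#' correlating with a microstate parameter; the two-sided p-value can be
#' Bonferroni-adjusted over a declared family of tests.
#'
#' @param x Non-negative covariate values.
#' @param y Parameter values (same length, n >= 3).
#' @param n_family Number of tests in the Bonferroni family (default 1 = no
#'   adjustment).
#' @return List with `r`, `p`, `p_adjusted`, `n`.
#' @export
log_transform_correlate <- function(x, y, n_family = 1) {
  if (any(x < 0)) stop("covariate must be non-negative for log(x+1)", call. = FALSE)
  if (length(x) != length(y) || length(x) < 3)
    stop("need n >= 3 paired observations", call. = FALSE)
  lx <- log1p(x)
  if (stats::sd(lx) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(lx, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       p_adjusted = min(1, ct$p.value * n_family), n = length(x))
}
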