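#' Monte-Carlo power of the group x condition interaction test
#'
#' Repeatedly simulates a two-group, two-condition cohort with a programmed
#' multiplicative effect on one class's mean run duration in a single cell
#' (group 2, condition 1), extracts each participant's class mean duration,
#' and tests the interaction with [mixed_anova_2x2()]. With
#' `measure = "truth"` (default) durations are computed from the generator's
#' ground-truth label sequences — this isolates the detection power of the
#' 2x2 design at the programmed effect size from estimation bias. With
#' `measure = "backfit"` the full noisy-EEG route is taken: simulate the
#' recording at `snr`, backfit the canonical templates, and use the
#' recovered durations (slower, and attenuated at low SNR; see the methods
#' vignette).
#'
#' @param n_rep Number of replicates.
#' @param effect Multiplier on the affected cell's class mean duration
#'   (e.g. 1.2 for +20%; 1 gives a null simulation).
#' @param seed Integer seed.
#' @param n_per_group Participants per group (default 13).
#' @param n_epochs Epochs per condition per participant (default 10).
#' @param snr Signal-to-noise ratio (backfit route only).
#' @param target_class Index of the affected class (default 3, class C).
#' @param duration_ms Baseline class mean durations (ms).
#' @param alpha Test level.
#' @param n_channels,fs,epoch_s Recording geometry.
#' @param subject_sdlog Lognormal sd of the per-participant duration
#'   multiplier.
#' @param measure `"truth"` (ground-truth labels) or `"backfit"` (noisy EEG
#'   + template backfitting).
#' @param shape Gamma shape of the run-length law.
#' @return List with `power` (rejection rate), `p_values`, `n_rep`.
#' @export
interaction_power_sim <- function(n_rep, effect = 1.2, seed = 1,
                                  n_per_group = 13, n_epochs = 10, snr = 2,
                                  target_class = 3,
                                  duration_ms = c(60, 75, 90, 100),
                                  alpha = 0.05, n_channels = 32, fs = 125,
                                  epoch_s = 2, subject_sdlog = 0.1,
                                  measure = c("truth", "backfit"),
                                  shape = 4) {
  measure <- match.arg(measure)
  set.seed(seed)
  K <- length(duration_ms)
  tm <- uniform_transition(K)
  ns <- round(fs * epoch_s)
  tpl <- NULL
  if (measure == "backfit")
    tpl <- make_canonical_templates(make_montage(n_channels))
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    rows <- vector("list", 4 * n_per_group)
    i <- 0
    for (g in 1:2) {
      for (s in seq_len(n_per_group)) {
        mult <- stats::rlnorm(1, -subject_sdlog^2 / 2, subject_sdlog)
        for (cond in 1:2) {
          d <- duration_ms * mult
          if (g == 2 && cond == 1) d[target_class] <- d[target_class] * effect
          if (measure == "truth") {
            sq <- sample_state_sequence(ns * n_epochs, d, tm, fs, shape)
            seg <- new_segmentation(
              matrix(sq$labels, ns, n_epochs),
              matrix(1, ns, n_epochs), matrix(1, ns, n_epochs), fs,
              paste0("S", seq_len(K)))
          } else {
            sim <- simulate_recording(tpl, duration_ms = d, transition = tm,
                                      snr = snr, fs = fs, epoch_s = epoch_s,
                                      n_epochs = n_epochs, shape = shape)
            seg <- backfit(average_reference(sim$epochs), tpl)
          }
          i <- i + 1
          rows[[i]] <- data.frame(
            participant = sprintf("g%ds%02d", g, s),
            group = c("g1", "g2")[g], condition = c("c1", "c2")[cond],
            value = mean_duration(seg)[[target_class]],
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    pvals[r] <- mixed_anova_2x2(tab)$effects$p[3]
  }
  list(power = mean(pvals < alpha), p_values = pvals, n_rep = n_rep)
}

#' Type-I error calibration of the interaction test under the null
#'
#' Simulates parameter tables directly under the null hypothesis (independent
#' normal errors, no group, condition or interaction effect; a shared
#' participant intercept induces the usual within-subject correlation) and
#' reports the interaction rejection rate, which should sit at the nominal
#' level.
#'
#' @param n_rep Number of simulated datasets (default 1000).
#' @param seed Integer seed.
#' @param n_per_group Participants per group (default 13).
#' @param subject_sd SD of the participant random intercept.
#' @param error_sd SD of the residual error.
#' @param alpha Test level.
#' @return List with `rejection_rate`, `p_values`, `n_rep`.
#' @export
null_rejection_sim <- function(n_rep = 1000, seed = 1, n_per_group = 13,
                               subject_sd = 1, error_sd = 1, alpha = 0.05) {
  set.seed(seed)
  N <- 2 * n_per_group
  grp <- rep(c("g1", "g2"), each = n_per_group)
  ids <- sprintf("s%03d", seq_len(N))
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    b <- stats::rnorm(N, 0, subject_sd)
    y1 <- b + stats::rnorm(N, 0, error_sd)
    y2 <- b + stats::rnorm(N, 0, error_sd)
    tab <- data.frame(participant = rep(ids, 2), group = rep(grp, 2),
                      condition = rep(c("c1", "c2"), each = N),
                      value = c(y1, y2), stringsAsFactors = FALSE)
    pvals[r] <- mixed_anova_2x2(tab)$effects$p[3]
  }
  list(rejection_rate = mean(pvals < alpha), p_values = pvals, n_rep = n_rep)
}
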