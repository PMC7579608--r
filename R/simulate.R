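#' Simulate one epoched EEG recording from a semi-Markov microstate model
#'
#' The hidden state sequence is generated continuously (so runs may be
#' truncated by the epoch grid, as in real segmented data): run lengths are
#' drawn from a gamma law with the class-specific mean (ms) and common shape,
#' rounded to at least one sample; the next class is drawn from the
#' corresponding row of the transition matrix (zero diagonal). The signal is
#' `s(t) * template[L(t)]` with per-sample amplitude
#' `s(t) = |N(1, 0.2^2)| * gfp_scale` applied to unit-GFP templates, plus
#' additive noise that is temporally pink (1/f) per channel and spatially
#' smoothed with a Gaussian kernel over inter-electrode great-circle
#' distances, scaled so that signal RMS / noise RMS equals `snr`.
#' `snr = Inf` gives noise-free data.
#'
#' @param templates `ms_templates` (the generating maps).
#' @param duration_ms Mean run duration per class, in ms.
#' @param transition K x K transition matrix, zero diagonal, rows summing
#'   to 1. Default: uniform over the other classes.
#' @param snr Signal-to-noise ratio (template RMS over noise RMS), > 0.
#' @param fs Sampling rate (Hz), default 125.
#' @param epoch_s Epoch length (s), default 2.
#' @param n_epochs Number of epochs, default 10.
#' @param gfp_scale Mean GFP of the clean signal, microvolts (default 10).
#' @param shape Gamma shape of the run-length law (default 4).
#' @param noise_kernel_rad Width (radians) of the spatial smoothing kernel of
#'   the noise (default 0.6).
#' @param seed Optional integer seed; when given the result is reproducible.
#' @return List with `epochs` (an `ms_epochs`) and `truth` (list: `labels`
#'   samples x epochs matrix, `run_lengths`, `templates`, plus programmed
#'   durations and stationary coverage).
#' @export
simulate_recording <- function(templates, duration_ms, transition = NULL,
                               snr = 2, fs = 125, epoch_s = 2, n_epochs = 10,
                               gfp_scale = 10, shape = 4,
                               noise_kernel_rad = 0.6, seed = NULL) {
  validate_templates(templates)
  K <- length(templates$labels)
  stopifnot(length(duration_ms) == K, all(duration_ms > 0), snr > 0,
            fs > 0, epoch_s > 0, n_epochs >= 1)
  if (is.null(transition)) transition <- uniform_transition(K)
  check_transition(transition, K)
  if (!is.null(seed)) set.seed(seed)

  ns <- round(fs * epoch_s)
  total <- ns * n_epochs
  sq <- sample_state_sequence(total, duration_ms, transition, fs, shape)
  lab <- matrix(sq$labels, nrow = ns, ncol = n_epochs)

  Tg <- apply(templates$maps, 2, function(m) (m - mean(m)) / gfp(m))
  amp <- abs(stats::rnorm(total, 1, 0.2)) * gfp_scale
  clean <- Tg[, sq$labels, drop = FALSE] * rep(amp, each = nrow(Tg))

  if (is.finite(snr)) {
    noise <- smoothed_pink_noise(nrow(Tg), total, templates$montage,
                                 noise_kernel_rad)
    noise <- noise * sqrt(mean(clean^2)) / (snr * sqrt(mean(noise^2)))
    dat <- clean + noise
  } else {
    dat <- clean
  }
  ep <- new_epochs(array(dat, dim = c(nrow(Tg), ns, n_epochs)),
                   fs, epoch_s, templates$montage)
  truth <- list(labels = lab, run_lengths = sq$runs, templates = templates,
                duration_ms = duration_ms,
                coverage = stationary_coverage(duration_ms, transition))
  list(epochs = ep, truth = truth)
}

uniform_transition <- function(K) {
  tm <- matrix(1 / (K - 1), K, K)
  diag(tm) <- 0
  tm
}

check_transition <- function(tm, K) {
  tm <- as.matrix(tm)
  if (!all(dim(tm) == K)) stop("transition matrix must be K x K", call. = FALSE)
  if (any(diag(tm) != 0)) stop("transition matrix must have zero diagonal", call. = FALSE)
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    stop("each transition row must be a probability vector", call. = FALSE)
  invisible(tm)
}

# hidden semi-Markov label sequence of exactly n samples
sample_state_sequence <- function(n, duration_ms, transition, fs, shape) {
  K <- length(duration_ms)
  mean_samples <- duration_ms * fs / 1000
  pi0 <- embedded_stationary(transition)
  cum_tm <- t(apply(transition, 1, cumsum))
  classes <- integer(0)
  lens <- integer(0)
  cur <- findInterval(stats::runif(1), cumsum(pi0)) + 1L
  while (sum(lens) < n) {
    block <- max(16L, ceiling(1.5 * (n - sum(lens)) / min(mean_samples)))
    cls <- integer(block)
    u <- stats::runif(block)
    for (j in seq_len(block)) {
      cls[j] <- cur
      cur <- findInterval(u[j], cum_tm[cur, ]) + 1L
    }
    ln <- pmax(1L, as.integer(round(stats::rgamma(
      block, shape = shape, rate = shape / mean_samples[cls]))))
    classes <- c(classes, cls)
    lens <- c(lens, ln)
  }
  keep <- which(cumsum(lens) >= n)[1]
  classes <- classes[seq_len(keep)]
  lens <- lens[seq_len(keep)]
  list(labels = rep.int(classes, lens)[seq_len(n)],
       runs = data.frame(class = classes, length = lens))
}

# stationary distribution of the embedded jump chain
embedded_stationary <- function(tm) {
  K <- nrow(tm)
  ev <- eigen(t(tm))
  i <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

#' Programmed stationary coverage of the semi-Markov state model
#'
#' Time share of each class implied by the run-duration means and the
#' embedded transition chain: `coverage_k` is proportional to
#' `pi_k * duration_k`, where `pi` is the stationary distribution of the
#' transition matrix.
#'
#' @param duration_ms Mean run duration per class (ms).
#' @param transition Transition matrix (default uniform off-diagonal).
#' @return Numeric vector of coverage fractions summing to 1.
#' @export
stationary_coverage <- function(duration_ms, transition = NULL) {
  K <- length(duration_ms)
  if (is.null(transition)) transition <- uniform_transition(K)
  pi0 <- embedded_stationary(as.matrix(transition))
  w <- pi0 * duration_ms
  w / sum(w)
}

# temporally pink (1/f amplitude) noise, spatially mixed by a Gaussian
# kernel over inter-electrode angles
smoothed_pink_noise <- function(nch, n, montage, kernel_rad) {
  white <- matrix(stats::rnorm(nch * n), nch, n)
  pink <- t(apply(white, 1, pink_filter))
  if (!is.null(montage)) {
    ang <- montage_angles(montage)
    Kmat <- exp(-(ang / kernel_rad)^2 / 2)
    Kmat <- Kmat / rowSums(Kmat)
    pink <- Kmat %*% pink
  }
  pink
}

pink_filter <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Describe a synthetic two-group, two-condition cohort
#'
#' Bundles the design constants of an eyes-closed / eyes-open resting-state
#' study: group sizes, per-cell state models (class mean durations,
#' transition matrix, SNR), epoch geometry, template jitter across
#' participants, and group covariate models. Defaults emulate a 13 + 13
#' children cohort recorded with a dense net, analyzed at 125 Hz in 2 s
#' epochs with 10 artifact-free epochs per condition.
#'
#' @param groups Named integer vector of group sizes.
#' @param conditions Condition names (within-subject factor).
#' @param n_epochs,epoch_s,fs Epoch count, length (s) and analysis rate (Hz).
#' @param n_channels Montage size (default 32; use 128 for a dense net).
#' @param duration_ms Baseline mean run duration per class (ms).
#' @param effects List of programmed cell effects, each a list with `group`,
#'   `condition`, `class`, `factor` (multiplier on that cell's class mean
#'   duration).
#' @param transition Transition matrix (default uniform off-diagonal).
#' @param snr Signal-to-noise ratio for every recording.
#' @param shape Gamma shape of run lengths.
#' @param gfp_scale Clean-signal GFP in microvolts.
#' @param template_jitter_sd Per-participant topographic jitter (sd of the
#'   additive unit-map perturbation; 0.25 keeps |r| to the canonical maps
#'   above 0.9).
#' @param duration_subject_sdlog Lognormal sd of the per-participant
#'   multiplier on all duration means.
#' @param covariates Named list of per-group `c(mean, sd)` pairs per
#'   covariate; defaults give age, IQ and two symptom scales with
#'   ASD-like / TD-like separations.
#' @return An object of class `ms_design`.
#' @export
cohort_design <- function(groups = c(TD = 13L, ASD = 13L),
                          conditions = c("EC", "EO"),
                          n_epochs = 10, epoch_s = 2, fs = 125,
                          n_channels = 32,
                          duration_ms = c(A = 60, B = 75, C = 90, D = 100),
                          effects = list(),
                          transition = NULL,
                          snr = 2, shape = 4, gfp_scale = 10,
                          template_jitter_sd = 0.25,
                          duration_subject_sdlog = 0.1,
                          covariates = NULL) {
  stopifnot(all(groups >= 0), length(conditions) >= 1, all(duration_ms > 0),
            snr > 0)
  K <- length(duration_ms)
  if (is.null(transition)) transition <- uniform_transition(K)
  check_transition(transition, K)
  if (is.null(covariates)) {
    covariates <- list(
      age = list(TD = c(10.4, 1.4), ASD = c(9.7, 1.5)),
      iq = list(TD = c(102.1, 9.9), ASD = c(101.3, 19.8)),
      srs_total = list(TD = c(45, 8), ASD = c(73, 10)),
      rbsr_total = list(TD = c(1.8, 2), ASD = c(34.9, 21.1))
    )
  }
  structure(
    list(groups = groups, conditions = conditions, n_epochs = n_epochs,
         epoch_s = epoch_s, fs = fs, n_channels = n_channels,
         duration_ms = duration_ms, effects = effects,
         transition = transition, snr = snr, shape = shape,
         gfp_scale = gfp_scale, template_jitter_sd = template_jitter_sd,
         duration_subject_sdlog = duration_subject_sdlog,
         covariates = covariates),
    class = "ms_design"
  )
}

#' @export
print.ms_design <- function(x, ...) {
  cat(sprintf("<ms_design> groups: %s; conditions: %s; %d x %gs epochs @ %g Hz, SNR %g\n",
              paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
              paste(x$conditions, collapse = "/"),
              x$n_epochs, x$epoch_s, x$fs, x$snr))
  invisible(x)
}

# duration vector for one group x condition cell, with programmed effects
cell_durations <- function(design, group, condition) {
  d <- design$duration_ms
  for (ef in design$effects) {
    if (identical(ef$group, group) && identical(ef$condition, condition))
      d[ef$class] <- d[ef$class] * ef$factor
  }
  d
}

#' Simulate a full synthetic cohort
#'
#' Draws, per participant: a jittered copy of the canonical templates (small
#' additive topographic perturbation, re-normalized; spatial correlation to
#' the canonical maps stays > 0.9 at the default jitter), a lognormal
#' participant effect on all run-duration means, one epoched recording per
#' condition via [simulate_recording()], and a covariate row. Fully
#' deterministic for a given seed.
#'
#' @param design An `ms_design` from [cohort_design()].
#' @param seed Integer seed.
#' @return An `ms_cohort`: list with `participants` (each: `id`, `group`,
#'   `templates`, `duration_multiplier`, and per-condition `epochs` +
#'   `truth`), `covariates` (data.frame), `manifest` (data.frame),
#'   `montage`, `canonical` templates and the `design`.
#' @export
simulate_cohort <- function(design, seed = 1) {
  stopifnot(inherits(design, "ms_design"))
  set.seed(seed)
  montage <- make_montage(design$n_channels)
  canonical <- make_canonical_templates(montage)
  participants <- list()
  cov_rows <- list()
  man_rows <- list()
  pid <- 0L
  for (gi in seq_along(design$groups)) {
    gname <- names(design$groups)[gi]
    for (s in seq_len(design$groups[gi])) {
      pid <- pid + 1L
      id <- sprintf("P%03d", pid)
      tpl <- jitter_templates(canonical, design$template_jitter_sd)
      mult <- stats::rlnorm(1, meanlog = -design$duration_subject_sdlog^2 / 2,
                            sdlog = design$duration_subject_sdlog)
      conds <- list()
      for (cond in design$conditions) {
        d <- cell_durations(design, gname, cond) * mult
        conds[[cond]] <- simulate_recording(
          tpl, duration_ms = d, transition = design$transition,
          snr = design$snr, fs = design$fs, epoch_s = design$epoch_s,
          n_epochs = design$n_epochs, gfp_scale = design$gfp_scale,
          shape = design$shape)
        man_rows[[length(man_rows) + 1]] <- data.frame(
          participant = id, group = gname, condition = cond,
          file = sprintf("%s_%s.edf", id, cond), stringsAsFactors = FALSE)
      }
      cv <- lapply(design$covariates, function(spec) {
        ms <- spec[[gname]]
        max(0, stats::rnorm(1, ms[1], ms[2]))
      })
      cov_rows[[pid]] <- data.frame(participant = id, group = gname,
                                    as.data.frame(cv),
                                    stringsAsFactors = FALSE)
      participants[[pid]] <- list(id = id, group = gname, templates = tpl,
                                  duration_multiplier = mult,
                                  conditions = conds)
    }
  }
  covariates <- if (length(cov_rows)) do.call(rbind, cov_rows) else
    data.frame(participant = character(0), group = character(0))
  manifest <- if (length(man_rows)) do.call(rbind, man_rows) else
    data.frame(participant = character(0), group = character(0),
               condition = character(0), file = character(0))
  structure(
    list(participants = participants, covariates = covariates,
         manifest = manifest, montage = montage, canonical = canonical,
         design = design, seed = seed),
    class = "ms_cohort"
  )
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf("<ms_cohort> %d participants (%s), conditions %s, seed %d\n",
              length(x$participants),
              paste(sprintf("%s=%d", names(x$design$groups), x$design$groups),
                    collapse = ", "),
              paste(x$design$conditions, collapse = "/"), x$seed))
  invisible(x)
}

# additive topographic jitter; keeps maps average-referenced and unit-norm
jitter_templates <- function(templates, sd) {
  maps <- apply(templates$maps, 2, function(m) {
    z <- stats::rnorm(length(m), 0, sd / sqrt(length(m) - 1))
    z <- z - mean(z)
    v <- m / sqrt(sum(m^2)) + z
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  })
  new_templates(templates$labels, maps, templates$montage)
}

#' Write a cohort to disk (EDF + ground truth + manifest)
#'
#' One EDF file per participant x condition (continuous concatenation of the
#' epochs), a JSON ground-truth sidecar with the true label sequences, the
#' montage as JSON, the covariates and the manifest as CSV.
#'
#' @param cohort An `ms_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest with absolute file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ms_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    for (cond in names(p$conditions)) {
      ep <- p$conditions[[cond]]$epochs
      dat <- matrix(ep$data, nrow = dim(ep$data)[1])
      rec <- eeg_recording(dat, ep$fs, ep$montage)
      write_edf(rec, file.path(dir, sprintf("%s_%s.edf", p$id, cond)))
      jsonlite::write_json(
        list(participant = p$id, condition = cond,
             labels = as.vector(p$conditions[[cond]]$truth$labels),
             duration_ms = p$conditions[[cond]]$truth$duration_ms),
        file.path(dir, sprintf("%s_%s_truth.json", p$id, cond)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    list(channel_ids = cohort$montage$channel_ids,
         positions = cohort$montage$positions),
    file.path(dir, "montage.json"), digits = NA)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  man <- cohort$manifest
  man$file <- file.path(dir, man$file)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
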