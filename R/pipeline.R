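#' Default end-to-end pipeline configuration
#'
#' Analysis constants default to the protocol of a 125 Hz, 2-20 Hz band-pass,
#' 60 Hz notch, 2 s epoch, first-10-artifact-free-epochs resting-state
#' microstate study with K = 4 classes, RM-ANOVAs at alpha 0.05 and
#' Bonferroni post hocs at 0.05/4 = 0.0125.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = NULL,          # list of cohort_design() arguments, or TRUE
    manifest = NULL,          # CSV path (participant,group,condition,file)
    resample_fs = 125,
    filter_lo = 2,
    filter_hi = 20,
    filter_notch = 60,
    epoch_s = 2,
    artifact_amp_uV = 200,
    artifact_flat_uV = 0.5,
    n_epochs = 10,
    K = 4,
    include_truncated = FALSE,
    anova_alpha = 0.05,
    posthoc_family_alpha = 0.05,
    shared_maps = FALSE,
    correlation_covariates = c("age", "iq", "srs_total", "rbsr_total"),
    correlation_parameter = "frequency_hz",
    correlation_class = "C"
  )
}

merge_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(config)] <- config
  base
}

# djb2-style rolling hash of the JSON serialization (mod 2^31-1 keeps the
# accumulator exact in double arithmetic); stable fingerprint for logs
config_hash <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Preprocess a raw continuous recording
#'
#' Applies the standard step order: down-sample, zero-phase band-pass +
#' notch, cut into epochs (with baseline correction), flag artifact epochs
#' and bad channels, keep the first `n_epochs` artifact-free epochs,
#' interpolate bad channels by spherical splines, and re-reference to the
#' common average.
#'
#' @param rec An `ms_recording`.
#' @param config Configuration list (see [default_config()]); only the
#'   preprocessing keys are used.
#' @return A clean, average-referenced `ms_epochs`.
#' @export
preprocess_recording <- function(rec, config = list()) {
  cfg <- merge_config(config)
  rec <- eeg_resample(rec, cfg$resample_fs)
  rec <- eeg_bandpass(rec, cfg$filter_lo, cfg$filter_hi, cfg$filter_notch)
  ep <- eeg_epoch(rec, cfg$epoch_s)
  ep <- flag_artifacts(ep, cfg$artifact_amp_uV, cfg$artifact_flat_uV)
  ep <- select_clean_epochs(ep, cfg$n_epochs)
  ep <- interpolate_channels(ep)
  average_reference(ep)
}

#' Run the full microstate analysis pipeline
#'
#' From epoched per-participant data to group statistics: individual T-AAHC
#' template maps from GFP-peak topographies, second-level group maps per
#' group x condition (or pooled, with `shared_maps = TRUE`), sorting to the
#' canonical A-D maps, backfitting of all samples, microstate parameter
#' extraction, per-class 2x2 mixed ANOVAs with partial eta squared and
#' observed power, Bonferroni post hocs for significant interactions, and
#' (when covariates are available) log-transformed Pearson correlations for
#' the declared family. The input is either a simulated cohort (via the
#' `simulate` config key or a pre-built `ms_cohort`) or a manifest of EDF
#' files. Bit-reproducible for a fixed seed and config.
#'
#' @param config List of configuration overrides (see [default_config()]).
#' @param cohort Optionally, an `ms_cohort` already in memory (overrides the
#'   `simulate`/`manifest` keys).
#' @return List with `parameters` (tidy long table), `total_gev`, `anova`,
#'   `posthoc`, `correlations`, `group_templates`, `individual_templates`,
#'   `segmentations`, `config`, `config_hash` and a per-stage `log`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL) {
  cfg <- merge_config(config)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.null(cohort)) {
    if (!is.null(cfg$simulate)) {
      args <- if (isTRUE(cfg$simulate)) list() else cfg$simulate
      design <- do.call(cohort_design, args)
      cohort <- simulate_cohort(design, seed = cfg$seed)
      note("simulate: %d participants, seed %d", length(cohort$participants),
           cfg$seed)
    } else if (!is.null(cfg$manifest)) {
      cohort <- load_manifest_cohort(cfg)
      note("manifest: %d participants loaded", length(cohort$participants))
    } else {
      stop("config needs either 'simulate' or 'manifest' (or pass a cohort)",
           call. = FALSE)
    }
  }
  montage <- cohort$montage
  canonical <- cohort$canonical %||% make_canonical_templates(montage)
  conditions <- cohort$design$conditions %||%
    sort(unique(unlist(lapply(cohort$participants,
                              function(p) names(p$conditions)))))

  # participants must have every condition (no imputation downstream)
  keep <- vapply(cohort$participants,
                 function(p) all(conditions %in% names(p$conditions)),
                 logical(1))
  if (any(!keep)) {
    dropped <- vapply(cohort$participants[!keep], `[[`, "", "id")
    warning("dropping participants without both conditions: ",
            paste(dropped, collapse = ", "))
    note("dropped %d participants with missing conditions", sum(!keep))
  }
  participants <- cohort$participants[keep]
  if (!length(participants)) stop("no complete participants", call. = FALSE)

  # stage 1: clean epochs + individual templates
  indiv <- list()
  for (p in participants) {
    for (cond in conditions) {
      ep <- p$conditions[[cond]]$epochs
      ep <- flag_artifacts(ep, cfg$artifact_amp_uV, cfg$artifact_flat_uV)
      ep <- select_clean_epochs(ep, cfg$n_epochs)
      ep <- average_reference(ep)
      pk <- gfp_peak_maps(ep)
      tpl <- taahc(pk$maps, pk$gfp, K = cfg$K, montage = montage)
      indiv[[paste(p$id, cond, sep = ".")]] <-
        list(id = p$id, group = p$group, condition = cond, epochs = ep,
             templates = tpl, n_peaks = ncol(pk$maps))
    }
  }
  note("individual templates: %d participant x condition sets", length(indiv))

  # stage 2: group-level maps per group x condition, sorted to canon
  groups <- unique(vapply(participants, `[[`, "", "group"))
  gmaps <- list()
  if (cfg$shared_maps) {
    pool <- lapply(indiv, `[[`, "templates")
    shared <- sort_to_normative(group_templates(pool, K = cfg$K), canonical)
    for (g in groups) for (cond in conditions)
      gmaps[[paste(g, cond, sep = ".")]] <- shared
  } else {
    for (g in groups) {
      for (cond in conditions) {
        pool <- lapply(Filter(function(x) x$group == g && x$condition == cond,
                              indiv), `[[`, "templates")
        gmaps[[paste(g, cond, sep = ".")]] <-
          sort_to_normative(group_templates(pool, K = cfg$K), canonical)
      }
    }
  }
  note("group templates: %d cells", length(gmaps))

  # stage 3: backfit + parameters
  param_rows <- list()
  gev_rows <- list()
  segs <- list()
  for (key in names(indiv)) {
    x <- indiv[[key]]
    tpl <- gmaps[[paste(x$group, x$condition, sep = ".")]]
    seg <- backfit(x$epochs, tpl)
    segs[[key]] <- seg
    rows <- parameter_rows(seg, x$id, x$group, x$condition,
                           include_truncated = cfg$include_truncated)
    param_rows[[key]] <- rows
    gev_rows[[key]] <- data.frame(participant = x$id, group = x$group,
                                  condition = x$condition,
                                  total_gev = attr(rows, "total_gev"),
                                  stringsAsFactors = FALSE)
  }
  parameters <- do.call(rbind, c(param_rows, list(make.row.names = FALSE)))
  total_gev <- do.call(rbind, c(gev_rows, list(make.row.names = FALSE)))
  note("parameters: %d rows", nrow(parameters))

  # stage 4: statistics
  anova_list <- list()
  posthoc_list <- list()
  if (length(groups) == 2 && length(conditions) == 2 &&
      length(participants) >= 4) {
    for (par in unique(parameters$parameter)) {
      for (cl in unique(parameters$class)) {
        sub <- parameters[parameters$parameter == par & parameters$class == cl, ]
        if (anyNA(sub$value)) next
        an <- mixed_anova_2x2(sub, alpha = cfg$anova_alpha)
        res <- an$effects
        res$parameter <- par; res$class <- cl
        anova_list[[paste(par, cl)]] <- res
        if (res$p[res$effect == "group:condition"] < cfg$anova_alpha) {
          ph <- posthoc_bonferroni(sub, alpha = cfg$posthoc_family_alpha)
          ph$parameter <- par; ph$class <- cl
          posthoc_list[[paste(par, cl)]] <- ph
        }
      }
    }
    gtab <- data.frame(participant = total_gev$participant,
                       group = total_gev$group,
                       condition = total_gev$condition,
                       value = total_gev$total_gev)
    res <- mixed_anova_2x2(gtab, alpha = cfg$anova_alpha)$effects
    res$parameter <- "total_gev"; res$class <- "all"
    anova_list[["total_gev"]] <- res
    note("ANOVA: %d tests", length(anova_list))
  } else {
    note("ANOVA skipped: need 2 groups x 2 conditions")
  }
  anova <- if (length(anova_list)) do.call(rbind, c(anova_list, list(make.row.names = FALSE))) else NULL
  posthoc <- if (length(posthoc_list)) do.call(rbind, c(posthoc_list, list(make.row.names = FALSE))) else NULL

  # stage 5: covariate correlations (declared family only)
  correlations <- NULL
  cov <- cohort$covariates
  have <- !is.null(cov) && all(cfg$correlation_covariates %in% names(cov)) &&
    length(groups) == 2
  if (have) {
    target_group <- groups[length(groups)]
    sub <- parameters[parameters$parameter == cfg$correlation_parameter &
                        parameters$class == cfg$correlation_class &
                        parameters$condition == conditions[1] &
                        parameters$group == target_group, ]
    sub <- sub[match(cov$participant[cov$group == target_group],
                     sub$participant), ]
    y <- sub$value
    fam <- length(cfg$correlation_covariates)
    correlations <- do.call(rbind, lapply(cfg$correlation_covariates,
                                          function(cn) {
      x <- cov[[cn]][cov$group == target_group]
      ct <- log_transform_correlate(x, y, n_family = fam)
      data.frame(covariate = cn, group = target_group,
                 parameter = cfg$correlation_parameter,
                 class = cfg$correlation_class, condition = conditions[1],
                 r = ct$r, p = ct$p, p_adjusted = ct$p_adjusted, n = ct$n,
                 stringsAsFactors = FALSE)
    }))
    note("correlations: %d tests (Bonferroni family of %d)",
         nrow(correlations), fam)
  }

  list(parameters = parameters, total_gev = total_gev, anova = anova,
       posthoc = posthoc, correlations = correlations,
       group_templates = gmaps, individual_templates = indiv,
       segmentations = segs, config = cfg, config_hash = config_hash(cfg),
       log = log)
}

# read a manifest of EDF files and preprocess from the raw recordings
load_manifest_cohort <- function(cfg) {
  man <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
  need <- c("participant", "group", "condition", "file")
  if (!all(need %in% names(man)))
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  montage_path <- file.path(dirname(cfg$manifest), "montage.json")
  montage <- NULL
  if (file.exists(montage_path)) {
    mj <- jsonlite::read_json(montage_path, simplifyVector = TRUE)
    montage <- structure(list(channel_ids = mj$channel_ids,
                              positions = as.matrix(mj$positions)),
                         class = "ms_montage")
    colnames(montage$positions) <- c("x", "y", "z")
  }
  participants <- list()
  for (id in unique(man$participant)) {
    rows <- man[man$participant == id, ]
    conds <- list()
    for (i in seq_len(nrow(rows))) {
      rec <- read_edf(rows$file[i], montage = montage)
      if (is.null(montage)) montage <- rec$montage
      conds[[rows$condition[i]]] <-
        list(epochs = preprocess_raw_for_pipeline(rec, cfg))
    }
    participants[[id]] <- list(id = id, group = rows$group[1],
                               conditions = conds)
  }
  cov_path <- file.path(dirname(cfg$manifest), "covariates.csv")
  covariates <- if (file.exists(cov_path))
    utils::read.csv(cov_path, stringsAsFactors = FALSE) else NULL
  structure(list(participants = participants, covariates = covariates,
                 montage = montage, canonical = NULL,
                 design = list(conditions = sort(unique(man$condition)))),
            class = "ms_cohort")
}

# raw-data branch: filter/epoch only; artifact selection and referencing
# happen inside run_pipeline like for simulated cohorts
preprocess_raw_for_pipeline <- function(rec, cfg) {
  rec <- eeg_resample(rec, cfg$resample_fs)
  rec <- eeg_bandpass(rec, cfg$filter_lo, cfg$filter_hi, cfg$filter_notch)
  eeg_epoch(rec, cfg$epoch_s)
}
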