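#' Global explained variance of a segmentation
#'
#' Total GEV is the GFP^2-weighted fraction of topographic variance explained
#' by the labeled templates:
#' `sum_t (GFP(t) * r_t)^2 / sum_t GFP(t)^2`, where `r_t` is the spatial
#' correlation of the frame at `t` with the template of its assigned class.
#' Per-class GEV restricts the numerator to that class; the per-class values
#' sum to the total.
#'
#' @param seg An `ms_segmentation` (from [backfit()] or [make_segmentation()]).
#' @return List with `total` and `per_class` (named by class labels).
#' @export
gev <- function(seg) {
  stopifnot(inherits(seg, "ms_segmentation"))
  denom <- sum(seg$gfp^2)
  if (denom == 0) stop("GEV undefined: all-zero GFP", call. = FALSE)
  contrib <- (seg$gfp * seg$best_corr)^2
  K <- length(seg$class_labels)
  per <- vapply(seq_len(K), function(k) sum(contrib[seg$labels == k]),
                numeric(1)) / denom
  names(per) <- seg$class_labels
  list(total = sum(per), per_class = per)
}

# run-length table: one row per contiguous same-label run within an epoch
run_table <- function(seg) {
  ns <- nrow(seg$labels)
  out <- lapply(seq_len(ncol(seg$labels)), function(e) {
    r <- rle(seg$labels[, e])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(epoch = e, class = r$values, length = r$lengths,
               truncated = starts == 1L | ends == ns)
  })
  do.call(rbind, out)
}

#' Mean microstate duration per class
#'
#' Average length of the contiguous same-label runs of each class, in
#' milliseconds. Runs touching an epoch boundary are excluded by default
#' (they are truncated by the epoching and bias the mean downward); set
#' `include_truncated = TRUE` to count every run. A class with no countable
#' run gets `NA`, not 0.
#'
#' @param seg An `ms_segmentation`.
#' @param include_truncated Count boundary-truncated runs too? Default FALSE.
#' @return Named numeric vector (ms) per class.
#' @export
mean_duration <- function(seg, include_truncated = FALSE) {
  rt <- run_table(seg)
  if (!include_truncated) rt <- rt[!rt$truncated, , drop = FALSE]
  K <- length(seg$class_labels)
  out <- vapply(seq_len(K), function(k) {
    len <- rt$length[rt$class == k]
    if (!length(len)) NA_real_ else mean(len) * 1000 / seg$fs
  }, numeric(1))
  names(out) <- seg$class_labels
  out
}

#' Microstate frequency (occurrence rate) per class
#'
#' Number of run onsets of each class per analyzed second. Uses the same
#' truncation convention as [mean_duration()].
#'
#' @inheritParams mean_duration
#' @return Named numeric vector (Hz) per class.
#' @export
ms_frequency <- function(seg, include_truncated = FALSE) {
  rt <- run_table(seg)
  if (!include_truncated) rt <- rt[!rt$truncated, , drop = FALSE]
  secs <- length(seg$labels) / seg$fs
  K <- length(seg$class_labels)
  out <- vapply(seq_len(K), function(k) sum(rt$class == k) / secs, numeric(1))
  names(out) <- seg$class_labels
  out
}

#' Microstate coverage per class
#'
#' Fraction of all labeled samples assigned to each class; sums to 1.
#'
#' @param seg An `ms_segmentation`.
#' @return Named numeric vector (fractions) per class.
#' @export
ms_coverage <- function(seg) {
  K <- length(seg$class_labels)
  out <- tabulate(seg$labels, nbins = K) / length(seg$labels)
  names(out) <- seg$class_labels
  out
}

#' Mean GFP during each microstate class
#'
#' @param seg An `ms_segmentation`.
#' @return Named numeric vector (microvolts); `NA` for an absent class.
#' @export
gfp_per_state <- function(seg) {
  K <- length(seg$class_labels)
  out <- vapply(seq_len(K), function(k) {
    g <- seg$gfp[seg$labels == k]
    if (!length(g)) NA_real_ else mean(g)
  }, numeric(1))
  names(out) <- seg$class_labels
  out
}

#' Transition probability matrix between microstate classes
#'
#' Counts label changes within epochs (never across an epoch boundary) and
#' row-normalizes; the diagonal is zero by construction and a class with no
#' outgoing transitions keeps an all-zero row. A chi-square statistic against
#' the coverage-implied independent null (next class drawn proportional to
#' its coverage among the other classes) is attached as attributes
#' `"chisq"`, `"df"` and `"counts"`.
#'
#' @param seg An `ms_segmentation`.
#' @return K x K transition probability matrix.
#' @export
ms_transitions <- function(seg) {
  K <- length(seg$class_labels)
  counts <- matrix(0, K, K, dimnames = list(seg$class_labels, seg$class_labels))
  for (e in seq_len(ncol(seg$labels))) {
    l <- seg$labels[, e]
    from <- l[-length(l)]; to <- l[-1]
    ch <- from != to
    if (any(ch))
      counts <- counts + table(factor(from[ch], levels = seq_len(K)),
                               factor(to[ch], levels = seq_len(K)))
  }
  rs <- rowSums(counts)
  P <- counts
  nz <- rs > 0
  P[nz, ] <- counts[nz, ] / rs[nz]
  cov <- ms_coverage(seg)
  chisq <- NA_real_
  if (sum(counts) > 0) {
    E <- outer(rs, cov)
    diag(E) <- 0
    E <- E / pmax(rowSums(E), 1e-300) * rs
    ok <- E > 0
    chisq <- sum((counts[ok] - E[ok])^2 / E[ok])
  }
  structure(P, chisq = chisq, df = K * (K - 2), counts = counts)
}

#' All microstate parameters of a segmentation
#'
#' Convenience wrapper returning the per-class parameter table reported in
#' microstate studies: GEV (fraction), mean duration (ms), frequency (Hz),
#' coverage (fraction), mean GFP (microvolts) and segment counts, plus the
#' total GEV, the transition matrix and the analyzed time.
#'
#' @inheritParams mean_duration
#' @return A list with elements `table` (data.frame, one row per class),
#'   `total_gev`, `transitions`, `analyzed_s`, `degenerate_frames`.
#' @export
microstate_parameters <- function(seg, include_truncated = FALSE) {
  g <- gev(seg)
  rt <- run_table(seg)
  if (!include_truncated) rt <- rt[!rt$truncated, , drop = FALSE]
  K <- length(seg$class_labels)
  nseg <- vapply(seq_len(K), function(k) sum(rt$class == k), numeric(1))
  tab <- data.frame(
    class = seg$class_labels,
    gev = as.numeric(g$per_class),
    duration_ms = as.numeric(mean_duration(seg, include_truncated)),
    frequency_hz = as.numeric(ms_frequency(seg, include_truncated)),
    coverage = as.numeric(ms_coverage(seg)),
    gfp_uV = as.numeric(gfp_per_state(seg)),
    n_segments = nseg,
    stringsAsFactors = FALSE
  )
  list(table = tab, total_gev = g$total, transitions = ms_transitions(seg),
       analyzed_s = length(seg$labels) / seg$fs,
       degenerate_frames = seg$degenerate_frames)
}

#' Tidy long-format parameter table for one participant x condition
#'
#' @param seg An `ms_segmentation`.
#' @param participant,group,condition Identifiers attached to every row.
#' @inheritParams mean_duration
#' @return data.frame with columns participant, group, condition, class,
#'   parameter, value (classes x 5 parameter rows) plus a `"total_gev"`
#'   attribute.
#' @export
parameter_rows <- function(seg, participant, group, condition,
                           include_truncated = FALSE) {
  p <- microstate_parameters(seg, include_truncated)
  long <- do.call(rbind, lapply(c("gev", "duration_ms", "frequency_hz",
                                  "coverage", "gfp_uV"), function(par)
    data.frame(participant = participant, group = group,
               condition = condition, class = p$table$class,
               parameter = par, value = p$table[[par]],
               stringsAsFactors = FALSE)))
  attr(long, "total_gev") <- p$total_gev
  long
}
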