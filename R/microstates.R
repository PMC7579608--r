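#' Global field power
#'
#' GFP at a time point is the population standard deviation of the
#' average-referenced potential over channels: `sqrt(mean((v - mean(v))^2))`.
#' It is invariant to adding a constant to all channels and scales linearly
#' with the data.
#'
#' @param x A numeric frame (one value per channel), a channels x samples
#'   matrix, or an `ms_epochs` object.
#' @return For a frame, a scalar; for a matrix, a vector per sample; for
#'   epochs, a samples x epochs matrix.
#' @examples
#' gfp(c(1, -1))    # 1
#' gfp(c(2, 0, -2, 0))
#' @export
gfp <- function(x) UseMethod("gfp")

#' @export
gfp.numeric <- function(x) {
  if (length(x) < 2) stop("GFP needs >= 2 channels", call. = FALSE)
  sqrt(mean((x - mean(x))^2))
}

#' @export
gfp.matrix <- function(x) {
  if (nrow(x) < 2) stop("GFP needs >= 2 channels", call. = FALSE)
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' @export
gfp.ms_epochs <- function(x) {
  vapply(seq_len(n_epochs(x)), function(e) gfp(x$data[, , e]),
         numeric(epoch_samples(x)))
}

#' Find peaks of a GFP curve
#'
#' Strict local maxima (greater than both neighbours); a flat plateau counts
#' once, at its first sample; the first and last samples of the curve are
#' never peaks. With `min_sep > 1`, of two peaks closer than `min_sep`
#' samples only the larger (earlier on ties) is kept.
#'
#' @param values Numeric GFP curve (one epoch).
#' @param min_sep Minimum separation between retained peaks, in samples.
#' @return Integer vector of peak indices (1-based), strictly increasing.
#' @examples
#' find_gfp_peaks(c(1, 3, 1, 2, 5, 2))  # 2, 5
#' @export
find_gfp_peaks <- function(values, min_sep = 1) {
  n <- length(values)
  if (n < 3) return(integer(0))
  r <- rle(values)
  starts <- cumsum(c(1, r$lengths[-length(r$lengths)]))
  k <- length(r$values)
  peaks <- integer(0)
  if (k >= 3) {
    is_peak <- c(FALSE,
                 r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                   r$values[2:(k - 1)] > r$values[3:k],
                 FALSE)
    peaks <- starts[is_peak]
  }
  peaks <- peaks[peaks > 1 & peaks < n]
  if (min_sep > 1 && length(peaks) > 1) {
    ord <- order(-values[peaks], peaks)
    kept <- integer(0)
    for (p in peaks[ord]) {
      if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  peaks
}

#' Extract topographic maps at GFP peaks
#'
#' @param ep An average-referenced `ms_epochs`.
#' @param min_sep Passed to [find_gfp_peaks()].
#' @return A list with `maps` (channels x n matrix), `gfp` (GFP at each
#'   peak), `peak_index` and `epoch` bookkeeping vectors.
#' @export
gfp_peak_maps <- function(ep, min_sep = 1) {
  stopifnot(inherits(ep, "ms_epochs"))
  g <- gfp(ep)
  maps <- list(); gv <- list(); pk <- list(); epi <- list()
  for (e in seq_len(n_epochs(ep))) {
    idx <- find_gfp_peaks(g[, e], min_sep = min_sep)
    if (!length(idx)) next
    sl <- ep$data[, , e]
    maps[[e]] <- sl[, idx, drop = FALSE]
    gv[[e]] <- g[idx, e]
    pk[[e]] <- idx
    epi[[e]] <- rep(e, length(idx))
  }
  list(maps = do.call(cbind, maps), gfp = unlist(gv),
       peak_index = unlist(pk), epoch = unlist(epi))
}

#' Spatial (topographic) Pearson correlation between two maps
#'
#' For polarity-invariant similarity, take the absolute value of the result:
#' spontaneous-EEG topographies are equivalent up to sign.
#'
#' @param u,v Numeric maps over the same channels (length >= 2, nonconstant).
#' @return Pearson r in \[-1, 1\].
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("maps differ in length", call. = FALSE)
  if (length(u) < 2) stop("maps need >= 2 channels", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("correlation undefined for a constant map", call. = FALSE)
  stats::cor(u, v)
}

# demean columns, return matrix plus column norms
demean_cols <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  list(m = m, norms = sqrt(colSums(m^2)))
}

# |r| between each column of maps and each centroid column (both demeaned)
abs_corr_to_centroids <- function(dm, centroids) {
  r <- crossprod(centroids, dm$m)            # K x n
  r <- sweep(r, 2, pmax(dm$norms, 1e-300), "/")
  abs(r)
}

# polarity-invariant cluster centroid: first left singular vector,
# re-centered and unit-normalized; sign canonicalized for determinism
cluster_centroid <- function(maps) {
  if (ncol(maps) == 1) {
    v <- maps[, 1] - mean(maps[, 1])
  } else {
    v <- svd(maps, nu = 1, nv = 0)$u[, 1]
    v <- v - mean(v)
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) return(v)
  v <- v / nrm
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Topographic Atomize and Agglomerate Hierarchical Clustering (T-AAHC)
#'
#' Bottom-up, polarity-invariant clustering of topographic maps. Every map
#' starts as its own cluster; at each step the cluster contributing least
#' global explained variance (sum over its members of (GFP x |spatial
#' correlation to the cluster centroid|)^2) is atomized and each of its
#' members is reassigned to the surviving cluster whose centroid it matches
#' best by absolute spatial correlation, until `K` clusters remain. Cluster
#' centroids are the first principal component of the member maps,
#' re-centered to zero mean and unit norm. Ties at the atomization step go to
#' the cluster with fewer members, then the lower index.
#'
#' @param maps channels x n matrix of average-referenced maps (e.g. from
#'   [gfp_peak_maps()]).
#' @param gfp_values GFP weight per map (defaults to each map's own GFP).
#' @param K Number of clusters to retain (default 4).
#' @param montage Optional `ms_montage` carried into the output templates.
#' @return An `ms_templates` with labels `M1..MK` (unsorted; see
#'   [sort_to_normative()]) and an integer attribute `"partition"` giving the
#'   final cluster of every input map.
#' @export
taahc <- function(maps, gfp_values = NULL, K = 4, montage = NULL) {
  maps <- as.matrix(maps)
  n <- ncol(maps)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (n < K) stop("fewer maps than clusters requested", call. = FALSE)
  if (is.null(gfp_values)) gfp_values <- gfp(maps)
  stopifnot(length(gfp_values) == n)
  dm <- demean_cols(maps)

  members <- as.list(seq_len(n))
  centroids <- matrix(0, nrow(maps), n)
  for (i in seq_len(n)) centroids[, i] <- cluster_centroid(maps[, i, drop = FALSE])
  contrib <- numeric(n)
  for (i in seq_len(n)) contrib[i] <- cluster_gev_contrib(members[[i]], centroids[, i], dm, gfp_values)

  alive <- rep(TRUE, n)
  n_alive <- n
  while (n_alive > K) {
    idx <- which(alive)
    sizes <- lengths(members[idx])
    ord <- order(contrib[idx], sizes, idx)
    worst <- idx[ord[1]]
    freed <- members[[worst]]
    alive[worst] <- FALSE
    n_alive <- n_alive - 1L
    idx <- which(alive)
    r <- abs_corr_to_centroids(
      list(m = dm$m[, freed, drop = FALSE], norms = dm$norms[freed]),
      centroids[, idx, drop = FALSE])              # n_alive x n_freed
    dest <- idx[apply(r, 2, which.max)]
    touched <- unique(dest)
    for (j in seq_along(freed)) members[[dest[j]]] <- c(members[[dest[j]]], freed[j])
    for (cl in touched) {
      centroids[, cl] <- cluster_centroid(maps[, members[[cl]], drop = FALSE])
      contrib[cl] <- cluster_gev_contrib(members[[cl]], centroids[, cl], dm, gfp_values)
    }
  }

  idx <- which(alive)
  out <- centroids[, idx, drop = FALSE]
  part <- integer(n)
  for (j in seq_along(idx)) part[members[[idx[j]]]] <- j
  tpl <- new_templates(paste0("M", seq_len(K)), out, montage)
  attr(tpl, "partition") <- part
  tpl
}

cluster_gev_contrib <- function(member_idx, centroid, dm, gfp_values) {
  m <- dm$m[, member_idx, drop = FALSE]
  r <- as.numeric(crossprod(centroid, m)) / pmax(dm$norms[member_idx], 1e-300)
  sum((gfp_values[member_idx] * r)^2)
}

#' Second-level (group) template maps
#'
#' Pools the individual template maps of several participants (each map
#' rescaled to unit GFP so every participant weighs equally) and clusters the
#' pool with [taahc()] into `K` group-level maps. Run this per group x
#' condition cell.
#'
#' @param template_list List of `ms_templates`, one per participant.
#' @param K Number of group classes (default 4).
#' @return An `ms_templates` of group maps (unsorted).
#' @export
group_templates <- function(template_list, K = 4) {
  if (!length(template_list)) stop("empty template pool", call. = FALSE)
  pool <- do.call(cbind, lapply(template_list, function(t) {
    apply(t$maps, 2, function(m) {
      m <- m - mean(m)
      m / gfp(m)
    })
  }))
  montage <- template_list[[1]]$montage
  taahc(pool, gfp_values = rep(1, ncol(pool)), K = K, montage = montage)
}

all_permutations <- function(v) {
  if (length(v) == 1) return(matrix(v))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_permutations(v[-i])))
  out
}

#' Sort template maps against a normative set
#'
#' Evaluates every permutation of the `K` template maps (`K! = 24` for the
#' canonical four classes) and keeps the assignment that maximizes the total
#' absolute spatial correlation with the normative maps. Output maps take the
#' normative labels (A-D) and are polarity-flipped where needed so that the
#' correlation with the matched normative map is non-negative.
#'
#' @param templates `ms_templates` to relabel.
#' @param normative `ms_templates` reference set (same K, same channel count).
#' @return An `ms_templates` with normative ordering, labels and polarity.
#'   Attribute `"similarity"` holds the per-class |r| achieved, `"order"`
#'   the permutation applied.
#' @export
sort_to_normative <- function(templates, normative) {
  if (nrow(templates$maps) != nrow(normative$maps))
    stop("montage mismatch between template sets", call. = FALSE)
  K <- length(normative$labels)
  if (length(templates$labels) != K)
    stop("template sets differ in class count", call. = FALSE)
  R <- abs(stats::cor(templates$maps, normative$maps))  # K x K: [tpl, norm]
  perms <- all_permutations(seq_len(K))
  scores <- apply(perms, 1, function(p) sum(R[cbind(p, seq_len(K))]))
  best <- perms[which.max(scores), ]
  maps <- templates$maps[, best, drop = FALSE]
  sim <- numeric(K)
  for (k in seq_len(K)) {
    r <- stats::cor(maps[, k], normative$maps[, k])
    if (r < 0) maps[, k] <- -maps[, k]
    sim[k] <- abs(r)
  }
  out <- new_templates(normative$labels, maps, templates$montage %||% normative$montage)
  attr(out, "similarity") <- sim
  attr(out, "order") <- best
  out
}

#' Backfit template maps onto continuous epoched data
#'
#' Labels every time point (all samples, not only GFP peaks) with the class
#' whose template it matches best by absolute spatial Pearson correlation.
#' No temporal smoothing or minimum-correlation rejection is applied. A
#' (numerically) constant frame inherits the previous sample's label (class 1
#' at an epoch start) and is counted as degenerate.
#'
#' @param ep An average-referenced `ms_epochs`.
#' @param templates `ms_templates` with K >= 2 classes.
#' @return An `ms_segmentation`: `labels` and `best_corr` (samples x epochs
#'   matrices), `gfp`, `fs`, `class_labels`, and a `degenerate_frames` count.
#' @export
backfit <- function(ep, templates) {
  stopifnot(inherits(ep, "ms_epochs"))
  K <- length(templates$labels)
  if (K < 2) stop("need >= 2 template classes", call. = FALSE)
  Tm <- apply(templates$maps, 2, function(m) {
    m <- m - mean(m)
    m / sqrt(sum(m^2))
  })
  ns <- epoch_samples(ep); ne <- n_epochs(ep)
  labels <- matrix(0L, ns, ne)
  best <- matrix(0, ns, ne)
  degen <- 0L
  for (e in seq_len(ne)) {
    dm <- demean_cols(ep$data[, , e])
    r <- abs(crossprod(Tm, dm$m))                 # K x ns
    const <- dm$norms < 1e-12
    r <- sweep(r, 2, pmax(dm$norms, 1e-300), "/")
    lab <- max.col(t(r), ties.method = "first")
    bc <- r[cbind(lab, seq_len(ns))]
    if (any(const)) {
      degen <- degen + sum(const)
      bc[const] <- 0
      for (i in which(const)) lab[i] <- if (i == 1) 1L else lab[i - 1]
    }
    labels[, e] <- lab
    best[, e] <- bc
  }
  new_segmentation(labels, best, gfp(ep), ep$fs, templates$labels,
                   degenerate_frames = degen)
}

new_segmentation <- function(labels, best_corr, gfp, fs, class_labels,
                             degenerate_frames = 0L) {
  stopifnot(all(dim(labels) == dim(best_corr)), all(dim(labels) == dim(gfp)))
  structure(
    list(labels = labels, best_corr = best_corr, gfp = gfp, fs = fs,
         class_labels = class_labels, degenerate_frames = degenerate_frames),
    class = "ms_segmentation"
  )
}

#' Build a segmentation from externally supplied labels
#'
#' Computes the per-sample absolute spatial correlation of each frame with the
#' template of its given label, yielding an `ms_segmentation` comparable with
#' [backfit()] output. Useful for evaluating ground-truth label sequences or
#' alternative labelings under the same GEV accounting.
#'
#' @param ep An `ms_epochs`.
#' @param templates `ms_templates`.
#' @param labels samples x epochs integer matrix of class indices.
#' @return An `ms_segmentation`.
#' @export
make_segmentation <- function(ep, templates, labels) {
  stopifnot(inherits(ep, "ms_epochs"))
  labels <- as.matrix(labels)
  ns <- epoch_samples(ep); ne <- n_epochs(ep)
  stopifnot(nrow(labels) == ns, ncol(labels) == ne)
  Tm <- apply(templates$maps, 2, function(m) {
    m <- m - mean(m)
    m / sqrt(sum(m^2))
  })
  best <- matrix(0, ns, ne)
  for (e in seq_len(ne)) {
    dm <- demean_cols(ep$data[, , e])
    r <- abs(crossprod(Tm, dm$m))
    r <- sweep(r, 2, pmax(dm$norms, 1e-300), "/")
    best[, e] <- r[cbind(labels[, e], seq_len(ns))]
  }
  new_segmentation(labels, best, gfp(ep), ep$fs, templates$labels)
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples x %d epochs @ %g Hz, %d classes\n",
              nrow(x$labels), ncol(x$labels), x$fs, length(x$class_labels)))
  invisible(x)
}
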