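#' Construct a scalp electrode montage
#'
#' Places `n_channels` electrodes approximately uniformly over the upper part
#' of the unit sphere (a Fibonacci lattice restricted to z >= -0.2, mimicking
#' scalp coverage down to just below the equator). The layout is
#' deterministic: the same `n_channels` always yields the same montage.
#'
#' Axis convention: +x is the subject's right, +y anterior (nose), +z vertex.
#'
#' @param n_channels Number of electrodes (>= 8). Default 32; use 128 for a
#'   high-density net.
#' @return An object of class `ms_montage`: a list with `channel_ids`
#'   (character) and `positions` (`n_channels` x 3 matrix of unit vectors).
#' @examples
#' mon <- make_montage(32)
#' range(sqrt(rowSums(mon$positions^2)))
#' @export
make_montage <- function(n_channels = 32L) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 8L)
    stop("n_channels must be an integer >= 8", call. = FALSE)
  # Fibonacci lattice on the spherical cap z in [-0.2, 1]
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n_channels)
  z <- 1 - 1.2 * (i - 0.5) / n_channels
  phi <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  structure(
    list(
      channel_ids = sprintf("E%03d", i),
      positions = pos
    ),
    class = "ms_montage"
  )
}

#' @export
print.ms_montage <- function(x, ...) {
  cat(sprintf("<ms_montage> %d channels on the unit sphere (z >= %.2f)\n",
              nrow(x$positions), min(x$positions[, 3])))
  invisible(x)
}

n_channels <- function(montage) nrow(montage$positions)

validate_montage <- function(montage) {
  if (!inherits(montage, "ms_montage"))
    stop("expected an 'ms_montage' object", call. = FALSE)
  norms <- sqrt(rowSums(montage$positions^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("montage positions must lie on the unit sphere", call. = FALSE)
  if (anyDuplicated(montage$channel_ids))
    stop("montage channel_ids must be unique", call. = FALSE)
  invisible(montage)
}

#' Canonical microstate template maps A-D
#'
#' Builds the four archetypal resting-state topographies analytically from the
#' montage geometry: class A has a right-frontal / left-occipital diagonal
#' orientation, class B the mirrored left-frontal / right-occipital diagonal,
#' class C an anterior-posterior axis, and class D a fronto-central maximum.
#' Each map is average-referenced (zero channel mean) and unit-normalized.
#'
#' @param montage An `ms_montage`.
#' @return An `ms_templates` object: list with `labels` (`c("A","B","C","D")`),
#'   `maps` (channels x 4 matrix, one column per class) and the `montage`.
#' @examples
#' tpl <- make_canonical_templates(make_montage(32))
#' colnames(tpl$maps)
#' @export
make_canonical_templates <- function(montage) {
  validate_montage(montage)
  p <- montage$positions
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  # D: radial Gaussian bump centred on a fronto-central scalp point
  fc <- c(0, 0.5, sqrt(1 - 0.25))
  ang <- acos(pmin(1, pmax(-1, p %*% fc)))
  maps <- cbind(
    A = x + y,
    B = -x + y,
    C = y,
    D = exp(-(ang / 0.8)^2 / 2)
  )
  maps <- apply(maps, 2, function(m) {
    m <- m - mean(m)
    m / sqrt(sum(m^2))
  })
  new_templates(labels = c("A", "B", "C", "D"), maps = maps, montage = montage)
}

new_templates <- function(labels, maps, montage) {
  maps <- as.matrix(maps)
  stopifnot(length(labels) == ncol(maps))
  colnames(maps) <- labels
  structure(
    list(labels = labels, maps = maps, montage = montage),
    class = "ms_templates"
  )
}

#' @export
print.ms_templates <- function(x, ...) {
  cat(sprintf("<ms_templates> %d classes (%s) over %d channels\n",
              length(x$labels), paste(x$labels, collapse = ","),
              nrow(x$maps)))
  invisible(x)
}

validate_templates <- function(templates) {
  if (!inherits(templates, "ms_templates"))
    stop("expected an 'ms_templates' object", call. = FALSE)
  mu <- colMeans(templates$maps)
  if (any(abs(mu) > 1e-8))
    stop("template maps must be average-referenced", call. = FALSE)
  nrm <- sqrt(colSums(templates$maps^2))
  if (any(nrm == 0))
    stop("template maps must have nonzero norm", call. = FALSE)
  invisible(templates)
}

# great-circle angles between all channel pairs, in radians
montage_angles <- function(montage) {
  cosang <- tcrossprod(montage$positions)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}
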