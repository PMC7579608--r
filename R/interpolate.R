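#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs the channels listed in `bad_channels` of each epoch from the
#' remaining good channels with the spherical-spline method of Perrin et al.:
#' the kernel is g(cos theta) = (1/4pi) * sum_{n=1}^{N} (2n+1) /
#' (n^m (n+1)^m) * P_n(cos theta) with stiffness m = 4 and N = 50 Legendre
#' terms. The constrained linear system (spline coefficients summing to zero
#' plus a constant term) is solved on the good channels and evaluated at the
#' bad-channel positions. Good channels are returned bit-for-bit unchanged.
#'
#' @param ep An `ms_epochs` with `bad_channels` filled (e.g. by
#'   [flag_artifacts()]).
#' @param montage Electrode montage; defaults to the one attached to `ep`.
#' @param m Spline stiffness (default 4).
#' @param nterms Number of Legendre terms (default 50).
#' @param lambda Ridge regularization added to the kernel diagonal
#'   (default 1e-8).
#' @return The `ms_epochs` with bad channels replaced by interpolated values
#'   and `bad_channels` cleared.
#' @export
interpolate_channels <- function(ep, montage = ep$montage, m = 4,
                                 nterms = 50, lambda = 1e-8) {
  stopifnot(inherits(ep, "ms_epochs"))
  validate_montage(montage)
  nch <- n_channels(montage)
  if (anyDuplicated(round(montage$positions, 9)))
    stop("duplicate electrode positions make the spline system singular",
         call. = FALSE)
  G <- spline_gmatrix(montage, m = m, nterms = nterms)
  for (e in seq_len(n_epochs(ep))) {
    bad <- ep$bad_channels[[e]]
    if (length(bad) == 0) next
    if (length(bad) >= 0.25 * nch)
      stop(sprintf(
        "epoch %d: %d of %d channels bad; refusing to interpolate >= 25%%",
        e, length(bad), nch), call. = FALSE)
    good <- setdiff(seq_len(nch), bad)
    ng <- length(good)
    A <- rbind(cbind(G[good, good] + diag(lambda, ng), 1),
               c(rep(1, ng), 0))
    sl <- matrix(ep$data[, , e], nrow = nch)
    rhs <- rbind(sl[good, , drop = FALSE], 0)
    sol <- solve(A, rhs)
    coef <- sol[seq_len(ng), , drop = FALSE]
    c0 <- sol[ng + 1, ]
    ep$data[bad, , e] <- G[bad, good, drop = FALSE] %*% coef +
      matrix(c0, nrow = length(bad), ncol = ncol(coef), byrow = TRUE)
    ep$bad_channels[[e]] <- integer(0)
  }
  ep
}

# Perrin kernel evaluated on all channel pairs
spline_gmatrix <- function(montage, m = 4, nterms = 50) {
  cosang <- tcrossprod(montage$positions)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  legendre_kernel(cosang, m = m, nterms = nterms)
}

# (1/4pi) sum_{n=1}^{N} (2n+1)/(n(n+1))^m * P_n(x), elementwise on x
legendre_kernel <- function(x, m = 4, nterms = 50) {
  p_prev <- array(1, dim = dim(x) %||% length(x))   # P_0
  p_cur <- x                                        # P_1
  acc <- 3 / (2^m) * p_cur
  for (n in 2:nterms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
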