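#' Spherical-spline parameters
#'
#' Parameters of the Perrin-style spherical-spline interpolator: spline
#' order `m` (stiffness; 4 is the standard choice for EEG), ridge
#' regularization `lambda` on the good-channel system, and the truncation
#' point of the Legendre series defining the kernel.
#'
#' @param m integer spline order (>= 2, default 4).
#' @param lambda regularization constant (default 1e-5).
#' @param n_legendre_terms number of series terms (default 50).
#' @return an object of class `spline_params`.
#' @export
spline_params <- function(m = 4L, lambda = 1e-5, n_legendre_terms = 50L) {
  if (m < 2L || lambda <= 0 || n_legendre_terms < 1L)
    stopf("invalid spline parameters")
  structure(list(m = as.integer(m), lambda = lambda,
                 n_legendre_terms = as.integer(n_legendre_terms)),
            class = "spline_params")
}

# Legendre polynomials P_1..P_nmax evaluated at x (vector), via the
# three-term recurrence. Returns matrix length(x) x nmax.
legendre_table <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pnm1 <- rep(1, length(x)) # P_0
  pn <- x                   # P_1
  out[, 1] <- pn
  for (n in seq_len(nmax - 1L)) {
    pnp1 <- ((2 * n + 1) * x * pn - n * pnm1) / (n + 1)
    out[, n + 1L] <- pnp1
    pnm1 <- pn
    pn <- pnp1
  }
  out
}

# Spherical-spline kernel g(cos theta) = (1/4pi) sum (2n+1)/(n(n+1))^m P_n.
spline_g <- function(cosang, params) {
  n <- seq_len(params$n_legendre_terms)
  w <- (2 * n + 1) / (n * (n + 1))^params$m
  p <- legendre_table(pmin(pmax(cosang, -1), 1), params$n_legendre_terms)
  as.vector(p %*% w) / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels, in every trial, by the Perrin-style
#' spherical-spline estimate fitted to the remaining channels: the kernel
#' `g(cos theta)` is a truncated Legendre series of order `m`, fitted with
#' a sum-to-zero constrained ridge system on the good channels. Good
#' channels are untouched; constant fields are reproduced exactly.
#'
#' @param epochs an `epoch_set`.
#' @param bad_ids electrode IDs to replace (empty vector = identity).
#' @param layout an `electrode_layout` (defaults to the one in `epochs`).
#' @param params a `spline_params`.
#' @return the `epoch_set` with bad channels replaced.
#' @export
interpolate_channels <- function(epochs, bad_ids,
                                 layout = epochs$layout,
                                 params = spline_params()) {
  if (!length(bad_ids)) return(epochs)
  bidx <- electrode_index(epochs, bad_ids)
  gidx <- setdiff(seq_len(dim(epochs$amp)[4]), bidx)
  if (!length(gidx)) stopf("all channels marked bad")
  if (length(gidx) < 4L)
    stopf("need at least 4 good channels for spline interpolation (have %d)",
          length(gidx))
  p <- layout_positions(layout)
  p <- p / sqrt(rowSums(p^2))
  cos_gg <- tcrossprod(p[gidx, , drop = FALSE])
  cos_bg <- tcrossprod(p[bidx, , drop = FALSE], p[gidx, , drop = FALSE])
  ng <- length(gidx)
  g_gg <- matrix(spline_g(as.vector(cos_gg), params), ng, ng)
  g_bg <- matrix(spline_g(as.vector(cos_bg), params), length(bidx), ng)
  sys <- rbind(cbind(g_gg + diag(params$lambda, ng), rep(1, ng)),
               c(rep(1, ng), 0))
  d <- dim(epochs$amp)
  # points = all (subject, condition, trial, time) combinations
  ap <- aperm(epochs$amp, c(4, 1, 2, 3, 5)) # (e, s, c, r, t)
  z <- matrix(ap[gidx, , , , ], ng, prod(d[c(1:3, 5)]))
  coef <- solve(sys, rbind(z, 0))
  pred <- g_bg %*% coef[seq_len(ng), , drop = FALSE] +
    rep(coef[ng + 1L, ], each = length(bidx))
  ap[bidx, , , , ] <- pred
  replace_amp(epochs, aperm(ap, c(2, 3, 4, 1, 5)))
}
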