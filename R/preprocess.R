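#' Re-reference to the average of two (pseudo-)mastoid channels
#'
#' Subtracts the mean of the two reference channels from every channel at
#' every sample, emulating an offline linked-mastoid reference. On the
#' synthetic montage the two designated scalp-border channels from
#' [default_mastoids()] stand in for the mastoids.
#'
#' @param epochs an `epoch_set`.
#' @param left_ref_id,right_ref_id electrode IDs of the two references.
#' @return the re-referenced `epoch_set`.
#' @export
rereference_mastoids <- function(epochs, left_ref_id, right_ref_id) {
  li <- electrode_index(epochs, left_ref_id)
  ri <- electrode_index(epochs, right_ref_id)
  d <- dim(epochs$amp)
  ref <- (epochs$amp[, , , li, , drop = FALSE] +
            epochs$amp[, , , ri, , drop = FALSE]) / 2 # (s, c, r, 1, t)
  ap <- aperm(epochs$amp, c(1, 2, 3, 5, 4)) # (s, c, r, t, e)
  ap <- ap - as.vector(ref) # recycles over the electrode axis
  replace_amp(epochs, aperm(ap, c(1, 2, 3, 5, 4)))
}

# nth-order Butterworth low-pass, bilinear transform. Returns list(b, a).
butter_lowpass <- function(order, cutoff, srate) {
  if (cutoff <= 0 || cutoff >= srate / 2)
    stopf("cutoff must lie in (0, Nyquist = %g)", srate / 2)
  n <- as.integer(order)
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n)) # left half-plane
  wc <- 2 * srate * tan(pi * cutoff / srate) # pre-warped analog cutoff
  p <- wc * p_proto
  fs2 <- 2 * srate
  zp <- (fs2 + p) / (fs2 - p) # bilinear-transformed poles
  gain <- Re(wc^n / prod(fs2 - p))
  poly_from_roots <- function(r) {
    cf <- 1
    for (root in r) cf <- c(cf, 0) - c(0, cf * root)
    cf
  }
  b <- Re(gain * poly_from_roots(rep(-1 + 0i, n)))
  a <- Re(poly_from_roots(zp))
  list(b = b, a = a / a[1])
}

# Steady-state initial filter state per unit input level (companion-matrix
# solve), so that forward/backward passes start transient-free.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  m <- diag(n)
  m[, 1] <- m[, 1] + a[-1]
  if (n > 1L) for (i in seq_len(n - 1L)) m[i, i + 1L] <- m[i, i + 1L] - 1
  rhs <- b[-1] - a[-1] * b[1]
  solve(m, rhs)
}

# Zero-phase (forward-backward) filtering of the columns of x, with odd
# end-reflection padding.
filtfilt_mat <- function(x, b, a, padlen) {
  n_t <- nrow(x)
  if (n_t <= padlen + 1L)
    stopf("epoch too short for the filter warm-up (%d samples <= padlen %d)",
          n_t, padlen)
  zi <- lfilter_zi(b, a)
  pre <- 2 * x[rep(1L, padlen), , drop = FALSE] -
    x[seq(padlen + 1L, 2L), , drop = FALSE]
  post <- 2 * x[rep(n_t, padlen), , drop = FALSE] -
    x[seq(n_t - 1L, n_t - padlen), , drop = FALSE]
  xp <- rbind(pre, x, post)
  y <- iir_filter_cpp(xp, b, a, zi)
  y <- iir_filter_cpp(y[nrow(y):1L, , drop = FALSE], b, a, zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[seq(padlen + 1L, padlen + n_t), , drop = FALSE]
}

#' Zero-phase low-pass filter
#'
#' Forward-backward application of an IIR Butterworth low-pass (default:
#' 4th order at 20 Hz), giving zero phase shift and a squared-magnitude
#' response (-6 dB at the cutoff; the effective roll-off is that of an
#' 8th-order magnitude response). DC is preserved exactly; startup
#' transients are suppressed by odd end-reflection padding with
#' steady-state initial conditions.
#'
#' @param epochs an `epoch_set`.
#' @param cutoff cutoff frequency in Hz (default 20); must be below
#'   Nyquist.
#' @param order filter order of each pass (default 4).
#' @return the filtered `epoch_set`.
#' @export
lowpass_filter <- function(epochs, cutoff = 20, order = 4L) {
  ba <- butter_lowpass(order, cutoff, epochs$srate)
  padlen <- 3L * (length(ba$a) + 2L)
  d <- dim(epochs$amp)
  ap <- aperm(epochs$amp, c(5, 1, 2, 3, 4))
  mat <- matrix(ap, d[5], prod(d[1:4]))
  mat <- filtfilt_mat(mat, ba$b, ba$a, padlen)
  ap <- array(mat, c(d[5], d[1:4]))
  replace_amp(epochs, aperm(ap, c(2, 3, 4, 5, 1)))
}

#' Baseline-correct every trial
#'
#' Subtracts, per trial and electrode, the mean amplitude over the
#' baseline window; afterwards the window mean is zero to numerical
#' precision.
#'
#' @param epochs an `epoch_set`.
#' @param window `c(start, end)` in seconds relative to the locking event.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window) {
  if (length(window) != 2L || window[1] >= window[2])
    stopf("baseline window must be c(start, end) with start < end")
  tidx <- time_index(epochs, window)
  d <- dim(epochs$amp)
  mat <- matrix(epochs$amp, prod(d[1:4]), d[5])
  bl <- rowMeans(mat[, tidx, drop = FALSE])
  replace_amp(epochs, array(mat - bl, d, dimnames = dimnames(epochs$amp)))
}

#' Window-averaged amplitude per subject and condition
#'
#' Averages over trials, then over the electrode set and the samples in
#' the time window, yielding one scalar per subject and condition — the
#' input to the window-based Bayes-factor analyses.
#'
#' @param epochs an `epoch_set`.
#' @param electrode_set electrode IDs (`NULL` = all).
#' @param time_window `c(start, end)` in seconds (`NULL` = whole epoch).
#' @return numeric matrix (subject x condition), in microvolts.
#' @export
window_mean <- function(epochs, electrode_set = NULL, time_window = NULL) {
  if (!is.null(electrode_set) && !length(electrode_set))
    stopf("empty electrode selection")
  eidx <- electrode_index(epochs, electrode_set)
  tidx <- time_index(epochs, time_window)
  sub <- epochs$amp[, , , eidx, tidx, drop = FALSE]
  d <- dim(sub)
  out <- rowMeans(matrix(sub, d[1] * d[2], prod(d[3:5])))
  matrix(out, d[1], d[2],
         dimnames = list(dimnames(epochs$amp)[[1]], epoch_conditions(epochs)))
}
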