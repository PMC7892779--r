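make_epochs <- function(amp, srate = 100, t0 = -0.3, layout = NULL) {
  d <- dim(amp)
  layout <- layout %||% tiny_layout(d[4])
  time <- t0 + (seq_len(d[5]) - 1) / srate
  dimnames(amp) <- list(NULL, paste0("C", seq_len(d[2])), NULL,
                        as.character(layout$id), NULL)
  epoch_set(amp, time, srate, layout)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("mastoid re-reference subtracts the mean of the two refs", {
  set.seed(1)
  amp <- array(rnorm(2 * 2 * 3 * 7 * 40), c(2, 2, 3, 7, 40))
  ep <- make_epochs(amp)
  ids <- ep$layout$id
  out <- rereference_mastoids(ep, ids[6], ids[7])
  ref <- (amp[, , , 6, ] + amp[, , , 7, ]) / 2
  for (e in 1:7)
    expect_equal(out$amp[, , , e, ], amp[, , , e, ] - ref, tolerance = 1e-12,
                 ignore_attr = TRUE)
  # refs identically zero leave the data unchanged
  amp0 <- amp; amp0[, , , 6:7, ] <- 0
  ep0 <- make_epochs(amp0)
  expect_equal(rereference_mastoids(ep0, ids[6], ids[7])$amp, amp0,
               ignore_attr = TRUE)
  # all channels equal to the refs -> all zero
  amp1 <- amp
  for (e in 1:7) amp1[, , , e, ] <- amp[, , , 6, ]
  out1 <- rereference_mastoids(make_epochs(amp1), ids[6], ids[7])
  expect_lt(max(abs(out1$amp)), 1e-12)
  expect_error(rereference_mastoids(ep, 999, ids[7]), "not present")
})

test_that("zero-phase low-pass preserves DC, kills 40 Hz, keeps symmetry", {
  srate <- 500
  n_t <- 601L
  tt <- (seq_len(n_t) - 1) / srate
  mk <- function(x) {
    amp <- array(0, c(1, 1, 1, 5, n_t))
    for (e in 1:5) amp[1, 1, 1, e, ] <- x
    make_epochs(amp, srate = srate, t0 = 0)
  }
  # constant passes untouched
  out <- lowpass_filter(mk(rep(5, n_t)), 20)
  expect_lt(max(abs(out$amp - 5)), 1e-9)
  # 40 Hz tone attenuated by at least 20 dB (measured away from edges)
  tone <- sin(2 * pi * 40 * tt)
  out <- lowpass_filter(mk(tone), 20)
  mid <- 150:450
  atten <- 20 * log10(sqrt(mean(out$amp[1, 1, 1, 1, mid]^2)) /
                        sqrt(mean(tone[mid]^2)))
  expect_lt(atten, -20)
  # 5 Hz tone passes nearly unchanged
  slow <- sin(2 * pi * 5 * tt)
  out <- lowpass_filter(mk(slow), 20)
  expect_gt(sqrt(mean(out$amp[1, 1, 1, 1, mid]^2)) /
              sqrt(mean(slow[mid]^2)), 0.95)
  # symmetric pulse keeps its peak sample (zero group delay)
  pulse <- exp(-((tt - tt[301])^2) / (2 * 0.02^2))
  out <- lowpass_filter(mk(pulse), 20)
  expect_equal(which.max(out$amp[1, 1, 1, 1, ]), 301L)
  cc <- ccf(out$amp[1, 1, 1, 1, ], pulse, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0L)
  expect_error(lowpass_filter(mk(rep(1, n_t)), cutoff = 300), "Nyquist")
  short <- array(rnorm(1 * 1 * 1 * 5 * 10), c(1, 1, 1, 5, 10))
  expect_error(lowpass_filter(make_epochs(short, srate = srate, t0 = 0), 20),
               "too short")
})

test_that("baseline correction zeroes the window mean", {
  set.seed(2)
  amp <- array(rnorm(2 * 2 * 2 * 5 * 50, mean = 3), c(2, 2, 2, 5, 50))
  ep <- make_epochs(amp)
  out <- baseline_correct(ep, c(-0.3, -0.2))
  tidx <- which(out$time <= -0.2 + 0.005)
  bl <- apply(out$amp[, , , , tidx, drop = FALSE], 1:4, mean)
  expect_lt(max(abs(bl)), 1e-12)
  # constant trace becomes identically zero
  cst <- make_epochs(array(5, c(1, 1, 1, 5, 50)))
  expect_lt(max(abs(baseline_correct(cst, c(-0.3, -0.2))$amp)), 1e-12)
  # already baseline-zero input is unchanged
  again <- baseline_correct(out, c(-0.3, -0.2))
  expect_equal(again$amp, out$amp, tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(0.2, 0.2)), "start < end")
  expect_error(baseline_correct(ep, c(5, 6)), "outside")
})

test_that("window_mean matches a brute-force nested-loop oracle", {
  set.seed(3)
  amp <- array(rnorm(3 * 2 * 4 * 6 * 30), c(3, 2, 4, 6, 30))
  ep <- make_epochs(amp)
  ids <- ep$layout$id[2:4]
  win <- c(-0.1, 0.1)
  wm <- window_mean(ep, ids, win)
  tidx <- which(ep$time >= win[1] - 0.005 & ep$time <= win[2] + 0.005)
  for (s in 1:3) for (ci in 1:2) {
    acc <- 0; cnt <- 0
    for (r in 1:4) for (e in 2:4) for (ti in tidx) {
      acc <- acc + amp[s, ci, r, e, ti]; cnt <- cnt + 1
    }
    expect_equal(wm[s, ci], acc / cnt, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # all-ones input -> 1 everywhere; single point -> that sample's trial mean
  ones <- make_epochs(array(1, c(2, 2, 2, 6, 30)))
  expect_true(all(window_mean(ones) == 1))
  single <- window_mean(ep, ep$layout$id[1], c(ep$time[7], ep$time[7]))
  expect_equal(unname(single[1, 1]), mean(amp[1, 1, , 1, 7]),
               tolerance = 1e-12)
  expect_error(window_mean(ep, integer(0), win), "empty")
})

test_that("spherical-spline interpolation is exact on constants and accurate on smooth fields", {
  lay <- build_default_layout()
  n_e <- nrow(lay)
  # constant field
  cst <- array(7, c(1, 1, 1, n_e, 3))
  ep <- make_epochs(cst, layout = lay)
  out <- interpolate_channels(ep, bad_ids = c(3, 20), layout = lay)
  expect_lt(max(abs(out$amp - 7)), 1e-6)
  # identity on empty bad set
  expect_identical(interpolate_channels(ep, integer(0)), ep)
  # smooth low-order field: leave-one-out error < 5% of the field range
  p <- as.matrix(lay[, c("x", "y", "z")])
  field <- 2 + 1.5 * p[, 1] + 0.8 * p[, 2] - 0.6 * p[, 3] +
    0.9 * p[, 1] * p[, 2] + 0.4 * (p[, 3]^2 - 1 / 3)
  amp <- array(rep(field, times = 2), c(1, 1, 1, n_e, 2))
  ep <- make_epochs(amp, layout = lay)
  rng <- diff(range(field))
  err <- vapply(seq(1, n_e, by = 4), function(e) {
    out <- interpolate_channels(ep, bad_ids = lay$id[e], layout = lay)
    abs(out$amp[1, 1, 1, e, 1] - field[e])
  }, numeric(1))
  expect_lt(max(err) / rng, 0.05)
  # good channels are untouched
  out <- interpolate_channels(ep, bad_ids = lay$id[5], layout = lay)
  expect_equal(out$amp[1, 1, 1, -5, ], amp[1, 1, 1, -5, ],
               ignore_attr = TRUE)
  expect_error(interpolate_channels(ep, lay$id), "all channels")
  expect_error(interpolate_channels(ep, lay$id[-(1:3)]), "at least 4")
})

test_that("slice_epochs re-locks around per-condition onsets", {
  set.seed(4)
  amp <- array(rnorm(2 * 2 * 2 * 5 * 120), c(2, 2, 2, 5, 120))
  ep <- make_epochs(amp)  # time -0.3 .. 0.89
  sl <- slice_epochs(ep, onsets = c(C1 = 0.2, C2 = 0.5), window = c(-0.1, 0.3),
                     lock = "word")
  expect_equal(dim(sl$amp)[5], 41L)
  expect_equal(sl$time[1], -0.1)
  i1 <- which.min(abs(ep$time - 0.1)) # C1: onset 0.2 + window start -0.1
  expect_equal(sl$amp[1, 1, 1, 1, 1], amp[1, 1, 1, 1, i1])
  i2 <- which.min(abs(ep$time - 0.4))
  expect_equal(sl$amp[2, 2, 2, 3, 1], amp[2, 2, 2, 3, i2])
  expect_error(slice_epochs(ep, onsets = c(C1 = 0.2, C2 = 5), c(-0.1, 0.3)),
               "outside")
  expect_error(slice_epochs(ep, onsets = c(C1 = 0.2), c(-0.1, 0.3)),
               "no onset")
})
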