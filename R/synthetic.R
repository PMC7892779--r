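#' Study design description
#'
#' Describes the factorial reading-study design emulated by the synthetic
#' generator: 4 sentence types (indirect question, direct question,
#' declarative, whether-question) crossed with 2 dependency lengths, 48
#' trials per condition, 37 subjects, RSVP presentation at a 600 ms SOA
#' (300 ms word + 300 ms blank), sampled at 500 Hz. Word onsets are stored
#' relative to the main-verb onset: the three (short) or five (long)
#' intervening words follow at multiples of the SOA and the target
#' wh-word/demonstrative appears at 2.4 s (short) or 3.6 s (long).
#'
#' @param n_subjects number of subjects (default 37).
#' @param trials_per_condition trials per condition per subject (default 48).
#' @param sampling_rate sampling rate in Hz (default 500).
#' @param soa stimulus-onset asynchrony in seconds (default 0.6).
#' @param epoch_window verb-locked epoch extent in seconds; the default
#'   `c(-0.3, 4.6)` covers the long-condition target-word epoch.
#' @param conditions condition labels; the default crosses
#'   `{indirectQ, directQ, declarative, whetherQ}` with `{short, long}` as
#'   `type.length`. Supplying custom labels yields a generic design with no
#'   word-onset metadata (useful for calibration datasets).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 37L, trials_per_condition = 48L,
                         sampling_rate = 500, soa = 0.6,
                         epoch_window = c(-0.3, 4.6), conditions = NULL) {
  std <- is.null(conditions)
  if (std) {
    types <- c("indirectQ", "directQ", "declarative", "whetherQ")
    conditions <- as.vector(outer(types, c("short", "long"), paste, sep = "."))
  }
  des <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_condition = as.integer(trials_per_condition),
    sampling_rate = sampling_rate,
    soa = soa,
    word_duration = soa / 2,
    epoch_window = epoch_window,
    conditions = conditions
  )
  if (std) {
    # onsets relative to the main verb (verb itself at 0)
    des$word_onsets <- list(
      short = c(verb = 0, adverb = soa, emb_subject = 2 * soa,
                emb_verb = 3 * soa, target = 4 * soa),
      long = c(verb = 0, adverb = soa, emb_subject = 2 * soa,
               emb_verb = 3 * soa, emb_np = 4 * soa, emb_verb2 = 5 * soa,
               target = 6 * soa)
    )
    des$target_onset <- c(short = 4 * soa, long = 6 * soa)
    des$interval_window <- list(short = c(-0.3, 2.2), long = c(-0.3, 3.0))
    des$target_window <- c(-0.3, 1.0)
  }
  structure(des, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design: %d subjects, %d conditions x %d trials, %g Hz, epoch [%g, %g] s>\n",
              x$n_subjects, length(x$conditions), x$trials_per_condition,
              x$sampling_rate, x$epoch_window[1], x$epoch_window[2]))
  invisible(x)
}

# Condition labels of a given length ("short"/"long"), or of a given type.
conditions_of <- function(design, type = NULL, length = NULL) {
  conds <- design$conditions
  if (!is.null(type))
    conds <- conds[sub("\\..*$", "", conds) %in% type]
  if (!is.null(length))
    conds <- conds[sub("^.*\\.", "", conds) %in% length]
  conds
}

#' Background-noise description
#'
#' The synthetic background is a minimal model of ongoing scalp EEG:
#' temporally a power-law (`1/f^exponent`) spectrum with an optional alpha
#' (10 Hz) bump, spatially a smooth exponential correlation across the
#' montage, with lognormal per-subject and per-trial gain variability.
#' The default single-trial, single-sample SD of 15 microvolts is typical
#' of 20 Hz low-passed scalp EEG.
#'
#' @param sd_broadband per-sample SD in microvolts (default 15).
#' @param spectral_exponent slope of the `1/f` power spectrum (default 1).
#' @param alpha_power_fraction fraction of variance in the alpha bump,
#'   in `[0, 1]` (default 0.2).
#' @param alpha_freq,alpha_width centre (Hz) and SD (Hz) of the alpha bump.
#' @param spatial_correlation_length e-folding distance of the inter-channel
#'   correlation, in units of the median inter-electrode distance (default 2;
#'   0 disables spatial correlation).
#' @param trial_sd_scale lognormal sigma of the per-trial gain (default 0.1).
#' @param subject_gain_sd lognormal sigma of the per-subject gain
#'   (default 0.1).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd_broadband = 15, spectral_exponent = 1,
                       alpha_power_fraction = 0.2, alpha_freq = 10,
                       alpha_width = 1.5, spatial_correlation_length = 2,
                       trial_sd_scale = 0.1, subject_gain_sd = 0.1) {
  if (sd_broadband < 0 || spectral_exponent < 0 ||
      spatial_correlation_length < 0 || trial_sd_scale < 0 ||
      subject_gain_sd < 0)
    stopf("noise_spec fields must be non-negative")
  if (alpha_power_fraction < 0 || alpha_power_fraction > 1)
    stopf("alpha_power_fraction must lie in [0, 1]")
  structure(list(sd_broadband = sd_broadband,
                 spectral_exponent = spectral_exponent,
                 alpha_power_fraction = alpha_power_fraction,
                 alpha_freq = alpha_freq, alpha_width = alpha_width,
                 spatial_correlation_length = spatial_correlation_length,
                 trial_sd_scale = trial_sd_scale,
                 subject_gain_sd = subject_gain_sd),
            class = "noise_spec")
}

#' ERP component description for the generator
#'
#' A deterministic spatio-temporal template added to selected conditions:
#' `amplitude` (signed; negativities are negative) times a temporal
#' envelope over `time_window` on `electrode_set`, with the subject-level
#' amplitude drawn from `Normal(amplitude, amplitude_sd)` (random
#' subject-effect structure, matching what a repeated-measures analysis
#' assumes).
#'
#' @param name label, e.g. `"SAN"`, `"P600"`, `"P2"`.
#' @param amplitude mean amplitude in microvolts (signed).
#' @param time_window `c(start, end)` in seconds relative to the epoch's
#'   locking event.
#' @param electrode_set integer electrode IDs carrying the component.
#' @param conditions condition labels carrying the component.
#' @param envelope `"hcos"` (half-cosine ramped plateau, default) or
#'   `"boxcar"`.
#' @param ramp ramp duration in seconds for the `"hcos"` envelope
#'   (default 0.05).
#' @param amplitude_sd across-subject SD of the amplitude in microvolts.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, amplitude, time_window, electrode_set,
                           conditions, envelope = c("hcos", "boxcar"),
                           ramp = 0.05, amplitude_sd = 0) {
  envelope <- match.arg(envelope)
  if (length(time_window) != 2L || time_window[1] >= time_window[2])
    stopf("time_window must be c(start, end) with start < end")
  if (amplitude_sd < 0) stopf("amplitude_sd must be non-negative")
  if (!length(conditions)) stopf("conditions must be non-empty")
  structure(list(name = name, amplitude = amplitude,
                 time_window = time_window,
                 electrode_set = as.integer(electrode_set),
                 conditions = conditions, envelope = envelope, ramp = ramp,
                 amplitude_sd = amplitude_sd),
            class = "component_spec")
}

# Temporal envelope of a component evaluated on the epoch time axis.
# Window edges carry a half-sample tolerance against floating-point drift
# of the time axis.
component_envelope <- function(spec, time) {
  tol <- if (length(time) > 1L) (time[2] - time[1]) / 2 else 0
  w <- numeric(length(time))
  inside <- time >= spec$time_window[1] - tol &
    time <= spec$time_window[2] + tol
  w[inside] <- 1
  if (spec$envelope == "hcos" && spec$ramp > 0) {
    up <- inside & time < spec$time_window[1] + spec$ramp
    dn <- inside & time > spec$time_window[2] - spec$ramp
    w[up] <- 0.5 * (1 - cos(pi * (time[up] - spec$time_window[1]) / spec$ramp))
    w[dn] <- 0.5 * (1 - cos(pi * (spec$time_window[2] - time[dn]) / spec$ramp))
  }
  w
}

# Spectral amplitude envelope (length T, symmetric in frequency) with
# sum(A^2) == T so that filtered unit-variance white noise stays unit
# variance.
spectral_envelope <- function(n_t, srate, spec) {
  f <- srate * (seq_len(n_t) - 1L) / n_t
  f <- pmin(f, srate - f) # fold to [0, Nyquist]
  p1 <- pmax(f, 0.75)^(-spec$spectral_exponent) # power-law, knee at 0.75 Hz
  pa <- exp(-(f - spec$alpha_freq)^2 / (2 * spec$alpha_width^2))
  p1 <- p1 / sum(p1)
  pa <- if (sum(pa) > 0) pa / sum(pa) else p1
  p <- (1 - spec$alpha_power_fraction) * p1 + spec$alpha_power_fraction * pa
  sqrt(p * n_t / sum(p))
}

#' Simulate background-only epochs
#'
#' Generates a zero-mean `epoch_set` whose trials are spatially correlated
#' `1/f + alpha` noise (see [noise_spec()]), with per-subject and per-trial
#' lognormal gains. Deterministic given `seed`.
#'
#' @param design a `study_design`.
#' @param noise a `noise_spec`.
#' @param layout an `electrode_layout`.
#' @param seed integer seed.
#' @return an `epoch_set`.
#' @export
simulate_noise_epochs <- function(design, noise = noise_spec(),
                                  layout = build_default_layout(),
                                  seed = 1L) {
  n_t <- round(diff(design$epoch_window) * design$sampling_rate) + 1L
  time <- design$epoch_window[1] + (seq_len(n_t) - 1L) / design$sampling_rate
  n_e <- nrow(layout)
  n_s <- design$n_subjects
  n_c <- length(design$conditions)
  n_r <- design$trials_per_condition
  amp <- array(0, c(n_s, n_c, n_r, n_e, n_t),
               dimnames = list(paste0("S", seq_len(n_s)), design$conditions,
                               NULL, as.character(layout$id), NULL))
  env <- spectral_envelope(n_t, design$sampling_rate, noise)
  mix <- NULL
  if (noise$spatial_correlation_length > 0 && n_e > 1L) {
    d <- layout_distances(layout)
    dn <- d / (noise$spatial_correlation_length *
                 median(nearest_neighbor_dist(layout)))
    cc <- exp(-dn)
    mix <- t(chol(cc + diag(1e-9, n_e)))
  }
  with_rng(seed, {
    g_subj <- rlnorm(n_s, 0, noise$subject_gain_sd)
    for (s in seq_len(n_s)) {
      for (ci in seq_len(n_c)) {
        for (r in seq_len(n_r)) {
          if (noise$sd_broadband == 0) {
            g <- rlnorm(1, 0, noise$trial_sd_scale) # keep RNG stream aligned
            next
          }
          w <- matrix(rnorm(n_t * n_e), n_t, n_e)
          x <- Re(mvfft(mvfft(w) * env, inverse = TRUE)) / n_t
          if (!is.null(mix)) x <- x %*% t(mix)
          g <- noise$sd_broadband * g_subj[s] *
            rlnorm(1, 0, noise$trial_sd_scale)
          amp[s, ci, r, , ] <- t(x) * g
        }
      }
    }
  })
  epoch_set(amp, time, design$sampling_rate, layout, design = design,
            lock = "verb",
            provenance = list(seed = seed, noise = unclass(noise)))
}

#' Add an ERP component to selected conditions
#'
#' Adds `envelope x amplitude` to every trial of the named conditions, with
#' the subject-level amplitude drawn from
#' `Normal(amplitude, amplitude_sd)`. All other entries are untouched.
#' Deterministic given `seed`.
#'
#' @param epochs an `epoch_set`.
#' @param spec a `component_spec`.
#' @param seed integer seed for the subject-amplitude draws.
#' @return the modified `epoch_set`.
#' @export
add_component <- function(epochs, spec, seed = 1L) {
  stopifnot(inherits(spec, "component_spec"))
  cidx <- condition_index(epochs, spec$conditions)
  eidx <- electrode_index(epochs, spec$electrode_set)
  tol <- 0.5 / epochs$srate
  if (spec$time_window[1] < min(epochs$time) - tol ||
      spec$time_window[2] > max(epochs$time) + tol)
    stopf("component window [%g, %g] lies outside the epoch [%g, %g]",
          spec$time_window[1], spec$time_window[2],
          min(epochs$time), max(epochs$time))
  env <- component_envelope(spec, epochs$time)
  tidx <- which(env != 0)
  if (!length(tidx)) return(epochs)
  n_s <- dim(epochs$amp)[1]
  amps <- with_rng(seed, rnorm(n_s, spec$amplitude, spec$amplitude_sd))
  for (s in seq_len(n_s)) {
    sub <- epochs$amp[s, cidx, , eidx, tidx, drop = FALSE]
    bump <- amps[s] * env[tidx]
    epochs$amp[s, cidx, , eidx, tidx] <-
      sub + rep(bump, each = prod(dim(sub)[1:4]))
  }
  epochs$provenance$components <- c(epochs$provenance$components,
                                    list(unclass(spec)))
  epochs
}

#' Component presets for the emulated study
#'
#' Builds the component list for [simulate_study()]. The `"paper"` preset
#' carries an early positivity (P2-like, +2 microvolts by default,
#' 150-250 ms after the target word, anterior electrodes) in the two
#' question conditions — the one effect the emulated study detected — plus
#' optional SAN (sustained anterior negativity over the verb-to-target
#' interval, indirect questions) and P600 (posterior, 500-700 ms
#' post-target, indirect questions) of configurable size. The `"null"`
#' preset is an empty list.
#'
#' @param design a standard `study_design`.
#' @param regions a `region_map`.
#' @param preset `"paper"` or `"null"`.
#' @param p2_amplitude,san_amplitude,p600_amplitude mean amplitudes in
#'   microvolts; magnitudes only, conventional signs (P2 and P600 positive,
#'   SAN negative) are applied internally. Zero omits the component.
#' @param amplitude_sd across-subject amplitude SD (microvolts).
#' @return list of `component_spec`s.
#' @export
study_components <- function(design, regions = build_region_map(warn = FALSE),
                             preset = c("paper", "null"), p2_amplitude = 2,
                             san_amplitude = 0, p600_amplitude = 0,
                             amplitude_sd = 0.5) {
  preset <- match.arg(preset)
  if (preset == "null") return(list())
  if (is.null(design$target_onset))
    stopf("design carries no word-onset metadata")
  out <- list()
  for (len in c("short", "long")) {
    t0 <- design$target_onset[[len]]
    if (p2_amplitude != 0)
      out <- c(out, list(component_spec(
        paste0("P2.", len), abs(p2_amplitude), t0 + c(0.15, 0.25),
        regions$anterior,
        conditions_of(design, c("indirectQ", "directQ"), len),
        amplitude_sd = amplitude_sd)))
    if (san_amplitude != 0)
      out <- c(out, list(component_spec(
        paste0("SAN.", len), -abs(san_amplitude), c(0, t0),
        regions$anterior, conditions_of(design, "indirectQ", len),
        amplitude_sd = amplitude_sd)))
    if (p600_amplitude != 0)
      out <- c(out, list(component_spec(
        paste0("P600.", len), abs(p600_amplitude), t0 + c(0.5, 0.7),
        regions$posterior, conditions_of(design, "indirectQ", len),
        amplitude_sd = amplitude_sd)))
  }
  out
}

#' Simulate a full synthetic study
#'
#' Background noise via [simulate_noise_epochs()] plus any number of
#' injected components via [add_component()], each with its own derived
#' seed. Deterministic given `seed`.
#'
#' @param design a `study_design`.
#' @param noise a `noise_spec`.
#' @param components list of `component_spec`s (e.g. from
#'   [study_components()]).
#' @param layout an `electrode_layout`.
#' @param seed integer seed.
#' @return an `epoch_set`.
#' @export
simulate_study <- function(design, noise = noise_spec(), components = list(),
                           layout = build_default_layout(), seed = 1L) {
  seeds <- derive_seeds(seed, 1L + length(components))
  epochs <- simulate_noise_epochs(design, noise, layout, seed = seeds[1])
  for (i in seq_along(components))
    epochs <- add_component(epochs, components[[i]], seed = seeds[1L + i])
  epochs$provenance$seed <- seed
  epochs
}
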