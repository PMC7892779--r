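#' Effect-injection specification
#'
#' Describes the data-grounded injection used by the power simulation: a
#' stochastic effect `E ~ Normal(mu, sigma_subject)` added, on a fixed
#' electrode set and time window, to one of three pseudo-condition
#' partitions of a subject's pooled single trials. `sigma_subject` is
#' estimated per subject from the across-trial SD at a single reference
#' (electrode, 250 ms) point. Sign convention: SAN-type effects are
#' injected negative-going, P600-type positive-going.
#'
#' @param component `"SAN"` or `"P600"` (sets the sign and the default
#'   electrode set / window), or `"custom"`.
#' @param mu mean injected amplitude in microvolts (>= 0).
#' @param electrode_set electrode IDs receiving the effect; defaults to
#'   the 24 anterior electrodes (SAN) or 20 posterior electrodes (P600).
#' @param time_window injection window in seconds relative to the epochs'
#'   locking event; defaults: SAN = the full 0-2.2 s interval, P600 =
#'   0.5-0.7 s (target-locked epochs).
#' @param sign `+1` or `-1`; default from `component`.
#' @param sigma_electrode electrode at which the per-subject trial SD is
#'   estimated (default 1, an anterior-midline electrode, for SAN; 4, a
#'   posterior-midline electrode, for P600).
#' @param sigma_time time of the SD estimate in seconds (default 0.250).
#' @param draw_level `"per_trial"` (default) or `"per_subject"`: whether
#'   `E` is redrawn for every trial or once per subject.
#' @param sigma_scale multiplier on the estimated sigma (default 1). With
#'   `sigma_scale = 0` the injected effect is the deterministic constant
#'   `mu`; combined with `mu = 0` this yields the exact exchangeable null
#'   used for calibration (a stochastic `E ~ N(0, sigma)` draw is not an
#'   exchangeable null: it adds condition-specific variance).
#' @param regions `region_map` used for the default electrode sets.
#' @return an object of class `injection_spec`.
#' @export
injection_spec <- function(component = c("SAN", "P600", "custom"), mu,
                           electrode_set = NULL, time_window = NULL,
                           sign = NULL, sigma_electrode = NULL,
                           sigma_time = 0.250,
                           draw_level = c("per_trial", "per_subject"),
                           sigma_scale = 1,
                           regions = build_region_map(warn = FALSE)) {
  component <- match.arg(component)
  draw_level <- match.arg(draw_level)
  if (mu < 0) stopf("mu must be non-negative")
  if (sigma_scale < 0) stopf("sigma_scale must be non-negative")
  if (component == "SAN") {
    electrode_set <- electrode_set %||% regions$anterior
    time_window <- time_window %||% c(0, 2.2)
    sign <- sign %||% -1
    sigma_electrode <- sigma_electrode %||% 1L
  } else if (component == "P600") {
    electrode_set <- electrode_set %||% regions$posterior
    time_window <- time_window %||% c(0.5, 0.7)
    sign <- sign %||% 1
    sigma_electrode <- sigma_electrode %||% 4L
  } else {
    if (is.null(electrode_set) || is.null(time_window) || is.null(sign))
      stopf("custom injection needs electrode_set, time_window and sign")
    sigma_electrode <- sigma_electrode %||% electrode_set[1]
  }
  structure(list(component = component, mu = mu,
                 electrode_set = as.integer(electrode_set),
                 time_window = time_window, sign = sign,
                 sigma_electrode = as.integer(sigma_electrode),
                 sigma_time = sigma_time, draw_level = draw_level,
                 sigma_scale = sigma_scale),
            class = "injection_spec")
}

#' Pool one subject's trials across conditions
#'
#' The simulation ignores the true condition labels: all of a subject's
#' trials form one pool from which pseudo-conditions are drawn.
#'
#' @param epochs an `epoch_set`.
#' @param subject subject index.
#' @return An object of class `trial_block`: list with `amp` (array
#'   `(trial, electrode, time)`), `time`, `electrodes`.
#' @export
pool_trials <- function(epochs, subject) {
  d <- dim(epochs$amp)
  sub <- epochs$amp[subject, , , , , drop = FALSE] # (1, c, r, e, t)
  amp <- array(aperm(sub, c(3, 2, 4, 5, 1)), c(d[3] * d[2], d[4], d[5]))
  structure(list(amp = amp, time = epochs$time,
                 electrodes = epochs$layout$id, srate = epochs$srate),
            class = "trial_block")
}

#' Random partition of a subject's trials into pseudo-conditions
#'
#' Shuffles the subject's pooled trials and splits them into `k`
#' near-equal sets (sizes differing by at most one). Deterministic given
#' `seed`.
#'
#' @param epochs an `epoch_set` (or a `trial_block`).
#' @param subject subject index (ignored for a `trial_block`).
#' @param k number of pseudo-conditions (default 3).
#' @param seed integer seed.
#' @return list of `k` integer vectors of trial indices into the pooled
#'   trial axis.
#' @export
partition_trials <- function(epochs, subject = 1L, k = 3L, seed = 1L) {
  n_tr <- if (inherits(epochs, "trial_block")) dim(epochs$amp)[1]
          else dim(epochs$amp)[2] * dim(epochs$amp)[3]
  if (n_tr < k) stopf("need at least %d trials (have %d)", k, n_tr)
  ord <- with_rng(seed, sample.int(n_tr))
  grp <- rep(seq_len(k), length.out = n_tr) # sizes differ by <= 1
  split(ord, grp)
}

#' Across-trial SD at a single (electrode, time) point
#'
#' Sample SD over all of a subject's pooled trials of the amplitude at the
#' given electrode and the sample nearest to `time` — the per-subject
#' `sigma` that scales the stochastic injected effect.
#'
#' @param epochs an `epoch_set` or `trial_block`.
#' @param subject subject index.
#' @param electrode electrode ID (default 1).
#' @param time time point in seconds (default 0.250).
#' @return scalar SD in microvolts.
#' @export
estimate_sigma <- function(epochs, subject = 1L, electrode = 1L,
                           time = 0.250) {
  blk <- if (inherits(epochs, "trial_block")) epochs
         else pool_trials(epochs, subject)
  if (dim(blk$amp)[1] < 2L) stopf("need at least 2 trials")
  ei <- match(electrode, blk$electrodes)
  if (is.na(ei)) stopf("electrode %s not in layout", electrode)
  if (time < min(blk$time) - 0.5 / blk$srate ||
      time > max(blk$time) + 0.5 / blk$srate)
    stopf("time %g s outside the epoch", time)
  ti <- which.min(abs(blk$time - time))
  sd(blk$amp[, ei, ti])
}

#' Inject a stochastic effect into a trial partition
#'
#' For the trials in `partition`, draws `E ~ Normal(mu, sigma)` (once per
#' trial or once per subject, per `spec$draw_level`), applies the
#' component's sign, and adds the result as a constant over
#' `spec$time_window` on `spec$electrode_set`. Other trials are untouched.
#' Deterministic given `seed`.
#'
#' @param block a `trial_block` (see [pool_trials()]).
#' @param partition integer vector of trial indices to modify.
#' @param spec an `injection_spec`.
#' @param sigma subject-level SD of the effect (microvolts), e.g. from
#'   [estimate_sigma()].
#' @param seed integer seed.
#' @return the modified `trial_block`.
#' @export
inject_effect <- function(block, partition, spec, sigma, seed = 1L) {
  stopifnot(inherits(block, "trial_block"), inherits(spec, "injection_spec"))
  tol <- 0.5 / block$srate
  if (spec$time_window[1] < min(block$time) - tol ||
      spec$time_window[2] > max(block$time) + tol)
    stopf("injection window [%g, %g] outside the epoch [%g, %g]",
          spec$time_window[1], spec$time_window[2],
          min(block$time), max(block$time))
  eidx <- match(spec$electrode_set, block$electrodes)
  if (anyNA(eidx)) stopf("injection electrodes missing from layout")
  tidx <- which(block$time >= spec$time_window[1] - tol &
                  block$time <= spec$time_window[2] + tol)
  sigma_eff <- sigma * (spec$sigma_scale %||% 1)
  e_draw <- with_rng(seed, {
    if (spec$draw_level == "per_trial")
      rnorm(length(partition), spec$mu, sigma_eff)
    else rep(rnorm(1, spec$mu, sigma_eff), length(partition))
  })
  e_draw <- spec$sign * e_draw
  for (j in seq_along(partition))
    block$amp[partition[j], eidx, tidx] <-
      block$amp[partition[j], eidx, tidx] + e_draw[j]
  block
}

# Partition -> per-pseudo-condition trial-average maps for one subject.
partition_means <- function(block, parts) {
  d <- dim(block$amp)
  vapply(parts, function(idx) {
    m <- colMeans(matrix(block$amp[idx, , , drop = FALSE],
                         length(idx), d[2] * d[3]))
    matrix(m, d[2], d[3])
  }, matrix(0, d[2], d[3]))
}

#' One cell of the injection power simulation
#'
#' Repeats, `repetitions` times: draw `n_subjects` subjects without
#' replacement; for each, pool trials, partition into three
#' pseudo-conditions, estimate `sigma`, and inject the effect into the
#' first partition; average each partition's trials; run the same
#' three-condition cluster permutation test as the experimental analysis;
#' record whether any cluster is significant. Deterministic given `seed`.
#'
#' @param epochs an `epoch_set` of pre-processed single trials.
#' @param spec an `injection_spec`.
#' @param n_subjects group size per repetition.
#' @param repetitions number of repetitions (default 100).
#' @param adjacency an `adjacency_graph` (default from the epoch layout).
#' @param P,alpha,threshold_p cluster-test configuration.
#' @param seed integer seed.
#' @param detect `"any"` (default: any significant cluster counts as a
#'   detection) or `"overlap"` (a significant cluster must include an
#'   injected electrode).
#' @return An object of class `sim_cell_result`: list with `mu`,
#'   `n_subjects`, `repetitions`, `detections`, `detection_rate`, `seed`.
#' @export
run_simulation_cell <- function(epochs, spec, n_subjects,
                                repetitions = 100L, adjacency = NULL,
                                P = 1000L, alpha = 0.05, threshold_p = 0.05,
                                seed = 1L, detect = c("any", "overlap")) {
  detect <- match.arg(detect)
  d <- dim(epochs$amp)
  if (n_subjects > d[1])
    stopf("n_subjects = %d exceeds available subjects (%d)", n_subjects, d[1])
  if (is.null(adjacency)) adjacency <- build_adjacency(epochs$layout)
  rep_seeds <- derive_seeds(seed, repetitions)
  detections <- 0L
  # trial pools and sigma estimates are rep-invariant: compute once
  blocks <- lapply(seq_len(d[1]), function(s) pool_trials(epochs, s))
  sigmas <- vapply(blocks, estimate_sigma, numeric(1),
                   electrode = spec$sigma_electrode, time = spec$sigma_time)
  for (rep_i in seq_len(repetitions)) {
    sseeds <- derive_seeds(rep_seeds[rep_i], 2L * n_subjects + 2L)
    subjects <- with_rng(sseeds[1], sample.int(d[1], n_subjects))
    maps <- array(0, c(n_subjects, 3L, d[4], d[5]))
    for (si in seq_len(n_subjects)) {
      blk <- blocks[[subjects[si]]]
      parts <- partition_trials(blk, k = 3L, seed = sseeds[2L * si])
      blk <- inject_effect(blk, parts[[1]], spec, sigmas[subjects[si]],
                           seed = sseeds[2L * si + 1L])
      maps[si, , , ] <- aperm(partition_means(blk, parts), c(3, 1, 2))
    }
    res <- run_cluster_test(sc_maps(maps, epochs$layout$id, epochs$time),
                            adjacency = adjacency, stat_kind = "F", P = P,
                            alpha = alpha, threshold_p = threshold_p,
                            seed = sseeds[2L * n_subjects + 2L])
    hit <- if (detect == "any") res$any_significant
           else detection_overlaps(res, epochs$layout$id, spec$electrode_set)
    detections <- detections + as.integer(hit)
  }
  structure(list(component = spec$component, mu = spec$mu,
                 n_subjects = n_subjects, repetitions = repetitions,
                 detections = detections,
                 detection_rate = detections / repetitions, seed = seed),
            class = "sim_cell_result")
}

# Stricter criterion: a significant cluster must touch the injected set.
detection_overlaps <- function(result, electrode_ids, injected) {
  for (cl in result$clusters) {
    if (cl$p < result$alpha &&
        any(electrode_ids[cl$members[, 1]] %in% injected))
      return(TRUE)
  }
  FALSE
}

#' @export
print.sim_cell_result <- function(x, ...) {
  cat(sprintf("<sim_cell: %s mu = %g, N = %d -> %d/%d detected (%.0f%%)>\n",
              x$component, x$mu, x$n_subjects, x$detections, x$repetitions,
              100 * x$detection_rate))
  invisible(x)
}

#' Detection-rate surface over effect size and sample size
#'
#' Full factorial of [run_simulation_cell()] over an effect-size grid and
#' a sample-size grid; the default grids are mu in
#' \{0.5, 1, 1.5, 2, 2.5, 3\} microvolts (SAN) or \{0.5, 1, 1.5, 2\}
#' (P600) by N in \{20, 30, 37\}, with 100 repetitions per cell.
#'
#' @param epochs an `epoch_set`.
#' @param component `"SAN"` or `"P600"`.
#' @param mu_grid effect sizes in microvolts (`NULL` = component default).
#' @param n_grid sample sizes (default `c(20, 30, 37)`).
#' @param repetitions repetitions per cell (default 100).
#' @param ... passed to [run_simulation_cell()] (`P`, `alpha`,
#'   `adjacency`, `threshold_p`, `detect`, injection window overrides via
#'   `time_window`...).
#' @param time_window,electrode_set,draw_level,sigma_scale injection
#'   overrides passed to [injection_spec()].
#' @param seed integer master seed.
#' @return An object of class `power_grid`: data frame with one row per
#'   (mu, N) cell (`component`, `mu`, `n_subjects`, `repetitions`,
#'   `detections`, `detection_rate`, `seed`).
#' @export
power_grid <- function(epochs, component = c("SAN", "P600"), mu_grid = NULL,
                       n_grid = c(20L, 30L, 37L), repetitions = 100L,
                       time_window = NULL, electrode_set = NULL,
                       draw_level = "per_trial", sigma_scale = 1,
                       seed = 1L, ...) {
  component <- match.arg(component)
  mu_grid <- mu_grid %||%
    if (component == "SAN") c(0.5, 1, 1.5, 2, 2.5, 3) else c(0.5, 1, 1.5, 2)
  if (!length(mu_grid) || !length(n_grid)) stopf("grids must be non-empty")
  cells <- expand.grid(mu = mu_grid, n = n_grid)
  seeds <- derive_seeds(seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    spec <- injection_spec(component, mu = cells$mu[i],
                           electrode_set = electrode_set,
                           time_window = time_window,
                           draw_level = draw_level,
                           sigma_scale = sigma_scale)
    cell <- run_simulation_cell(epochs, spec, n_subjects = cells$n[i],
                                repetitions = repetitions, seed = seeds[i],
                                ...)
    rows[[i]] <- data.frame(component = component, mu = cell$mu,
                            n_subjects = cell$n_subjects,
                            repetitions = cell$repetitions,
                            detections = cell$detections,
                            detection_rate = cell$detection_rate,
                            seed = seeds[i])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Export a power grid
#'
#' @param grid a `power_grid`.
#' @param path file path (`.json` or `.tsv` chosen by `format`).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_power_grid <- function(grid, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  else jsonlite::write_json(as.data.frame(grid), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}
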