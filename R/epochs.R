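#' Single-trial epoch container
#'
#' An `epoch_set` holds a 5-D amplitude tensor indexed
#' (subject, condition, trial, electrode, time), in microvolts, together
#' with its time axis (seconds, relative to the locking event), sampling
#' rate, electrode layout and provenance. It is the common currency of all
#' preprocessing, statistics and simulation functions in the package.
#'
#' @param amplitudes 5-D numeric array `(subject, condition, trial,
#'   electrode, time)` in microvolts.
#' @param time numeric time axis in seconds, strictly increasing at
#'   `1/sampling_rate`.
#' @param sampling_rate sampling rate in Hz.
#' @param layout an `electrode_layout` whose rows match the electrode axis.
#' @param design optional `study_design` metadata (word onsets etc.).
#' @param lock label of the locking event (e.g. `"verb"`, `"target"`).
#' @param provenance free-form list (seed, generator specs, ...).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(amplitudes, time, sampling_rate, layout,
                      design = NULL, lock = "verb", provenance = list()) {
  if (length(dim(amplitudes)) != 5L)
    stopf("amplitudes must be a 5-D array (subject, condition, trial, electrode, time)")
  if (dim(amplitudes)[5] != length(time))
    stopf("time axis length (%d) does not match tensor (%d)",
          length(time), dim(amplitudes)[5])
  dt <- diff(time)
  if (length(dt) && (any(dt <= 0) ||
                     max(abs(dt - 1 / sampling_rate)) > 1e-6 / sampling_rate))
    stopf("time axis must increase in steps of 1/sampling_rate")
  if (nrow(layout) != dim(amplitudes)[4])
    stopf("layout has %d electrodes but tensor has %d",
          nrow(layout), dim(amplitudes)[4])
  if (anyNA(amplitudes) || any(!is.finite(amplitudes)))
    stopf("amplitudes must be finite")
  structure(list(amp = amplitudes, time = time, srate = sampling_rate,
                 layout = layout, design = design, lock = lock,
                 provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$amp)
  cat(sprintf(paste0("<epoch_set: %d subjects x %d conditions x %d trials x ",
                     "%d electrodes x %d samples @ %g Hz, %s-locked ",
                     "[%.3f, %.3f] s>\n"),
              d[1], d[2], d[3], d[4], d[5], x$srate, x$lock,
              min(x$time), max(x$time)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$amp)

epoch_conditions <- function(epochs) dimnames(epochs$amp)[[2]]

# Resolve electrode IDs to positions along the electrode axis.
electrode_index <- function(epochs, ids) {
  if (is.null(ids)) return(seq_len(dim(epochs$amp)[4]))
  idx <- match(ids, epochs$layout$id)
  if (anyNA(idx))
    stopf("electrode id(s) %s not present in layout",
          paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# Sample indices covering [window[1], window[2]] (inclusive, half-sample
# tolerance at the edges).
time_index <- function(epochs, window) {
  if (is.null(window)) return(seq_along(epochs$time))
  if (length(window) != 2L || window[1] > window[2])
    stopf("time window must be c(start, end) with start <= end")
  tol <- 0.5 / epochs$srate
  idx <- which(epochs$time >= window[1] - tol & epochs$time <= window[2] + tol)
  if (!length(idx))
    stopf("time window [%g, %g] is outside the epoch [%g, %g]",
          window[1], window[2], min(epochs$time), max(epochs$time))
  idx
}

condition_index <- function(epochs, conditions) {
  if (is.null(conditions)) return(seq_len(dim(epochs$amp)[2]))
  idx <- match(conditions, epoch_conditions(epochs))
  if (anyNA(idx))
    stopf("unknown condition(s): %s",
          paste(conditions[is.na(idx)], collapse = ", "))
  idx
}

replace_amp <- function(epochs, amp) {
  epochs$amp <- amp
  epochs
}

#' Re-epoch around per-condition event onsets
#'
#' Extracts a new epoch set time-locked to an event whose onset (relative
#' to the current locking event) may differ by condition — e.g. the target
#' word, which appears later in long sentences than in short ones.
#'
#' @param epochs an `epoch_set`.
#' @param onsets a single onset in seconds, or a named vector with one
#'   onset per condition.
#' @param window `c(start, end)` in seconds relative to the new event.
#' @param lock label for the new locking event.
#' @return an `epoch_set` on the window `window`, time re-referenced to the
#'   event onset.
#' @export
slice_epochs <- function(epochs, onsets, window, lock = "event") {
  conds <- epoch_conditions(epochs)
  if (length(onsets) == 1L && is.null(names(onsets)))
    onsets <- setNames(rep(onsets, length(conds)), conds)
  missing <- setdiff(conds, names(onsets))
  if (length(missing))
    stopf("no onset given for condition(s): %s", paste(missing, collapse = ", "))
  n_t <- round((window[2] - window[1]) * epochs$srate) + 1L
  d <- dim(epochs$amp)
  out <- array(NA_real_, c(d[1:4], n_t))
  new_time <- window[1] + (seq_len(n_t) - 1L) / epochs$srate
  tol <- 0.5 / epochs$srate
  for (ci in seq_along(conds)) {
    t0 <- onsets[[conds[ci]]] + window[1]
    i0 <- which.min(abs(epochs$time - t0))
    if (abs(epochs$time[i0] - t0) > tol || i0 + n_t - 1L > d[5])
      stopf("window [%g, %g] around onset %g s is outside the epoch for condition %s",
            window[1], window[2], onsets[[conds[ci]]], conds[ci])
    out[, ci, , , ] <- epochs$amp[, ci, , , i0:(i0 + n_t - 1L), drop = FALSE]
  }
  dimnames(out) <- dimnames(epochs$amp)[c(1:4, 5)]
  dimnames(out)[[5]] <- NULL
  epoch_set(out, new_time, epochs$srate, epochs$layout, design = epochs$design,
            lock = lock, provenance = c(epochs$provenance,
                                        list(sliced_from = epochs$lock)))
}

#' Persist / restore an epoch set
#'
#' Epoch sets are stored as a single serialized R object with a documented
#' internal schema (`amp`, `time`, `srate`, `layout`, `design`, `lock`,
#' `provenance`), the R analogue of a hierarchical binary container.
#'
#' @param epochs an `epoch_set`.
#' @param path file path.
#' @return `save_epoch_set` returns `path` invisibly; `load_epoch_set`
#'   returns the `epoch_set`.
#' @export
save_epoch_set <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname save_epoch_set
#' @export
load_epoch_set <- function(path) {
  x <- readRDS(path)
  epoch_set(x$amp, x$time, x$srate, {
    lay <- x$layout
    class(lay) <- c("electrode_layout", "data.frame")
    lay
  }, design = x$design, lock = x$lock, provenance = x$provenance)
}

#' Export condition-average ERPs as TSV
#'
#' Writes the grand-average ERP (mean over subjects and trials) in long
#' format with columns `condition`, `electrode`, `time`, `amplitude`.
#'
#' @param epochs an `epoch_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
export_erp_tsv <- function(epochs, path) {
  ga <- apply(epochs$amp, c(2, 4, 5), mean) # condition x electrode x time
  conds <- epoch_conditions(epochs) %||% as.character(seq_len(dim(ga)[1]))
  df <- expand.grid(condition = conds, electrode = epochs$layout$id,
                    time = epochs$time, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$amplitude <- as.vector(ga)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
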