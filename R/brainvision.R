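#' Minimal BrainVision recording reader
#'
#' Reads a BrainVision triplet (`.vhdr` header, binary `.eeg` data,
#' optional `.vmrk` markers) into a continuous-recording object. Supports
#' the common binary layouts: multiplexed or vectorized orientation with
#' `IEEE_FLOAT_32`, `INT_16` or `INT_32` samples, applying per-channel
#' resolutions. This is a pragmatic reader for re-analysing existing
#' recordings with this package; it is not a general-purpose converter.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return An object of class `bv_recording`: list with `data` (channels x
#'   samples matrix, microvolts), `channel_names`, `srate`, `markers`
#'   (data frame or `NULL`).
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stopf("no such file: %s", vhdr_path)
  lines <- readLines(vhdr_path, warn = FALSE)
  ini <- parse_ini(lines)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stopf("malformed header: no [Common Infos] section")
  if (!identical(toupper(ci[["DataFormat"]] %||% "BINARY"), "BINARY"))
    stopf("only BINARY DataFormat is supported")
  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(ci[["SamplingInterval"]]) # microseconds
  fmt <- toupper(bi[["BinaryFormat"]] %||% "IEEE_FLOAT_32")
  chan <- ini[["Channel Infos"]]
  ch_names <- character(n_ch)
  resolution <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    entry <- chan[[sprintf("Ch%d", i)]]
    if (is.null(entry)) {
      ch_names[i] <- sprintf("Ch%d", i)
      next
    }
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    ch_names[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[i] <- as.numeric(parts[3])
  }
  eeg_path <- file.path(dirname(vhdr_path), ci[["DataFile"]])
  size <- switch(fmt, IEEE_FLOAT_32 = 4L, INT_16 = 2L, INT_32 = 4L,
                 stopf("unsupported BinaryFormat: %s", fmt))
  what <- if (fmt == "IEEE_FLOAT_32") "numeric" else "integer"
  n_vals <- file.size(eeg_path) %/% size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what, n = n_vals, size = size, endian = "little")
  n_samp <- length(raw_vals) %/% n_ch
  data <- if (orientation == "MULTIPLEXED")
    matrix(raw_vals[seq_len(n_ch * n_samp)], n_ch, n_samp)
  else t(matrix(raw_vals[seq_len(n_ch * n_samp)], n_samp, n_ch))
  data <- data * resolution
  rownames(data) <- ch_names
  markers <- NULL
  vmrk <- file.path(dirname(vhdr_path), ci[["MarkerFile"]] %||% "")
  if (nzchar(ci[["MarkerFile"]] %||% "") && file.exists(vmrk))
    markers <- parse_vmrk(vmrk, srate)
  structure(list(data = data, channel_names = ch_names, srate = srate,
                 markers = markers),
            class = "bv_recording")
}

# INI-style parser: list of sections, each a named character vector.
parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (!is.null(section) && grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <-
        trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

parse_vmrk <- function(path, srate) {
  ini <- parse_ini(readLines(path, warn = FALSE))
  mk <- ini[["Marker Infos"]]
  if (is.null(mk) || !length(mk)) return(NULL)
  rows <- lapply(names(mk), function(nm) {
    parts <- strsplit(mk[[nm]], ",", fixed = TRUE)[[1]]
    data.frame(type = parts[1], description = parts[2],
               sample = as.integer(parts[3]),
               onset_s = (as.integer(parts[3]) - 1L) / srate)
  })
  do.call(rbind, rows)
}

#' @export
print.bv_recording <- function(x, ...) {
  cat(sprintf("<bv_recording: %d channels x %d samples @ %g Hz>\n",
              nrow(x$data), ncol(x$data), x$srate))
  invisible(x)
}

#' Epoch a continuous recording around tabulated events
#'
#' Slices a continuous recording into an `epoch_set` using an event table
#' (columns `onset_s`, `condition`, and optionally `word_index`; read from
#' TSV with [read_event_table()]). Trials are balanced to the smallest
#' per-condition count (with a warning when counts differ). The single
#' recording becomes subject 1 of the resulting epoch set.
#'
#' @param recording a `bv_recording`.
#' @param events data frame with `onset_s` and `condition` columns.
#' @param window epoch window `c(start, end)` in seconds around each onset.
#' @param layout an `electrode_layout`; defaults to unit positions on a
#'   generated layout matched by channel count.
#' @param lock locking-event label.
#' @return an `epoch_set` with one subject.
#' @export
epoch_recording <- function(recording, events, window,
                            layout = NULL, lock = "event") {
  stopifnot(inherits(recording, "bv_recording"))
  if (!all(c("onset_s", "condition") %in% names(events)))
    stopf("event table needs onset_s and condition columns")
  if (is.null(layout)) {
    n_ch <- nrow(recording$data)
    layout <- build_default_layout(
      n_rings = ceiling((3 + sqrt(9 + 12 * (n_ch - 1))) / 6) + 1L,
      n_keep = n_ch)
  }
  srate <- recording$srate
  n_t <- round(diff(window) * srate) + 1L
  conds <- sort(unique(events$condition))
  counts <- table(events$condition)
  n_r <- min(counts)
  if (length(unique(counts)) > 1L)
    warning(sprintf("unbalanced conditions; keeping first %d trials each",
                    n_r), call. = FALSE)
  amp <- array(0, c(1L, length(conds), n_r, nrow(recording$data), n_t),
               dimnames = list("S1", conds, NULL,
                               as.character(layout$id), NULL))
  for (ci in seq_along(conds)) {
    ons <- events$onset_s[events$condition == conds[ci]][seq_len(n_r)]
    for (r in seq_len(n_r)) {
      i0 <- round((ons[r] + window[1]) * srate) + 1L
      if (i0 < 1L || i0 + n_t - 1L > ncol(recording$data))
        stopf("epoch around onset %g s exceeds the recording", ons[r])
      amp[1, ci, r, , ] <- recording$data[, i0:(i0 + n_t - 1L)]
    }
  }
  time <- window[1] + (seq_len(n_t) - 1L) / srate
  epoch_set(amp, time, srate, layout, lock = lock,
            provenance = list(source = "brainvision"))
}

#' @param path TSV file with columns `onset_s`, `condition`, and
#'   optionally `word_index`.
#' @rdname epoch_recording
#' @export
read_event_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
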