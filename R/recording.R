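# Recording container and CSV I/O.
#
# A recording is a channels x samples matrix of scalp potentials in microvolts
# together with ordered channel labels and the sampling rate. All downstream
# stages (filters, decomposition, power tables) operate on this container.

#' Construct an EEG recording
#'
#' Bundles a channels-by-samples matrix of potentials (microvolts) with its
#' channel labels and sampling rate, after validation. Channel labels are
#' normalised to the modern 10-20 nomenclature (legacy T3/T4/T5/T6 are mapped
#' to T7/T8/P7/P8).
#'
#' @param data numeric matrix, one row per channel, one column per sample.
#' @param channel_labels character vector of unique 10-20 labels, one per row.
#' @param sfreq sampling rate in Hz (default 250).
#' @param meta free-form provenance list; stages append to `meta$stages`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sfreq = 250, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channel_labels <- normalize_channel_labels(as.character(channel_labels))
  if (nrow(data) != length(channel_labels)) {
    stop("dimension mismatch: ", nrow(data), " data rows but ",
         length(channel_labels), " channel labels")
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop("sfreq must be a single positive number")
  }
  if (anyNA(data)) stop("recording contains missing values")
  rownames(data) <- channel_labels
  structure(
    list(data = data, channel_labels = channel_labels,
         sfreq = as.numeric(sfreq), meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$sfreq, n_samples(x) / x$sfreq))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = " "),
      if (n_channels(x) > 8) "..." else "", "\n")
  if (length(x$meta$stages)) {
    cat("  stages:", paste(vapply(x$meta$stages, `[[`, "", "stage"),
                           collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Number of channels / samples in a recording
#' @param recording an `eeg_recording`.
#' @return integer count.
#' @export
n_channels <- function(recording) nrow(recording$data)

#' @rdname n_channels
#' @export
n_samples <- function(recording) ncol(recording$data)

# Legacy 10-20 aliases used in older literature.
.label_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Map legacy 10-20 channel names to modern equivalents
#'
#' @param labels character vector of channel labels.
#' @return labels with T3/T4/T5/T6 replaced by T7/T8/P7/P8.
#' @export
normalize_channel_labels <- function(labels) {
  hit <- labels %in% names(.label_aliases)
  labels[hit] <- .label_aliases[labels[hit]]
  labels
}

# Record a processing stage in the provenance metadata.
add_stage <- function(recording, stage, params = list()) {
  recording$meta$stages <- c(recording$meta$stages,
                             list(c(list(stage = stage), params)))
  recording
}

#' Read a recording from a CSV file
#'
#' Reads a comma-separated matrix of potentials (microvolts). By default each
#' row is a channel; set `transpose = TRUE` for sample-per-row files. A header
#' row of channel labels is auto-detected (any non-numeric first line); labels
#' passed via `labels` take precedence and their count must match the file.
#'
#' @param path CSV file path.
#' @param labels optional channel labels; required when the file has none.
#' @param sfreq sampling rate in Hz.
#' @param transpose if TRUE the file stores one sample per row.
#' @return an `eeg_recording`.
#' @export
read_recording_csv <- function(path, labels = NULL, sfreq = 250,
                               transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  file_labels <- if (has_header) trimws(first) else NULL
  if (has_header) lines <- lines[-1]
  n_col <- length(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  # scan() rather than read.csv: recordings are wide (one column per sample)
  vals <- tryCatch(
    scan(text = lines, sep = ",", quiet = TRUE),
    error = function(e) stop("non-numeric cell in ", path))
  if (length(vals) != n_col * length(lines)) {
    stop("ragged CSV: rows differ in length in ", path)
  }
  m <- matrix(vals, nrow = length(lines), byrow = TRUE)
  if (transpose) m <- t(m)
  if (is.null(labels)) {
    # a header row labels columns, so it names channels only in
    # sample-per-row orientation
    if (transpose && !is.null(file_labels)) labels <- file_labels
    else stop("no channel labels: pass `labels` or use a labelled file")
  }
  if (nrow(m) != length(labels)) {
    stop("dimension mismatch: file has ", nrow(m), " channels but ",
         length(labels), " labels were given")
  }
  dimnames(m) <- NULL
  eeg_recording(m, labels, sfreq = sfreq,
                meta = list(source = path))
}

#' Write a recording to CSV
#'
#' One row per channel, full double precision, no header (labels travel in the
#' marker/montage sidecars). `read_recording_csv()` round-trips the values
#' bit-for-bit.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  lines <- apply(recording$data, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
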