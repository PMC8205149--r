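# FFT band decomposition and mean band power.
#
# Band extraction is an exact spectral mask: real FFT of the segment, zero
# every coefficient whose bin frequency falls outside [fmin, fmax), inverse
# FFT back to a real series of the original length. No window is applied
# here, so complementary masks reconstruct the input exactly; the Kaiser
# window is used only in the diagnostic PSD.

# logical mask over the n FFT bins (two-sided) selecting [fmin, fmax)
.band_mask <- function(n, sfreq, fmin, fmax) {
  f <- (seq_len(n) - 1) * sfreq / n
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]  # fold negative frequencies
  f >= fmin & f < fmax
}

#' Extract one frequency band from a time series
#'
#' @param x numeric time series (one channel segment), microvolts.
#' @param band a [band_definition()]; bins with `fmin <= f < fmax` are kept.
#' @param sfreq sampling rate, Hz.
#' @return numeric series of the same length, class `band_signal`, with the
#'   band carried in attributes.
#' @export
band_decompose <- function(x, band, sfreq) {
  n <- length(x)
  if (n < 2) stop("segment too short")
  if (band$fmin > sfreq / 2) stop("band lies entirely above Nyquist")
  X <- stats::fft(x)
  X[!.band_mask(n, sfreq, band$fmin, band$fmax)] <- 0 + 0i
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  structure(y, band = band$name, fmin = band$fmin, fmax = band$fmax,
            sfreq = sfreq, class = "band_signal")
}

#' Mean power of a signal segment
#'
#' `(1/T) * sum(x^2)` over the segment, microvolts squared.
#'
#' @param x numeric series (typically a `band_signal`).
#' @return non-negative scalar.
#' @export
mean_power <- function(x) {
  if (length(x) == 0) stop("empty signal")
  sum(as.numeric(x)^2) / length(x)
}

#' Mean band power per electrode, band, scene and condition
#'
#' Decomposes each condition segment of each channel independently and
#' tabulates mean band power over the complete electrode x band x scene x
#' condition grid. Powers are computed in the frequency domain (Parseval sum
#' over the masked bins), which equals `mean_power(band_decompose(...))`
#' exactly up to floating-point rounding.
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param segments data.frame from [build_segments()].
#' @param bands list of [band_definition()]s (default [analysis_bands()]).
#' @return data.frame of class `power_table` with columns `electrode`,
#'   `band`, `scene`, `condition`, `power_uV2`.
#' @export
segment_power_table <- function(recording, segments,
                                bands = analysis_bands()) {
  if (any(segments$end_sample > n_samples(recording))) {
    stop("segment extends past end of recording")
  }
  if (any(segments$start_sample >= segments$end_sample)) stop("empty segment")
  labs <- recording$channel_labels
  fs <- recording$sfreq
  band_names <- vapply(bands, `[[`, "", "name")
  rows <- vector("list", nrow(segments) * length(labs))
  k <- 0L
  for (j in seq_len(nrow(segments))) {
    idx <- (segments$start_sample[j] + 1L):segments$end_sample[j]
    n <- length(idx)
    masks <- lapply(bands, function(b) .band_mask(n, fs, b$fmin, b$fmax))
    for (i in seq_along(labs)) {
      X <- stats::fft(recording$data[i, idx])
      p2 <- Mod(X)^2
      pw <- vapply(masks, function(m) sum(p2[m]) / n^2, 0)
      k <- k + 1L
      rows[[k]] <- data.frame(
        electrode = labs[i], band = band_names,
        scene = segments$scene[j], condition = segments$condition[j],
        power_uV2 = pw, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Look up one power-table cell
#'
#' @param power_table a `power_table`.
#' @param electrode,band,scene,condition cell coordinates.
#' @return the mean power of that cell (scalar).
#' @export
power_at <- function(power_table, electrode, band, scene, condition) {
  hit <- power_table$electrode == electrode & power_table$band == band &
    power_table$scene == scene & power_table$condition == condition
  if (sum(hit) != 1L) stop("expected exactly one cell, found ", sum(hit))
  power_table$power_uV2[hit]
}

#' Write / read a power table as tidy CSV
#'
#' @param power_table a `power_table`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `power_table` (read).
#' @export
write_power_table <- function(power_table, path) {
  df <- as.data.frame(power_table)
  df$power_uV2 <- sprintf("%.17g", df$power_uV2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("power_table", "data.frame")
  out
}

#' Kaiser-windowed periodogram (diagnostic PSD)
#'
#' One-sided windowed periodogram with the window's power gain compensated,
#' so the integrated spectrum of a sinusoid recovers its mean power A^2/2.
#' With `kaiser_beta = 0` the window is rectangular and this is the plain
#' periodogram.
#'
#' @param x numeric time series.
#' @param sfreq sampling rate, Hz.
#' @param kaiser_beta Kaiser window shape parameter (0 = rectangular).
#' @return data.frame with `freq` (Hz) and `power` (µV², per-bin, summing to
#'   the windowed estimate of total mean power).
#' @export
psd_estimate <- function(x, sfreq, kaiser_beta = 14) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  w <- as.numeric(signal::kaiser(n, kaiser_beta))
  xw <- x * w
  X <- stats::fft(xw)
  gain <- sum(w^2)  # window power gain; divides out so Parseval holds
  p_full <- Mod(X)^2 / (n * gain)
  half <- seq_len(floor(n / 2) + 1L)
  p <- p_full[half]
  # fold negative-frequency power onto the positive half
  interior <- half[-1]
  interior <- interior[interior != n - interior + 2]  # exclude Nyquist self-pair
  p[interior] <- p[interior] + p_full[n - interior + 2]
  data.frame(freq = (half - 1) * sfreq / n, power = p)
}
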