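# Synthetic EEG sessions with the study protocol's structure and known,
# closed-form band powers.
#
# Each channel is 1/f background noise plus one narrowband oscillator per
# primitive band: a sinusoid at the band's centre frequency with a random
# phase and a slow sinusoidal amplitude modulation normalised so that the
# expected mean power of an amplitude-A oscillator is exactly A^2/2.
# Condition effects scale oscillator amplitudes inside the marked guided /
# self-produced windows; posterior channels get an extra alpha boost
# (eyes-closed posterior alpha dominance).

#' Configuration for the synthetic-session generator
#'
#' Defaults mirror the recording protocol: 30 channels at 250 Hz, six scenes,
#' guided script of 33-47 s (drawn per scene), a 2-s wash-out break, 60 s of
#' self-produced imagery, and a short rest between scene blocks. Default
#' condition effects are a 1.3x low-alpha amplitude boost in self-produced
#' imagery and 1.3x high-alpha and SMR boosts in guided imagery.
#'
#' @param seed RNG seed; the whole session is deterministic given the config.
#' @param montage an [eeg_montage()]; channels are its electrodes.
#' @param sfreq sampling rate, Hz.
#' @param scene_names scene identifiers, in order.
#' @param guided_duration_range_s range the per-scene guided duration is
#'   drawn from, uniformly.
#' @param break_s wash-out break between the conditions, seconds.
#' @param imagery_s self-produced imagery duration, seconds.
#' @param inter_scene_gap_s rest between scene blocks, seconds.
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param noise_scale background-noise standard deviation, microvolts.
#' @param band_amplitudes named vector: primitive band -> baseline oscillator
#'   amplitude in microvolts.
#' @param condition_multipliers named list: band -> c(guided=, self_produced=)
#'   amplitude factors (1 outside the named bands).
#' @param posterior_alpha_boost amplitude factor applied to alpha-range
#'   oscillators (bands inside 8-12 Hz) on `posterior_channels`.
#' @param posterior_channels channels receiving the alpha boost.
#' @param modulation_depth,modulation_freq slow amplitude-modulation depth
#'   (0 = pure sinusoid) and frequency (Hz); the modulation is normalised so
#'   expected power is amplitude-independent of depth.
#' @param artifact list(amplitude, rate_per_min, weights) describing an
#'   optional shared low-frequency frontal transient source; amplitude 0
#'   disables it. `weights` is a named vector of mixing weights.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         montage = default_montage(),
                         sfreq = 250,
                         scene_names = protocol_scenes(),
                         guided_duration_range_s = c(33, 47),
                         break_s = 2,
                         imagery_s = 60,
                         inter_scene_gap_s = 5,
                         noise_exponent = 1,
                         noise_scale = 5,
                         band_amplitudes = c("theta" = 3, "low alpha" = 4,
                                             "high alpha" = 3, "SMR" = 2,
                                             "low beta" = 1.5, "high beta" = 1),
                         condition_multipliers = list(
                           "low alpha"  = c(guided = 1,   self_produced = 1.3),
                           "high alpha" = c(guided = 1.3, self_produced = 1),
                           "SMR"        = c(guided = 1.3, self_produced = 1)),
                         posterior_alpha_boost = 2,
                         posterior_channels = c("P3", "Pz", "P4",
                                                "PO7", "PO8", "O1", "O2"),
                         modulation_depth = 0.3,
                         modulation_freq = 0.1,
                         artifact = list(amplitude = 0, rate_per_min = 4,
                                         weights = c(Fp1 = 1, Fp2 = 0.8))) {
  stopifnot(all(band_amplitudes >= 0), noise_scale >= 0,
            posterior_alpha_boost >= 0, modulation_depth >= 0,
            guided_duration_range_s[1] > 0,
            diff(guided_duration_range_s) >= 0)
  known <- names(default_bands())
  bad <- setdiff(c(names(band_amplitudes), names(condition_multipliers)), known)
  if (length(bad)) stop("unknown band names: ", paste(bad, collapse = ", "))
  structure(list(
    seed = as.integer(seed), montage = montage, sfreq = sfreq,
    scene_names = scene_names,
    guided_duration_range_s = guided_duration_range_s,
    break_s = break_s, imagery_s = imagery_s,
    inter_scene_gap_s = inter_scene_gap_s,
    noise_exponent = noise_exponent, noise_scale = noise_scale,
    band_amplitudes = band_amplitudes,
    condition_multipliers = condition_multipliers,
    posterior_alpha_boost = posterior_alpha_boost,
    posterior_channels = posterior_channels,
    modulation_depth = modulation_depth, modulation_freq = modulation_freq,
    artifact = artifact), class = "synth_config")
}

# amplitude factor for (channel, band, condition) implied by the config
.synth_factor <- function(config, channel, band_name, condition) {
  band <- default_bands()[[band_name]]
  f <- 1
  cm <- config$condition_multipliers[[band_name]]
  if (!is.null(cm) && condition %in% names(cm)) f <- f * cm[[condition]]
  if (band$fmin >= 8 && band$fmax <= 12 &&
      channel %in% config$posterior_channels) {
    f <- f * config$posterior_alpha_boost
  }
  f
}

#' Closed-form expected oscillator band power
#'
#' The expected mean power contributed by the band oscillator on a given
#' channel under a given condition: `(boost * multiplier * A)^2 / 2`.
#' Background 1/f noise adds on top of this in generated data.
#'
#' @param config a [synth_config()].
#' @param channel channel label.
#' @param band_name primitive band name.
#' @param condition "guided" or "self_produced".
#' @return expected mean power, microvolts squared.
#' @export
expected_band_power <- function(config, channel, band_name, condition) {
  a <- config$band_amplitudes[[band_name]]
  if (is.null(a) || is.na(a)) return(0)
  (a * .synth_factor(config, channel, band_name, condition))^2 / 2
}

#' Generate a synthetic session
#'
#' @param config a [synth_config()].
#' @return list with `recording` (an [eeg_recording()]), `markers`
#'   (a [session_markers()]) and `ground_truth` (data.frame of closed-form
#'   expected oscillator powers per channel, primitive band and condition).
#' @export
generate_session <- function(config) {
  set.seed(config$seed)
  fs <- config$sfreq
  labs <- config$montage$positions$label
  n_ch <- length(labs)

  # protocol timeline; guided durations at 2-s marker resolution, which with
  # half-Hz carriers makes every oscillator exactly bin-aligned in every
  # condition segment (no spectral leakage across band masks)
  n_scene <- length(config$scene_names)
  guided_s <- 2 * round(stats::runif(n_scene,
                                     config$guided_duration_range_s[1],
                                     config$guided_duration_range_s[2]) / 2)
  onset <- numeric(n_scene)
  cur <- 0
  scene_len <- round((guided_s + config$break_s + config$imagery_s) * fs)
  gap <- round(config$inter_scene_gap_s * fs)
  for (i in seq_len(n_scene)) {
    onset[i] <- cur
    cur <- cur + scene_len[i] + gap
  }
  n <- cur - gap  # no trailing rest
  markers <- session_markers(data.frame(
    scene = config$scene_names, guided_onset_sample = onset,
    guided_duration_s = guided_s, break_duration_s = config$break_s,
    imagery_duration_s = config$imagery_s, stringsAsFactors = FALSE))
  segs <- build_segments(markers, fs)

  t <- seq_len(n) / fs
  bands <- default_bands()
  amp_bands <- names(config$band_amplitudes)
  # per-channel carrier frequencies on the half-Hz grid strictly inside each
  # band: spatially varying peak frequencies are physiological, and distinct
  # carriers fall on orthogonal FFT bins, so neighboring channels mixed by
  # the Laplacian contribute band power additively (no coherent cross terms)
  carrier_grid <- lapply(amp_bands, function(b) {
    g <- seq(bands[[b]]$fmin + 0.5, bands[[b]]$fmax - 0.5, by = 0.5)
    # at most five carriers per band, evenly spread across the interior
    if (length(g) > 5) g <- g[round(seq(1, length(g), length.out = 5))]
    g
  })

  # per-sample condition multiplier envelope, per band (1 outside segments)
  env <- matrix(1, nrow = length(amp_bands), ncol = n,
                dimnames = list(amp_bands, NULL))
  for (j in seq_len(nrow(segs))) {
    idx <- (segs$start_sample[j] + 1L):segs$end_sample[j]
    for (b in amp_bands) {
      cm <- config$condition_multipliers[[b]]
      if (!is.null(cm)) env[b, idx] <- cm[[segs$condition[j]]]
    }
  }

  depth <- config$modulation_depth
  mod_norm <- sqrt(1 + depth^2)
  mod_s <- sin(2 * pi * config$modulation_freq * t)
  mod_c <- cos(2 * pi * config$modulation_freq * t)
  data <- pink_noise_matrix(n_ch, n, fs, config$noise_exponent,
                            config$noise_scale)
  # modulated oscillator m(t) * sin(2*pi*f0*t + phi) expands over six fixed
  # time-course basis vectors per carrier; channels sharing a carrier then
  # come from one coefficient-matrix product
  n_band <- length(amp_bands)
  phi <- matrix(stats::runif(n_ch * n_band, 0, 2 * pi), n_ch, n_band)
  psi <- matrix(stats::runif(n_ch * n_band, 0, 2 * pi), n_ch, n_band)
  carrier <- vapply(seq_len(n_band), function(b_i) {
    grid <- carrier_grid[[b_i]]
    grid[sample.int(length(grid), n_ch, replace = TRUE)]
  }, numeric(n_ch))
  if (is.null(dim(carrier))) carrier <- matrix(carrier, nrow = n_ch)
  d2 <- depth * sqrt(2)
  for (b_i in seq_len(n_band)) {
    b <- amp_bands[b_i]
    a0 <- config$band_amplitudes[[b]]
    if (a0 == 0) next
    boost <- ifelse(bands[[b]]$fmin >= 8 && bands[[b]]$fmax <= 12 &
                      labs %in% config$posterior_channels,
                    config$posterior_alpha_boost, 1)
    amp <- a0 * boost / mod_norm
    e <- env[b, ]
    for (f0 in unique(carrier[, b_i])) {
      ch <- which(carrier[, b_i] == f0)
      cs <- sin(2 * pi * f0 * t)
      cc <- cos(2 * pi * f0 * t)
      basis <- rbind(cs * e, cc * e, mod_s * cs * e, mod_s * cc * e,
                     mod_c * cs * e, mod_c * cc * e)
      cph <- cos(phi[ch, b_i]); sph <- sin(phi[ch, b_i])
      cps <- cos(psi[ch, b_i]); sps <- sin(psi[ch, b_i])
      coef <- amp[ch] * cbind(cph, sph, d2 * cps * cph, d2 * cps * sph,
                              d2 * sps * cph, d2 * sps * sph)
      data[ch, ] <- data[ch, ] + coef %*% basis
    }
  }

  gt <- expand.grid(channel = labs, band = amp_bands,
                    condition = c("guided", "self_produced"),
                    stringsAsFactors = FALSE)
  gt$expected_power <- mapply(function(ch, b, cond)
    expected_band_power(config, ch, b, cond),
    gt$channel, gt$band, gt$condition)

  rec <- eeg_recording(data, labs, sfreq = fs,
                       meta = list(generator = "synth",
                                   seed = config$seed))
  list(recording = rec, markers = markers, ground_truth = gt)
}

# 1/f^alpha background noise by spectral shaping of white noise, rescaled to
# standard deviation `scale`. Shaping is clamped below 1 Hz (the preprocessing
# highpass removes that range anyway).
pink_noise <- function(n, sfreq, exponent = 1, scale = 1) {
  drop(pink_noise_matrix(1L, n, sfreq, exponent, scale))
}

# one row per channel. The spectral shaping is a real, symmetric filter, so
# two real channels can ride in one complex FFT (real and imaginary parts
# are filtered independently), halving the transform work.
pink_noise_matrix <- function(n_ch, n, sfreq, exponent = 1, scale = 1) {
  if (scale == 0) return(matrix(0, n_ch, n))
  m <- stats::nextn(n, c(2, 3, 5))  # smooth FFT length; excess is discarded
  n_pair <- ceiling(n_ch / 2)
  w <- matrix(stats::rnorm(m * 2 * n_pair), m, 2 * n_pair)
  Wc <- stats::mvfft(w[, seq_len(n_pair), drop = FALSE] +
                       1i * w[, n_pair + seq_len(n_pair), drop = FALSE])
  f <- (seq_len(m) - 1) * sfreq / m
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]  # mirror for negative freqs
  shape <- pmax(f, 1)^(-exponent / 2)
  shape[1] <- 0  # no DC
  y <- stats::mvfft(Wc * shape, inverse = TRUE)[seq_len(n), , drop = FALSE] / m
  x <- cbind(Re(y), Im(y))[, seq_len(n_ch), drop = FALSE]
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  t(x) * (scale / sds)
}

#' Mix a shared low-frequency transient source into frontal channels
#'
#' Adds `amplitude`-scaled raised-cosine transients (about 1 s wide, at
#' `rate_per_min` random onsets) to the channels named in
#' `config$artifact$weights`, with those mixing weights. The unmixed data
#' matrix and the artifact time course are stored in the result's
#' `meta$clean` and `meta$artifact_source` for recovery scoring.
#'
#' @param recording an [eeg_recording()].
#' @param config a [synth_config()] with a non-NULL `artifact` element.
#' @return the mixed `eeg_recording`.
#' @export
inject_artifact <- function(recording, config) {
  art <- config$artifact
  if (is.null(art)) stop("config has no artifact settings")
  out <- recording
  out$meta$clean <- recording$data
  n <- n_samples(recording)
  fs <- recording$sfreq
  src <- numeric(n)
  if (art$amplitude > 0) {
    n_events <- max(1L, round(art$rate_per_min * n / fs / 60))
    width <- round(fs)  # ~1 s transients
    onsets <- sort(sample.int(max(1L, n - width), n_events))
    pulse <- art$amplitude * (1 - cos(2 * pi * seq_len(width) / width)) / 2
    for (o in onsets) {
      idx <- o:(o + width - 1L)
      src[idx] <- src[idx] + pulse
    }
    for (ch in names(art$weights)) {
      i <- match(ch, recording$channel_labels)
      if (is.na(i)) stop("artifact channel ", ch, " not in recording")
      out$data[i, ] <- out$data[i, ] + art$weights[[ch]] * src
    }
  }
  out$meta$artifact_source <- src
  add_stage(out, "inject_artifact", list(amplitude = art$amplitude))
}
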