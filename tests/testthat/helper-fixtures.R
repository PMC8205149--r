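# Shared fixtures, built in code.

# 5-channel toy montage with explicit, hand-checkable adjacency
toy_montage <- function() {
  pos <- data.frame(
    label = c("A", "B", "C", "D", "E"),
    x = c(0, 1, -1, 0, 0),
    y = c(0, 0, 0, 1, -1))
  eeg_montage(pos, neighbors = list(
    A = c("B", "C", "D", "E"),
    B = c("A", "D"),
    C = c("A", "E"),
    D = c("A", "B"),
    E = c("A", "C")))
}

toy_recording <- function(n = 1000, sfreq = 250, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(5 * n), 5, n),
                c("A", "B", "C", "D", "E"), sfreq = sfreq)
}

# single-scene markers starting at sample 0
one_scene_markers <- function(guided_s = 40, break_s = 2, imagery_s = 60,
                              scene = "fitness_activity") {
  session_markers(data.frame(
    scene = scene, guided_onset_sample = 0, guided_duration_s = guided_s,
    break_duration_s = break_s, imagery_duration_s = imagery_s),
    guided_range = c(1, 120))
}

# small fast synthetic session: default montage, two short scenes
quick_synth_config <- function(seed = 1, ...) {
  synth_config(seed = seed,
               scene_names = protocol_scenes()[1:2],
               guided_duration_range_s = c(8, 10),
               imagery_s = 12, inter_scene_gap_s = 1, ...)
}

# sine sampled at sfreq for d seconds
sine_wave <- function(freq, d = 10, sfreq = 250, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(d * sfreq) / sfreq + phase)
}
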