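# Session protocol: scene markers and the guided / self-produced condition
# segmentation. Each scene is a guided (script-listening) block, a short
# wash-out break, then a self-produced imagery block.

.protocol_scenes <- c("fitness_activity", "start_high_level_championship",
                      "successful_competition", "slow_start",
                      "training_session", "your_home_venue")

#' The six protocol scene names
#' @return character vector of scene identifiers, in protocol order.
#' @export
protocol_scenes <- function() .protocol_scenes

#' Construct session markers
#'
#' @param scenes data.frame with columns `scene`, `guided_onset_sample`
#'   (0-based), `guided_duration_s`, `break_duration_s`, `imagery_duration_s`.
#' @param guided_range plausible guided-script duration range in seconds;
#'   markers outside it are rejected (the recorded scripts span 33-47 s, so
#'   the default check is deliberately loose).
#' @return object of class `session_markers`.
#' @export
session_markers <- function(scenes, guided_range = c(5, 120)) {
  need <- c("scene", "guided_onset_sample", "guided_duration_s",
            "break_duration_s", "imagery_duration_s")
  stopifnot(is.data.frame(scenes), all(need %in% names(scenes)))
  scenes <- scenes[, need]
  if (any(scenes$guided_duration_s <= 0) || any(scenes$imagery_duration_s <= 0) ||
      any(scenes$break_duration_s < 0)) {
    stop("durations must be positive (break may be zero)")
  }
  if (any(scenes$guided_duration_s < guided_range[1]) ||
      any(scenes$guided_duration_s > guided_range[2])) {
    stop("guided duration outside plausible range [",
         guided_range[1], ", ", guided_range[2], "] s")
  }
  if (anyDuplicated(scenes$scene)) stop("duplicate scene names")
  if (is.unsorted(scenes$guided_onset_sample, strictly = TRUE)) {
    stop("scene onsets must be strictly increasing")
  }
  structure(list(scenes = scenes), class = "session_markers")
}

#' @export
print.session_markers <- function(x, ...) {
  cat(sprintf("<session_markers> %d scenes\n", nrow(x$scenes)))
  print(x$scenes, row.names = FALSE)
  invisible(x)
}

#' Split the protocol timeline into condition segments
#'
#' For each scene produces two half-open, 0-based sample intervals: the guided
#' block `[onset, onset + guided_duration)` and the self-produced block
#' starting after the wash-out break and lasting `imagery_duration_s`.
#'
#' @param markers a `session_markers`.
#' @param sfreq sampling rate in Hz.
#' @return data.frame with columns `scene`, `condition` (guided /
#'   self_produced), `start_sample`, `end_sample`; sorted, pairwise disjoint.
#' @export
build_segments <- function(markers, sfreq) {
  sc <- markers$scenes
  segs <- do.call(rbind, lapply(seq_len(nrow(sc)), function(i) {
    on <- sc$guided_onset_sample[i]
    g_end <- on + round(sc$guided_duration_s[i] * sfreq)
    s_start <- g_end + round(sc$break_duration_s[i] * sfreq)
    s_end <- s_start + round(sc$imagery_duration_s[i] * sfreq)
    data.frame(scene = sc$scene[i],
               condition = c("guided", "self_produced"),
               start_sample = c(on, s_start),
               end_sample = c(g_end, s_end),
               stringsAsFactors = FALSE)
  }))
  if (any(segs$start_sample >= segs$end_sample)) stop("empty segment")
  ord <- order(segs$start_sample)
  if (any(segs$end_sample[ord][-nrow(segs)] > segs$start_sample[ord][-1])) {
    stop("overlapping scene windows")
  }
  segs
}

#' Read / write session markers as YAML or JSON
#'
#' On disk: a list of scene records with `scene`, `guided_onset_sample`,
#' `guided_duration_s`, `break_duration_s`, `imagery_duration_s`.
#'
#' @param path file path (.yaml/.yml or .json).
#' @param markers a `session_markers` (for writing).
#' @return `session_markers` (read) or `path` invisibly (write).
#' @export
read_markers <- function(path) {
  obj <- read_structured(path)
  rows <- lapply(obj$scenes, function(s) {
    data.frame(scene = s$scene,
               guided_onset_sample = as.numeric(s$guided_onset_sample),
               guided_duration_s = as.numeric(s$guided_duration_s),
               break_duration_s = as.numeric(s$break_duration_s),
               imagery_duration_s = as.numeric(s$imagery_duration_s),
               stringsAsFactors = FALSE)
  })
  session_markers(do.call(rbind, rows))
}

#' @rdname read_markers
#' @export
write_markers <- function(markers, path) {
  recs <- lapply(seq_len(nrow(markers$scenes)), function(i)
    as.list(markers$scenes[i, ]))
  write_structured(list(scenes = recs), path)
}
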