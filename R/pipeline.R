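# End-to-end orchestration: preprocess -> band power -> maps -> comparison
# tables, with provenance, plus the synthetic-session entry point.

#' Run the imagery band-power analysis
#'
#' The central entry point. Executes the full chain on one session: channel
#' QC, zero-phase Butterworth bandpass, small-Laplacian spatial filter,
#' per-channel demeaning, the ICA stage, FFT band decomposition and mean
#' power per condition segment, per-scene condition/difference head maps,
#' and the scene-level and ROI-level Wilcoxon comparison tables.
#'
#' @param recording an [eeg_recording()], or a path (or vector of per-scene
#'   paths, concatenated in order) to CSV data readable by
#'   [read_recording_csv()].
#' @param markers a [session_markers()] or a marker-file path.
#' @param montage an [eeg_montage()] or a montage-file path
#'   (default [default_montage()]).
#' @param bands named list of [band_definition()]s to analyse
#'   (default [analysis_bands()]: low alpha, high alpha, SMR).
#' @param rois named list of [roi_spec()]s (default [default_rois()]).
#' @param electrodes paired-unit electrode set for scene-level tests.
#' @param fmin,fmax,order bandpass parameters.
#' @param ica run the ICA stage? (With no rejections it is an identity map.)
#' @param qc run the report-only QC stage?
#' @param reject,artifact_ref components to remove, see [run_ica()].
#' @param method Wilcoxon method ("auto", "exact", "normal_approx").
#' @param seed master seed for the ICA initialisation.
#' @param labels,sfreq used when `recording` is a path.
#' @return an object of class `imagery_analysis` with elements
#'   `power_table`, `scene_table`, `roi_table`, `maps` (band -> scene ->
#'   guided / self_produced / difference [electrode_map()]s), `segments`,
#'   `montage`, `qc`, and `provenance`.
#' @export
imagery_analysis <- function(recording, markers, montage = default_montage(),
                             bands = analysis_bands(), rois = default_rois(),
                             electrodes = default_analysis_electrodes(),
                             fmin = 1, fmax = 40, order = 5,
                             ica = TRUE, qc = TRUE,
                             reject = NULL, artifact_ref = NULL,
                             method = "auto", seed = 1L,
                             labels = NULL, sfreq = 250) {
  if (is.character(montage)) montage <- read_montage(montage)
  if (is.character(markers)) markers <- read_markers(markers)
  if (is.character(recording)) {
    parts <- lapply(recording, read_recording_csv, labels = labels,
                    sfreq = sfreq)
    recording <- parts[[1]]
    if (length(parts) > 1) {
      recording$data <- do.call(cbind, lapply(parts, `[[`, "data"))
    }
  }
  segments <- build_segments(markers, recording$sfreq)
  if (max(segments$end_sample) > n_samples(recording)) {
    stop("markers extend past the end of the recording")
  }

  pre <- preprocess(recording, montage, fmin = fmin, fmax = fmax,
                    order = order, ica = ica, qc = qc, reject = reject,
                    artifact_ref = artifact_ref, seed = seed)
  pt <- segment_power_table(pre, segments, bands = bands)

  band_names <- vapply(bands, `[[`, "", "name")
  scenes <- markers$scenes$scene
  maps <- lapply(stats::setNames(band_names, band_names), function(b) {
    lapply(stats::setNames(scenes, scenes), function(sc) {
      cm <- condition_maps(pt, b, sc)
      c(cm, list(difference = difference_map(cm$guided, cm$self_produced)))
    })
  })

  scene_table <- scene_comparison_table(pt, bands = band_names,
                                        electrodes = electrodes,
                                        method = method)
  roi_table <- roi_comparison_table(pt, rois = rois, bands = band_names,
                                    method = method)

  structure(list(
    power_table = pt, scene_table = scene_table, roi_table = roi_table,
    maps = maps, segments = segments, montage = montage,
    qc = pre$meta$qc,
    provenance = list(
      package_version = as.character(utils::packageVersion("eegimagery")),
      seed = seed,
      stages = pre$meta$stages,
      parameters = list(fmin = fmin, fmax = fmax, order = order, ica = ica,
                        reject = reject, method = method,
                        bands = band_names, electrodes = electrodes),
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "imagery_analysis")
}

#' @export
print.imagery_analysis <- function(x, ...) {
  cat("<imagery_analysis>\n")
  cat(sprintf("  %d power cells (%d electrodes x %d bands x %d scenes x 2 conditions)\n",
              nrow(x$power_table), length(unique(x$power_table$electrode)),
              length(unique(x$power_table$band)),
              length(unique(x$power_table$scene))))
  cat(sprintf("  scene table: %d rows; ROI table: %d rows; QC verdict: %s\n",
              nrow(x$scene_table), nrow(x$roi_table), x$qc$verdict))
  invisible(x)
}

#' @export
summary.imagery_analysis <- function(object, alpha = 0.05, ...) {
  sig_scene <- object$scene_table[object$scene_table$p < alpha, ]
  sig_roi <- object$roi_table[object$roi_table$p < alpha, ]
  cat("Imagery condition comparison (self-produced vs guided)\n\n")
  cat(sprintf("Scene-level: %d of %d rows significant at alpha = %g\n",
              nrow(sig_scene), nrow(object$scene_table), alpha))
  for (b in unique(object$scene_table$band)) {
    sub <- sig_scene[sig_scene$band == b, ]
    if (nrow(sub)) {
      dirs <- table(sub$direction)
      cat(sprintf("  %-11s %s\n", paste0(b, ":"),
                  paste(sprintf("%s in %d scenes", names(dirs), dirs),
                        collapse = ", ")))
    }
  }
  cat(sprintf("\nROI-level: %d of %d rows significant at alpha = %g\n",
              nrow(sig_roi), nrow(object$roi_table), alpha))
  invisible(list(scene = sig_scene, roi = sig_roi))
}

#' @export
plot.imagery_analysis <- function(x, band = NULL, scene = NULL,
                                  kind = "difference", ...) {
  if (is.null(band)) band <- names(x$maps)[1]
  if (is.null(scene)) scene <- names(x$maps[[band]])[1]
  plot_headmap(x$maps[[band]][[scene]][[kind]], x$montage, ...)
}

# "low alpha" -> "low_alpha" for filenames
slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Run the pipeline and write an output bundle
#'
#' Calls [imagery_analysis()] and writes a run directory: `provenance.json`,
#' `tables/power_table.csv`, `tables/scene_comparison.csv`,
#' `tables/roi_comparison.csv`, and one `maps/<band>_<scene>_<kind>.json`
#' head map per band x scene x {guided, self_produced, difference}. Given
#' the same inputs and seed, tables and maps are byte-identical across runs.
#'
#' @param out_dir output directory (created if needed).
#' @param ... passed to [imagery_analysis()].
#' @return the `imagery_analysis` object, invisibly.
#' @export
run_pipeline <- function(out_dir, ...) {
  an <- imagery_analysis(...)
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  write_power_table(an$power_table,
                    file.path(out_dir, "tables", "power_table.csv"))
  write_comparison_table(an$scene_table,
                         file.path(out_dir, "tables", "scene_comparison.csv"))
  write_comparison_table(an$roi_table,
                         file.path(out_dir, "tables", "roi_comparison.csv"))
  for (b in names(an$maps)) {
    for (sc in names(an$maps[[b]])) {
      for (kind in names(an$maps[[b]][[sc]])) {
        export_headmap(an$maps[[b]][[sc]][[kind]], an$montage,
                       file.path(out_dir, "maps",
                                 sprintf("%s_%s_%s.json", slug(b), slug(sc),
                                         kind)))
      }
    }
  }
  writeLines(jsonlite::toJSON(an$provenance, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "provenance.json"))
  invisible(an)
}

#' Generate a synthetic session, analyse it, and score recovery
#'
#' Runs [generate_session()], feeds the session through
#' [imagery_analysis()] / [run_pipeline()], and scores how well the
#' comparison tables recover the condition effects built into the
#' generator: for each analysis band with a condition multiplier, the
#' expected direction, the fraction of scene rows significant in that
#' direction, and the fraction of scene rows significant in any direction.
#'
#' @param config a [synth_config()].
#' @param out_dir optional bundle directory; when NULL nothing is written.
#' @param alpha significance level for the recovery score.
#' @param ... passed to [imagery_analysis()] (e.g. `ica = FALSE`).
#' @return list with `analysis` (the `imagery_analysis`), `ground_truth`,
#'   and `recovery` (data.frame: band, expected direction, agreement and
#'   rejection fractions over scene rows).
#' @export
simulate_and_run <- function(config, out_dir = NULL, alpha = 0.05, ...) {
  sess <- generate_session(config)
  an <- if (is.null(out_dir)) {
    imagery_analysis(sess$recording, sess$markers,
                     montage = config$montage, ...)
  } else {
    run_pipeline(out_dir, recording = sess$recording, markers = sess$markers,
                 montage = config$montage, ...)
  }
  st <- an$scene_table
  rec <- do.call(rbind, lapply(unique(st$band), function(b) {
    cm <- config$condition_multipliers[[b]]
    expected <- if (is.null(cm) || cm[["guided"]] == cm[["self_produced"]])
      "none"
    else if (cm[["self_produced"]] > cm[["guided"]]) "self > guided"
    else "guided > self"
    sub <- st[st$band == b, ]
    data.frame(band = b, expected_direction = expected,
               n_rows = nrow(sub),
               frac_correct_rejections =
                 mean(sub$p < alpha & sub$direction == expected),
               frac_rejections = mean(sub$p < alpha),
               stringsAsFactors = FALSE)
  }))
  list(analysis = an, ground_truth = sess$ground_truth, recovery = rec)
}
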