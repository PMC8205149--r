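# Scene-level and ROI-level condition comparison tables.
#
# Scene-level rows pair guided vs self-produced mean power per electrode of
# the analysis set (a configurable paired-unit choice, 14 electrodes by
# default). ROI-level rows pair the per-scene ROI mean powers (six scenes).

#' Mean power of a region of interest
#'
#' Unweighted mean of the ROI electrodes' mean powers for one band, scene
#' and condition.
#'
#' @param power_table a `power_table`.
#' @param roi an [roi_spec()].
#' @param band,scene,condition cell coordinates.
#' @return scalar mean power.
#' @export
roi_power <- function(power_table, roi, band, scene, condition) {
  vals <- vapply(roi$electrodes, function(el)
    power_at(power_table, el, band, scene, condition), 0)
  mean(vals)
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

.comparison_row <- function(grouping, band, guided, self_produced, method) {
  wt <- wilcoxon_signed_rank(self_produced, guided, method = method)
  data.frame(grouping, band = band,
             mean_guided = mean(guided), sd_guided = stats::sd(guided),
             mean_self = mean(self_produced), sd_self = stats::sd(self_produced),
             n = wt$n_used, z = wt$z, p = wt$p, method = wt$method,
             direction = ifelse(wt$direction > 0, "self > guided",
                                ifelse(wt$direction < 0, "guided > self",
                                       "none")),
             stringsAsFactors = FALSE, row.names = NULL)
}

.finalize_table <- function(rows) {
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p)
  out
}

#' Scene-by-band condition comparison (per-electrode pairing)
#'
#' For every scene and band, a Wilcoxon signed-rank test of self-produced vs
#' guided mean power paired over the electrodes of the analysis set, with
#' per-condition mean and SD over those same electrodes. Raw p values carry
#' star marks (* < 0.05, ** < 0.01, *** < 0.001); a Benjamini-Hochberg
#' column is included alongside for transparency (no family-wise correction
#' is applied to the stars).
#'
#' @param power_table a complete `power_table`.
#' @param bands band names to test (default the three analysis bands).
#' @param electrodes paired-unit electrode set
#'   (default [default_analysis_electrodes()]).
#' @param method Wilcoxon method ("auto", "exact", "normal_approx").
#' @return data.frame with one row per scene x band: condition means/SDs,
#'   `n`, `z`, `p`, `p_bh`, `stars`, `direction`.
#' @export
scene_comparison_table <- function(power_table,
                                   bands = names(analysis_bands()),
                                   electrodes = default_analysis_electrodes(),
                                   method = "auto") {
  scenes <- unique(power_table$scene)
  rows <- list()
  for (sc in scenes) {
    for (b in bands) {
      g <- vapply(electrodes, function(el)
        power_at(power_table, el, b, sc, "guided"), 0)
      s <- vapply(electrodes, function(el)
        power_at(power_table, el, b, sc, "self_produced"), 0)
      rows[[length(rows) + 1L]] <- .comparison_row(
        data.frame(scene = sc, stringsAsFactors = FALSE), b, g, s, method)
    }
  }
  .finalize_table(rows)
}

#' Hemisphere-region-by-band condition comparison (per-scene pairing)
#'
#' For every ROI and band, a Wilcoxon signed-rank test of self-produced vs
#' guided ROI mean power paired over scenes.
#'
#' @param power_table a complete `power_table`.
#' @param rois named list of [roi_spec()]s (default [default_rois()]).
#' @param bands band names to test.
#' @param method Wilcoxon method.
#' @return data.frame with one row per hemisphere x region x band; columns
#'   as in [scene_comparison_table()].
#' @export
roi_comparison_table <- function(power_table, rois = default_rois(),
                                 bands = names(analysis_bands()),
                                 method = "auto") {
  scenes <- unique(power_table$scene)
  rows <- list()
  for (r in rois) {
    for (b in bands) {
      g <- vapply(scenes, function(sc)
        roi_power(power_table, r, b, sc, "guided"), 0)
      s <- vapply(scenes, function(sc)
        roi_power(power_table, r, b, sc, "self_produced"), 0)
      rows[[length(rows) + 1L]] <- .comparison_row(
        data.frame(hemisphere = r$hemisphere, region = r$name,
                   stringsAsFactors = FALSE), b, g, s, method)
    }
  }
  .finalize_table(rows)
}

#' Write a comparison table as CSV
#'
#' Numeric columns are serialised at fixed full precision so identical
#' analyses produce byte-identical files.
#'
#' @param table data.frame from [scene_comparison_table()] or
#'   [roi_comparison_table()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  num <- vapply(table, is.numeric, TRUE)
  table[num] <- lapply(table[num], function(x) sprintf("%.17g", x))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
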