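# Frequency-band and region-of-interest registries.
#
# Band edges are half-open [fmin, fmax): adjacent bands such as low and high
# alpha share the 10 Hz edge on paper but never double-count a frequency bin.

#' Define a frequency band
#'
#' @param name band name.
#' @param fmin,fmax band edges in Hz; the band covers `[fmin, fmax)`.
#' @return a `band_definition` (named list).
#' @export
band_definition <- function(name, fmin, fmax) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(fmin), is.numeric(fmax), fmin > 0, fmin < fmax)
  structure(list(name = name, fmin = as.numeric(fmin), fmax = as.numeric(fmax)),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s [%g, %g) Hz\n", x$name, x$fmin, x$fmax))
  invisible(x)
}

#' Canonical EEG band registry
#'
#' The eight bands of the analysis: theta, low/high alpha, the aggregate
#' alpha, SMR, low/high beta and the aggregate beta. Alpha is exactly the
#' union of low and high alpha, beta of low and high beta.
#'
#' @return named list of [band_definition()]s.
#' @export
default_bands <- function() {
  defs <- list(
    c("theta",       4,  8),
    c("low alpha",   8, 10),
    c("high alpha", 10, 12),
    c("alpha",       8, 12),
    c("SMR",        12, 15),
    c("low beta",   15, 23),
    c("high beta",  23, 30),
    c("beta",       15, 30)
  )
  bands <- lapply(defs, function(d)
    band_definition(d[1], as.numeric(d[2]), as.numeric(d[3])))
  stats::setNames(bands, vapply(bands, `[[`, "", "name"))
}

#' The three bands the condition comparison focuses on
#' @return named list of band definitions: low alpha, high alpha, SMR.
#' @export
analysis_bands <- function() default_bands()[c("low alpha", "high alpha", "SMR")]

#' Define a region of interest
#'
#' @param name region name (e.g. "frontal").
#' @param hemisphere "left" or "right".
#' @param electrodes character vector of member electrode labels.
#' @return an `roi_spec`.
#' @export
roi_spec <- function(name, hemisphere, electrodes) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  structure(list(name = name, hemisphere = hemisphere,
                 electrodes = normalize_channel_labels(electrodes)),
            class = "roi_spec")
}

#' Default hemisphere-region registry
#'
#' The ten regions of interest: frontal, central, temporal, central-parietal
#' and parieto-occipital electrode sets for each hemisphere (24 distinct
#' electrodes in total).
#'
#' @return named list of [roi_spec()]s, names `<region>_<hemisphere>`.
#' @export
default_rois <- function() {
  defs <- list(
    roi_spec("frontal",          "right", c("Fp2", "F4")),
    roi_spec("frontal",          "left",  c("Fp1", "F3")),
    roi_spec("central",          "right", c("C2", "C4", "FC2")),
    roi_spec("central",          "left",  c("C1", "C3", "FC1")),
    roi_spec("temporal",         "right", c("T8", "C6", "FC6")),
    roi_spec("temporal",         "left",  c("T7", "C5", "FC5")),
    roi_spec("central_parietal", "right", c("CP2", "CP6")),
    roi_spec("central_parietal", "left",  c("CP1", "CP5")),
    roi_spec("parieto_occipital", "right", c("P4", "PO8")),
    roi_spec("parieto_occipital", "left",  c("P3", "PO7"))
  )
  stats::setNames(defs, vapply(defs, function(r)
    paste(r$name, r$hemisphere, sep = "_"), ""))
}

#' Default paired-electrode analysis set for scene-level comparisons
#'
#' Scene-level condition tests pair guided and self-produced mean power per
#' electrode. The paired-unit set is configuration, not a claim about any
#' particular dataset; the default is 14 electrodes spread over prefrontal,
#' fronto-central, central, temporal, centro-parietal, midline parietal and
#' occipital sites, chosen to be as close to pairwise non-adjacent on the
#' default montage as the scalp coverage allows — electrodes that are
#' Laplacian neighbors share filtered activity, which would make the paired
#' differences strongly dependent.
#'
#' @return character vector of 14 electrode labels.
#' @export
default_analysis_electrodes <- function() {
  c("Fp1", "Fp2", "FC5", "FC6", "C1", "C2", "T7", "T8",
    "CP5", "CP6", "CPz", "Pz", "O1", "O2")
}

#' Load band and ROI registries from a YAML/JSON config
#'
#' Expected keys: `bands: {name: [fmin, fmax]}` and
#' `rois: {key: {name, hemisphere, electrodes}}`; either may be absent, in
#' which case the default registry is returned.
#'
#' @param path config file path.
#' @return list with elements `bands` and `rois`.
#' @export
read_band_config <- function(path) {
  obj <- read_structured(path)
  bands <- if (is.null(obj$bands)) default_bands() else {
    stats::setNames(
      lapply(names(obj$bands), function(nm)
        band_definition(nm, as.numeric(obj$bands[[nm]][[1]]),
                        as.numeric(obj$bands[[nm]][[2]]))),
      names(obj$bands))
  }
  rois <- if (is.null(obj$rois)) default_rois() else {
    stats::setNames(
      lapply(obj$rois, function(r)
        roi_spec(r$name, r$hemisphere, as.character(unlist(r$electrodes)))),
      names(obj$rois))
  }
  list(bands = bands, rois = rois)
}
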