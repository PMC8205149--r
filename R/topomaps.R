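# Condition power maps, self-minus-guided differences, MinMax normalisation
# and head-map export. The tested contract is the exported per-electrode
# values; rendering is a convenience.

#' Construct an electrode map
#'
#' @param values named numeric vector: electrode -> value.
#' @param band,scene map coordinates (strings).
#' @param kind "guided", "self_produced" or "difference".
#' @return an `electrode_map` carrying both raw and MinMax-normalised values.
#' @export
electrode_map <- function(values, band, scene, kind) {
  kind <- match.arg(kind, c("guided", "self_produced", "difference"))
  stopifnot(!is.null(names(values)), !anyNA(values))
  values <- values[order(names(values))]  # canonical electrode order
  structure(list(band = band, scene = scene, kind = kind,
                 values = values, normalized = minmax_normalize(values)),
            class = "electrode_map")
}

#' @export
print.electrode_map <- function(x, ...) {
  cat(sprintf("<electrode_map> %s / %s / %s, %d electrodes, range [%g, %g]\n",
              x$band, x$scene, x$kind, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' MinMax normalisation to [0, 1]
#'
#' `v -> (v - min) / (max - min)`. A constant input maps to 0.5 everywhere
#' (neutral midpoint rather than implying structure).
#'
#' @param values numeric vector.
#' @return values rescaled into [0, 1], names preserved.
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0) stop("empty value set")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(stats::setNames(rep(0.5, length(values)), names(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Per-condition raw power maps for one band and scene
#'
#' @param power_table a `power_table` covering the requested slice.
#' @param band band name.
#' @param scene scene name.
#' @return list with `guided` and `self_produced` [electrode_map()]s.
#' @export
condition_maps <- function(power_table, band, scene) {
  slice <- power_table[power_table$band == band &
                         power_table$scene == scene, ]
  if (nrow(slice) == 0) stop("no cells for band ", band, ", scene ", scene)
  one <- function(cond) {
    s <- slice[slice$condition == cond, ]
    if (nrow(s) == 0) stop("missing condition ", cond)
    electrode_map(stats::setNames(s$power_uV2, s$electrode),
                  band = band, scene = scene, kind = cond)
  }
  list(guided = one("guided"), self_produced = one("self_produced"))
}

#' Self-produced minus guided difference map
#'
#' Sign convention: positive where self-produced power exceeds guided power.
#'
#' @param guided,self_produced [electrode_map()]s over the same electrodes.
#' @return a `difference` [electrode_map()].
#' @export
difference_map <- function(guided, self_produced) {
  if (!setequal(names(guided$values), names(self_produced$values))) {
    stop("electrode sets differ")
  }
  els <- names(guided$values)
  d <- self_produced$values[els] - guided$values[els]
  electrode_map(d, band = guided$band, scene = guided$scene,
                kind = "difference")
}

#' Export a head map as JSON
#'
#' One record per electrode with scalp coordinates, the raw value and the
#' per-map MinMax-normalised value. Records are sorted by electrode label
#' and numbers serialised at full precision, so re-exporting an identical
#' map is byte-identical.
#'
#' @param map an [electrode_map()].
#' @param montage an [eeg_montage()] positioning every map electrode.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_headmap <- function(map, montage, path) {
  pos <- montage$positions
  missing <- setdiff(names(map$values), pos$label)
  if (length(missing)) {
    stop("electrodes not in montage: ", paste(missing, collapse = ", "))
  }
  els <- names(map$values)  # already sorted canonically
  i <- match(els, pos$label)
  records <- lapply(seq_along(els), function(j) list(
    electrode = els[j], x = pos$x[i[j]], y = pos$y[i[j]],
    raw = unname(map$values[j]), normalized = unname(map$normalized[j])))
  obj <- list(band = map$band, scene = map$scene, kind = map$kind,
              electrodes = records)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Plot a head map
#'
#' Inverse-distance-weighted interpolation of the normalised values on a
#' unit head disc (nose up), with electrode positions overlaid. Decorative;
#' the quantitative product is [export_headmap()].
#'
#' @param map an [electrode_map()].
#' @param montage an [eeg_montage()].
#' @param resolution interpolation grid resolution.
#' @param ... passed to [graphics::image()].
#' @return the interpolated grid, invisibly.
#' @export
plot_headmap <- function(map, montage, resolution = 64, ...) {
  pos <- montage$positions
  i <- match(names(map$values), pos$label)
  px <- pos$x[i]; py <- pos$y[i]; v <- unname(map$normalized)
  g <- seq(-1, 1, length.out = resolution)
  z <- matrix(NA_real_, resolution, resolution)
  for (a in seq_len(resolution)) for (b in seq_len(resolution)) {
    if (g[a]^2 + g[b]^2 > 1) next
    d2 <- (px - g[a])^2 + (py - g[b])^2
    if (any(d2 < 1e-12)) z[a, b] <- v[which.min(d2)]
    else z[a, b] <- sum(v / d2) / sum(1 / d2)
  }
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(g, g, z, col = pal, zlim = c(0, 1), asp = 1,
                  xlab = "", ylab = "", axes = FALSE,
                  main = sprintf("%s / %s / %s", map$band, map$scene,
                                 map$kind), ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  graphics::points(px, py, pch = 20)
  graphics::text(px, py, names(map$values), pos = 3, cex = 0.5)
  invisible(z)
}
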