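# Montage: 2-D scalp positions plus the neighbor adjacency consumed by the
# small-Laplacian spatial filter. Positions live on a unit head disc with the
# nose at +y and the right ear at +x.

#' Construct a montage
#'
#' @param positions data.frame with columns `label`, `x`, `y` (unit head disc,
#'   nose +y, right +x).
#' @param neighbors optional named list: label -> character vector of neighbor
#'   labels. When NULL, adjacency is derived from positions: each channel is
#'   linked to its `k` nearest channels within `radius`, the relation is then
#'   symmetrised, and any channel left with fewer than two neighbors is joined
#'   to its two nearest channels unconditionally.
#' @param k maximum nearest neighbors per channel when deriving adjacency.
#' @param radius maximum neighbor distance when deriving adjacency.
#' @return an object of class `eeg_montage` with elements `positions` and
#'   `neighbors`.
#' @export
eeg_montage <- function(positions, neighbors = NULL, k = 4, radius = 0.5) {
  stopifnot(is.data.frame(positions),
            all(c("label", "x", "y") %in% names(positions)))
  positions$label <- normalize_channel_labels(as.character(positions$label))
  if (anyDuplicated(positions$label)) stop("duplicate montage labels")
  if (is.null(neighbors)) {
    neighbors <- derive_adjacency(positions, k = k, radius = radius)
  } else {
    names(neighbors) <- normalize_channel_labels(names(neighbors))
    neighbors <- lapply(neighbors, normalize_channel_labels)
    neighbors <- symmetrize_adjacency(neighbors)
  }
  m <- structure(list(positions = positions, neighbors = neighbors),
                 class = "eeg_montage")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  labs <- m$positions$label
  for (ch in names(m$neighbors)) {
    nb <- m$neighbors[[ch]]
    if (ch %in% nb) stop("channel ", ch, " is its own neighbor")
    if (!all(nb %in% labs)) stop("neighbor of ", ch, " missing from positions")
    for (other in nb) {
      if (!(ch %in% m$neighbors[[other]])) {
        stop("asymmetric adjacency: ", ch, " -> ", other)
      }
    }
  }
  invisible(m)
}

symmetrize_adjacency <- function(neighbors) {
  labs <- names(neighbors)
  for (ch in labs) {
    for (other in neighbors[[ch]]) {
      neighbors[[other]] <- union(neighbors[[other]], ch)
    }
  }
  lapply(neighbors, function(nb) sort(unique(nb)))
}

derive_adjacency <- function(positions, k = 4, radius = 0.5) {
  labs <- positions$label
  xy <- as.matrix(positions[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(labs, labs)
  neighbors <- stats::setNames(vector("list", length(labs)), labs)
  for (ch in labs) {
    ord <- labs[order(d[ch, ])]
    ord <- setdiff(ord, ch)
    within <- ord[d[ch, ord] <= radius]
    nb <- utils::head(within, k)
    if (length(nb) < 2) nb <- utils::head(ord, 2)  # boundary electrodes
    neighbors[[ch]] <- nb
  }
  symmetrize_adjacency(neighbors)
}

#' @export
print.eeg_montage <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<eeg_montage> %d channels, neighbor degree %d-%d\n",
              nrow(x$positions), min(deg), max(deg)))
  invisible(x)
}

#' Default 30-channel montage
#'
#' A 10-20/10-10 montage covering the 24 region-of-interest electrodes
#' (frontal, central, temporal, centro-parietal and parieto-occipital pairs)
#' plus the midline (Fz, Cz, CPz, Pz) and occipital O1/O2. Coordinates are a
#' standard 2-D head-disc projection; adjacency is derived by nearest
#' neighbors (see [eeg_montage()]).
#'
#' @param k,radius adjacency parameters passed to [eeg_montage()].
#' @return an `eeg_montage` with 30 channels.
#' @export
default_montage <- function(k = 4, radius = 0.5) {
  pos <- default_positions()
  eeg_montage(pos, k = k, radius = radius)
}

default_positions <- function() {
  tab <- c(
    "Fp1", -0.31,  0.95,   "Fp2",  0.31,  0.95,
    "F3",  -0.36,  0.52,   "Fz",   0.00,  0.50,   "F4",   0.36,  0.52,
    "FC5", -0.57,  0.28,   "FC1", -0.20,  0.26,   "FC2",  0.20,  0.26,
    "FC6",  0.57,  0.28,
    "T7",  -0.95,  0.00,   "C5",  -0.72,  0.00,   "C3",  -0.48,  0.00,
    "C1",  -0.24,  0.00,   "Cz",   0.00,  0.00,   "C2",   0.24,  0.00,
    "C4",   0.48,  0.00,   "C6",   0.72,  0.00,   "T8",   0.95,  0.00,
    "CP5", -0.57, -0.28,   "CP1", -0.20, -0.26,   "CPz",  0.00, -0.25,
    "CP2",  0.20, -0.26,   "CP6",  0.57, -0.28,
    "P3",  -0.36, -0.52,   "Pz",   0.00, -0.50,   "P4",   0.36, -0.52,
    "PO7", -0.57, -0.78,   "PO8",  0.57, -0.78,
    "O1",  -0.31, -0.95,   "O2",   0.31, -0.95
  )
  idx <- seq(1, length(tab), by = 3)
  data.frame(label = tab[idx],
             x = as.numeric(tab[idx + 1]),
             y = as.numeric(tab[idx + 2]),
             stringsAsFactors = FALSE)
}

#' Read / write a montage as YAML or JSON
#'
#' The on-disk form is a map `channels: {label: [x, y]}` with an optional
#' `neighbors: {label: [labels...]}` override; format chosen by file
#' extension (.yaml/.yml or .json).
#'
#' @param path file path.
#' @param montage an `eeg_montage` (for writing).
#' @param ... passed to [eeg_montage()] (adjacency parameters).
#' @return an `eeg_montage` (read) or `path` invisibly (write).
#' @export
read_montage <- function(path, ...) {
  obj <- read_structured(path)
  stopifnot(!is.null(obj$channels))
  labs <- names(obj$channels)
  pos <- data.frame(label = labs,
                    x = vapply(obj$channels, function(p) as.numeric(p[[1]]), 0),
                    y = vapply(obj$channels, function(p) as.numeric(p[[2]]), 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  rownames(pos) <- NULL
  nb <- obj$neighbors
  if (!is.null(nb)) nb <- lapply(nb, function(v) as.character(unlist(v)))
  eeg_montage(pos, neighbors = nb, ...)
}

#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  chans <- stats::setNames(
    lapply(seq_len(nrow(montage$positions)),
           function(i) c(montage$positions$x[i], montage$positions$y[i])),
    montage$positions$label)
  write_structured(list(channels = chans, neighbors = montage$neighbors), path)
}

# Shared YAML/JSON sidecar I/O, dispatched on extension.
read_structured <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::fromJSON(path, simplifyVector = FALSE),
         yaml = ,
         yml = yaml::read_yaml(path),
         stop("unsupported sidecar format: .", ext))
}

write_structured <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                            digits = NA, pretty = TRUE), path),
         yaml = ,
         yml = yaml::write_yaml(obj, path),
         stop("unsupported sidecar format: .", ext))
  invisible(path)
}
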