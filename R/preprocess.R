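# Preprocessing chain: channel QC -> zero-phase Butterworth bandpass ->
# small-Laplacian spatial filter -> per-channel demeaning -> ICA stage.

#' Automated channel quality control
#'
#' Flags channels showing non-physiological behaviour with documented
#' thresholds in place of visual inspection: constant-value runs, amplitude
#' excursions beyond a ceiling, and across-channel variance outliers
#' (z-score of log variance). Flagged channels are reported, never dropped.
#'
#' @param recording an [eeg_recording()].
#' @param max_constant_run longest tolerated run of identical samples.
#' @param amp_limit_uV absolute amplitude ceiling, microvolts.
#' @param var_z z-score threshold on log channel variance.
#' @return a `qc_report`: per-channel logical flags plus a `verdict`
#'   ("clean" iff no channel is flagged).
#' @export
qc_channels <- function(recording, max_constant_run = 125,
                        amp_limit_uV = 500, var_z = 3.5) {
  d <- recording$data
  constant_region <- apply(d, 1L, function(x) {
    r <- rle(x)
    max(r$lengths) > max_constant_run
  })
  extreme_amplitude <- apply(abs(d), 1L, max) > amp_limit_uV
  lv <- log(pmax(apply(d, 1L, stats::var), .Machine$double.xmin))
  s <- stats::sd(lv)
  outlier_variance <- if (isTRUE(s > 0)) abs(lv - mean(lv)) / s > var_z
    else rep(FALSE, nrow(d))
  flags <- data.frame(channel = recording$channel_labels,
                      constant_region = unname(constant_region),
                      extreme_amplitude = unname(extreme_amplitude),
                      outlier_variance = unname(outlier_variance),
                      stringsAsFactors = FALSE)
  flagged <- flags$constant_region | flags$extreme_amplitude |
    flags$outlier_variance
  structure(list(flags = flags,
                 verdict = if (any(flagged)) "flagged" else "clean",
                 thresholds = list(max_constant_run = max_constant_run,
                                   amp_limit_uV = amp_limit_uV,
                                   var_z = var_z)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> verdict:", x$verdict, "\n")
  if (is.null(x$flags)) return(invisible(x))
  bad <- x$flags[x$flags$constant_region | x$flags$extreme_amplitude |
                   x$flags$outlier_variance, ]
  if (nrow(bad)) print(bad, row.names = FALSE)
  invisible(x)
}

#' Zero-phase Butterworth bandpass
#'
#' Designs an order-`order` Butterworth bandpass (defaults 1-40 Hz) and
#' applies it forward-backward per channel (zero phase, squared magnitude
#' response), so band-power estimates are not distorted by filter phase.
#'
#' @param recording an [eeg_recording()].
#' @param fmin,fmax passband edges in Hz.
#' @param order filter order.
#' @return the filtered `eeg_recording`.
#' @export
butterworth_bandpass <- function(recording, fmin = 1, fmax = 40, order = 5) {
  nyq <- recording$sfreq / 2
  if (!(fmin > 0 && fmin < fmax)) stop("need 0 < fmin < fmax")
  if (fmax >= nyq) stop("fmax must be below the Nyquist frequency ", nyq, " Hz")
  bf <- signal::butter(order, c(fmin, fmax) / nyq, type = "pass")
  out <- recording
  for (i in seq_len(n_channels(recording))) {
    out$data[i, ] <- zero_phase_filter(bf$b, bf$a, recording$data[i, ])
  }
  add_stage(out, "butterworth_bandpass",
            list(fmin = fmin, fmax = fmax, order = order))
}

# direct-form IIR pass with zero initial conditions (C-level stats::filter)
iir_pass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1), x), b, method = "convolution",
                     sides = 1)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- stats::filter(v / a[1], -a[-1] / a[1], method = "recursive")
  }
  as.numeric(v)
}

# forward-backward filtering with odd-reflection edge padding (pad length
# 3 * filter length, capped by the signal length)
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1, 3 * max(length(a), length(b)))
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- iir_pass(b, a, c(pre, x, post))
  y <- rev(iir_pass(b, a, rev(y)))
  y[(np + 1):(np + n)]
}

#' Laplacian operator matrix for a montage
#'
#' Returns the dense matrix `L = I - A` where row i of `A` spreads weight
#' `1/N_i` over the `N_i` neighbors of channel i, so `L %*% X` subtracts the
#' neighbor-average potential from every channel simultaneously.
#'
#' @param montage an [eeg_montage()].
#' @param labels channel labels giving row/column order.
#' @return `length(labels)` square matrix.
#' @export
laplacian_matrix <- function(montage, labels) {
  n <- length(labels)
  L <- diag(n)
  dimnames(L) <- list(labels, labels)
  for (ch in labels) {
    nb <- montage$neighbors[[ch]]
    if (is.null(nb)) stop("channel ", ch, " missing from montage adjacency")
    nb <- intersect(nb, labels)
    if (length(nb) == 0) stop("channel ", ch, " has no neighbors in recording")
    L[ch, nb] <- -1 / length(nb)
  }
  L
}

#' Small-Laplacian (Hjorth) spatial filter
#'
#' Per sample, each channel's output is its own potential minus the mean
#' potential of its montage neighbors, computed simultaneously from the
#' input values (a single matrix product, no sequential update). Attenuates
#' volume-conducted common activity.
#'
#' @param recording an [eeg_recording()].
#' @param montage an [eeg_montage()] covering every recording channel.
#' @return the spatially filtered `eeg_recording`.
#' @export
small_laplacian <- function(recording, montage) {
  L <- laplacian_matrix(montage, recording$channel_labels)
  out <- recording
  out$data <- L %*% recording$data
  add_stage(out, "small_laplacian", list())
}

#' Remove each channel's temporal mean
#'
#' @param recording an [eeg_recording()].
#' @return the demeaned `eeg_recording` (every channel mean 0).
#' @export
demean <- function(recording) {
  out <- recording
  out$data <- recording$data - rowMeans(recording$data)
  add_stage(out, "demean", list())
}

#' ICA artifact stage
#'
#' Decomposes the recording into as many independent components as channels
#' (seeded symmetric FastICA, deterministic for a given seed), optionally
#' removes components, and reconstructs. Components can be rejected by
#' explicit index or automatically by absolute correlation of their time
#' course with a supplied artifact reference signal. The default rejects
#' nothing, in which case the reconstruction equals the input up to
#' numerical precision.
#'
#' @param recording a demeaned [eeg_recording()] with many more samples than
#'   channels.
#' @param reject integer component indices to remove, or NULL.
#' @param artifact_ref optional reference time course; components with
#'   `|cor| > cor_threshold` against it are rejected.
#' @param cor_threshold auto-rejection correlation threshold.
#' @param seed RNG seed for the unmixing initialisation.
#' @param maxit,tol FastICA iteration cap and convergence tolerance.
#' @param max_fit_samples the unmixing matrix is estimated on an evenly
#'   decimated subset of at most this many samples (the sources and the
#'   reconstruction always use the full recording).
#' @return an `ica_result`: `mixing` (channels x components), `unmixing`,
#'   `sources` (components x samples), `rejected`, `converged`, and
#'   `recording` (the reconstruction).
#' @export
run_ica <- function(recording, reject = NULL, artifact_ref = NULL,
                    cor_threshold = 0.8, seed = 1L, maxit = 200, tol = 1e-4,
                    max_fit_samples = 40000L) {
  X <- recording$data
  n_c <- nrow(X)
  if (ncol(X) <= n_c * 10) {
    warning("few samples relative to channels; ICA may be unstable")
  }
  dec <- fastica_symmetric(X, seed = seed, maxit = maxit, tol = tol,
                           max_fit_samples = max_fit_samples)
  if (!dec$converged) {
    warning("ICA did not converge within ", maxit,
            " iterations; using last iterate")
  }
  S <- dec$unmixing %*% X
  if (!is.null(artifact_ref)) {
    cors <- abs(apply(S, 1L, stats::cor, y = artifact_ref))
    reject <- union(reject, which(cors > cor_threshold))
  }
  keep <- setdiff(seq_len(n_c), reject)
  recon <- recording
  recon$data <- dec$mixing[, keep, drop = FALSE] %*% S[keep, , drop = FALSE]
  rownames(recon$data) <- recording$channel_labels
  recon <- add_stage(recon, "ica",
                     list(n_components = n_c, rejected = reject,
                          seed = seed, converged = dec$converged))
  structure(list(mixing = dec$mixing, unmixing = dec$unmixing,
                 sources = S, rejected = sort(reject),
                 converged = dec$converged, recording = recon),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> %d components, %d rejected%s\n",
              nrow(x$sources), length(x$rejected),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' QC -> Butterworth bandpass -> small Laplacian -> demean -> ICA, recording
#' each stage in the result's provenance metadata. The ICA stage can be
#' skipped (`ica = FALSE`); with no rejected components it is an identity map
#' of the pipeline, so skipping it changes nothing downstream.
#'
#' @param recording an [eeg_recording()].
#' @param montage an [eeg_montage()].
#' @param fmin,fmax,order bandpass parameters.
#' @param ica run the ICA stage? With an empty rejection list the stage is an
#'   identity map, so disabling it leaves the output unchanged.
#' @param qc run the (report-only) QC stage? It never alters the data.
#' @param reject,artifact_ref,cor_threshold,seed passed to [run_ica()].
#' @param qc_params list of [qc_channels()] threshold overrides.
#' @return the preprocessed `eeg_recording`; the QC report is attached as
#'   `meta$qc`.
#' @export
preprocess <- function(recording, montage, fmin = 1, fmax = 40, order = 5,
                       ica = TRUE, qc = TRUE, reject = NULL,
                       artifact_ref = NULL, cor_threshold = 0.8, seed = 1L,
                       qc_params = list()) {
  qc <- if (qc) do.call(qc_channels, c(list(recording), qc_params)) else
    structure(list(flags = NULL, verdict = "skipped"), class = "qc_report")
  rec <- butterworth_bandpass(recording, fmin = fmin, fmax = fmax,
                              order = order)
  rec <- small_laplacian(rec, montage)
  rec <- demean(rec)
  if (ica) {
    rec <- run_ica(rec, reject = reject, artifact_ref = artifact_ref,
                   cor_threshold = cor_threshold, seed = seed)$recording
  }
  rec$meta$qc <- qc
  rec
}

# Symmetric FastICA with tanh contrast on whitened data. Deterministic for a
# given seed: the rotation is initialised from the seeded RNG, and component
# order and sign are canonicalised (decreasing source variance in the
# original scale... sources are unit-variance after whitening, so order by
# mixing-column norm; sign so each mixing column's largest-magnitude loading
# is positive).
fastica_symmetric <- function(X, seed = 1L, maxit = 200, tol = 1e-4,
                              max_fit_samples = 40000L) {
  n <- nrow(X)
  m <- ncol(X)
  Xc <- X - rowMeans(X)
  C <- Xc %*% t(Xc) / m
  e <- eigen(C, symmetric = TRUE)
  # floor tiny eigenvalues (the Laplacian stage leaves one near-null
  # direction) so whitening stays finite; reconstruction is exact either way
  vals <- pmax(e$values, max(e$values) * 1e-10)
  K <- diag(1 / sqrt(vals)) %*% t(e$vectors)     # whitening
  K_inv <- e$vectors %*% diag(sqrt(vals))
  # rotation estimated on an evenly decimated subset; 40k samples are ample
  # for a 30 x 30 rotation and keep the fixed-point iterations cheap
  step <- max(1L, ceiling(m / max_fit_samples))
  Z <- K %*% Xc[, seq(1L, m, by = step), drop = FALSE]
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_rng))
    assign(".Random.seed", old_rng, envir = globalenv()))
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    g_prime <- rowMeans(1 - G^2)
    W_new <- G %*% t(Z) / ncol(Z) - diag(g_prime) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  unmixing <- W %*% K
  mixing <- K_inv %*% t(W)
  # canonical order and sign for determinism
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  unmixing <- unmixing[ord, , drop = FALSE]
  for (j in seq_len(n)) {
    i <- which.max(abs(mixing[, j]))
    if (mixing[i, j] < 0) {
      mixing[, j] <- -mixing[, j]
      unmixing[j, ] <- -unmixing[j, ]
    }
  }
  list(mixing = mixing, unmixing = unmixing, converged = converged)
}
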