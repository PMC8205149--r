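test_that("QC flags constant regions, amplitude excursions and variance outliers", {
  set.seed(3)
  labs <- default_montage()$positions$label  # 30 channels
  d <- matrix(rnorm(30 * 2000), 30, 2000)
  clean <- qc_channels(eeg_recording(d, labs))
  expect_equal(clean$verdict, "clean")

  d_const <- d; d_const[2, ] <- 0
  r <- qc_channels(eeg_recording(d_const, labs))
  expect_true(r$flags$constant_region[2])
  expect_equal(r$verdict, "flagged")

  # one channel scaled x100 stands out of the cross-channel variance
  # distribution
  d_big <- d; d_big[4, ] <- d_big[4, ] * 100
  r <- qc_channels(eeg_recording(d_big, labs))
  expect_true(r$flags$outlier_variance[4])
  expect_false(any(r$flags$outlier_variance[-4]))

  # a single 600 uV excursion breaches the amplitude ceiling
  d_peak <- d; d_peak[7, 1000] <- 600
  r <- qc_channels(eeg_recording(d_peak, labs))
  expect_true(r$flags$extreme_amplitude[7])
})

test_that("the bandpass keeps 10 Hz, rejects DC and 60 Hz", {
  n <- 5000
  interior <- 500:4500
  labs <- "Cz"
  # DC: attenuation beyond 40 dB
  dc <- butterworth_bandpass(eeg_recording(matrix(1, 1, n), labs))
  expect_lt(max(abs(dc$data[1, interior])), 10^(-40 / 20))
  # mid-band sine passes within 5%
  s10 <- butterworth_bandpass(eeg_recording(
    matrix(sine_wave(10, 20), 1, n), labs))
  expect_equal(max(abs(s10$data[1, interior])), 1, tolerance = 0.05)
  # 60 Hz residual RMS < 5%
  s60 <- butterworth_bandpass(eeg_recording(
    matrix(sine_wave(60, 20), 1, n), labs))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(s60$data[1, interior]) / rms(sine_wave(60, 20)[interior]),
            0.05)
})

test_that("the bandpass is idempotent for mid-band content", {
  n <- 5000
  rec <- eeg_recording(matrix(sine_wave(10, 20), 1, n), "Cz")
  once <- butterworth_bandpass(rec)
  twice <- butterworth_bandpass(once)
  interior <- 500:4500
  a1 <- max(abs(once$data[1, interior]))
  a2 <- max(abs(twice$data[1, interior]))
  expect_lt(abs(a2 - a1) / a1, 0.10)
})

test_that("bandpass validates its frequency arguments", {
  rec <- toy_recording(100)
  expect_error(butterworth_bandpass(rec, fmax = 125), "Nyquist")
  expect_error(butterworth_bandpass(rec, fmin = 0), "fmin")
})

test_that("the Laplacian removes common-mode activity", {
  m <- toy_montage()
  uniform <- eeg_recording(matrix(rep(sin(1:500), each = 5), 5, 500),
                           c("A", "B", "C", "D", "E"))
  out <- small_laplacian(uniform, m)
  expect_lt(max(abs(out$data)), 1e-12)
})

test_that("the Laplacian subtracts the neighbor average", {
  m <- toy_montage()
  # channel A = 2 with neighbors B, C, D, E all equal to 1 -> 2 - 1 = 1
  rec <- eeg_recording(matrix(c(2, 1, 1, 1, 1), 5, 1),
                       c("A", "B", "C", "D", "E"))
  out <- small_laplacian(rec, m)
  expect_equal(unname(out$data["A", 1]), 1)
})

test_that("the Laplacian equals the dense-matrix oracle and is linear", {
  m <- toy_montage()
  labs <- c("A", "B", "C", "D", "E")
  # hand-built operator: identity minus row-normalised adjacency
  A_norm <- rbind(
    c(0, 1 / 4, 1 / 4, 1 / 4, 1 / 4),
    c(1 / 2, 0, 0, 1 / 2, 0),
    c(1 / 2, 0, 0, 0, 1 / 2),
    c(1 / 2, 1 / 2, 0, 0, 0),
    c(1 / 2, 0, 1 / 2, 0, 0))
  L_hand <- diag(5) - A_norm
  set.seed(7)
  X <- matrix(rnorm(5 * 200), 5, 200)
  rec <- eeg_recording(X, labs)
  out <- small_laplacian(rec, m)
  expect_lt(max(abs(out$data - L_hand %*% X)), 1e-12)

  # linearity: L(aX + bY) = a L(X) + b L(Y)
  Y <- matrix(rnorm(5 * 200), 5, 200)
  lhs <- small_laplacian(eeg_recording(3 * X - 2 * Y, labs), m)$data
  rhs <- 3 * out$data -
    2 * small_laplacian(eeg_recording(Y, labs), m)$data
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # missing channel is an error
  rec6 <- eeg_recording(rbind(X, 0), c(labs, "Z"))
  expect_error(small_laplacian(rec6, m), "missing|neighbors")
})

test_that("demeaning zeroes every channel mean and nothing else", {
  rec <- eeg_recording(matrix(c(1, 2, 3), 1, 3), "Cz")
  out <- demean(rec)
  expect_equal(out$data[1, ], c(-1, 0, 1))
  r2 <- toy_recording(400)
  r2$data <- r2$data - rowMeans(r2$data)
  expect_equal(demean(r2)$data, r2$data)
  expect_lt(max(abs(rowMeans(demean(toy_recording(333))$data))), 1e-9)
})

test_that("ICA yields one component per channel and reconstructs exactly", {
  set.seed(10)
  rec <- demean(toy_recording(4000))
  res <- run_ica(rec, seed = 2)
  expect_equal(nrow(res$sources), 5)
  expect_equal(ncol(res$mixing), 5)
  rel <- max(abs(res$recording$data - rec$data)) / max(abs(rec$data))
  expect_lt(rel, 1e-6)
})

test_that("ICA is deterministic under a fixed seed", {
  rec <- demean(toy_recording(3000, seed = 4))
  r1 <- run_ica(rec, seed = 5)
  r2 <- run_ica(rec, seed = 5)
  expect_identical(r1$mixing, r2$mixing)
  expect_identical(r1$recording$data, r2$recording$data)
})

test_that("auto-rejection against an artifact reference cleans Fp1", {
  cfg <- quick_synth_config(seed = 20, noise_scale = 2)
  cfg$artifact$amplitude <- 80
  s <- generate_session(cfg)
  set.seed(2)
  mixed <- inject_artifact(s$recording, cfg)
  pre <- demean(mixed)
  clean_fp1 <- s$recording$data["Fp1", ] -
    mean(s$recording$data["Fp1", ])
  res <- suppressWarnings(
    run_ica(pre, artifact_ref = mixed$meta$artifact_source,
            cor_threshold = 0.6, seed = 3))
  expect_gt(length(res$rejected), 0)
  cor_before <- cor(pre$data["Fp1", ], clean_fp1)
  cor_after <- cor(res$recording$data["Fp1", ], clean_fp1)
  expect_gt(cor_after, cor_before)
})

test_that("the composed preprocessing chain records its stage order", {
  cfg <- quick_synth_config(seed = 21)
  s <- generate_session(cfg)
  pre <- suppressWarnings(preprocess(s$recording, cfg$montage))
  stages <- vapply(pre$meta$stages, `[[`, "", "stage")
  expect_equal(stages, c("butterworth_bandpass", "small_laplacian",
                         "demean", "ica"))
  expect_s3_class(pre$meta$qc, "qc_report")
  expect_lt(max(abs(rowMeans(pre$data))), 1e-6)

  # skipping the report-only QC and identity ICA leaves the data unchanged
  pre2 <- preprocess(s$recording, cfg$montage, ica = FALSE, qc = FALSE)
  expect_equal(pre2$data, demean(small_laplacian(
    butterworth_bandpass(s$recording), cfg$montage))$data)
  expect_equal(max(abs(pre2$data - pre$data)) / max(abs(pre$data)), 0,
               tolerance = 1e-6)
})
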