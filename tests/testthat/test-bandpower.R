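test_that("a pure sine is confined to its own band", {
  x <- sine_wave(11, d = 10)  # inside high alpha [10, 12)
  hi <- band_decompose(x, default_bands()[["high alpha"]], 250)
  lo <- band_decompose(x, default_bands()[["low alpha"]], 250)
  v <- stats::var(x)
  expect_gte(stats::var(as.numeric(hi)) / v, 0.999)
  expect_lte(stats::var(as.numeric(lo)) / v, 0.001)
})

test_that("complementary band masks reconstruct the signal exactly", {
  set.seed(5)
  x <- rnorm(2500)
  x <- x - mean(x)
  parts <- list(band_definition("lo", 1e-9, 8),
                band_definition("mid", 8, 30),
                band_definition("hi", 30, 126))  # over Nyquist end
  recon <- Reduce(`+`, lapply(parts, function(b)
    as.numeric(band_decompose(x, b, 250))))
  expect_lt(max(abs(recon - x)), 1e-9)
})

test_that("two well-separated sines split their variance across bands", {
  x <- sine_wave(5, d = 10) + sine_wave(20, d = 10)
  th <- band_decompose(x, default_bands()$theta, 250)
  lb <- band_decompose(x, default_bands()[["low beta"]], 250)
  expect_equal(mean_power(th), 0.5, tolerance = 1e-9)
  expect_equal(mean_power(lb), 0.5, tolerance = 1e-9)
})

test_that("mean power matches its definition", {
  expect_equal(mean_power(numeric(5)), 0)
  expect_equal(mean_power(sine_wave(10, d = 2, amp = 3)), 9 / 2,
               tolerance = 1e-12)
  set.seed(9)
  x <- rnorm(777)
  acc <- 0
  for (v in x) acc <- acc + v * v  # explicit loop-sum oracle
  expect_equal(mean_power(x), acc / length(x), tolerance = 1e-12)
  expect_error(mean_power(numeric(0)), "empty")
})

test_that("frequency-domain powers equal decompose-then-average exactly", {
  set.seed(13)
  rec <- toy_recording(n = 2000)
  mk <- one_scene_markers(guided_s = 3, break_s = 1, imagery_s = 3)
  segs <- build_segments(mk, 250)
  pt <- segment_power_table(rec, segs, default_bands())
  for (i in sample(nrow(pt), 20)) {
    row <- pt[i, ]
    seg <- segs[segs$scene == row$scene & segs$condition == row$condition, ]
    x <- rec$data[row$electrode, (seg$start_sample + 1):seg$end_sample]
    direct <- mean_power(band_decompose(x, default_bands()[[row$band]], 250))
    expect_equal(row$power_uV2, direct, tolerance = 1e-10)
  }
})

test_that("alpha power is exactly low-alpha plus high-alpha power", {
  set.seed(17)
  rec <- toy_recording(n = 3000)
  segs <- build_segments(one_scene_markers(guided_s = 5, break_s = 1,
                                           imagery_s = 5), 250)
  pt <- segment_power_table(rec, segs, default_bands())
  for (el in rec$channel_labels) {
    for (cond in c("guided", "self_produced")) {
      a <- power_at(pt, el, "alpha", "fitness_activity", cond)
      lo <- power_at(pt, el, "low alpha", "fitness_activity", cond)
      hi <- power_at(pt, el, "high alpha", "fitness_activity", cond)
      expect_equal(a, lo + hi, tolerance = 1e-12)
    }
  }
})

test_that("disjoint primitive band powers never exceed the total", {
  prim <- default_bands()[c("theta", "low alpha", "high alpha", "SMR",
                            "low beta", "high beta")]
  set.seed(19)
  x <- rnorm(2500)
  total <- mean_power(x)
  band_sum <- sum(vapply(prim, function(b)
    mean_power(band_decompose(x, b, 250)), 0))
  expect_lte(band_sum, total + 1e-12)

  # equality when all energy lies inside 4-30 Hz
  y <- sine_wave(6, 10) + sine_wave(13, 10) + sine_wave(25, 10)
  band_sum_y <- sum(vapply(prim, function(b)
    mean_power(band_decompose(y, b, 250)), 0))
  expect_equal(band_sum_y, mean_power(y), tolerance = 1e-9)
})

test_that("band power is invariant to energy outside the band", {
  b <- default_bands()$SMR
  x <- sine_wave(13, 10, amp = 2)
  contaminated <- x + sine_wave(7, 10, amp = 5) + sine_wave(35, 10, amp = 3)
  expect_equal(mean_power(band_decompose(contaminated, b, 250)),
               mean_power(band_decompose(x, b, 250)), tolerance = 1e-9)
})

test_that("the power table covers the full grid and zeros propagate", {
  cfg <- quick_synth_config(seed = 2)
  s <- generate_session(cfg)
  segs <- build_segments(s$markers, 250)
  pt <- segment_power_table(s$recording, segs)
  expect_equal(nrow(pt), 30 * 3 * 2 * 2)  # electrodes x bands x scenes x cond
  expect_true(all(pt$power_uV2 >= 0))
  expect_equal(anyDuplicated(pt[, 1:4]), 0)

  zero <- eeg_recording(matrix(0, 2, 30000), c("Cz", "Pz"))
  ptz <- segment_power_table(zero, build_segments(one_scene_markers(
    guided_s = 40, break_s = 2, imagery_s = 60), 250))
  expect_true(all(ptz$power_uV2 == 0))
  expect_error(segment_power_table(zero, data.frame(
    scene = "x", condition = "guided", start_sample = 0,
    end_sample = 40000)), "past end")
})

test_that("power tables round-trip through CSV", {
  cfg <- quick_synth_config(seed = 3)
  s <- generate_session(cfg)
  pt <- segment_power_table(s$recording, build_segments(s$markers, 250))
  path <- withr::local_tempfile(fileext = ".csv")
  write_power_table(pt, path)
  back <- read_power_table(path)
  expect_equal(back$power_uV2, pt$power_uV2)
  expect_equal(back$electrode, pt$electrode)
})

test_that("the Kaiser periodogram localises and conserves power", {
  x <- sine_wave(10, d = 8)
  psd <- psd_estimate(x, 250)
  expect_equal(psd$freq[which.max(psd$power)], 10)
  # integrated white-noise PSD approximates the variance
  set.seed(23)
  w <- rnorm(5000)
  psd_w <- psd_estimate(w, 250)
  expect_equal(sum(psd_w$power), stats::var(w), tolerance = 0.05)
  # beta = 0 reduces to the plain periodogram
  psd0 <- psd_estimate(x, 250, kaiser_beta = 0)
  X <- stats::fft(x)
  plain <- Mod(X)^2 / length(x)^2
  expect_equal(psd0$power[1], plain[1], tolerance = 1e-12)
  expect_equal(psd0$power[81], plain[81] + plain[length(x) - 79],
               tolerance = 1e-12)  # 10 Hz bin, folded
})
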