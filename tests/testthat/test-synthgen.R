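test_that("generation is deterministic under a fixed seed", {
  s1 <- generate_session(quick_synth_config(seed = 99))
  s2 <- generate_session(quick_synth_config(seed = 99))
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$markers$scenes, s2$markers$scenes)
  s3 <- generate_session(quick_synth_config(seed = 100))
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("silence in, silence out", {
  cfg <- quick_synth_config(seed = 1, noise_scale = 0,
                            band_amplitudes = c("low alpha" = 0))
  s <- generate_session(cfg)
  expect_true(all(s$recording$data == 0))
})

test_that("unknown band names in the config are rejected", {
  expect_error(quick_synth_config(band_amplitudes = c(gamma = 1)), "unknown")
  expect_error(quick_synth_config(
    condition_multipliers = list(ripple = c(guided = 1, self_produced = 1))),
    "unknown")
})

test_that("markers follow the protocol structure", {
  cfg <- synth_config(seed = 4)
  s <- generate_session(cfg)
  sc <- s$markers$scenes
  expect_equal(sc$scene, protocol_scenes())
  expect_true(all(sc$guided_duration_s >= 33 & sc$guided_duration_s <= 47))
  expect_true(all(sc$break_duration_s == 2))
  expect_true(all(sc$imagery_duration_s == 60))
  segs <- build_segments(s$markers, cfg$sfreq)
  expect_lte(max(segs$end_sample), n_samples(s$recording))
})

test_that("noise-free mean powers equal the closed-form ground truth", {
  # pure-oscillator configuration: the expectation A^2/2 is exact
  cfg <- synth_config(seed = 7, noise_scale = 0, modulation_depth = 0)
  s <- generate_session(cfg)
  pt <- segment_power_table(s$recording, build_segments(s$markers, 250))
  chk <- merge(pt, s$ground_truth,
               by.x = c("electrode", "band", "condition"),
               by.y = c("channel", "band", "condition"))
  expect_equal(nrow(chk), nrow(pt))
  expect_lt(max(abs(chk$power_uV2 / chk$expected_power - 1)), 0.01)
})

test_that("a 1.3x amplitude multiplier yields a 1.69x power ratio", {
  cfg <- synth_config(seed = 8, noise_scale = 0)
  s <- generate_session(cfg)
  pt <- segment_power_table(s$recording, build_segments(s$markers, 250))
  la <- pt[pt$band == "low alpha", ]
  ratio <- vapply(split(la, la$electrode), function(d)
    mean(d$power_uV2[d$condition == "self_produced"]) /
      mean(d$power_uV2[d$condition == "guided"]), 0)
  expect_equal(mean(ratio), 1.69, tolerance = 0.05)
})

test_that("doubling an oscillator amplitude quadruples its band power", {
  base <- c("SMR" = 1.5)
  p <- function(amp) {
    cfg <- quick_synth_config(seed = 12, noise_scale = 0,
                              modulation_depth = 0,
                              band_amplitudes = amp,
                              condition_multipliers = list())
    s <- generate_session(cfg)
    pt <- segment_power_table(s$recording, build_segments(s$markers, 250))
    mean(pt$power_uV2[pt$band == "SMR"])
  }
  expect_equal(p(2 * base) / p(base), 4, tolerance = 1e-6)
})

test_that("oscillator variance stays inside its own band", {
  # noise off, default modulation: decompose each band's solo session
  for (b in c("low alpha", "SMR")) {
    amp <- stats::setNames(2, b)
    cfg <- quick_synth_config(seed = 14, noise_scale = 0,
                              band_amplitudes = amp,
                              condition_multipliers = list())
    s <- generate_session(cfg)
    x <- s$recording$data[1, ]
    inband <- mean_power(band_decompose(x, default_bands()[[b]], 250))
    expect_gte(inband / mean_power(x), 0.95)
  }
})

test_that("posterior channels carry boosted alpha but untouched SMR", {
  cfg <- synth_config(seed = 15)
  gt <- generate_session(cfg)$ground_truth
  post <- gt$channel %in% cfg$posterior_channels
  la <- gt$band == "low alpha" & gt$condition == "guided"
  expect_equal(unique(gt$expected_power[la & post]) /
                 unique(gt$expected_power[la & !post]), 4)  # 2^2
  smr <- gt$band == "SMR" & gt$condition == "guided"
  expect_length(unique(gt$expected_power[smr]), 1)
})

test_that("artifact injection touches only the weighted frontal channels", {
  cfg <- quick_synth_config(seed = 16)
  cfg$artifact$amplitude <- 50
  s <- generate_session(cfg)
  set.seed(1)
  mixed <- inject_artifact(s$recording, cfg)
  fp1 <- match("Fp1", mixed$channel_labels)
  pz <- match("Pz", mixed$channel_labels)
  others <- setdiff(seq_len(30), match(c("Fp1", "Fp2"),
                                       mixed$channel_labels))
  expect_identical(mixed$data[others, ], s$recording$data[others, ])
  expect_false(identical(mixed$data[fp1, ], s$recording$data[fp1, ]))
  # the artifact time course is visible frontally, not posteriorly
  src <- mixed$meta$artifact_source
  expect_gt(abs(cor(src, mixed$data[fp1, ])), abs(cor(src, mixed$data[pz, ])))

  # zero amplitude is a no-op on the data
  cfg$artifact$amplitude <- 0
  clean <- inject_artifact(s$recording, cfg)
  expect_identical(clean$data, s$recording$data)
})
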