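test_that("null generator (no components, no noise) is identically zero", {
  cfg <- generator_config(sampling_rate = 200, components = list(),
                          noise_sd = 0)
  s <- generate_session(tiny_design(), cfg, seed = 1)
  expect_true(all(s$recording == 0))
  ep <- generate_epochs(tiny_design(), cfg, seed = 1)
  expect_true(all(ep$data == 0))
})

test_that("identical (design, config, seed) gives bit-identical output", {
  cfg <- generator_config(sampling_rate = 200)
  d <- tiny_design()
  expect_identical(generate_session(d, cfg, seed = 12),
                   generate_session(d, cfg, seed = 12))
  expect_identical(generate_epochs(d, cfg, seed = 12)$data,
                   generate_epochs(d, cfg, seed = 12)$data)
})

test_that("noiseless epoch mean matches the closed-form envelope average", {
  lat <- 450; w <- 60; amp <- 3.5
  comp <- component_spec("P300", lat, width_ms = w, amplitude_mean = amp,
                         amplitude_sd = 0, latency_jitter_sd = 0,
                         topography = topography_gaussian("Pz"),
                         applies_to = "target")
  ep <- planted_epochs(tiny_design(), comp)
  # window centered on the peak: +/- 2 envelope SDs
  win <- c(lat - 2 * w, lat + 2 * w)
  sel <- ep$time_ms >= win[1] & ep$time_ms < win[2]
  # independent closed form: discrete average of the Gaussian envelope
  topo <- topography_gaussian("Pz")
  expected <- amp * topo["Pz"] *
    mean(exp(-(ep$time_ms[sel] - lat)^2 / (2 * w^2)))
  tgt <- which(ep$labels$is_target)[1]
  pz <- match("Pz", ep$channel_labels)
  expect_equal(mean(ep$data[tgt, pz, sel]), unname(expected),
               tolerance = 1e-12)
  # non-target epochs carry no target component
  non <- which(!ep$labels$is_target)[1]
  expect_true(all(ep$data[non, , ] == 0))
})

test_that("background noise has the configured 1/f spectral slope", {
  cfg <- generator_config(sampling_rate = 200, components = list(),
                          noise_sd = 8, noise_1f_exponent = 1)
  d <- tiny_design(n_blocks = 2, n_repetitions = 10)
  s <- generate_session(d, cfg, seed = 31)
  n <- ncol(s$recording)
  freqs <- (seq_len(n) - 1) / n * 200
  sel <- freqs >= 1 & freqs <= 40
  # periodogram averaged over channels
  pgram <- rowMeans(vapply(seq_len(10), function(ch) {
    Mod(stats::fft(s$recording[ch, ]))^2 / n
  }, numeric(n)))
  fitln <- stats::lm(log(pgram[sel]) ~ log(freqs[sel]))
  expect_equal(unname(coef(fitln)[2]), -1, tolerance = 0.2)
})

test_that("epoch averages converge to the template at the 1/sqrt(n) rate", {
  comp <- component_spec("P300", 450, width_ms = 60, amplitude_mean = 4,
                         amplitude_sd = 0, latency_jitter_sd = 0,
                         topography = topography_gaussian("Pz"),
                         applies_to = "target")
  template <- planted_epochs(tiny_design(n_repetitions = 1), comp)
  pz <- match("Pz", template$channel_labels)
  tgt1 <- which(template$labels$is_target)[1]
  tmpl <- template$data[tgt1, pz, ]
  # noisy target-only sessions of growing trial count
  rms <- vapply(c(25, 100, 400), function(n_trials) {
    d <- session_design(n_blocks = 1, n_repetitions = n_trials,
                        names = c("SON", "ON1"))
    cfg <- generator_config(sampling_rate = 200, components = list(comp),
                            noise_sd = 8)
    ep <- generate_epochs(d, cfg, seed = 99)
    avg <- erp_average(ep, "target")
    sqrt(mean((avg[pz, ] - tmpl)^2))
  }, numeric(1))
  expect_true(rms[1] > rms[2])
  expect_true(rms[2] > rms[3])
  # 16x the trials should shrink the error ~4x
  expect_gt(rms[1] / rms[3], 2)
  expect_lt(rms[1] / rms[3], 8)
})

test_that("topography mismatch raises a configuration error", {
  bad <- component_spec("P300", 450, width_ms = 60, amplitude_mean = 4,
                        topography = c(0.5, 0.5), applies_to = "target")
  cfg <- generator_config(sampling_rate = 200, components = list(bad),
                          noise_sd = 0)
  expect_error(generate_epochs(tiny_design(), cfg, seed = 1),
               "topography has length 2")
})

test_that("cohorts are sized, reproducible and piecewise regenerable", {
  designs <- list(session_design(n_blocks = 1, n_repetitions = 2,
                                 mode = "active"),
                  session_design(n_blocks = 1, n_repetitions = 2,
                                 mode = "passive"))
  cfg <- generator_config(sampling_rate = 200)
  ch1 <- generate_cohort(2, designs, cfg, seed = 77)
  expect_length(ch1, 2)
  expect_length(ch1[[1]], 2)
  ch2 <- generate_cohort(2, designs, cfg, seed = 77)
  expect_identical(ch1, ch2)
  expect_error(generate_cohort(0, designs, cfg, seed = 1), ">= 1")
  # single-subject cohort reproduces under the same master seed
  one <- generate_cohort(1, designs[1], cfg, seed = 5)
  expect_identical(one, generate_cohort(1, designs[1], cfg, seed = 5))
})

test_that("per-condition P300 defaults follow the reported group means", {
  conds <- list(c("passive", "3CC", 3.02), c("active", "3CC", 5.40),
                c("passive", "2CC", 1.87), c("active", "2CC", 4.43))
  for (cc in conds) {
    comps <- condition_components(cc[1], cc[2])
    p300 <- comps[[which(vapply(comps, `[[`, "", "label") == "P300")]]
    expect_equal(p300$amplitude_mean, as.numeric(cc[3]))
    expect_identical(p300$applies_to, "target")
  }
  # P300 parietal focus, P200 frontal focus
  comps <- condition_components("active", "3CC")
  p300 <- comps[[1]]; p200 <- comps[[3]]
  expect_gt(p300$topography["Pz"], p300$topography["Fz"])
  expect_gt(p200$topography["Fz"], p200$topography["Pz"])
})
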