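test_that("band-pass filter rejects DC, keeps 10 Hz, attenuates 60 Hz", {
  fs <- 1000
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  interior <- (5 * fs):(15 * fs)  # away from edge transients
  # DC: constant 5 uV -> ~0
  dc <- bandpass_filter(rep(5, n), sampling_rate = fs)
  expect_lt(max(abs(dc[interior])), 0.1)
  # 10 Hz tone inside the passband: amplitude preserved within 5%
  tone10 <- bandpass_filter(sin(2 * pi * 10 * t), sampling_rate = fs)
  amp10 <- sqrt(2 * mean(tone10[interior]^2))
  expect_equal(amp10, 1, tolerance = 0.05)
  # 60 Hz tone in the stopband: attenuated by >= 20 dB
  tone60 <- bandpass_filter(sin(2 * pi * 60 * t), sampling_rate = fs)
  amp60 <- sqrt(2 * mean(tone60[interior]^2))
  expect_lt(20 * log10(amp60 / 1), -20)
})

test_that("filter band edges are validated", {
  expect_error(bandpass_filter(rnorm(100), low = 0, sampling_rate = 100),
               "Nyquist")
  expect_error(bandpass_filter(rnorm(100), low = 10, high = 60,
                               sampling_rate = 100), "Nyquist")
})

test_that("decimation keeps lengths, low tones, and drops high tones", {
  fs <- 1000
  n <- 10 * fs
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 30 * t) + sin(2 * pi * 150 * t)
  y <- downsample(x, 200, sampling_rate = fs)
  expect_length(y, 2000)
  interior <- 500:1500
  td <- (seq_along(y) - 1) / 200
  # 30 Hz survives
  a30 <- 2 * abs(mean(y[interior] * exp(-2i * pi * 30 * td[interior])))
  expect_equal(a30, 1, tolerance = 0.05)
  # 150 Hz (above the new Nyquist) is gone rather than aliased to 50 Hz
  a50 <- 2 * abs(mean(y[interior] * exp(-2i * pi * 50 * td[interior])))
  expect_lt(a50, 0.05)
  # same-rate decimation is the identity; upsampling is refused
  expect_identical(downsample(x, 1000, sampling_rate = fs), x)
  expect_error(downsample(x, 2000, sampling_rate = fs), "upsampling")
})

test_that("epoching slices the recording at event onsets", {
  fs <- 200
  rec <- matrix(rnorm(2 * 30 * fs), nrow = 2)
  rownames(rec) <- c("Fz", "Pz")
  events <- data.frame(onset_ms = c(5000, 8000, 12000),
                       name_id = c("SON", "ON1", "SON"),
                       is_target = c(TRUE, FALSE, TRUE),
                       block = 0L, repetition = 0:2)
  ep <- epoch_data(rec, events, sampling_rate = fs)
  expect_s3_class(ep, "aerp_epochs")
  expect_equal(dim(ep$data), c(3, 2, 200))
  expect_equal(ep$time_ms[1], -200)
  expect_equal(ep$time_ms[200], 795)
  # epoch 2 must equal the raw slice around 8000 ms
  i0 <- round(8000 / 1000 * fs) + 1 - 40
  expect_equal(ep$data[2, , ], rec[, i0:(i0 + 199)], ignore_attr = TRUE)
  expect_identical(ep$labels$name_id, events$name_id)
})

test_that("events at the recording edge are dropped with a warning", {
  rec <- matrix(0, 1, 600)
  events <- data.frame(onset_ms = c(0, 1500), name_id = c("SON", "ON1"),
                       is_target = c(TRUE, FALSE), block = 0L,
                       repetition = 0:1)
  expect_warning(ep <- epoch_data(rec, events, sampling_rate = 200),
                 "dropped")
  expect_equal(dim(ep$data)[1], 1)
  expect_identical(ep$labels$name_id, "ON1")
})

test_that("baseline correction zeroes the pre-stimulus mean exactly", {
  ep <- planted_epochs(tiny_design(), noise_sd = 5,
                       component = component_spec(
                         "P300", 450, 60, 4, topography = rep(0.5, 60),
                         applies_to = "target"))
  bc <- baseline_correct(ep)
  sel <- bc$time_ms >= -200 & bc$time_ms < 0
  bl <- apply(bc$data[, , sel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # constant-offset epoch becomes all-zero
  const <- make_epochs(array(7, dim = c(2, 1, 200)))
  expect_true(all(abs(baseline_correct(const)$data) < 1e-12))
  # linear trend: post-stimulus values shift by the analytic baseline mean
  n_t <- 200
  tms <- -200 + (seq_len(n_t) - 1) * 5
  tr <- make_epochs(array(rep(0.01 * tms, each = 2), dim = c(2, 1, n_t)))
  trc <- baseline_correct(tr)
  base_mean <- mean(0.01 * tms[tms >= -200 & tms < 0])
  expect_equal(trc$data[1, 1, ], 0.01 * tms - base_mean, tolerance = 1e-12)
})

test_that("amplitude rejection flags exactly the planted epochs", {
  set.seed(4)
  dat <- array(rnorm(50 * 3 * 100, sd = 10), dim = c(50, 3, 100))
  planted <- sort(sample(50, 5))
  for (i in planted) dat[i, sample(3, 1), sample(100, 1)] <- 150
  dat[abs(dat) > 100 & !(slice.index(dat, 1) %in% planted)] <- 99  # cap others
  ep <- make_epochs(dat)
  rej <- reject_amplitude(ep, 100)
  expect_identical(which(rej$rejected), planted)
  # all-quiet data: zero rejections
  quiet <- make_epochs(array(rnorm(10 * 2 * 50, sd = 5), dim = c(10, 2, 50)))
  expect_equal(sum(reject_amplitude(quiet, 100)$rejected), 0)
  expect_error(reject_amplitude(quiet, 0), "positive")
  # one epoch with a single +150 uV sample -> exactly that epoch
  one <- array(0, dim = c(4, 2, 50)); one[3, 2, 25] <- 150
  expect_identical(which(reject_amplitude(make_epochs(one), 100)$rejected), 3L)
})

test_that("artifact component removal is a no-op without an ocular source", {
  set.seed(11)
  n <- 4000
  clean <- matrix(rnorm(4 * n), 4)
  rownames(clean) <- c("Fp1", "Fp2", "Cz", "Pz")
  # threshold 1.0 can never be exceeded -> guaranteed identity
  out <- remove_artifact_components(clean, "Fp1", threshold = 1.0, seed = 2)
  expect_equal(unname(attr(out, "removed_components")), 0)
  expect_equal(out[, ], clean[, ], tolerance = 1e-12)
  expect_error(remove_artifact_components(clean, "EOGv"), "not found")
})

test_that("a planted blink source is removed from frontal channels", {
  set.seed(21)
  n <- 8000
  src <- matrix(rnorm(3 * n), 3)             # neural background
  blink <- numeric(n)
  starts <- seq(400, n - 400, by = 800)
  for (s in starts) blink[s:(s + 80)] <- 60 * sin(pi * (0:80) / 80)
  mix <- rbind(c(1.0, 0.1, 0.2, 0.05),      # blink loads frontally
               c(0.9, 0.2, 0.1, 0.1),
               c(0.2, 1.0, 0.3, 0.2),
               c(0.05, 0.3, 1.0, 0.4))
  clean_rec <- mix[, -1] %*% src
  rec <- clean_rec + mix[, 1, drop = FALSE] %*% t(blink)
  rownames(rec) <- rownames(clean_rec) <- c("Fp1", "Fp2", "Cz", "Pz")
  out <- remove_artifact_components(rec, c("Fp1", "Fp2"), threshold = 0.8,
                                    seed = 3)
  expect_gte(attr(out, "removed_components"), 1)
  # frontal variance drops toward the blink-free reference
  v_before <- var(rec["Fp1", ])
  v_after <- var(out["Fp1", ])
  v_ref <- var(clean_rec["Fp1", ])
  expect_lt(v_after, 0.5 * v_before)
  expect_lt(abs(v_after - v_ref), 0.5 * v_ref)
})

test_that("the full chain preserves a planted component through filtering", {
  comp <- component_spec("P300", 450, width_ms = 60, amplitude_mean = 6,
                         amplitude_sd = 0, latency_jitter_sd = 0,
                         topography = topography_gaussian("Pz"),
                         applies_to = "target")
  d <- tiny_design(n_repetitions = 3)
  cfg <- generator_config(sampling_rate = 1000, components = list(comp),
                          noise_sd = 0)
  s <- generate_session(d, cfg, seed = 6)
  ep <- preprocess(s)
  expect_equal(dim(ep$data), c(15, 60, 200))
  avg <- erp_average(ep, "target")
  m <- measure_window(avg, "Pz", c(300, 600), ep$time_ms)
  # the 0.5-40 Hz filter barely touches a 60 ms-wide component
  expect_equal(m$peak_latency_ms, 450, tolerance = 15)
  expect_equal(m$peak_amplitude, 6 * topography_gaussian("Pz")[["Pz"]],
               tolerance = 0.4)
})
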