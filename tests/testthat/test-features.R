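test_that("selection score adds channel mean and channel max of |r2|", {
  tms <- seq(100, 295, by = 5)
  v <- matrix(0.2, nrow = 3, ncol = length(tms))
  v[, 10] <- c(0.1, 0.2, 0.6)
  map <- make_map(v, tms)
  w <- constraint_window("T1", 100, 300)
  sc <- score_trace(map, w)
  expect_equal(unname(sc[10]), mean(c(0.1, 0.2, 0.6)) + 0.6)  # 0.3 + 0.6
  expect_equal(unname(sc[1]), 0.2 + 0.2)
  # single channel: score = 2 |r2|
  map1 <- make_map(v[3, , drop = FALSE], tms)
  expect_equal(unname(score_trace(map1, w)), 2 * abs(v[3, ]))
  # all-zero map: score identically 0
  expect_true(all(score_trace(make_map(v * 0, tms), w) == 0))
  # signs do not matter: magnitudes are aggregated
  expect_equal(score_trace(make_map(-v, tms), w), sc)
  expect_error(score_trace(map, constraint_window("T2", 400, 600)),
               "overlap")
})

test_that("adjacent-time correlation is the plain cosine of trial vectors", {
  dat <- array(0, dim = c(3, 1, 2))
  dat[, 1, 1] <- c(1, 0, 1)
  dat[, 1, 2] <- c(1, 1, 0)
  ep <- make_epochs(dat)
  expect_equal(adjacent_correlation(ep, 1, -200, -195), 0.5)
  # collinear vectors -> 1 regardless of scale
  dat[, 1, 2] <- 2 * dat[, 1, 1]
  expect_equal(adjacent_correlation(make_epochs(dat), 1, -200, -195), 1)
  # orthogonal vectors -> 0
  dat[, 1, 1] <- c(1, 0, 0); dat[, 1, 2] <- c(0, 1, 0)
  expect_equal(adjacent_correlation(make_epochs(dat), 1, -200, -195), 0)
  # zero-norm vector -> flagged missing
  dat[, 1, 1] <- 0
  expect_true(is.na(adjacent_correlation(make_epochs(dat), 1, -200, -195)))
  expect_error(adjacent_correlation(ep, "nope", -200, -195), "channel")
  expect_error(adjacent_correlation(ep, 1, -200, 12.3), "time point")
})

test_that("range selection recovers a smooth unimodal plateau", {
  # strong smooth component: adjacent correlations ~1, score unimodal
  comp <- component_spec("P300", 450, width_ms = 60, amplitude_mean = 8,
                         amplitude_sd = 1, latency_jitter_sd = 10,
                         topography = topography_gaussian("Pz"),
                         applies_to = "target")
  d <- session_design(n_blocks = 2, n_repetitions = 10)
  cfg <- generator_config(sampling_rate = 200, components = list(comp),
                          noise_sd = 4)
  ep <- baseline_correct(generate_epochs(d, cfg, seed = 23))
  map <- r2_map(ep)
  w2 <- constraint_window("T2", 300, 600)
  r <- select_range(map, ep, w2)
  expect_s3_class(r, "aerp_range")
  expect_false(r$fallback)
  # contiguous, inside the window, contains the peak and the plateau
  expect_true(all(diff(r$times_ms) == 5))
  expect_gte(r$t_start_ms, 300)
  expect_lt(r$t_end_ms, 600)
  expect_true(450 >= r$t_start_ms && 450 <= r$t_end_ms)
  # exactly the super-half-maximum points connected to the peak
  sc <- r$score_trace
  expect_true(all(sc[names(sc) %in% format(r$times_ms, trim = TRUE)] >
                    0.5 * max(sc)))
})

test_that("independent noise degenerates to single-point ranges", {
  set.seed(12)
  dat <- array(rnorm(60 * 2 * 100), dim = c(60, 2, 100))
  ep <- make_epochs(dat)
  map <- r2_map(ep)
  w <- constraint_window("T1", 100, 300)
  r <- select_range(map, ep, w)
  # unsmoothed white noise: adjacent cosine ~0 < 0.7, so no links form
  expect_lte(length(r$times_ms), 2)
})

test_that("planted peaks are recovered across seeds", {
  comp <- component_spec("P300", 450, width_ms = 60, amplitude_mean = 5.4,
                         amplitude_sd = 2, latency_jitter_sd = 25,
                         topography = topography_gaussian("Pz"),
                         applies_to = "target")
  d <- session_design(n_blocks = 2, n_repetitions = 10)
  cfg <- generator_config(sampling_rate = 200, components = list(comp),
                          noise_sd = 8)
  hits <- vapply(1:10, function(s) {
    ep <- baseline_correct(generate_epochs(d, cfg, seed = s))
    map <- r2_map(ep)
    r <- select_range(map, ep, constraint_window("T2", 300, 600))
    450 >= r$t_start_ms && 450 <= r$t_end_ms
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("feature extraction averages the selected range per channel", {
  # constant epochs: every feature equals the constant
  dat <- array(3.25, dim = c(4, 2, 100))
  ep <- make_epochs(dat)
  r <- structure(list(window_label = "T1", t_start_ms = -100,
                      t_end_ms = -50,
                      times_ms = ep$time_ms[ep$time_ms >= -100 &
                                              ep$time_ms <= -50],
                      score_trace = numeric(0),
                      correlation_trace = numeric(0), fallback = FALSE),
                 class = "aerp_range")
  fe <- extract_features(ep, list(r))
  expect_equal(dim(fe$x), c(4, 2))
  expect_true(all(fe$x == 3.25))
  expect_identical(fe$y, ifelse(ep$labels$is_target, 1L, -1L))
  # noiseless planted component: feature equals the envelope mean over t_r
  lat <- 450; wdt <- 60; amp <- 5
  ep2 <- planted_epochs(tiny_design(), component_spec(
    "P300", lat, wdt, amp, amplitude_sd = 0, latency_jitter_sd = 0,
    topography = topography_gaussian("Pz"), applies_to = "target"))
  ep2 <- baseline_correct(ep2)
  map <- r2_map(ep2)
  rng <- select_range(map, ep2, constraint_window("T2", 300, 600))
  fe2 <- extract_features(ep2, list(rng))
  pz_col <- paste0("T2.", "Pz")
  # baseline is flat zero here, so the closed form needs no correction
  expected <- amp * topography_gaussian("Pz")[["Pz"]] *
    mean(exp(-(rng$times_ms - lat)^2 / (2 * wdt^2)))
  tgt_rows <- fe2$name_id == "SON"
  expect_equal(unname(fe2$x[tgt_rows, pz_col]),
               rep(expected, sum(tgt_rows)), tolerance = 1e-10)
})

test_that("feature matrix bookkeeping matches surviving epochs", {
  set.seed(3)
  ep <- planted_epochs(tiny_design(n_repetitions = 4), noise_sd = 6)
  ep <- baseline_correct(ep)
  ep$rejected[c(2, 9)] <- TRUE
  map <- r2_map(ep)
  ranges <- lapply(default_windows(), function(w) select_range(map, ep, w))
  fe <- extract_features(ep, ranges)
  expect_equal(ncol(fe$x), 2 * 60)
  expect_equal(nrow(fe$x), sum(!ep$rejected))
  expect_equal(sum(fe$y == 1),
               sum(ep$labels$is_target & !ep$rejected))
  expect_equal(sum(fe$y == -1),
               sum(!ep$labels$is_target & !ep$rejected))
  # delimited round trip of the two-level header
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fe, path)
  hdr <- readLines(path, n = 2)
  expect_match(hdr[1], "^T1\t")
  expect_match(hdr[2], "label$")
})
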