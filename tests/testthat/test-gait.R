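test_that("heel strikes are detected within one frame on synthetic gait", {
  truth <- fx_model()
  proto <- redundant_marker_set(truth)
  tr <- generate_trial(truth, proto, gait_trajectory_config(n_strides = 3),
                       noise_config(white_sigma = 0.3, seed = 31))
  pelv <- rowMeans(tr$markers$positions[, c("LASI", "RASI", "LPSI", "RPSI"), 1])
  ev <- detect_heel_strikes(tr$markers$positions[, "RHEE", 1], pelv,
                            tr$markers$times)
  expect_identical(ev$source, "detected")
  # away from the data edges (where the boundary strike's flat peak sits),
  # detections match the generator's strike times one-for-one
  tmax <- max(tr$markers$times)
  interior <- tr$truth_events$times[tr$truth_events$times > 0.2 &
                                      tr$truth_events$times < tmax - 0.2]
  found <- ev$times[ev$times > 0.2 & ev$times < tmax - 0.2]
  expect_length(found, length(interior))
  expect_lt(max(abs(found - interior)), 0.010 + 1e-9)  # 1 frame @ 100 Hz
  # every detection sits within 2 frames of some true strike
  expect_lt(max(vapply(ev$times, function(t0)
    min(abs(t0 - tr$truth_events$times)), numeric(1))), 0.020 + 1e-9)
})

test_that("a stationary heel yields no events, annotations pass through", {
  n <- 200
  expect_warning(
    ev <- detect_heel_strikes(rep(100, n), rep(0, n), seq_len(n) / 100),
    "no heel-strike")
  expect_length(ev$times, 0)
  ann <- detect_heel_strikes(NULL, NULL, NULL, events = c(2.2, 1.1))
  expect_identical(ann$source, "annotated")
  expect_identical(ann$times, c(1.1, 2.2))
})

test_that("time normalization returns exactly 101 points and reproduces simple signals", {
  tt <- seq(0, 1.1, by = 0.01)
  ser <- data.frame(time = tt, const = rep(12.5, length(tt)),
                    ramp = 10 * tt / 1.1)
  norm <- time_normalize(ser, c(0, 1.1))
  expect_identical(nrow(norm), 101L)
  expect_equal(norm$const, rep(12.5, 101))
  expect_equal(norm$ramp, 0.1 * (0:100), tolerance = 1e-9)
  # endpoints interpolate the data at the event times
  ser$sine <- sin(2 * pi * tt / 1.1)
  norm2 <- time_normalize(ser, c(0.11, 0.99), angles = "sine")
  expect_equal(norm2$sine[1], sin(2 * pi * 0.11 / 1.1), tolerance = 1e-6)
  expect_equal(norm2$sine[101], sin(2 * pi * 0.99 / 1.1), tolerance = 1e-6)
})

test_that("cycles outside the data or too short are rejected", {
  ser <- data.frame(time = seq(0, 1, by = 0.01), a = 0)
  expect_error(time_normalize(ser, c(0.5, 1.5)), "outside")
  expect_error(time_normalize(ser, c(0.50, 0.52)), "4 frames")
  expect_error(time_normalize(ser, c(0.6, 0.4)), "t_end")
})

test_that("kinematic variables match closed forms and a brute-force scan", {
  k <- 0:100
  sine <- 5 + 15 * sin(2 * pi * k / 100)
  v <- extract_variables(sine)
  expect_equal(v$rom, 30)
  expect_equal(v$peak_max, 20)
  expect_equal(v$peak_min, -10)
  expect_equal(v$initial_angle, 5)
  vc <- extract_variables(rep(7.25, 101))
  expect_equal(unlist(vc), c(initial_angle = 7.25, peak_max = 7.25,
                             peak_min = 7.25, rom = 0))
  # knee-flexion-like template vs exhaustive scan
  set.seed(32)
  templ <- 30 - 25 * cos(2 * pi * k / 100) + 6 * sin(4 * pi * k / 100) +
    rnorm(101, 0, 0.5)
  v2 <- extract_variables(templ)
  expect_identical(v2$peak_max, max(templ))
  expect_identical(v2$peak_min, min(templ))
  expect_identical(v2$initial_angle, templ[1])
  expect_error(extract_variables(c(templ[-101], NA)), "non-finite")
  expect_error(extract_variables(templ[-1]), "101")
})

test_that("MAV matches its definition and basic algebra", {
  expect_equal(mav(rbind(rep(5, 101), rep(7, 101))), 2)
  expect_equal(mav(rbind(rep(3, 101))), 0)
  set.seed(33)
  curves <- matrix(rnorm(3 * 101), 3)
  expect_equal(mav(curves),
               mean(vapply(1:101, function(j) max(curves[, j]) - min(curves[, j]),
                           numeric(1))))
  # shift invariance and linear scaling
  expect_equal(mav(curves + 100), mav(curves))
  expect_equal(mav(curves * 3), 3 * mav(curves))
  expect_gte(mav(curves), 0)
  expect_error(mav(list(rnorm(101), rnorm(100))), "unequal")
})

test_that("variable extraction commutes with adding a constant", {
  set.seed(34)
  curve <- cumsum(rnorm(101))
  v0 <- extract_variables(curve)
  v1 <- extract_variables(curve + 12)
  expect_equal(v1$rom, v0$rom)
  expect_equal(v1$peak_max, v0$peak_max + 12)
  expect_equal(v1$initial_angle, v0$initial_angle + 12)
})
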