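test_that("noiseless standing trial recovers lengths and static pose", {
  truth <- build_model(c(pelvic_width = 250, thigh_L = 400, thigh_R = 420,
                         shank_L = 390, shank_R = 405, foot_L = 245,
                         foot_R = 255))
  st <- generate_standing(truth, redundant_marker_set(truth),
                          white_sigma = 0, n_frames = 5)
  fit <- estimate_scaling(st, redundant_marker_set(), build_model())
  expect_lt(abs(fit$model$lengths[["thigh_R"]] - 420), 1)
  expect_lt(max(abs(fit$model$lengths - truth$lengths)), 1)
  expect_lt(max(abs(fit$q0[4:22])), 0.1)   # true q0 = 0
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("a nonzero standing pose is recovered jointly with the lengths", {
  truth <- build_model()
  q0 <- rep(0, 22); q0[4] <- 6; q0[7] <- -4; q0[10] <- 8; q0[13] <- -3
  st <- generate_standing(truth, redundant_marker_set(truth),
                          white_sigma = 0, n_frames = 3, q0 = q0)
  fit <- estimate_scaling(st, redundant_marker_set(), build_model())
  expect_lt(max(abs(fit$q0[4:22] - q0[4:22])), 0.1)
  expect_lt(max(abs(fit$model$lengths - truth$lengths)), 1)
})

test_that("lengths are recovered within 5 mm under 2 mm standing noise", {
  truth <- build_model(c(pelvic_width = 250, thigh_L = 400, thigh_R = 420,
                         shank_L = 390, shank_R = 405, foot_L = 245,
                         foot_R = 255))
  proto <- redundant_marker_set(truth)
  nominal <- build_model()
  worst <- 0
  for (s in 1:20) {
    st <- generate_standing(truth, proto, white_sigma = 2, n_frames = 20,
                            seed = 500 + s)
    fit <- estimate_scaling(st, redundant_marker_set(nominal), nominal)
    worst <- max(worst, max(abs(fit$model$lengths - truth$lengths)))
  }
  expect_lt(worst, 5)
})

test_that("offsets nullify the standing residual by construction", {
  cal <- fx_cal_R()
  truth <- fx_model()
  st_mean <- predict_markers(truth, redundant_marker_set(truth)$markers,
                             rep(0, 22))
  pred <- predict_markers(cal$model, cal$attachments, cal$q0)
  expect_lt(max(abs(pred - st_mean[rownames(pred), ])), 1e-9)
})

test_that("a displaced marker shifts its offset by the same vector", {
  truth <- fx_model()
  proto <- redundant_marker_set(truth)
  st_mean <- predict_markers(truth, proto$markers, rep(0, 22))
  st_shift <- st_mean
  st_shift["RTHI", ] <- st_shift["RTHI", ] + c(10, 0, 0)  # +10 mm anterior
  att0 <- compute_offsets(truth, rep(0, 22), st_mean, proto)
  att1 <- compute_offsets(truth, rep(0, 22), st_shift, proto)
  i <- att0$name == "RTHI"
  expect_equal(unlist(att1[i, c("ox", "oy", "oz")]) -
                 unlist(att0[i, c("ox", "oy", "oz")]),
               c(ox = 10, oy = 0, oz = 0), tolerance = 1e-12)
  expect_identical(att1[!i, ], att0[!i, ])
})

test_that("plugin reduction of a redundant calibration keeps offsets bit-identical", {
  cal_R <- fx_cal_R()
  cal_P <- fx_cal_P()
  shared <- cal_R$attachments[cal_R$attachments$name %in% plugin_marker_names(), ]
  rownames(shared) <- rownames(cal_P$attachments) <- NULL
  expect_identical(cal_P$attachments, shared)
  expect_identical(cal_P$model$lengths, cal_R$model$lengths)
  expect_identical(cal_P$q0, cal_R$q0)
})

test_that("degenerate or empty standing input is rejected", {
  proto <- redundant_marker_set()
  expect_error(calibrate(matrix(numeric(0), 0, 3), proto), "empty")
  # marker missing from the standing data
  st_mean <- predict_markers(fx_model(), proto$markers, rep(0, 22))
  expect_error(calibrate(st_mean[-1, ], proto), "LASI")
})

test_that("calibrated model round-trips through YAML", {
  cal <- fx_cal_R()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_calibrated_model(cal, f)
  back <- read_calibrated_model(f)
  expect_equal(back$model$lengths, cal$model$lengths, tolerance = 1e-9)
  expect_equal(back$q0, cal$q0, tolerance = 1e-9)
  expect_equal(back$attachments$ox, cal$attachments$ox, tolerance = 1e-9)
  expect_identical(back$protocol_name, "redundant")
})
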