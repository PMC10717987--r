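test_that("FK -> IK round trip recovers the pose from a cold start", {
  cal <- fx_cal_R()
  set.seed(21)
  for (rep in 1:20) {
    q <- c(runif(3, -300, 300), runif(19, -60, 60))
    mk <- predict_markers(cal$model, cal$attachments, q)
    r <- solve_frame(cal, mk, q_init = rep(0, 22))
    expect_lt(max(abs(r$q[4:22] - q[4:22])), 1e-4)
    expect_lt(max(abs(r$q[1:3] - q[1:3])), 1e-4)
    expect_lt(r$residual_rms, 1e-6)
    expect_true(r$converged)
  }
})

test_that("occluded thigh markers do not hurt the redundant solve", {
  cal <- fx_cal_R()
  q <- rep(0, 22); q[7] <- 25; q[10] <- 40; q[13] <- -10
  mk <- predict_markers(cal$model, cal$attachments, q)
  mk[c("LTHI", "LTHI_A"), ] <- NA
  r <- solve_frame(cal, mk, q_init = rep(0, 22))
  expect_lt(max(abs(r$q - q)), 0.1)
  expect_identical(r$n_markers_used, 36L)
})

test_that("occluding all pelvis markers makes the plugin pose underdetermined", {
  cal <- fx_cal_P()
  mk <- predict_markers(cal$model, cal$attachments, rep(0, 22))
  mk[c("LASI", "RASI", "LPSI", "RPSI"), ] <- NA
  expect_error(solve_frame(cal, mk, rep(0, 22), ik_config(min_markers = 10)),
               "underdetermined")
})

test_that("losing every femur marker leaves a free thigh-rotation gauge", {
  cal <- fx_cal_P()
  mk <- predict_markers(cal$model, cal$attachments, rep(0, 22))
  mk[c("RTHI", "RKNE"), ] <- NA
  expect_error(solve_frame(cal, mk, rep(0, 22), ik_config(min_markers = 10)),
               "underdetermined")
})

test_that("solution is invariant to rescaling all marker weights", {
  cal <- fx_cal_R()
  set.seed(22)
  q <- c(runif(3, -100, 100), runif(19, -30, 30))
  mk <- predict_markers(cal$model, cal$attachments, q)
  mk <- mk + matrix(rnorm(length(mk), 0, 2), nrow(mk))  # noise so argmin nontrivial
  r1 <- solve_frame(cal, mk, rep(0, 22), ik_config(weights = 1))
  r7 <- solve_frame(cal, mk, rep(0, 22), ik_config(weights = 7))
  expect_equal(r1$q, r7$q, tolerance = 1e-6)
})

test_that("reported cost at the solution never exceeds the cost at the start", {
  cal <- fx_cal_R()
  cost <- function(q, mk) sum((predict_markers(cal$model, cal$attachments, q) - mk)^2)
  set.seed(23)
  for (rep in 1:5) {
    q <- c(runif(3, -100, 100), runif(19, -40, 40))
    mk <- predict_markers(cal$model, cal$attachments, q) +
      matrix(rnorm(38 * 3, 0, 3), 38)
    q_init <- rep(0, 22)
    r <- solve_frame(cal, mk, q_init)
    expect_lte(cost(r$q, mk), cost(q_init, mk))
  }
})

test_that("noiseless walking trial is recovered frame-by-frame", {
  truth <- fx_model()
  proto <- redundant_marker_set(truth)
  tr <- generate_trial(truth, proto,
                       gait_trajectory_config(n_strides = 2, sample_rate = 50))
  cal_R <- fx_cal_R()
  sol_R <- solve_trajectory(cal_R, tr$markers)
  err_R <- max(abs(solved_angle_matrix(sol_R) - truth_angle_matrix(tr)))
  expect_lt(err_R, 0.01)
  # plugin arm on the identical (reduced) data agrees with the redundant arm
  sol_P <- solve_trajectory(fx_cal_P(), reduce_to_plugin(tr$markers))
  expect_lt(max(abs(solved_angle_matrix(sol_P) - solved_angle_matrix(sol_R))),
            0.05)
  expect_true(all(sol_R$converged))
  expect_true(all(sol_R$n_markers == 38))
})

test_that("an occlusion window is handled mid-trajectory", {
  truth <- fx_model()
  proto <- redundant_marker_set(truth)
  tr <- generate_trial(truth, proto,
                       gait_trajectory_config(n_strides = 1, sample_rate = 50),
                       noise_config(occlusion = list(
                         list(marker = "LTHI", frames = 10:20),
                         list(marker = "RKNE", frames = 15:25))))
  sol <- solve_trajectory(fx_cal_R(), tr$markers)
  expect_lt(max(abs(solved_angle_matrix(sol) - truth_angle_matrix(tr))), 0.01)
  expect_identical(sort(unique(sol$n_markers)), c(36L, 37L, 38L))
})

test_that("empty trials and tiny marker counts are rejected", {
  cal <- fx_cal_R()
  mk <- predict_markers(cal$model, cal$attachments, rep(0, 22))
  mk[6:38, ] <- NA
  expect_error(solve_frame(cal, mk, rep(0, 22)), "visible markers")
  expect_error(ik_config(weights = -1), "nonnegative")
})
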