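test_that("model construction gives the 9-segment, 22-DOF tree", {
  m <- build_model()
  expect_s3_class(m, "gait_model")
  expect_identical(n_dof(m), 22L)
  expect_length(m$segments, 9)
  # tree rooted at pelvis: every non-root has exactly one existing parent
  parents <- vapply(m$segments, function(s) s$parent, character(1))
  expect_identical(sum(is.na(parents)), 1L)
  expect_true(all(parents[!is.na(parents)] %in% names(m$segments)))
  # 8 joints besides the pelvis free joint
  expect_identical(sum(!is.na(parents)), 8L)
  expect_length(pose_names(), 22)
})

test_that("non-positive or missing lengths are rejected", {
  bad <- default_lengths(); bad["thigh_L"] <- 0
  expect_error(build_model(bad), "positive")
  expect_error(build_model(c(pelvic_width = 240)), "missing")
})

test_that("zero pose is the anatomical reference configuration", {
  m <- build_model()
  poses <- segment_poses(m, rep(0, 22))
  for (p in poses) expect_equal(p$R, diag(3))
  expect_equal(poses$pelvis$t, c(0, 0, 0))
  expect_equal(poses$femur_R$t, c(0, -120, 0))
  expect_equal(poses$shank_R$t, c(0, -120, -410))
  expect_equal(poses$talus_L$t, c(0, 120, -810))
  expect_equal(poses$foot_L$t, c(0, 120, -820))
})

test_that("pelvis translation rigidly shifts every segment", {
  m <- build_model()
  q <- rep(0, 22); q[1:3] <- c(10, -5, 2)
  p0 <- segment_poses(m, rep(0, 22))
  p1 <- segment_poses(m, q)
  for (nm in names(p0)) {
    expect_equal(p1[[nm]]$t, p0[[nm]]$t + c(10, -5, 2))
    expect_equal(p1[[nm]]$R, p0[[nm]]$R)
  }
})

test_that("90-degree right hip flexion matches hand-composed rotation", {
  m <- build_model()
  q <- rep(0, 22); q[7] <- 90  # hip_flexion_R, axis (0,-1,0)
  poses <- segment_poses(m, q)
  R_exp <- oracle_rot(c(0, -1, 0), 90)
  expect_equal(poses$femur_R$R, R_exp, tolerance = 1e-12)
  # thigh points forward: knee centre at hip + 410 along +X
  expect_equal(poses$shank_R$t, c(410, -120, 0), tolerance = 1e-9)
  # two-link composition: add 90 deg knee flexion (axis (0,1,0) in femur)
  q[10] <- 90
  poses <- segment_poses(m, q)
  expect_equal(poses$shank_R$R, R_exp %*% oracle_rot(c(0, 1, 0), 90),
               tolerance = 1e-12)
  # shank now hangs straight down again from the forward knee
  expect_equal(poses$talus_R$t, c(410, -120, -400), tolerance = 1e-9)
})

test_that("pose vector of wrong length is rejected", {
  m <- build_model()
  expect_error(segment_poses(m, rep(0, 21)), "22")
  expect_error(predict_markers(m, plugin_marker_set(m), rep(0, 23)), "22")
})

test_that("predict_markers agrees with a brute-force chain oracle", {
  m <- build_model()
  att <- redundant_marker_set(m)$markers
  set.seed(11)
  for (rep in 1:5) {
    q <- c(runif(3, -200, 200), runif(19, -60, 60))
    expect_equal(predict_markers(m, att, q), oracle_predict(m, att, q),
                 tolerance = 1e-10)
  }
  # random offsets too
  att2 <- att
  att2[, c("ox", "oy", "oz")] <- matrix(runif(38 * 3, -80, 80), 38)
  q <- c(runif(3, -200, 200), runif(19, -60, 60))
  expect_equal(predict_markers(m, att2, q), oracle_predict(m, att2, q),
               tolerance = 1e-10)
})

test_that("markers on one segment keep rigid pairwise distances across poses", {
  m <- build_model()
  att <- redundant_marker_set(m)$markers
  set.seed(12)
  ref <- predict_markers(m, att, rep(0, 22))
  for (rep in 1:10) {
    q <- c(runif(3, -500, 500), runif(19, -70, 70))
    pos <- predict_markers(m, att, q)
    for (seg in unique(att$segment)) {
      i <- which(att$segment == seg)
      if (length(i) < 2) next
      expect_equal(as.numeric(dist(pos[i, ])), as.numeric(dist(ref[i, ])),
                   tolerance = 1e-9)
    }
  }
})

test_that("marker prediction is consistent under attachment subsetting", {
  m <- build_model()
  att38 <- redundant_marker_set(m)$markers
  att16 <- plugin_marker_set(m)$markers
  q <- c(50, -20, 10, 5, -3, 8, 20, 5, -10, 40, 2, 3, -10, 5,
         -15, -4, 8, 10, -2, 6, 12, -8)
  p38 <- predict_markers(m, att38, q)
  p16 <- predict_markers(m, att16, q)
  expect_equal(p38[rownames(p16), ], p16)
})

test_that("attachments to unknown segments are rejected", {
  m <- build_model()
  att <- plugin_marker_set(m)$markers
  att$segment[3] <- "humerus"
  expect_error(predict_markers(m, att, rep(0, 22)), "humerus")
})
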