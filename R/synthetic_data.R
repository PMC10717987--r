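# Synthetic gait generator with known ground truth: smooth stride-periodic
# joint-angle trajectories driving the forward kinematics of a scaled model,
# corrupted by soft-tissue artifact (stride-periodic sinusoid per marker +
# white noise), optional constant marker misplacement, and frame-wise
# occlusion.  Heel-strike truth is defined at the stride boundaries of the
# trajectory parameterization (no contact mechanics).
#
# Default coefficients are cosine-only, so every angle is an even function
# of cycle phase about the heel strike; the heel-forward peak then falls
# exactly on the stride boundary, making the coordinate-based event rule
# exact on noiseless data.  Curve shapes and ranges are chosen to resemble
# normal level walking (hip flexion about -10..30 deg, knee flexion about
# 5..59 deg); left-leg angles are the right-leg curves shifted by half a
# stride.

#' Default stride-periodic joint-trajectory coefficients
#'
#' Per right-leg angle (and pelvis orientation): mean plus up to 4 cosine
#' and sine harmonics of the stride frequency, deg.
#'
#' @return Named list of `list(mean, cos, sin)` per angle.
#' @export
default_gait_coefficients <- function() {
  co <- function(mean, cos = numeric(0), sin = numeric(0))
    list(mean = mean, cos = cos, sin = sin)
  list(
    pelvis_tilt        = co(5),
    pelvis_obliquity   = co(0, cos = 1.5),
    pelvis_rotation    = co(0, cos = 3),
    hip_flexion        = co(10, cos = 20),
    hip_adduction      = co(2, cos = 3),
    hip_rotation       = co(0, cos = 4),
    knee_flexion       = co(32, cos = -27),
    knee_adduction     = co(1, cos = 2),
    knee_rotation      = co(0, cos = -4),
    ankle_dorsiflexion = co(2, cos = -6),
    subtalar_inversion = co(0, cos = 4)
  )
}

#' Gait trajectory configuration
#'
#' @param stride_duration Stride (right heel strike to right heel strike)
#'   duration, s; default 1.1.
#' @param n_strides Number of strides; default 3.
#' @param sample_rate Hz; default 100.
#' @param speed Pelvis forward speed, mm/s; default 1200.
#' @param coefficients Fourier coefficients per angle
#'   ([default_gait_coefficients()]); entries override the defaults.
#' @return List of class `gait_trajectory_config`.
#' @export
gait_trajectory_config <- function(stride_duration = 1.1, n_strides = 3,
                                   sample_rate = 100, speed = 1200,
                                   coefficients = list()) {
  if (stride_duration <= 0) stop("stride_duration must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (n_strides < 1) stop("n_strides must be >= 1")
  cf <- utils::modifyList(default_gait_coefficients(), coefficients)
  structure(list(stride_duration = stride_duration, n_strides = n_strides,
                 sample_rate = sample_rate, speed = speed,
                 coefficients = cf),
            class = "gait_trajectory_config")
}

.eval_fourier <- function(cf, phase) {
  v <- rep(cf$mean, length(phase))
  for (h in seq_along(cf$cos)) v <- v + cf$cos[h] * cos(2 * pi * h * phase)
  for (h in seq_along(cf$sin)) v <- v + cf$sin[h] * sin(2 * pi * h * phase)
  v
}

#' Ground-truth gait pose trajectories
#'
#' Evaluates the stride-periodic Fourier trajectories on a uniform time
#' grid; pelvis translates forward at constant speed; left-leg angles are
#' the right-leg curves phase-shifted by half a stride.  Heel strikes (right
#' leg) are at the stride boundaries `0, T, 2T, ...` by construction.
#'
#' @param cfg A [gait_trajectory_config()].
#' @return List: `angles` (data.frame: `time` + 22 pose columns),
#'   `events` (`gait_events`, right heel-strike times incl. both ends).
#' @export
default_gait_trajectories <- function(cfg = gait_trajectory_config()) {
  n <- round(cfg$n_strides * cfg$stride_duration * cfg$sample_rate)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  phase <- (t / cfg$stride_duration) %% 1
  cf <- cfg$coefficients
  q <- matrix(0, n, 22, dimnames = list(NULL, pose_names()))
  q[, "pelvis_tx"] <- cfg$speed * t
  for (p in c("pelvis_tilt", "pelvis_obliquity", "pelvis_rotation"))
    q[, p] <- .eval_fourier(cf[[p]], phase)
  legs <- c("hip_flexion", "hip_adduction", "hip_rotation", "knee_flexion",
            "knee_adduction", "knee_rotation", "ankle_dorsiflexion",
            "subtalar_inversion")
  for (a in legs) {
    q[, paste0(a, "_R")] <- .eval_fourier(cf[[a]], phase)
    q[, paste0(a, "_L")] <- .eval_fourier(cf[[a]], (phase + 0.5) %% 1)
  }
  events <- structure(
    list(times = cfg$stride_duration * (0:cfg$n_strides), source = "truth"),
    class = "gait_events")
  list(angles = data.frame(time = t, q, check.names = FALSE),
       events = events)
}

#' Noise configuration for synthetic trials
#'
#' @param white_sigma SD of isotropic white marker noise, mm; default 0.
#' @param sta_amplitude Soft-tissue-artifact amplitude scale, mm: each
#'   marker coordinate receives a stride-periodic sinusoid with random phase
#'   and amplitude `sta_amplitude` times a segment-dependent weight
#'   (femur 1.0, shank 0.7, pelvis 0.5, foot 0.3); default 0.
#' @param misplacement Named list marker -> constant 3-vector (mm) added to
#'   that marker's trajectory (misplacement relative to calibration).
#' @param occlusion List of `list(marker, frames)` masking frame ranges.
#' @param seed Integer; makes generation bit-for-bit reproducible.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(white_sigma = 0, sta_amplitude = 0,
                         misplacement = NULL, occlusion = NULL, seed = NULL) {
  if (white_sigma < 0 || sta_amplitude < 0)
    stop("noise amplitudes must be >= 0")
  structure(list(white_sigma = white_sigma, sta_amplitude = sta_amplitude,
                 misplacement = misplacement, occlusion = occlusion,
                 seed = seed),
            class = "noise_config")
}

.sta_weight <- function(segment) {
  base <- sub("_[LR]$", "", segment)
  c(pelvis = 0.5, femur = 1.0, shank = 0.7, talus = 0, foot = 0.3)[base]
}

#' Generate a synthetic standing reference trial
#'
#' Forward kinematics at a static pose, repeated over frames with white
#' marker noise.
#'
#' @param truth_model Ground-truth `gait_model`.
#' @param protocol A `marker_protocol` (nominal offsets from `truth_model`).
#' @param white_sigma White-noise SD, mm; default 0.
#' @param n_frames Number of frames; default 100.
#' @param q0 Static pose (default all-zero anatomical standing).
#' @param seed Optional RNG seed.
#' @param sample_rate Hz; default 100.
#' @return A [marker_trajectory_set()].
#' @export
generate_standing <- function(truth_model, protocol, white_sigma = 0,
                              n_frames = 100, q0 = NULL, seed = NULL,
                              sample_rate = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(q0)) q0 <- rep(0, 22)
  att <- protocol$nominal_fun(truth_model)
  base <- predict_markers(truth_model, att, q0)
  n_mk <- nrow(base)
  pos <- array(rep(t(base), each = n_frames), c(n_frames, n_mk, 3),
               dimnames = list(NULL, rownames(base), c("X", "Y", "Z")))
  # replicate check: array fills frame-fastest; rebuild explicitly
  for (k in 1:3) pos[, , k] <- matrix(base[, k], n_frames, n_mk, byrow = TRUE)
  if (white_sigma > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, white_sigma), dim(pos))
  marker_trajectory_set((seq_len(n_frames) - 1) / sample_rate, pos,
                        sample_rate = sample_rate)
}

#' Generate a synthetic walking trial with ground truth
#'
#' Forward kinematics of the truth trajectories, then soft-tissue-artifact
#' sinusoids, white noise, constant misplacement offsets, and occlusion
#' masking, exactly as configured.  The truth (angles, events, model,
#' attachments) is retained for parameter-recovery testing.
#'
#' @param truth_model Ground-truth `gait_model`.
#' @param protocol A `marker_protocol`.
#' @param traj_cfg A [gait_trajectory_config()].
#' @param noise_cfg A [noise_config()].
#' @return List of class `synthetic_trial`: `markers` (mts), `truth_angles`
#'   (data.frame), `truth_events`, `truth_model`, `truth_attachments`.
#' @export
generate_trial <- function(truth_model, protocol,
                           traj_cfg = gait_trajectory_config(),
                           noise_cfg = noise_config()) {
  if (!is.null(noise_cfg$seed)) set.seed(noise_cfg$seed)
  traj <- default_gait_trajectories(traj_cfg)
  att <- protocol$nominal_fun(truth_model)
  n <- nrow(traj$angles); n_mk <- nrow(att)
  t <- traj$angles$time
  pos <- array(NA_real_, c(n, n_mk, 3),
               dimnames = list(NULL, att$name, c("X", "Y", "Z")))
  qmat <- as.matrix(traj$angles[, pose_names()])
  for (i in seq_len(n))
    pos[i, , ] <- predict_markers(truth_model, att, qmat[i, ])
  if (noise_cfg$sta_amplitude > 0) {
    w <- noise_cfg$sta_amplitude * .sta_weight(att$segment)
    phase <- matrix(stats::runif(n_mk * 3, 0, 2 * pi), n_mk, 3)
    arg <- 2 * pi * t / traj_cfg$stride_duration
    for (j in seq_len(n_mk)) for (k in 1:3)
      pos[, j, k] <- pos[, j, k] + w[j] * sin(arg + phase[j, k])
  }
  if (noise_cfg$white_sigma > 0)
    pos <- pos + array(stats::rnorm(length(pos), 0, noise_cfg$white_sigma),
                       dim(pos))
  for (nm in names(noise_cfg$misplacement)) {
    j <- match(nm, att$name)
    if (is.na(j)) stop("misplacement for unknown marker: ", nm)
    for (k in 1:3) pos[, j, k] <- pos[, j, k] + noise_cfg$misplacement[[nm]][k]
  }
  for (oc in noise_cfg$occlusion) {
    j <- match(oc$marker, att$name)
    if (is.na(j)) stop("occlusion for unknown marker: ", oc$marker)
    fr <- intersect(oc$frames, seq_len(n))
    pos[fr, j, ] <- NA_real_
  }
  structure(list(
    markers = marker_trajectory_set(t, pos, sample_rate = traj_cfg$sample_rate),
    truth_angles = traj$angles, truth_events = traj$events,
    truth_model = truth_model, truth_attachments = att),
    class = "synthetic_trial")
}

# Per-angle RMSE of a solved trajectory against truth (joint angles only).
angle_rmse <- function(solved, truth_angles) {
  ang <- setdiff(pose_names(), c("pelvis_tx", "pelvis_ty", "pelvis_tz"))
  vapply(ang, function(a)
    sqrt(mean((solved[[a]] - truth_angles[[a]])^2)), numeric(1))
}

#' Marker-set robustness experiment
#'
#' For each noise scenario, seed and protocol arm: generate a standing trial
#' and a walking trial from the ground-truth model, calibrate with the
#' redundant protocol (deriving the Plugin arm by [reduce_to_plugin()], the
#' controlled-comparison construction), solve IK, and measure per-angle
#' RMSE against the known truth.
#'
#' @param scenarios Named list of [noise_config()]s (seeds are assigned per
#'   repetition from `seeds`).
#' @param seeds Integer vector of RNG seeds (one repetition each).
#' @param traj_cfg A [gait_trajectory_config()]; default 2 strides.
#' @param truth_model Ground-truth model; default [build_model()].
#' @param standing_sigma White-noise SD for the standing trial, mm;
#'   default: the scenario's `white_sigma`.
#' @return Long data.frame: `scenario`, `seed`, `protocol` ("redundant",
#'   "plugin"), `angle`, `rmse` (deg for angle entries).
#' @export
run_robustness_experiment <- function(scenarios, seeds = 1:20,
                                      traj_cfg = gait_trajectory_config(n_strides = 2),
                                      truth_model = build_model(),
                                      standing_sigma = NULL) {
  proto_R <- redundant_marker_set(truth_model)
  rows <- list()
  for (sc in names(scenarios)) {
    base_cfg <- scenarios[[sc]]
    for (s in seeds) {
      ncfg <- base_cfg; ncfg$seed <- s
      st_sig <- if (is.null(standing_sigma)) base_cfg$white_sigma
                else standing_sigma
      standing <- generate_standing(truth_model, proto_R, white_sigma = st_sig,
                                    n_frames = 50, seed = s + 10000L)
      cal_R <- calibrate(standing, proto_R)
      cal_P <- reduce_to_plugin(cal_R)
      trial <- generate_trial(truth_model, proto_R, traj_cfg, ncfg)
      for (arm in c("redundant", "plugin")) {
        cal <- if (arm == "redundant") cal_R else cal_P
        mk <- if (arm == "redundant") trial$markers
              else reduce_to_plugin(trial$markers)
        solved <- solve_trajectory(cal, mk)
        rm <- angle_rmse(solved, trial$truth_angles)
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sc, seed = s, protocol = arm,
          angle = names(rm), rmse = unname(rm), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a robustness experiment
#'
#' Median and interquartile range of RMSE over seeds, per scenario,
#' protocol and angle.
#'
#' @param results Output of [run_robustness_experiment()].
#' @return Data.frame with `scenario`, `protocol`, `angle`, `median_rmse`,
#'   `iqr_rmse`.
#' @export
summarize_robustness <- function(results) {
  sp <- split(results, list(results$scenario, results$protocol, results$angle),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    scenario = g$scenario[1], protocol = g$protocol[1], angle = g$angle[1],
    median_rmse = stats::median(g$rmse), iqr_rmse = stats::IQR(g$rmse),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
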