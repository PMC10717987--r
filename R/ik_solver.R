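# Per-frame global-optimization inverse kinematics: find the 22-entry pose
# minimizing the weighted sum of squared distances between experimental and
# model-predicted markers, with trajectory solving by warm starts and
# per-frame occlusion handling.
#
# Solver: damped nonlinear least squares (Levenberg-Marquardt).  Pelvis
# translations are rescaled to centimetres inside the optimizer so their
# step sizes are commensurate with the angle entries (degrees).

# translation entries are q[1:3]; internal parameter = q * .q_scale
.q_scale <- c(rep(0.1, 3), rep(1, 19))

#' IK solver configuration
#'
#' @param weights Per-marker nonnegative weights: a named numeric vector
#'   (missing names default to 1), a scalar, or `NULL` (all 1).
#' @param tolerance Convergence tolerance on the cost (mm^2); default 1e-10.
#' @param max_iterations Maximum solver iterations per frame; default 100.
#' @param min_markers Minimum visible markers required per frame; default 12
#'   for protocols of up to 16 markers, 20 for larger ones.
#' @param check_rank Verify pose observability via the rank of the residual
#'   Jacobian when markers are occluded (default TRUE).
#' @param restart_threshold Residual RMS (mm) above which a small fixed set
#'   of alternative initial poses is tried and the best kept (deterministic
#'   fallback against local minima when solving far from the solution);
#'   default 1.  [solve_trajectory()] raises it per frame to twice the
#'   previous frame's residual, so warm-started solves on noisy data do not
#'   restart needlessly.
#' @return List of class `ik_config`.
#' @export
ik_config <- function(weights = NULL, tolerance = 1e-10, max_iterations = 100,
                      min_markers = NULL, check_rank = TRUE,
                      restart_threshold = 1) {
  if (!is.null(weights) && any(weights < 0))
    stop("marker weights must be nonnegative")
  structure(list(weights = weights, tolerance = tolerance,
                 max_iterations = max_iterations, min_markers = min_markers,
                 check_rank = check_rank,
                 restart_threshold = restart_threshold),
            class = "ik_config")
}

.marker_weights <- function(cfg, nms) {
  w <- rep(1, length(nms)); names(w) <- nms
  if (!is.null(cfg$weights)) {
    if (is.null(names(cfg$weights)) && length(cfg$weights) == 1)
      w[] <- cfg$weights
    else w[intersect(names(cfg$weights), nms)] <-
        cfg$weights[intersect(names(cfg$weights), nms)]
  }
  if (all(w == 0)) stop("at least one marker weight must be positive")
  w
}

# Forward-difference Jacobian of predicted marker coordinates wrt q.
.ik_jacobian <- function(fk, q, h = 1e-5) {
  base <- as.vector(fk(q))
  J <- matrix(0, length(base), 22)
  for (j in 1:22) {
    qj <- q; qj[j] <- qj[j] + h
    J[, j] <- (as.vector(fk(qj)) - base) / h
  }
  J
}

# Observability check: residual Jacobian must have full column rank.
.check_observable <- function(model, fk, q) {
  J <- .ik_jacobian(fk, q)
  sv <- svd(J)
  tol <- max(dim(J)) * max(sv$d) * 1e-10
  r <- sum(sv$d > tol)
  if (r < 22) {
    weak <- apply(abs(sv$v[, sv$d <= tol, drop = FALSE]), 1, max)
    bad <- model$q_names[weak > 0.3]
    stop("pose underdetermined from visible markers (Jacobian rank ", r,
         "/22); weakly observed DOFs: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Canonical angle parameterization: wrap every angle to (-180, 180] and
# resolve the Cardan alias (f, a, r) ~ (f + 180, 180 - a, r + 180) so the
# middle angle of each 3-DOF joint lies in [-90, 90].  The rotation (and
# hence the marker fit) is unchanged.
.canonicalize_q <- function(q) {
  wrap <- function(x) ((x + 180) %% 360) - 180
  q[4:22] <- wrap(q[4:22])
  for (trip in list(4:6, 7:9, 10:12, 15:17, 18:20)) {
    if (abs(q[trip[2]]) > 90) {
      q[trip[1]] <- wrap(q[trip[1]] + 180)
      q[trip[2]] <- wrap(180 - q[trip[2]])
      q[trip[3]] <- wrap(q[trip[3]] + 180)
    }
  }
  q
}

.fixed_restart_poses <- function(q_init) {
  alt1 <- q_init; alt1[c(10, 18)] <- alt1[c(10, 18)] + 45   # knees flexed
  alt2 <- q_init; alt2[c(7, 15)] <- alt2[c(7, 15)] + 30     # hips flexed
  alt2[c(10, 18)] <- alt2[c(10, 18)] + 60
  alt3 <- q_init; alt3[c(7, 15)] <- alt3[c(7, 15)] - 30
  alt4 <- q_init                                            # ankles flipped
  alt4[c(13, 21)] <- alt4[c(13, 21)] + 40
  alt4[c(12, 20)] <- alt4[c(12, 20)] - 30
  alt5 <- q_init
  alt5[c(13, 21)] <- alt5[c(13, 21)] - 40
  alt5[c(12, 20)] <- alt5[c(12, 20)] + 30
  list(alt1, alt2, alt3, alt4, alt5)
}

.solve_frame_once <- function(fk, q_names, target, w, q_init, cfg) {
  sw <- rep(sqrt(w), 3)  # residual vector is column-major (all X, Y, Z)
  tv <- as.vector(target)
  q_init <- as.numeric(q_init)
  # The update is optimized relative to the current pose, so the parameter
  # vector starts at exactly zero each (re-)centering: minpack then uses a
  # well-sized initial trust region (delta = factor) regardless of the pose
  # magnitude.  Because minpack's relative step test cannot fire near a
  # zero-centred optimum, the solve runs in short chunks, re-centering at
  # the current iterate, and stops when a chunk no longer reduces the cost
  # (stagnation at the optimum / noise floor).  gtol (gradient
  # orthogonality, scale-free) stops cleanly at a noisy-data floor.
  # Convergence is reported via the `converged` flag; nls.lm's own maxiter
  # warning would only duplicate it.
  q_cur <- q_init
  chunk <- min(15L, cfg$max_iterations)
  used <- 0L
  cost_prev <- Inf
  converged <- FALSE
  floor_w <- length(tv) * 1e-12  # numerical floor: residual rms 1e-6 mm
  repeat {
    resid_fn <- function(par) {
      q <- q_cur + par / .q_scale
      sw * (as.vector(fk(q)) - tv)
    }
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = rep(0, 22), fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = chunk, ftol = cfg$tolerance, ptol = 1e-12, gtol = 1e-10)))
    q_cur <- q_cur + fit$par / .q_scale
    cost_w <- sum(fit$fvec^2)
    used <- used + chunk
    if (fit$info %in% 1:4 || cost_w <= floor_w) { converged <- TRUE; break }
    if (cost_prev - cost_w <= cfg$tolerance * max(cost_w, 1)) {
      converged <- TRUE  # stagnated at a (possibly local) optimum
      break
    }
    if (used >= cfg$max_iterations) break
    cost_prev <- cost_w
  }
  q <- q_cur
  names(q) <- q_names
  d2 <- rowSums((fk(q) - target)^2)
  list(q = q, cost = sum(w * d2), residual_rms = sqrt(mean(d2)),
       converged = converged)
}

#' Solve one frame of inverse kinematics
#'
#' Minimizes `sum_i w_i * ||m_exp_i - m_model_i(q)||^2` over the 22-entry
#' pose.  Occluded markers (NA rows) are dropped from the objective; the
#' reported residual RMS is the per-marker distance RMS over the markers
#' actually used.
#'
#' @param cal A `calibrated_model`.
#' @param markers Matrix of experimental positions (rownames = labels, mm);
#'   `NA` rows are treated as occluded.  Extra markers not in the calibrated
#'   attachment set are ignored.
#' @param q_init Initial pose (default: the calibration static pose).
#' @param cfg An [ik_config()].
#' @return List of class `ik_frame`: `q`, `residual_rms` (mm),
#'   `n_markers_used`, `converged`.
#' @export
solve_frame <- function(cal, markers, q_init = NULL, cfg = ik_config()) {
  att <- cal$attachments
  if (is.null(q_init)) q_init <- cal$q0
  q_init <- .check_q(cal$model, q_init)
  markers <- as.matrix(markers)
  keep <- intersect(att$name, rownames(markers))
  vis <- keep[stats::complete.cases(markers[keep, , drop = FALSE])]
  min_mk <- cfg$min_markers
  if (is.null(min_mk)) min_mk <- if (nrow(att) <= 16) 12L else 20L
  if (length(vis) < min_mk)
    stop("only ", length(vis), " visible markers; need at least ", min_mk)
  att_vis <- att[att$name %in% vis, , drop = FALSE]
  fk <- .compile_fk(cal$model, att_vis)
  if (isTRUE(cfg$check_rank) && length(vis) < nrow(att))
    .check_observable(cal$model, fk, q_init)
  .solve_frame_compiled(fk, cal$model$q_names, att_vis,
                        markers[att_vis$name, , drop = FALSE], q_init, cfg)
}

# Core solve on a compiled FK closure (shared by solve_frame and
# solve_trajectory, which reuses the closure across frames).
.solve_frame_compiled <- function(fk, q_names, att_vis, target, q_init, cfg) {
  w <- .marker_weights(cfg, att_vis$name)
  best <- .solve_frame_once(fk, q_names, target, w, q_init, cfg)
  if (best$residual_rms > cfg$restart_threshold) {
    for (alt in .fixed_restart_poses(q_init)) {
      cand <- .solve_frame_once(fk, q_names, target, w, alt, cfg)
      if (cand$cost < best$cost) best <- cand
      if (best$residual_rms <= cfg$restart_threshold) break
    }
  }
  best$q <- .canonicalize_q(best$q)
  structure(list(q = best$q, residual_rms = best$residual_rms,
                 n_markers_used = nrow(att_vis), converged = best$converged),
            class = "ik_frame")
}

#' Solve inverse kinematics over a whole trial
#'
#' Frame-by-frame IK with warm starting: frame 1 starts from the calibration
#' static pose, each later frame from the previous solution.  Occluded
#' markers are dropped per frame; observability is re-checked whenever the
#' occlusion pattern changes.  Angle entries are unwrapped along the
#' trajectory to avoid 360-degree jumps.
#'
#' @param cal A `calibrated_model`.
#' @param trial A [marker_trajectory_set()].
#' @param cfg An [ik_config()].
#' @return A data.frame (joint-angle series): `time`, the 22 pose columns
#'   (deg / mm), `residual_rms`, `n_markers`, `converged`.
#' @export
solve_trajectory <- function(cal, trial, cfg = ik_config()) {
  if (!inherits(trial, "mts")) stop("trial must be a marker trajectory set")
  nf <- n_frames(trial)
  if (nf == 0) stop("empty trial")
  qn <- cal$model$q_names
  out <- matrix(NA_real_, nf, 22, dimnames = list(NULL, qn))
  rms <- numeric(nf); nmk <- integer(nf); conv <- logical(nf)
  att <- cal$attachments
  min_mk <- cfg$min_markers
  if (is.null(min_mk)) min_mk <- if (nrow(att) <= 16) 12L else 20L
  in_att <- marker_names(trial) %in% att$name
  q_prev <- cal$q0
  mask_prev <- NULL
  fk <- NULL; att_vis <- NULL
  for (i in seq_len(nf)) {
    mask_i <- trial$mask[i, ] & in_att
    res <- tryCatch({
      if (is.null(mask_prev) || any(mask_i != mask_prev)) {
        vis <- marker_names(trial)[mask_i]
        if (length(vis) < min_mk)
          stop("only ", length(vis), " visible markers; need at least ", min_mk)
        att_vis <- att[match(intersect(att$name, vis), att$name), , drop = FALSE]
        fk <- .compile_fk(cal$model, att_vis)
        if (isTRUE(cfg$check_rank) && nrow(att_vis) < nrow(att))
          .check_observable(cal$model, fk, q_prev)
      }
      target <- frame_positions(trial, i)[att_vis$name, , drop = FALSE]
      cfg_i <- cfg
      if (i > 1)
        cfg_i$restart_threshold <- max(cfg$restart_threshold,
                                       2 * rms[i - 1] + 0.1)
      .solve_frame_compiled(fk, cal$model$q_names, att_vis, target, q_prev, cfg_i)
    }, error = function(e) stop("IK failed at frame ", i, ": ",
                                conditionMessage(e), call. = FALSE))
    # unwrap angles relative to the previous frame
    ang <- 4:22
    res$q[ang] <- res$q[ang] - 360 * round((res$q[ang] - q_prev[ang]) / 360)
    out[i, ] <- res$q
    rms[i] <- res$residual_rms; nmk[i] <- res$n_markers_used
    conv[i] <- res$converged
    q_prev <- res$q
    mask_prev <- mask_i
  }
  df <- data.frame(time = trial$times, out, residual_rms = rms,
                   n_markers = nmk, converged = conv, check.names = FALSE)
  attr(df, "sample_rate") <- trial$sample_rate
  df
}
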