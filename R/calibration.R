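# Standing-trial calibration: joint least-squares estimation of the seven
# segment lengths and the 22-entry static pose from time-averaged standing
# marker positions (using the protocol's nominal placement rule), followed
# by per-marker offset computation in the fitted segment frames.  Offsets
# absorb the remaining residual by construction, so the calibrated model
# reproduces the standing means exactly at q0.

#' Estimate segment lengths and static pose from a standing trial
#'
#' Minimizes the sum of squared distances between the time-averaged standing
#' marker positions and model-predicted markers (nominal offsets regenerated
#' from the candidate lengths) over the seven length parameters and the
#' 22-entry static pose, by damped nonlinear least squares
#' (Levenberg-Marquardt).  Lengths are bounded to [0.5, 1.5] x nominal and
#' angles to +/-45 deg around the anatomical standing pose; the fit is
#' deterministic (no random restarts).
#'
#' @param standing A [marker_trajectory_set()] of quiet anatomical standing,
#'   or a precomputed matrix of mean marker positions (rownames = labels).
#' @param protocol A `marker_protocol`; all its markers must be visible in
#'   at least one standing frame.
#' @param nominal Nominal `gait_model` providing initial lengths and bounds.
#' @param control List: `max_iterations` (default 200), `tolerance`
#'   (cost tolerance, default 1e-10).
#' @return List with `model` (fitted `gait_model`), `q0` (named pose),
#'   `residual_rms` (mm) and `info` (solver diagnostics).
#' @export
estimate_scaling <- function(standing, protocol, nominal = build_model(),
                             control = list()) {
  ctl <- utils::modifyList(list(max_iterations = 200, tolerance = 1e-10),
                           control)
  target <- if (inherits(standing, "mts")) mean_positions(standing)
            else as.matrix(standing)
  if (is.null(rownames(target)) || nrow(target) == 0)
    stop("empty standing trial")
  nms <- protocol$markers$name
  missing <- setdiff(nms, rownames(target))
  if (length(missing))
    stop("standing trial lacks protocol marker(s): ",
         paste(missing, collapse = ", "))
  target <- target[nms, , drop = FALSE]
  if (any(!is.finite(target))) stop("standing means contain non-finite values")

  len0 <- nominal$lengths
  nlen <- length(len0)
  # initial pelvis translation from the pelvis-marker centroid shift
  pelv <- intersect(c("LASI", "RASI", "LPSI", "RPSI"), nms)
  pred0 <- predict_markers(nominal, protocol$markers, rep(0, 22))
  t_init <- if (length(pelv) >= 1)
    colMeans(target[pelv, , drop = FALSE]) - colMeans(pred0[pelv, , drop = FALSE])
  else c(0, 0, 0)
  par0 <- c(len0, t_init, rep(0, 19))
  lower <- c(0.5 * len0, t_init - 1000, rep(-45, 19))
  upper <- c(1.5 * len0, t_init + 1000, rep(45, 19))

  resid_fn <- .scaling_residual(protocol, nominal, target)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = ctl$max_iterations, ftol = ctl$tolerance, ptol = 1e-12))
  rms <- sqrt(mean(fit$fvec^2))
  if (!fit$info %in% 1:4)
    stop("scaling optimization did not converge (info = ", fit$info,
         ", residual rms = ", signif(rms, 4), " mm)")
  # observability: finite-difference Jacobian at the solution must have
  # full column rank (nls.lm's internal hessian is not reliable here)
  f0 <- resid_fn(fit$par)
  J <- vapply(seq_along(fit$par), function(j) {
    p <- fit$par; h <- 1e-6 * max(1, abs(p[j])); p[j] <- p[j] + h
    (resid_fn(p) - f0) / h
  }, numeric(length(f0)))
  sv <- svd(J)$d
  if (min(sv) < 1e-7 * max(sv))
    stop("standing marker geometry is degenerate: scaling underdetermined")
  lens <- fit$par[seq_len(nlen)]
  names(lens) <- names(len0)
  q0 <- fit$par[nlen + 1:22]
  names(q0) <- nominal$q_names
  list(model = build_model(lens), q0 = q0, residual_rms = rms,
       info = list(code = fit$info, iterations = fit$niter))
}

#' Compute subject-specific marker offsets
#'
#' Expresses each marker's mean standing position in its segment's fitted
#' frame at the static pose: `offset = t(R_seg) %*% (p - t_seg)`.  Predicted
#' markers at `q0` then reproduce the standing means exactly.
#'
#' @param scaled Fitted `gait_model`.
#' @param q0 Static pose (length 22).
#' @param standing_mean Matrix of mean marker positions (rownames = labels).
#' @param protocol A `marker_protocol` giving marker-to-segment assignment.
#' @return Attachment data.frame (`name`, `segment`, `side`, `ox`, `oy`, `oz`).
#' @export
compute_offsets <- function(scaled, q0, standing_mean, protocol) {
  att <- protocol$markers
  missing <- setdiff(att$name, rownames(standing_mean))
  if (length(missing))
    stop("marker never visible in standing trial: ",
         paste(missing, collapse = ", "))
  poses <- segment_poses(scaled, q0)
  for (i in seq_len(nrow(att))) {
    p <- standing_mean[att$name[i], ]
    if (any(!is.finite(p)))
      stop("marker never visible in standing trial: ", att$name[i])
    sp <- poses[[att$segment[i]]]
    off <- crossprod(sp$R, p - sp$t)
    att$ox[i] <- off[1]; att$oy[i] <- off[2]; att$oz[i] <- off[3]
  }
  att
}

#' Calibrate a model from a standing reference trial
#'
#' Composition of [estimate_scaling()] (segment lengths + static pose) and
#' [compute_offsets()] (per-marker offsets), the standard standing-trial
#' scaling workflow.  Calibrating with the redundant protocol and then
#' applying [reduce_to_plugin()] yields the controlled Plugin-arm model:
#' shared markers keep bit-identical offsets.
#'
#' @inheritParams estimate_scaling
#' @return An object of class `calibrated_model`: `model`, `attachments`,
#'   `q0`, `protocol_name`, `residual_rms`.
#' @export
calibrate <- function(standing, protocol, nominal = build_model(),
                      control = list()) {
  if (inherits(standing, "mts") && n_frames(standing) == 0)
    stop("empty standing trial")
  target <- if (inherits(standing, "mts")) mean_positions(standing)
            else as.matrix(standing)
  fit <- estimate_scaling(target, protocol, nominal, control)
  att <- compute_offsets(fit$model, fit$q0, target, protocol)
  structure(list(model = fit$model, attachments = att, q0 = fit$q0,
                 protocol_name = protocol$name,
                 residual_rms = fit$residual_rms),
            class = "calibrated_model")
}

#' @export
print.calibrated_model <- function(x, ...) {
  cat("calibrated_model (", x$protocol_name, " protocol, ",
      nrow(x$attachments), " markers)\n", sep = "")
  cat("scaling residual rms:", signif(x$residual_rms, 4), "mm\n")
  print(round(x$model$lengths, 1))
  invisible(x)
}

#' Serialize / restore a calibrated model (YAML)
#'
#' @param cal A `calibrated_model`.
#' @param path YAML file path.
#' @return `read_calibrated_model` returns a `calibrated_model`.
#' @export
write_calibrated_model <- function(cal, path) {
  obj <- list(protocol = cal$protocol_name,
              lengths = as.list(cal$model$lengths),
              q0 = as.list(cal$q0),
              residual_rms = cal$residual_rms,
              markers = lapply(seq_len(nrow(cal$attachments)), function(i)
                list(name = cal$attachments$name[i],
                     segment = cal$attachments$segment[i],
                     side = cal$attachments$side[i],
                     offset_mm = as.numeric(cal$attachments[i, c("ox", "oy", "oz")]))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_calibrated_model
#' @export
read_calibrated_model <- function(path) {
  obj <- yaml::read_yaml(path)
  att <- do.call(rbind, lapply(obj$markers, function(m)
    data.frame(name = m$name, segment = m$segment, side = m$side,
               ox = m$offset_mm[1], oy = m$offset_mm[2], oz = m$offset_mm[3],
               stringsAsFactors = FALSE)))
  structure(list(model = build_model(unlist(obj$lengths)),
                 attachments = att,
                 q0 = stats::setNames(unlist(obj$q0), names(obj$q0)),
                 protocol_name = obj$protocol,
                 residual_rms = obj$residual_rms),
            class = "calibrated_model")
}
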