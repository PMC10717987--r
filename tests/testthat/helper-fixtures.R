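# Shared fixtures and independent oracles.  Heavy objects (noiseless
# calibrations) are memoized so the suite builds them once.

.fx_env <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx_env[[key]])) .fx_env[[key]] <- builder()
  .fx_env[[key]]
}

fx_model <- function() fx_memo("model", build_model)

fx_cal_R <- function() fx_memo("cal_R", function() {
  m <- fx_model()
  proto <- redundant_marker_set(m)
  calibrate(generate_standing(m, proto, white_sigma = 0, n_frames = 3), proto)
})

fx_cal_P <- function() fx_memo("cal_P", function() reduce_to_plugin(fx_cal_R()))

# --- independent oracles -----------------------------------------------

# Rodrigues rotation, written independently of the package internals.
oracle_rot <- function(axis, deg) {
  th <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * u %*% t(u)
}

# Brute-force marker prediction: walk each marker's chain from the root,
# composing transforms one joint at a time (independent of segment_poses'
# iteration order and of the compiled FK path).
oracle_predict <- function(model, attachments, q) {
  chain_of <- function(seg) {
    ch <- seg
    while (!is.na(model$segments[[ch[1]]]$parent))
      ch <- c(model$segments[[ch[1]]]$parent, ch)
    ch
  }
  out <- matrix(NA_real_, nrow(attachments), 3,
                dimnames = list(attachments$name, c("X", "Y", "Z")))
  for (i in seq_len(nrow(attachments))) {
    R <- diag(3); t <- c(0, 0, 0)
    for (seg in chain_of(attachments$segment[i])) {
      sg <- model$segments[[seg]]
      if (is.na(sg$parent)) {
        t <- q[1:3]
      } else {
        t <- t + R %*% sg$joint_offset
      }
      for (k in seq_along(sg$q_idx))
        R <- R %*% oracle_rot(sg$axes[, k], q[sg$q_idx[k]])
    }
    out[i, ] <- t + R %*% as.numeric(attachments[i, c("ox", "oy", "oz")])
  }
  out
}

# Closed-form t-test oracles.
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

oracle_welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Truth angle matrix (angle columns only) from a synthetic trial.
truth_angle_matrix <- function(trial)
  as.matrix(trial$truth_angles[, pose_names()[4:22]])

solved_angle_matrix <- function(solved)
  as.matrix(solved[, pose_names()[4:22]])
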