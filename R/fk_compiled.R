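# Internal fast path for forward kinematics.  `predict_markers()` is the
# reference implementation; the IK inner loop evaluates FK hundreds of times
# per frame, so attachment tables are "compiled" once into index vectors and
# offset matrices, and joint rotations (always about signed coordinate axes)
# are built directly instead of via Rodrigues.

.rot_coord <- function(axis_id, s, deg) {
  th <- s * deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  if (axis_id == 1L)
    matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3, 3)
  else if (axis_id == 2L)
    matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3, 3)
  else
    matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3, 3)
}

# Compile model + attachments into a closure q -> m x 3 position matrix
# (rows in attachment order, rownames = marker names).
.compile_fk <- function(model, attachments) {
  att <- as_attachments(attachments)
  segs <- model$segments
  seg_names <- names(segs)
  n_seg <- length(segs)
  parent_idx <- match(vapply(segs, `[[`, character(1), "parent"), seg_names)
  joint_off <- lapply(segs, `[[`, "joint_offset")
  q_idx <- lapply(segs, `[[`, "q_idx")
  ax_id <- lapply(segs, function(s)
    vapply(seq_len(ncol(s$axes)), function(k) which(s$axes[, k] != 0)[1],
           integer(1)))
  ax_sgn <- lapply(segs, function(s) {
    id <- vapply(seq_len(ncol(s$axes)), function(k) which(s$axes[, k] != 0)[1],
                 integer(1))
    vapply(seq_len(ncol(s$axes)), function(k) s$axes[id[k], k], numeric(1))
  })
  seg_of <- match(att$segment, seg_names)
  if (any(is.na(seg_of)))
    stop("attachment references unknown segment(s): ",
         paste(unique(att$segment[is.na(seg_of)]), collapse = ", "))
  by_seg <- split(seq_len(nrow(att)), seg_of)
  off_mats <- lapply(by_seg, function(i) t(as.matrix(att[i, c("ox", "oy", "oz")])))
  used_segs <- as.integer(names(by_seg))
  m <- nrow(att)
  nms <- att$name

  function(q) {
    Rs <- vector("list", n_seg)
    ts <- vector("list", n_seg)
    for (i in seq_len(n_seg)) {
      id <- ax_id[[i]]; sg <- ax_sgn[[i]]; qi <- q_idx[[i]]
      Rj <- .rot_coord(id[1], sg[1], q[qi[1]])
      for (k in seq_along(qi)[-1])
        Rj <- Rj %*% .rot_coord(id[k], sg[k], q[qi[k]])
      p <- parent_idx[i]
      if (is.na(p)) {
        Rs[[i]] <- Rj; ts[[i]] <- q[1:3]
      } else {
        Rs[[i]] <- Rs[[p]] %*% Rj
        ts[[i]] <- ts[[p]] + as.numeric(Rs[[p]] %*% joint_off[[i]])
      }
    }
    out <- matrix(NA_real_, m, 3, dimnames = list(nms, c("X", "Y", "Z")))
    for (k in seq_along(used_segs)) {
      i <- used_segs[k]
      out[by_seg[[k]], ] <- t(Rs[[i]] %*% off_mats[[k]] + ts[[i]])
    }
    out
  }
}
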