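# Internal fast residual for standing-trial scaling.  The optimizer
# evaluates the residual hundreds of times; rebuilding protocol tables and
# model objects each time dominates the cost, so the kinematic structure is
# compiled once and only the length-dependent quantities (joint-centre
# offsets, nominal marker offsets) are recomputed per evaluation.

.scaling_residual <- function(protocol, nominal, target) {
  att <- protocol$nominal_fun(nominal)
  builtin <- protocol$name %in% c("plugin", "redundant")
  segs <- nominal$segments
  seg_names <- names(segs)
  parent_idx <- match(vapply(segs, `[[`, character(1), "parent"), seg_names)
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
  by_seg <- split(seq_len(nrow(att)), seg_of)
  used_segs <- as.integer(names(by_seg))
  base <- sub("^[LR]", "", att$name)
  side <- att$side
  talus_h <- nominal$talus_height
  lnames <- names(nominal$lengths)
  tmat <- t(target)  # 3 x m, marker order as att

  # length-dependent joint-centre offsets (parent frame, zero pose)
  joint_off <- function(lens) {
    out <- vector("list", length(segs))
    for (i in seq_along(segs)) {
      nm <- seg_names[i]
      out[[i]] <- if (nm == "pelvis") c(0, 0, 0)
      else if (startsWith(nm, "femur"))
        c(0, (if (endsWith(nm, "L")) 1 else -1) * lens[["pelvic_width"]] / 2, 0)
      else if (startsWith(nm, "shank"))
        c(0, 0, -lens[[paste0("thigh_", substr(nm, 7, 7))]])
      else if (startsWith(nm, "talus"))
        c(0, 0, -lens[[paste0("shank_", substr(nm, 7, 7))]])
      else c(0, 0, -talus_h)
    }
    out
  }
  # length-dependent nominal marker offsets, 3 x m
  off_mat <- function(lens) {
    if (builtin) {
      byside <- list(L = .nominal_offsets(lens, "L"),
                     R = .nominal_offsets(lens, "R"))
      vapply(seq_along(base), function(i) byside[[side[i]]][[base[i]]][[2]],
             numeric(3))
    } else {
      m <- build_model(lens)
      t(as.matrix(protocol$nominal_fun(m)[, c("ox", "oy", "oz")]))
    }
  }

  function(par) {
    lens <- par[seq_along(lnames)]
    names(lens) <- lnames
    q <- par[length(lnames) + 1:22]
    jo <- joint_off(lens)
    off <- off_mat(lens)
    Rs <- vector("list", length(segs))
    ts <- vector("list", length(segs))
    for (i in seq_along(segs)) {
      id <- ax_id[[i]]; sg <- ax_sgn[[i]]; qi <- q_idx[[i]]
      Rj <- .rot_coord(id[1], sg[1], q[qi[1]])
      for (k in seq_along(qi)[-1])
        Rj <- Rj %*% .rot_coord(id[k], sg[k], q[qi[k]])
      p <- parent_idx[i]
      if (is.na(p)) {
        Rs[[i]] <- Rj; ts[[i]] <- q[1:3]
      } else {
        Rs[[i]] <- Rs[[p]] %*% Rj
        ts[[i]] <- ts[[p]] + as.numeric(Rs[[p]] %*% jo[[i]])
      }
    }
    res <- matrix(NA_real_, 3, ncol(off))
    for (k in seq_along(used_segs)) {
      i <- used_segs[k]; j <- by_seg[[k]]
      res[, j] <- Rs[[i]] %*% off[, j, drop = FALSE] + ts[[i]] - tmat[, j]
    }
    as.vector(t(res))  # marker-major per coordinate, matching target layout
  }
}
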