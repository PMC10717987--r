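# Labelled marker-trajectory container: the experimental side of the IK
# objective.  Positions are mm in the lab frame; occlusion is carried both as
# NA positions and as a logical visibility mask.

#' Create a marker trajectory set
#'
#' @param times Numeric vector of frame times, s; strictly increasing and
#'   uniformly spaced (tolerance 1e-6 s).
#' @param positions Numeric array `[frame, marker, 3]`; `dimnames[[2]]` are
#'   the marker labels.  `NA` triples mark occluded samples.
#' @param sample_rate Hz; default inferred from `times`.
#' @return An object of class `mts`.
#' @export
marker_trajectory_set <- function(times, positions, sample_rate = NULL) {
  times <- as.numeric(times)
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3)
    stop("positions must be an [frame, marker, 3] array")
  if (dim(positions)[1] != length(times))
    stop("positions has ", dim(positions)[1], " frames but times has ",
         length(times))
  if (is.null(dimnames(positions)[[2]]))
    stop("positions must carry marker names on dim 2")
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stop("times must be uniformly spaced (tolerance 1e-6 s)")
    if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  }
  if (is.null(sample_rate)) sample_rate <- NA_real_
  mask <- !apply(is.na(positions), c(1, 2), any)
  # enforce whole-sample occlusion: any NA coordinate blanks the triple
  for (k in 1:3) positions[, , k][!mask] <- NA_real_
  bad <- !is.na(positions) & !is.finite(positions)
  if (any(bad)) stop("non-finite visible positions")
  structure(list(times = times, positions = positions, mask = mask,
                 sample_rate = sample_rate), class = "mts")
}

#' @export
print.mts <- function(x, ...) {
  cat("marker trajectory set:", n_frames(x), "frames x",
      length(marker_names(x)), "markers @", round(x$sample_rate, 3), "Hz\n")
  occ <- sum(!x$mask)
  if (occ) cat("  occluded samples:", occ, "\n")
  invisible(x)
}

#' @export
#' @rdname marker_trajectory_set
n_frames <- function(x) length(x$times)

#' @export
#' @rdname marker_trajectory_set
marker_names <- function(x) dimnames(x$positions)[[2]]

# One frame as an m x 3 matrix (rownames = marker names, NA if occluded).
frame_positions <- function(x, i) {
  m <- x$positions[i, , , drop = FALSE]
  dim(m) <- dim(x$positions)[2:3]
  rownames(m) <- marker_names(x)
  colnames(m) <- c("X", "Y", "Z")
  m
}

# Per-marker mean position over frames where visible; error if a marker is
# never visible.
mean_positions <- function(x) {
  nm <- marker_names(x)
  out <- matrix(NA_real_, length(nm), 3, dimnames = list(nm, c("X", "Y", "Z")))
  for (j in seq_along(nm)) {
    vis <- x$mask[, j]
    if (!any(vis)) stop("marker never visible in trial: ", nm[j])
    out[j, ] <- colMeans(x$positions[vis, j, , drop = FALSE])
  }
  out
}

#' Restrict a trajectory set to a subset of markers
#' @param x An `mts`.
#' @param names Marker labels to keep (all must exist).
#' @return An `mts` with the selected markers, order as in `names`.
#' @export
subset_markers <- function(x, names) {
  missing <- setdiff(names, marker_names(x))
  if (length(missing))
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  idx <- match(names, marker_names(x))
  x$positions <- x$positions[, idx, , drop = FALSE]
  x$mask <- x$mask[, idx, drop = FALSE]
  x
}
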