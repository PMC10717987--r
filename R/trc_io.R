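# TRC reader/writer.  TRC is the tab-separated ASCII marker-trajectory
# format common in optical motion capture: a 5-line header (PathFileType;
# metadata keys; metadata values; marker-name row; X/Y/Z component row)
# followed by one row per frame (Frame#, Time, then X/Y/Z per marker).
# Blank cells encode occluded samples.  No installed package parses TRC, so
# the dialect is implemented here.

#' Read a TRC marker-trajectory file
#'
#' @param path Path to a TRC file.  Units must be declared `mm` or `m`
#'   (metres are converted to mm).
#' @return A [marker_trajectory_set()].
#' @export
read_trc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("TRC parse error: fewer than 6 lines")
  if (!startsWith(lines[1], "PathFileType"))
    stop("TRC parse error at line 1: expected 'PathFileType' header")
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (!all(c("DataRate", "NumFrames", "NumMarkers", "Units") %in% keys))
    stop("TRC parse error at line 2: missing metadata key(s)")
  meta <- stats::setNames(as.list(vals[seq_along(keys)]), keys)
  rate <- as.numeric(meta$DataRate)
  n_fr <- as.integer(meta$NumFrames)
  n_mk <- as.integer(meta$NumMarkers)
  units <- meta$Units
  if (!units %in% c("mm", "m"))
    stop("TRC unit must be 'mm' or 'm', got '", units, "'")
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  nms <- name_row[-(1:2)]
  nms <- nms[nzchar(nms)]
  if (length(nms) != n_mk)
    stop("TRC parse error at line 4: header declares ", n_mk,
         " markers but ", length(nms), " names found")
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_fr)
    stop("TRC parse error: header declares ", n_fr, " frames but ",
         length(body), " data rows found")
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_need <- 2 + 3 * n_mk
  times <- numeric(n_fr)
  pos <- array(NA_real_, c(n_fr, n_mk, 3),
               dimnames = list(NULL, nms, c("X", "Y", "Z")))
  for (i in seq_len(n_fr)) {
    row <- cells[[i]]
    if (length(row) < ncol_need) row <- c(row, rep("", ncol_need - length(row)))
    times[i] <- as.numeric(row[2])
    v <- suppressWarnings(as.numeric(row[3:ncol_need]))
    v[!nzchar(trimws(row[3:ncol_need]))] <- NA_real_
    pos[i, , ] <- matrix(v, n_mk, 3, byrow = TRUE)
  }
  if (units == "m") pos <- pos * 1000
  marker_trajectory_set(times, pos, sample_rate = rate)
}

#' Write a TRC marker-trajectory file
#'
#' @param data A [marker_trajectory_set()]; must be non-empty with uniform
#'   frame times.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(data, path) {
  if (!inherits(data, "mts")) stop("data must be a marker trajectory set")
  if (n_frames(data) == 0 || length(marker_names(data)) == 0)
    stop("cannot write an empty trajectory set")
  nms <- marker_names(data)
  n_mk <- length(nms); n_fr <- n_frames(data)
  rate <- data$sample_rate
  hdr <- c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(format(rate), format(rate), n_fr, n_mk, "mm",
          format(rate), 1, n_fr, sep = "\t"),
    paste(c("Frame#", "Time", as.vector(rbind(nms, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), n_mk),
                           rep(seq_len(n_mk), each = 3))), collapse = "\t")
  )
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, format = "f", digits = 6))
  rows <- vapply(seq_len(n_fr), function(i) {
    flat <- as.vector(t(frame_positions(data, i)))
    paste(c(i, formatC(data$times[i], format = "f", digits = 6), fmt(flat)),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, "", rows), path)
  invisible(path)
}
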