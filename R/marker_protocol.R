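# Marker protocols: the 16-marker Plugin set and the 38-marker Redundant set
# (Plugin + 22 extras, 11 per side), marker-to-segment assignment, nominal
# local offsets, and reduction of redundant data back to the Plugin set.
#
# Marker-name dialect follows Vicon Plug-in-Gait labels for the base 16
# (LASI, RASI, LPSI, RPSI; per side THI, KNE, TIB, ANK, HEE, TOE).  Extras
# per side: IC (iliac crest), THI_A/THI_P/THI_I (anterior/posterior/inferior
# to THI), KNE_M (medial femoral epicondyle), TIB_A/TIB_P/TIB_I, ANK_M
# (medial malleolus), M5 (5th metatarsal, dorsal), T (tarsal, dorsal).
#
# Note on ANK_M: published descriptions of this redundant set list ten of
# the eleven per-side extras explicitly; the eleventh implemented here is
# the medial malleolus (the standard medial partner of KNE_M), attached to
# the shank.  It is isolated in `.nominal_offsets()` so it can be swapped.

# Nominal marker offsets, segment frame, mm.  Longitudinal placement scales
# with the owning segment's length parameter so that standing-trial scaling
# can observe every length (including foot length via the foot markers).
# sgn = +1 left, -1 right (lateral is +Y on the left, -Y on the right).
.nominal_offsets <- function(lengths, side) {
  sgn <- if (side == "L") 1 else -1
  pw <- lengths[["pelvic_width"]]
  lth <- lengths[[paste0("thigh_", side)]]
  lsh <- lengths[[paste0("shank_", side)]]
  lf <- lengths[[paste0("foot_", side)]]
  thi <- c(15, sgn * 60, -0.42 * lth)
  tib <- c(12, sgn * 48, -0.42 * lsh)
  list(
    ASI   = list("pelvis", c(70, sgn * 0.48 * pw, 30)),
    PSI   = list("pelvis", c(-95, sgn * 0.21 * pw, 45)),
    IC    = list("pelvis", c(-10, sgn * 0.56 * pw, 95)),
    THI   = list("femur", thi),
    THI_A = list("femur", thi + c(33, sgn * -15, 0)),
    THI_P = list("femur", thi + c(-37, sgn * -5, 0)),
    THI_I = list("femur", thi + c(0, sgn * -2, -45)),
    KNE   = list("femur", c(0, sgn * 55, -lth + 12)),
    KNE_M = list("femur", c(0, -sgn * 48, -lth + 12)),
    TIB   = list("shank", tib),
    TIB_A = list("shank", tib + c(30, sgn * -13, 0)),
    TIB_P = list("shank", tib + c(-37, sgn * -6, 0)),
    TIB_I = list("shank", tib + c(0, sgn * -3, -40)),
    ANK   = list("shank", c(0, sgn * 42, -lsh + 10)),
    ANK_M = list("shank", c(0, -sgn * 38, -lsh + 10)),
    HEE   = list("foot", c(-0.28 * lf, 0, -30)),
    TOE   = list("foot", c(0.62 * lf, -sgn * 10, -35)),
    M5    = list("foot", c(0.45 * lf, sgn * 48, -35)),
    T     = list("foot", c(0.20 * lf, sgn * 8, 8))
  )
}

.plugin_base <- c("ASI", "PSI", "THI", "KNE", "TIB", "ANK", "HEE", "TOE")
.extra_base <- c("IC", "THI_A", "THI_P", "THI_I", "KNE_M",
                 "TIB_A", "TIB_P", "TIB_I", "ANK_M", "M5", "T")

.make_protocol <- function(set, model) {
  base <- if (set == "plugin") .plugin_base else c(.plugin_base, .extra_base)
  rows <- list()
  for (side in c("L", "R")) {
    off <- .nominal_offsets(model$lengths, side)
    for (b in base) {
      seg <- off[[b]][[1]]
      seg <- if (seg == "pelvis") "pelvis" else paste0(seg, "_", side)
      v <- off[[b]][[2]]
      rows[[paste0(side, b)]] <- data.frame(
        name = paste0(side, b), segment = seg, side = side,
        ox = v[1], oy = v[2], oz = v[3], stringsAsFactors = FALSE)
    }
  }
  markers <- do.call(rbind, rows)
  # conventional ordering: pelvis markers first, then left leg, then right
  ord <- c("LASI", "RASI", "LPSI", "RPSI")
  if (set != "plugin") ord <- c(ord, "LIC", "RIC")
  leg <- if (set == "plugin") c("THI", "KNE", "TIB", "ANK", "HEE", "TOE")
         else c("THI", "THI_A", "THI_P", "THI_I", "KNE", "KNE_M",
                "TIB", "TIB_A", "TIB_P", "TIB_I", "ANK", "ANK_M",
                "HEE", "TOE", "M5", "T")
  ord <- c(ord, paste0("L", leg), paste0("R", leg))
  markers <- markers[match(ord, markers$name), ]
  rownames(markers) <- NULL
  structure(list(name = set, markers = markers,
                 nominal_fun = function(m) .make_protocol(set, m)$markers),
            class = "marker_protocol")
}

#' The 16-marker Plugin protocol
#'
#' Four pelvis markers (LASI, RASI, LPSI, RPSI) and, per side, THI and KNE on
#' the femur, TIB and ANK on the shank, HEE and TOE on the foot.  Nominal
#' offsets are placement defaults derived from the model's segment lengths;
#' subject-specific offsets come from calibration.
#'
#' @param model A `gait_model` supplying segment lengths for the nominal
#'   offsets (default [build_model()]).
#' @return A `marker_protocol` with 16 markers.
#' @export
plugin_marker_set <- function(model = build_model()) .make_protocol("plugin", model)

#' The 38-marker Redundant protocol
#'
#' The Plugin set plus 22 extra markers (11 per side): iliac crest (IC),
#' thigh cluster extras (THI_A/P/I), medial femoral epicondyle (KNE_M),
#' shank cluster extras (TIB_A/P/I), medial malleolus (ANK_M), 5th
#' metatarsal (M5) and dorsal tarsal (T).
#'
#' @inheritParams plugin_marker_set
#' @return A `marker_protocol` with 38 markers.
#' @export
redundant_marker_set <- function(model = build_model()) .make_protocol("redundant", model)

#' @export
print.marker_protocol <- function(x, ...) {
  cat("marker_protocol '", x$name, "': ", nrow(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Names of the 16 Plugin markers
#' @return Character vector, length 16.
#' @export
plugin_marker_names <- function() {
  c("LASI", "RASI", "LPSI", "RPSI",
    paste0("L", c("THI", "KNE", "TIB", "ANK", "HEE", "TOE")),
    paste0("R", c("THI", "KNE", "TIB", "ANK", "HEE", "TOE")))
}

.check_plugin_present <- function(nms) {
  missing <- setdiff(plugin_marker_names(), nms)
  if (length(missing))
    stop("cannot reduce to Plugin set; missing marker(s): ",
         paste(missing, collapse = ", "))
}

#' Reduce redundant-set data to the Plugin set
#'
#' Drops the 22 extra markers, keeping the 16 Plugin markers untouched
#' (positions / offsets bit-identical for retained names).  This is the
#' controlled-comparison construction: the Plugin-arm model and data are
#' derived from the Redundant arm by pure column removal.
#'
#' Methods exist for marker protocols, attachment tables (data.frames),
#' trajectory sets ([marker_trajectory_set()]) and calibrated models.
#'
#' @param x Object carrying named markers; must contain all 16 Plugin names.
#' @return Same type as `x`, restricted to the 16 Plugin markers.
#' @export
reduce_to_plugin <- function(x) UseMethod("reduce_to_plugin")

#' @export
reduce_to_plugin.marker_protocol <- function(x) {
  .check_plugin_present(x$markers$name)
  x$markers <- x$markers[x$markers$name %in% plugin_marker_names(), ]
  rownames(x$markers) <- NULL
  x$name <- "plugin"
  x$nominal_fun <- function(m) .make_protocol("plugin", m)$markers
  x
}

#' @export
reduce_to_plugin.data.frame <- function(x) {
  .check_plugin_present(x$name)
  out <- x[x$name %in% plugin_marker_names(), ]
  rownames(out) <- NULL
  out
}

#' @export
reduce_to_plugin.mts <- function(x) {
  .check_plugin_present(marker_names(x))
  keep <- marker_names(x) %in% plugin_marker_names()
  x$positions <- x$positions[, keep, , drop = FALSE]
  x$mask <- x$mask[, keep, drop = FALSE]
  x
}

#' @export
reduce_to_plugin.calibrated_model <- function(x) {
  x$attachments <- reduce_to_plugin(x$attachments)
  x$protocol_name <- "plugin"
  x
}
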